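#' Write a deletion profile to a tab-delimited table
#'
#' The table dialect is fixed by this package: a `#`-prefixed metadata
#' header (package version, sample id, reference name/length, caller
#' parameters), a `#`-prefixed column-name line, then one row per deletion:
#' `ref_name, five_prime_site, three_prime_site, raw_count, depth,
#' normalized_rate, net_rate`. Rows are sorted by `net_rate` descending,
#' ties by `(five_prime_site, three_prime_site)` ascending. Rates are
#' printed with full precision so the table round-trips losslessly through
#' [read_deletion_table()].
#'
#' @param profile A `deletion_profile`.
#' @param path Output path.
#' @param parameters Optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_deletion_table <- function(profile, path, parameters = NULL) {
  stopifnot(inherits(profile, "deletion_profile"))
  e <- copy(profile$entries)
  setorder(e, -net_rate, five, three)
  hdr <- c(
    paste0("# jumpdel deletion table v", utils::packageVersion("jumpdel")),
    paste0("# sample=", profile$sample_id),
    paste0("# reference=", profile$ref_name, " length=", profile$ref_length)
  )
  if (!is.null(parameters)) {
    hdr <- c(hdr, paste0("# params ",
                         paste(names(parameters), unlist(parameters),
                               sep = "=", collapse = " ")))
  }
  hdr <- c(hdr, paste0("# ", paste(
    c("ref_name", "five_prime_site", "three_prime_site", "raw_count",
      "depth", "normalized_rate", "net_rate"), collapse = "\t")))
  rows <- sprintf("%s\t%d\t%d\t%d\t%.17g\t%.17g\t%.17g",
                  profile$ref_name, e$five, e$three, e$count, e$depth,
                  e$normalized_rate, e$net_rate)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a deletion table written by [write_deletion_table()]
#'
#' @param path Path to a deletion table.
#' @return A `deletion_profile` (the per-position depth vector is not part
#'   of the table and is absent from the reconstructed profile).
#' @export
read_deletion_table <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  sample_id <- sub("^# sample=", "", grep("^# sample=", hdr, value = TRUE)[1])
  refline <- grep("^# reference=", hdr, value = TRUE)[1]
  ref_name <- sub("^# reference=(\\S+) length=\\d+$", "\\1", refline)
  ref_length <- as.integer(sub("^.* length=(\\d+)$", "\\1", refline))
  if (length(body)) {
    e <- fread(text = body, header = FALSE,
               col.names = c("ref_name", "five", "three", "count",
                             "depth", "normalized_rate", "net_rate"))
    e[, ref_name := NULL]
  } else {
    e <- data.table(five = integer(), three = integer(), count = integer(),
                    depth = numeric(), normalized_rate = numeric(),
                    net_rate = numeric())
  }
  deletion_profile(e, sample_id = sample_id, ref_name = ref_name,
                   ref_length = ref_length)
}
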