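#' Parse alignments from a SAM or BAM file
#'
#' Loads mapped alignment records into a `data.table`, one row per segment,
#' with clip-aware query spans derived from the CIGAR. SAM text is converted
#' through [Rsamtools::asBam()]; BAM is read directly.
#'
#' @param path SAM (`.sam`) or BAM (`.bam`) file with a header.
#' @param ref Optional `reference_sequence`; when given, records must be
#'   mapped to a reference of that name (mismatch is an error).
#' @return A `data.table` with columns `read_id`, `flag`, `ref_name`,
#'   `strand`, `ref_start`, `ref_end`, `mapq`, `cigar`, `seq` (SEQ-local,
#'   hard clips absent), `query_start`/`query_end` (original-read
#'   coordinates, hard clips counted), `read_len`, `leadH`,
#'   `is_secondary`, `is_supplementary`. Unmapped records are skipped.
#' @export
parse_alignments <- function(path, ref = NULL) {
  stopifnot(file.exists(path))
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  res <- Rsamtools::scanBam(
    bam,
    param = Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "strand", "pos", "mapq",
               "cigar", "seq"))
  )[[1]]
  keep <- !bitwAnd(res$flag, 4L)
  dt <- data.table(
    read_id   = res$qname[keep],
    flag      = res$flag[keep],
    ref_name  = as.character(res$rname[keep]),
    strand    = as.character(res$strand[keep]),
    ref_start = res$pos[keep],
    mapq      = res$mapq[keep],
    cigar     = res$cigar[keep],
    seq       = as.character(res$seq)[keep]
  )
  dt[, is_secondary := bitwAnd(flag, 256L) > 0L]
  dt[, is_supplementary := bitwAnd(flag, 2048L) > 0L]
  if (!is.null(ref) && nrow(dt) && !all(dt$ref_name == ref$name)) {
    stop("alignments mapped to '", setdiff(dt$ref_name, ref$name)[1],
         "' but reference is '", ref$name, "'")
  }
  if (nrow(dt)) {
    s <- cigar_summaries(cigar_op_table(dt$cigar))
    dt[, `:=`(ref_end = ref_start + s$ref_len - 1L,
              query_start = s$query_start,
              query_end = s$query_end,
              read_len = s$read_len,
              leadH = s$leadH)]
  } else {
    dt[, `:=`(ref_end = integer(), query_start = integer(),
              query_end = integer(), read_len = integer(),
              leadH = integer())]
  }
  dt[]
}
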