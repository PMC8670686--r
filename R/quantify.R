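#' Construct a deletion profile
#'
#' A deletion profile holds aggregated deletion counts with their
#' depth-normalized rates and (after background subtraction) net rates.
#'
#' @param entries `data.table`/data.frame with columns `five`, `three`,
#'   `count`, and optionally `depth`, `normalized_rate`, `net_rate`.
#' @param sample_id Sample label.
#' @param ref_name,ref_length Reference identity.
#' @param depth_vector Optional per-position read depth over the reference.
#' @return An object of class `deletion_profile`.
#' @export
deletion_profile <- function(entries, sample_id = "sample", ref_name = "ref",
                             ref_length = NA_integer_, depth_vector = NULL) {
  e <- as.data.table(entries)
  stopifnot(all(c("five", "three", "count") %in% names(e)))
  for (cl in c("depth", "normalized_rate", "net_rate")) {
    if (!cl %in% names(e)) e[, (cl) := NA_real_]
  }
  stopifnot(all(e$three > e$five + 1L))
  setorder(e, five, three)
  structure(list(sample_id = sample_id, ref_name = ref_name,
                 ref_length = as.integer(ref_length),
                 entries = e[], depth_vector = depth_vector),
            class = "deletion_profile")
}

#' @export
print.deletion_profile <- function(x, ...) {
  cat("deletion_profile '", x$sample_id, "' on ", x$ref_name, ": ",
      nrow(x$entries), " deletion sites, ", sum(x$entries$count),
      " deletion events\n", sep = "")
  invisible(x)
}

#' Per-position read depth from alignment footprints
#'
#' A read covers every reference position between its first and last
#' aligned position, inclusive of deleted (D-op) positions: a read spanning
#' a deletion still evidences sequencing through that locus. Each read is
#' counted once per position even when split into multiple segments.
#'
#' @param aln Alignment table from [parse_alignments()], or a list of them
#'   (segments of one sample; e.g. merged plus unmerged).
#' @param ref A `reference_sequence`.
#' @return Integer vector of length `ref$length`.
#' @export
compute_depth <- function(aln, ref) {
  if (is.list(aln) && !is.data.frame(aln)) aln <- rbindlist(aln)
  aln <- as.data.table(aln)
  aln <- aln[strand == "+" & !is_secondary & ref_name == ref$name]
  if (!nrow(aln)) return(integer(ref$length))
  spans <- aln[, .(start = pmax(1L, ref_start), end = pmin(ref$length, ref_end))]
  spans[, read_id := aln$read_id]
  ir <- IRanges::reduce(
    S4Vectors::split(IRanges::IRanges(spans$start, spans$end), spans$read_id))
  ir <- unlist(ir, use.names = FALSE)
  as.integer(IRanges::coverage(ir, width = ref$length))
}

#' Normalize deletion counts by local read depth
#'
#' Each deletion's depth is the median read depth over the five reference
#' positions starting at its 3' site (`[three, three + 4]`, clipped at the
#' reference end); `normalized_rate = count / depth`. Entries with zero
#' depth are excluded and tallied.
#'
#' @param deletions Per-read deletion records (from [detect_deletions()],
#'   its `deletions` table, or any table with `read_id`, `five`, `three`),
#'   or pre-aggregated counts with columns `five`, `three`, `count`.
#' @param depth_vector Per-position depth from [compute_depth()].
#' @param sample_id,ref_name Profile labels.
#' @return A `deletion_profile` with `normalized_rate` filled in.
#' @export
normalize_counts <- function(deletions, depth_vector, sample_id = "sample",
                             ref_name = "ref") {
  if (inherits(deletions, "deletion_calls")) deletions <- deletions$deletions
  d <- as.data.table(deletions)
  counts <- if ("count" %in% names(d)) {
    d[, .(five, three, count)]
  } else {
    d[, .(count = .N), by = .(five, three)]
  }
  L <- length(depth_vector)
  counts[, depth := vapply(three, function(p) {
    stats::median(depth_vector[p:min(p + 4L, L)])
  }, numeric(1))]
  n_zero <- sum(counts$depth <= 0)
  counts <- counts[depth > 0]
  counts[, normalized_rate := count / depth]
  prof <- deletion_profile(counts, sample_id = sample_id, ref_name = ref_name,
                           ref_length = L, depth_vector = depth_vector)
  attr(prof, "n_zero_depth") <- n_zero
  prof
}

#' Subtract a mono-adduct (background) profile from a crosslinked profile
#'
#' `net_rate = crosslinked rate - control rate` for sites present in both
#' profiles; deletions detected only in the crosslinked sample retain their
#' full rate. Entries whose net rate is not positive are removed (the
#' subtraction is a denoising step), and control-only sites never appear.
#'
#' @param crosslinked,control `deletion_profile` objects on the same
#'   reference.
#' @return A `deletion_profile` with `net_rate` filled in.
#' @export
subtract_background <- function(crosslinked, control) {
  stopifnot(inherits(crosslinked, "deletion_profile"),
            inherits(control, "deletion_profile"))
  if (!identical(crosslinked$ref_name, control$ref_name)) {
    stop("profiles are on different references: '", crosslinked$ref_name,
         "' vs '", control$ref_name, "'")
  }
  x <- copy(crosslinked$entries)
  ctl <- control$entries[, .(five, three, ctl_rate = normalized_rate)]
  x <- ctl[x, on = c("five", "three")]
  x[is.na(ctl_rate), ctl_rate := 0]
  x[, net_rate := normalized_rate - ctl_rate]
  x <- x[net_rate > 0]
  x[, ctl_rate := NULL]
  deletion_profile(x, sample_id = crosslinked$sample_id,
                   ref_name = crosslinked$ref_name,
                   ref_length = crosslinked$ref_length,
                   depth_vector = crosslinked$depth_vector)
}

#' Site-shift configuration
#'
#' The reverse transcriptase jumps the crosslink 3' to 5' and tends to land
#' short: reported 5' deletion sites sit upstream of the crosslinked
#' nucleotide. By default 5' sites are therefore shifted two nucleotides in
#' the 3' direction; 3' sites are not shifted.
#'
#' @param shift_5p Nucleotides added to each 5' site (3' direction), 0-5.
#' @param shift_3p Nucleotides subtracted from each 3' site (5' direction),
#'   0-5.
#' @return A `shift_config` list.
#' @export
shift_config <- function(shift_5p = 2L, shift_3p = 0L) {
  stopifnot(shift_5p >= 0L, shift_5p <= 5L, shift_3p >= 0L, shift_3p <= 5L)
  structure(list(shift_5p = as.integer(shift_5p),
                 shift_3p = as.integer(shift_3p)), class = "shift_config")
}

#' Shift deletion sites to compensate for the RT landing mechanism
#'
#' Each `(five, three)` becomes `(five + shift_5p, three - shift_3p)`.
#' Entries whose shifted sites cross (`three <= five + 1`) are dropped and
#' tallied; rates are unchanged. Entries colliding on the same shifted key
#' have their counts and rates summed.
#'
#' @param profile A `deletion_profile`.
#' @param cfg A [shift_config()].
#' @return A `deletion_profile`.
#' @export
shift_sites <- function(profile, cfg = shift_config()) {
  e <- copy(profile$entries)
  e[, `:=`(five = five + cfg$shift_5p, three = three - cfg$shift_3p)]
  n_crossed <- sum(e$three <= e$five + 1L)
  e <- e[three > five + 1L]
  e <- e[, .(count = sum(count), depth = depth[1],
             normalized_rate = sum(normalized_rate),
             net_rate = sum(net_rate)), by = .(five, three)]
  out <- deletion_profile(e, sample_id = profile$sample_id,
                          ref_name = profile$ref_name,
                          ref_length = profile$ref_length,
                          depth_vector = profile$depth_vector)
  attr(out, "n_crossed") <- n_crossed
  out
}

#' Select the most frequent fraction of deletions
#'
#' Keeps the `ceiling(fraction * N)` entries with the highest `net_rate`
#' (falling back to `normalized_rate` when net rates are absent); ties are
#' broken by ascending `(five, three)` for determinism.
#'
#' @param profile A `deletion_profile`.
#' @param fraction Fraction in (0, 1].
#' @return A `deletion_profile` containing the selected subset.
#' @export
select_top_fraction <- function(profile, fraction = 0.03) {
  stopifnot(fraction > 0, fraction <= 1)
  e <- copy(profile$entries)
  if (!nrow(e)) return(profile)
  key <- if (all(is.na(e$net_rate))) e$normalized_rate else e$net_rate
  e[, .rank_key := key]
  setorder(e, -.rank_key, five, three)
  e <- e[seq_len(ceiling(fraction * .N))]
  e[, .rank_key := NULL]
  deletion_profile(e, sample_id = profile$sample_id,
                   ref_name = profile$ref_name,
                   ref_length = profile$ref_length,
                   depth_vector = profile$depth_vector)
}
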