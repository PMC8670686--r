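#' Quality-trimming configuration
#'
#' @param window Sliding-window width in nucleotides. The window slides in
#'   steps of one (the stricter reading of a "first set" of low-quality
#'   nucleotides, and the behavior of the trimmer this rule mirrors).
#' @param min_mean_q Phred threshold on the window mean.
#' @param min_len Reads shorter than this after trimming are dropped.
#' @return A `trim_config` list.
#' @export
trim_config <- function(window = 5L, min_mean_q = 20, min_len = 25L) {
  stopifnot(window >= 1L, min_len >= 1L)
  structure(list(window = as.integer(window), min_mean_q = min_mean_q,
                 min_len = as.integer(min_len)), class = "trim_config")
}

# First failing window start for one quality vector; 0L when none fails.
.first_bad_window <- function(q, window, thr) {
  n <- length(q)
  if (n < window) return(0L)
  cs <- cumsum(c(0, q))
  means <- (cs[(window + 1L):(n + 1L)] - cs[1:(n - window + 1L)]) / window
  i <- which(means < thr)
  if (length(i)) i[1] else 0L
}

#' Trim one read by windowed base-call quality
#'
#' Scans 5' to 3'; at the first `window`-nucleotide stretch whose mean
#' Phred quality falls below `min_mean_q`, that stretch and everything
#' downstream are removed. Reads shorter than `min_len` after trimming are
#' dropped.
#'
#' @param sequence Character scalar read sequence.
#' @param qualities Integer vector of per-base Phred scores.
#' @param cfg A [trim_config()].
#' @return `list(sequence, qualities)` for a kept read, or `NULL` when the
#'   trimmed read is dropped.
#' @export
trim_read_quality <- function(sequence, qualities, cfg = trim_config()) {
  stopifnot(nchar(sequence) == length(qualities))
  i <- .first_bad_window(qualities, cfg$window, cfg$min_mean_q)
  keep <- if (i > 0L) i - 1L else length(qualities)
  if (keep < cfg$min_len) return(NULL)
  list(sequence = substr(sequence, 1L, keep), qualities = qualities[seq_len(keep)])
}

#' Trim a read set by windowed base-call quality
#'
#' Vector version of [trim_read_quality()].
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param cfg A [trim_config()].
#' @return A list with `reads` (the trimmed, kept reads) and `n_dropped`.
#' @export
trim_reads <- function(reads, cfg = trim_config()) {
  if (!length(reads)) return(list(reads = reads, n_dropped = 0L))
  quals <- read_qualities(reads)
  keep_len <- vapply(quals, function(q) {
    i <- .first_bad_window(q, cfg$window, cfg$min_mean_q)
    if (i > 0L) i - 1L else length(q)
  }, integer(1))
  keep <- keep_len >= cfg$min_len
  out <- IRanges::narrow(reads[keep], start = 1L, end = keep_len[keep])
  list(reads = out, n_dropped = sum(!keep))
}

#' Pair-merging configuration
#'
#' Overlap scoring follows the conventions of standard overlap mergers:
#' the candidate overlap minimizing mismatch density wins, and merged
#' qualities are capped at 41.
#'
#' @param min_overlap Minimum overlap length considered.
#' @param max_mismatch_density Maximum fraction of mismatching bases in the
#'   accepted overlap.
#' @return A `merge_config` list.
#' @export
merge_config <- function(min_overlap = 10L, max_mismatch_density = 0.25) {
  stopifnot(max_mismatch_density >= 0, max_mismatch_density <= 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_density = max_mismatch_density),
            class = "merge_config")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Merge one read pair by 3' overlap
#'
#' The mate is reverse-complemented, the overlap between the 5' read's 3'
#' end and the mate's 5' end minimizing mismatch density (ties to the
#' longer overlap) is found, and if its density is at most
#' `max_mismatch_density` a single merged read is emitted. In the overlap
#' the base with the higher quality is kept and its quality raised to
#' `min(q1 + q2, 41)`. Pairs that do not overlap are returned unmerged, not
#' removed.
#'
#' @param r1_seq,r1_qual 5' read sequence and integer Phred qualities.
#' @param r2_seq,r2_qual Mate sequence/qualities (as sequenced; reverse
#'   complementing is performed here).
#' @param cfg A [merge_config()].
#' @return `list(merged = TRUE, sequence, qualities)` or
#'   `list(merged = FALSE)`.
#' @export
merge_read_pair <- function(r1_seq, r1_qual, r2_seq, r2_qual,
                            cfg = merge_config()) {
  v1 <- strsplit(r1_seq, "")[[1]]
  v2 <- strsplit(.revcomp(r2_seq), "")[[1]]
  q2 <- rev(r2_qual)
  l1 <- length(v1)
  l2 <- length(v2)
  best_o <- 0L
  best_d <- Inf
  for (o in seq(cfg$min_overlap, min(l1, l2))) {
    mm <- sum(v1[(l1 - o + 1L):l1] != v2[1:o])
    d <- mm / o
    if (d < best_d || (d == best_d && o > best_o)) {
      best_d <- d
      best_o <- o
    }
  }
  if (!is.finite(best_d) || best_d > cfg$max_mismatch_density) {
    return(list(merged = FALSE))
  }
  o <- best_o
  i1 <- (l1 - o + 1L):l1
  i2 <- 1:o
  take1 <- r1_qual[i1] >= q2[i2]
  ov_base <- ifelse(take1, v1[i1], v2[i2])
  ov_q <- pmin(r1_qual[i1] + q2[i2], 41L)
  list(
    merged = TRUE,
    sequence = paste(c(v1[seq_len(l1 - o)], ov_base,
                       if (o < l2) v2[(o + 1L):l2]), collapse = ""),
    qualities = c(r1_qual[seq_len(l1 - o)], ov_q,
                  if (o < l2) q2[(o + 1L):l2])
  )
}

#' Merge a trimmed read-pair set
#'
#' @param r1,r2 [Biostrings::QualityScaledDNAStringSet] mates, matched by
#'   position (names are matched on shared ids when both are named).
#' @param cfg A [merge_config()].
#' @return List with `merged` (QualityScaledDNAStringSet),
#'   `unmerged_r1`, `unmerged_r2`, and counts.
#' @export
merge_reads <- function(r1, r2, cfg = merge_config()) {
  if (!is.null(names(r1)) && !is.null(names(r2))) {
    shared <- intersect(names(r1), names(r2))
    r1 <- r1[shared]
    r2 <- r2[shared]
  }
  stopifnot(length(r1) == length(r2))
  q1 <- read_qualities(r1)
  q2 <- read_qualities(r2)
  s1 <- as.character(r1)
  s2 <- as.character(r2)
  res <- lapply(seq_along(r1), function(i) {
    merge_read_pair(s1[i], q1[[i]], s2[i], q2[[i]], cfg)
  })
  ok <- vapply(res, `[[`, logical(1), "merged")
  merged <- if (any(ok)) {
    make_reads(vapply(res[ok], `[[`, character(1), "sequence"),
               lapply(res[ok], `[[`, "qualities"),
               ids = names(r1)[ok])
  } else {
    make_reads(character(0), list(), ids = character(0))
  }
  list(merged = merged, unmerged_r1 = r1[!ok], unmerged_r2 = r2[!ok],
       n_merged = sum(ok), n_unmerged = sum(!ok))
}
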