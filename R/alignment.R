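#' Aligner scoring configuration
#'
#' Defaults are the scoring parameters tuned for crosslink-jump reads:
#' gap-open penalty lowered to 2 to promote alignment across long
#' deletions, mismatch penalty lowered to 2 to tolerate the high
#' reverse-transcriptase mutation rate, seed shortened to 10 and output
#' score threshold lowered to 15 so that short sequence flanking a deletion
#' still anchors an alignment.
#'
#' @param gap_open Gap open penalty (`-O`).
#' @param mismatch Mismatch penalty (`-B`).
#' @param min_seed Minimum seed length (`-k`).
#' @param score_threshold Minimum output alignment score (`-T`).
#' @param executable Aligner executable (BWA).
#' @param extra_args Additional arguments appended after the scoring flags.
#' @return An `aligner_config` list.
#' @seealso [default_aligner_config()] for the aligner's own stock scoring.
#' @export
aligner_config <- function(gap_open = 2L, mismatch = 2L, min_seed = 10L,
                           score_threshold = 15L, executable = "bwa",
                           extra_args = character()) {
  stopifnot(gap_open >= 0, mismatch >= 0, min_seed >= 1, score_threshold >= 0)
  extra_args <- as.character(unlist(extra_args))
  structure(list(gap_open = as.integer(gap_open),
                 mismatch = as.integer(mismatch),
                 min_seed = as.integer(min_seed),
                 score_threshold = as.integer(score_threshold),
                 executable = executable, extra_args = extra_args),
            class = "aligner_config")
}

#' Stock aligner scoring configuration
#'
#' The aligner's unmodified defaults (`-O 6 -B 4 -k 19 -T 30`), used as the
#' pre-optimization baseline in benchmarks.
#'
#' @inheritParams aligner_config
#' @return An `aligner_config`.
#' @export
default_aligner_config <- function(executable = "bwa",
                                   extra_args = character()) {
  aligner_config(gap_open = 6L, mismatch = 4L, min_seed = 19L,
                 score_threshold = 30L, executable = executable,
                 extra_args = extra_args)
}

#' Build the aligner argument list
#'
#' Pure and deterministic; testable without the binary.
#'
#' @param cfg An [aligner_config()].
#' @param reference_path Indexed (or indexable) reference FASTA.
#' @param reads_path FASTQ of reads to align.
#' @return Character vector of arguments for the `bwa` executable.
#' @export
build_aligner_invocation <- function(cfg, reference_path, reads_path) {
  c("mem",
    "-O", cfg$gap_open, "-B", cfg$mismatch,
    "-k", cfg$min_seed, "-T", cfg$score_threshold,
    cfg$extra_args, reference_path, reads_path)
}

.check_aligner <- function(cfg) {
  exe <- Sys.which(cfg$executable)
  if (!nzchar(exe)) {
    stop("aligner executable '", cfg$executable, "' not found on PATH; ",
         "install bwa or supply pre-computed SAM alignments instead")
  }
  exe
}

# Build the BWA index next to the FASTA once; cached by file presence.
ensure_reference_index <- function(reference_path, cfg = aligner_config()) {
  exe <- .check_aligner(cfg)
  if (!file.exists(paste0(reference_path, ".bwt"))) {
    out <- suppressWarnings(
      system2(exe, c("index", reference_path), stdout = TRUE, stderr = TRUE))
    if (!file.exists(paste0(reference_path, ".bwt"))) {
      stop("bwa index failed:\n", paste(out, collapse = "\n"))
    }
  }
  invisible(reference_path)
}

#' Align one FASTQ to a reference with BWA-MEM
#'
#' @param cfg An [aligner_config()].
#' @param reference_path Reference FASTA (indexed on first use; the index is
#'   cached beside the file).
#' @param reads_path Single-end FASTQ.
#' @param out_sam Output SAM path; defaults to a temp file.
#' @return Path to the SAM file.
#' @export
align_fastq <- function(cfg, reference_path, reads_path,
                        out_sam = tempfile(fileext = ".sam")) {
  exe <- .check_aligner(cfg)
  ensure_reference_index(reference_path, cfg)
  args <- build_aligner_invocation(cfg, reference_path, reads_path)
  err <- tempfile()
  status <- system2(exe, args, stdout = out_sam, stderr = err)
  if (!identical(status, 0L)) {
    stop("bwa mem exited with status ", status, ":\n",
         paste(readLines(err, warn = FALSE), collapse = "\n"))
  }
  out_sam
}

#' Align merged and unmerged read sets separately
#'
#' Merged and unmergeable reads are aligned in separate invocations (their
#' deletion calls are combined downstream, with duplicates removed).
#'
#' @param cfg An [aligner_config()].
#' @param reference_path Reference FASTA.
#' @param merged_fastq FASTQ of merged reads (may be `NULL`).
#' @param unmerged_fastqs Character vector of FASTQs of unmerged reads
#'   (mates aligned single-end; may be empty).
#' @return List with `sam_merged` and `sam_unmerged` (vectors of SAM paths;
#'   `NULL`/empty where no input was given).
#' @export
align_reads <- function(cfg, reference_path, merged_fastq = NULL,
                        unmerged_fastqs = character()) {
  sam_merged <- if (!is.null(merged_fastq)) {
    align_fastq(cfg, reference_path, merged_fastq)
  }
  sam_unmerged <- vapply(unmerged_fastqs, function(fq) {
    align_fastq(cfg, reference_path, fq)
  }, character(1))
  list(sam_merged = sam_merged, sam_unmerged = unname(sam_unmerged))
}
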