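#' Full pipeline configuration
#'
#' Bundles every stage configuration with the RNG seed; defaults everywhere
#' are the tuned pipeline defaults. Serializable to a single JSON file so a
#' run's provenance can be recorded and replayed.
#'
#' @param trim A [trim_config()].
#' @param merge A [merge_config()].
#' @param aligner An [aligner_config()].
#' @param detect A [detect_config()].
#' @param shift A [shift_config()].
#' @param seed Integer RNG seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trim = trim_config(), merge = merge_config(),
                            aligner = aligner_config(),
                            detect = detect_config(), shift = shift_config(),
                            seed = 1L) {
  structure(list(trim = trim, merge = merge, aligner = aligner,
                 detect = detect, shift = shift, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration
#'
#' @param cfg A [pipeline_config()].
#' @param path JSON file path.
#' @return `write_pipeline_config`: `path` invisibly;
#'   `read_pipeline_config`: a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(lapply(unclass(cfg), unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    trim = do.call(trim_config, x$trim),
    merge = do.call(merge_config, x$merge),
    aligner = do.call(aligner_config, x$aligner),
    detect = do.call(detect_config, x$detect),
    shift = do.call(shift_config, x$shift),
    seed = x$seed
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# preprocess + align + detect + normalize for one sample
process_sample <- function(fastqs, ref, reference_path, cfg, sample_id,
                           verbose = TRUE) {
  say <- function(...) if (verbose) message("[", sample_id, "] ", ...)
  paired <- length(fastqs) == 2L
  trimmed <- .stage("preprocess", {
    r1 <- trim_reads(parse_reads(fastqs[1]), cfg$trim)
    r2 <- if (paired) trim_reads(parse_reads(fastqs[2]), cfg$trim)
    say("trimmed: ", length(r1$reads), " R1 kept (", r1$n_dropped,
        " dropped)", if (paired) paste0(", ", length(r2$reads), " R2 kept"))
    list(r1 = r1$reads, r2 = if (paired) r2$reads)
  })
  wd <- tempfile(paste0("jumpdel_", sample_id, "_"))
  dir.create(wd)
  fq_sets <- .stage("merge", {
    if (paired) {
      m <- merge_reads(trimmed$r1, trimmed$r2, cfg$merge)
      say("merged ", m$n_merged, " pairs; ", m$n_unmerged, " unmerged")
      sets <- list(merged = m$merged, unmerged_r1 = m$unmerged_r1,
                   unmerged_r2 = m$unmerged_r2)
    } else {
      sets <- list(single = trimmed$r1)
    }
    sets <- Filter(length, sets)
    paths <- character(0)
    for (nm in names(sets)) {
      p <- file.path(wd, paste0(nm, ".fastq"))
      write_reads(sets[[nm]], p)
      paths[nm] <- p
    }
    paths
  })
  sams <- .stage("align", {
    vapply(fq_sets, function(fq) align_fastq(cfg$aligner, reference_path, fq),
           character(1))
  })
  alns <- .stage("parse alignments", lapply(sams, parse_alignments, ref = ref))
  calls <- .stage("detect", detect_deletions(alns, ref, cfg$detect))
  say("deletions: ", nrow(calls$deletions))
  depth <- .stage("depth", compute_depth(alns, ref))
  profile <- .stage("normalize",
                    normalize_counts(calls, depth, sample_id = sample_id,
                                     ref_name = ref$name))
  list(profile = profile, calls = calls, alignments = alns, sams = sams)
}

#' Run the full crosslink-deletion pipeline
#'
#' Executes preprocess (quality trim, pair merge), alignment, deletion
#' detection and depth normalization for the crosslinked and control
#' samples, subtracts the control rates, applies the RT-landing site shift,
#' and writes the final deletion table. Identical configuration and inputs
#' give identical output.
#'
#' @param xlink_fastqs Character vector of one (single-end) or two (paired)
#'   FASTQ paths for the crosslinked sample.
#' @param control_fastqs FASTQ paths for the mono-/no-adduct control, same
#'   shape; `NULL` skips background subtraction (net rate = normalized
#'   rate).
#' @param reference_path Reference FASTA path.
#' @param out_table Output deletion-table path, or `NULL` to skip writing.
#' @param cfg A [pipeline_config()].
#' @param target,cassette_5p,cassette_3p Passed to [parse_reference()].
#' @param verbose Emit per-stage count messages.
#' @return List with the final `profile` (a `deletion_profile`), the
#'   per-sample results (`xlink`, `control`), and `out_table`.
#' @export
run_pipeline <- function(xlink_fastqs, control_fastqs, reference_path,
                         out_table = NULL, cfg = pipeline_config(),
                         target = NULL, cassette_5p = NULL,
                         cassette_3p = NULL, verbose = TRUE) {
  .stage("input validation", {
    missing <- c(xlink_fastqs, control_fastqs, reference_path)
    missing <- missing[!file.exists(missing)]
    if (length(missing)) stop("input file not found: ", missing[1])
  })
  set.seed(cfg$seed)
  ref <- .stage("reference", parse_reference(reference_path, target = target,
                                             cassette_5p = cassette_5p,
                                             cassette_3p = cassette_3p))
  xl <- process_sample(xlink_fastqs, ref, reference_path, cfg, "xlink",
                       verbose)
  ctl <- if (!is.null(control_fastqs)) {
    process_sample(control_fastqs, ref, reference_path, cfg, "control",
                   verbose)
  }
  prof <- .stage("subtract", {
    if (is.null(ctl)) {
      p <- xl$profile
      p$entries[, net_rate := normalized_rate]
      p
    } else {
      subtract_background(xl$profile, ctl$profile)
    }
  })
  prof <- .stage("shift", shift_sites(prof, cfg$shift))
  if (!is.null(out_table)) {
    .stage("write", write_deletion_table(prof, out_table, parameters = list(
      shift_5p = cfg$shift$shift_5p, shift_3p = cfg$shift$shift_3p,
      min_del = cfg$detect$min_deletion_length,
      max_ins = cfg$detect$max_insertion_length,
      O = cfg$aligner$gap_open, B = cfg$aligner$mismatch,
      k = cfg$aligner$min_seed, T = cfg$aligner$score_threshold)))
  }
  list(profile = prof, xlink = xl, control = ctl, out_table = out_table)
}

# score a stage; ambiguity-removal stages are scored over the truth reads
# whose encoded deletion is itself unambiguous
.score_stage <- function(deletions, truth, restrict_to_unambiguous) {
  if (inherits(deletions, "deletion_calls")) deletions <- deletions$deletions
  if (restrict_to_unambiguous) {
    truth <- truth[ambiguous == FALSE]
    deletions <- deletions[read_id %in% truth$read_id]
  }
  score_dataset(deletions, truth[, .(read_id, encoded_five, encoded_three)])
}

#' Run one synthetic benchmark configuration
#'
#' Simulates a read set, aligns it, detects deletions under the given
#' toggles, and scores accuracy against the encoded truth. When
#' `detect$remove_ambiguous` is on, percentages are computed over the truth
#' reads whose encoded deletion is unambiguous.
#'
#' @param mode Simulation mode (see [sim_config()]).
#' @param n_reads Number of synthetic reads.
#' @param seed RNG seed.
#' @param ref A `reference_sequence` (default: the bundled synthetic
#'   benchmark reference).
#' @param aligner An [aligner_config()].
#' @param detect A [detect_config()].
#' @param model A [mutation_model()].
#' @return List with `report` (an `accuracy_report`), `detection_fraction`
#'   (fraction of all reads with at least one qualifying deletion
#'   detected), `calls`, and `truth`.
#' @export
run_benchmark <- function(mode = "deletion", n_reads = 10000L, seed = 1L,
                          ref = benchmark_reference(),
                          aligner = aligner_config(),
                          detect = detect_config(),
                          model = mutation_model()) {
  wd <- tempfile("bench")
  dir.create(wd)
  ref_fa <- file.path(wd, "ref.fa")
  write_reference(ref, ref_fa)
  sim <- generate_dataset(ref, sim_config(mode = mode, n_reads = n_reads),
                          model, seed = seed,
                          out_prefix = file.path(wd, "sim"))
  sam <- align_fastq(aligner, ref_fa, sim$fastq)
  calls <- detect_deletions(sam, ref, detect)
  report <- .score_stage(calls, sim$truth, detect$remove_ambiguous)
  det_frac <- length(unique(calls$deletions$read_id)) / nrow(sim$truth)
  list(report = report, detection_fraction = det_frac, calls = calls,
       truth = sim$truth)
}

#' Run the four-stage alignment-optimization ladder
#'
#' Reproduces the benchmark ladder on one synthetic read set: (1) stock
#' aligner scoring, no post-processing; (2) tuned scoring parameters;
#' (3) plus ambiguous-deletion removal; (4) plus exact edge matching.
#' The read set is simulated once and aligned twice (stock and tuned
#' scoring); stages 2-4 share the tuned alignment. Stages with ambiguity
#' removal are scored over unambiguously encoded truth reads.
#'
#' @inheritParams run_benchmark
#' @param verbose Emit stage progress messages.
#' @return List with `stages` (a `data.table`: stage, exact/close/
#'   incorrect/undetected percentages, denominator) and
#'   `detection_fraction_default` (fraction of reads with any qualifying
#'   deletion under stage-1 settings).
#' @export
run_benchmark_ladder <- function(mode = "deletion", n_reads = 10000L,
                                 seed = 1L, ref = benchmark_reference(),
                                 model = mutation_model(), verbose = TRUE) {
  say <- function(...) if (verbose) message("[ladder] ", ...)
  wd <- tempfile("ladder")
  dir.create(wd)
  ref_fa <- file.path(wd, "ref.fa")
  write_reference(ref, ref_fa)
  say("simulating ", n_reads, " ", mode, " reads")
  sim <- generate_dataset(ref, sim_config(mode = mode, n_reads = n_reads),
                          model, seed = seed,
                          out_prefix = file.path(wd, "sim"))
  say("aligning (stock and tuned scoring)")
  sam_def <- align_fastq(default_aligner_config(), ref_fa, sim$fastq)
  sam_opt <- align_fastq(aligner_config(), ref_fa, sim$fastq)
  aln_def <- parse_alignments(sam_def, ref)
  aln_opt <- parse_alignments(sam_opt, ref)
  base_cfg <- detect_config(remove_ambiguous = FALSE, edge_matching = FALSE)
  col_def <- collect_deletion_candidates(aln_def, ref, base_cfg)
  col_opt <- collect_deletion_candidates(aln_opt, ref, base_cfg)
  stage_defs <- list(
    list(name = "default_params", col = col_def, ambig = FALSE, edge = FALSE),
    list(name = "optimized_params", col = col_opt, ambig = FALSE, edge = FALSE),
    list(name = "ambiguity_removed", col = col_opt, ambig = TRUE, edge = FALSE),
    list(name = "edge_matched", col = col_opt, ambig = TRUE, edge = TRUE)
  )
  rows <- list()
  det_frac_default <- NA_real_
  for (sd in stage_defs) {
    cfg <- detect_config(remove_ambiguous = sd$ambig, edge_matching = sd$edge)
    fin <- finalize_deletions(sd$col, ref, cfg)
    dels <- unique(fin$deletions, by = c("read_id", "five", "three"))
    rep <- .score_stage(dels, sim$truth, sd$ambig)
    if (sd$name == "default_params") {
      det_frac_default <- length(unique(dels$read_id)) / nrow(sim$truth)
    }
    say(sd$name, ": exact ", round(rep$percentages[["exact"]], 1), "%")
    rows[[sd$name]] <- data.table(
      stage = sd$name,
      exact = rep$percentages[["exact"]],
      close = rep$percentages[["close"]],
      incorrect = rep$percentages[["incorrect"]],
      undetected = rep$percentages[["undetected"]],
      n_truth = rep$n_reads
    )
  }
  list(stages = rbindlist(rows),
       detection_fraction_default = det_frac_default)
}
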