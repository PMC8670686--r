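.BASES <- c("A", "C", "G", "T")

#' Reverse-transcriptase mutation model
#'
#' Synthetic reads are mutated at single nucleotides at an overall rate of
#' 3.75% per nucleotide; of these mutation events, 71% are single-nucleotide
#' changes, 26% are single-nucleotide deletions and 3% are single-nucleotide
#' insertions — the error profile of the engineered crosslink-traversing
#' reverse transcriptase that the benchmark reads emulate.
#'
#' @param per_nt_rate Per-nucleotide mutation probability.
#' @param p_mismatch,p_del1,p_ins1 Category proportions; must sum to 1.
#' @return A `mutation_model` list.
#' @export
mutation_model <- function(per_nt_rate = 0.0375, p_mismatch = 0.71,
                           p_del1 = 0.26, p_ins1 = 0.03) {
  stopifnot(per_nt_rate >= 0, per_nt_rate <= 1,
            abs(p_mismatch + p_del1 + p_ins1 - 1) < 1e-9)
  structure(list(per_nt_rate = per_nt_rate, p_mismatch = p_mismatch,
                 p_del1 = p_del1, p_ins1 = p_ins1),
            class = "mutation_model")
}

#' Default junction-insertion length distribution
#'
#' A truncated geometric distribution (ratio 0.5) on lengths 1-9, matching
#' the qualitative decay of insertion lengths seen at crosslink junctions
#' in experimental reads. The empirical distribution is not tabulated
#' anywhere, so this default is a declared substitute, configurable via
#' [sim_config()].
#'
#' @return Named numeric vector of probabilities for lengths 1..9.
#' @export
default_insertion_distribution <- function() {
  w <- 0.5^(1:9)
  stats::setNames(w / sum(w), 1:9)
}

#' Simulation configuration
#'
#' @param mode `"deletion"` (one random deletion per read),
#'   `"deletion_insertion"` (the deletion also carries a random-nucleotide
#'   junction insertion), or `"increasing_insertion"` (a block of reads per
#'   insertion length).
#' @param n_reads Number of reads (`deletion`/`deletion_insertion` modes).
#' @param min_encoded_del Minimum encoded deletion length.
#' @param insertion_length_distribution Probabilities over insertion
#'   lengths 1..9 (`deletion_insertion` mode).
#' @param insertion_lengths Insertion lengths (`increasing_insertion` mode).
#' @param reads_per_length Reads per insertion length (`increasing` mode).
#' @param read_quality Constant Phred score written to the FASTQ. The
#'   default (38) makes quality trimming a no-op, so the benchmark isolates
#'   the aligner and detector.
#' @return A `sim_config` list.
#' @export
sim_config <- function(mode = c("deletion", "deletion_insertion",
                                "increasing_insertion"),
                       n_reads = 1000000L, min_encoded_del = 10L,
                       insertion_length_distribution = default_insertion_distribution(),
                       insertion_lengths = 0:30,
                       reads_per_length = 100000L,
                       read_quality = 38L) {
  mode <- match.arg(mode)
  stopifnot(n_reads >= 1L,
            abs(sum(insertion_length_distribution) - 1) < 1e-9)
  structure(list(mode = mode, n_reads = as.integer(n_reads),
                 min_encoded_del = as.integer(min_encoded_del),
                 insertion_length_distribution = insertion_length_distribution,
                 insertion_lengths = as.integer(insertion_lengths),
                 reads_per_length = as.integer(reads_per_length),
                 read_quality = as.integer(read_quality)),
            class = "sim_config")
}

# All (five, three) pairs with both sites outside the cassettes and a
# deleted block of at least min_encoded_del nucleotides.
legal_deletion_pairs <- function(ref, min_encoded_del = 10L) {
  allowed <- setdiff(seq_len(ref$length),
                     c(.iv_seq(ref$cassette_5p), .iv_seq(ref$cassette_3p)))
  pairs <- CJ(five = allowed, three = allowed)
  pairs <- pairs[three - five - 1L >= min_encoded_del]
  if (!nrow(pairs)) stop("no legal deletion placement for this reference")
  pairs
}

.iv_seq <- function(iv) if (is.null(iv)) integer(0) else iv[1]:iv[2]

#' Mutate reads under the RT error model
#'
#' Each position independently mutates with probability `per_nt_rate`; a
#' mutation is a mismatch (replaced by a uniformly chosen different base),
#' a single-nucleotide deletion, or a single-nucleotide insertion (one
#' uniform random base inserted after the position), with the model's
#' category probabilities.
#'
#' @param sequences Character vector of reads.
#' @param model A [mutation_model()].
#' @param detail If `TRUE`, also return the event log.
#' @return Mutated character vector; with `detail = TRUE`, a list
#'   `(sequences, events)` where `events` is a `data.table` with `read`,
#'   `pos`, `category` (`mismatch`/`deletion`/`insertion`).
#' @export
mutate_reads <- function(sequences, model = mutation_model(), detail = FALSE) {
  n <- length(sequences)
  lens <- nchar(sequences)
  k <- stats::rbinom(n, lens, model$per_nt_rate)
  tot <- sum(k)
  if (tot == 0L) {
    if (detail) {
      return(list(sequences = sequences,
                  events = data.table(read = integer(), pos = integer(),
                                      category = character())))
    }
    return(sequences)
  }
  read_idx <- rep.int(seq_len(n), k)
  cats <- sample.int(3L, tot, replace = TRUE,
                     prob = c(model$p_mismatch, model$p_del1, model$p_ins1))
  mm_shift <- sample.int(3L, tot, replace = TRUE)
  ins_base <- sample(.BASES, tot, replace = TRUE)
  pos <- integer(tot)
  off <- c(0L, cumsum(k))
  for (i in which(k > 0L)) {
    pos[(off[i] + 1L):off[i + 1L]] <- sample.int(lens[i], k[i])
  }
  out <- sequences
  sp <- strsplit(sequences[k > 0L], "", fixed = TRUE)
  ii <- 0L
  for (i in which(k > 0L)) {
    ii <- ii + 1L
    v <- sp[[ii]]
    ev <- (off[i] + 1L):off[i + 1L]
    p <- pos[ev]
    ct <- cats[ev]
    mm <- p[ct == 1L]
    if (length(mm)) {
      bi <- match(v[mm], .BASES)
      repl <- .BASES[((bi - 1L + mm_shift[ev][ct == 1L]) %% 4L) + 1L]
      repl[is.na(bi)] <- "N"  # non-ACGT stays N
      v[mm] <- repl
    }
    pd <- p[ct == 2L]
    pi <- p[ct == 3L]
    if (length(pd) || length(pi)) {
      keep <- rep(TRUE, lens[i])
      keep[pd] <- FALSE
      chr <- c(v[keep], ins_base[ev][ct == 3L])
      o <- order(c(seq_len(lens[i])[keep], pi + 0.5))
      out[i] <- paste(chr[o], collapse = "")
    } else {
      out[i] <- paste(v, collapse = "")
    }
  }
  if (detail) {
    list(sequences = out,
         events = data.table(read = read_idx, pos = pos,
                             category = c("mismatch", "deletion",
                                          "insertion")[cats]))
  } else {
    out
  }
}

#' @rdname mutate_reads
#' @param sequence A single read sequence.
#' @export
mutate_read <- function(sequence, model = mutation_model()) {
  mutate_reads(sequence, model)[1]
}

# Core generator: encoded deletions (and junction insertions) on the full
# reference, then RT-model mutation.
generate_reads <- function(ref, cfg = sim_config(), model = mutation_model()) {
  pairs <- legal_deletion_pairs(ref, cfg$min_encoded_del)
  n <- if (cfg$mode == "increasing_insertion") {
    length(cfg$insertion_lengths) * cfg$reads_per_length
  } else {
    cfg$n_reads
  }
  sel <- pairs[sample.int(nrow(pairs), n, replace = TRUE)]
  ins_len <- switch(
    cfg$mode,
    deletion = integer(n),
    deletion_insertion = {
      d <- cfg$insertion_length_distribution
      as.integer(names(d))[sample.int(length(d), n, replace = TRUE, prob = d)]
    },
    increasing_insertion = rep(cfg$insertion_lengths,
                               each = cfg$reads_per_length)
  )
  ins_str <- rep("", n)
  with_ins <- which(ins_len > 0L)
  if (length(with_ins)) {
    bases <- sample(.BASES, sum(ins_len), replace = TRUE)
    grp <- rep.int(seq_along(with_ins), ins_len[with_ins])
    ins_str[with_ins] <- vapply(split(bases, grp), paste, character(1),
                                collapse = "")
  }
  seqs <- paste0(substring(ref$sequence, 1L, sel$five), ins_str,
                 substring(ref$sequence, sel$three, ref$length))
  if (model$per_nt_rate > 0) seqs <- mutate_reads(seqs, model)
  ids <- sprintf("sim%07d", seq_len(n))
  truth <- data.table(
    read_id = ids,
    encoded_five = sel$five,
    encoded_three = sel$three,
    encoded_insertion_length = ins_len,
    ambiguous = is_ambiguous_deletion(sel$five, sel$three, ref)
  )
  list(sequences = seqs, ids = ids, truth = truth)
}

#' Generate a single synthetic deletion read
#'
#' @param ref A `reference_sequence` with declared cassette intervals.
#' @param cfg A [sim_config()].
#' @param model A [mutation_model()].
#' @return `list(sequence, truth)` where `truth` is a one-row `data.table`
#'   of the encoded sites.
#' @export
generate_deletion_read <- function(ref, cfg = sim_config(n_reads = 1L),
                                   model = mutation_model()) {
  cfg$n_reads <- 1L
  g <- generate_reads(ref, cfg, model)
  list(sequence = g$sequences[1], truth = g$truth[1])
}

#' Generate a synthetic benchmark dataset
#'
#' Writes single-end FASTQ reads (full-length amplicon reads covering the
#' whole reference, minus one encoded deletion each) and a tab-delimited
#' truth table with one row per read. Encoded sites are drawn uniformly
#' over placements outside the structure cassettes; the truth table flags
#' encodings whose placement is ambiguous (slide test). Fully reproducible
#' from `seed`.
#'
#' @param ref A `reference_sequence`.
#' @param cfg A [sim_config()].
#' @param model A [mutation_model()].
#' @param seed Integer RNG seed.
#' @param out_prefix Output path prefix; writes `<prefix>.fastq` and
#'   `<prefix>.truth.tsv`.
#' @return Invisibly, `list(fastq, truth_path, truth)`.
#' @export
generate_dataset <- function(ref, cfg = sim_config(), model = mutation_model(),
                             seed = 1L, out_prefix = tempfile("sim")) {
  set.seed(seed)
  g <- generate_reads(ref, cfg, model)
  fastq <- paste0(out_prefix, ".fastq")
  qline <- strrep(rawToChar(as.raw(cfg$read_quality + 33L)),
                  nchar(g$sequences))
  writeLines(paste0("@", g$ids, "\n", g$sequences, "\n+\n", qline),
             fastq, sep = "\n")
  truth_path <- paste0(out_prefix, ".truth.tsv")
  fwrite(g$truth, truth_path, sep = "\t")
  invisible(list(fastq = fastq, truth_path = truth_path, truth = g$truth))
}

#' The bundled synthetic benchmark reference
#'
#' A fixed 325-nt synthetic stand-in for a catalytic-domain-sized RNA with
#' flanking structure cassettes (5' positions 1-14, 3' positions 283-325).
#' It is a seeded random sequence, not a natural RNA; benchmarks accept any
#' user reference via [parse_reference()].
#'
#' @return A `reference_sequence`.
#' @export
benchmark_reference <- function() {
  parse_reference(system.file("extdata", "synthetic_rnasep_like.fa",
                              package = "jumpdel", mustWork = TRUE),
                  cassette_5p = c(1L, 14L), cassette_3p = c(283L, 325L))
}
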