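make_ref <- function(n = 400L, seed = 1L) {
  set.seed(seed)
  reference_sequence(random_seq(n), name = "ref")
}

test_that("CIGAR deletion extraction applies the length rule and insertion adjacency", {
  ref <- make_ref()
  seg <- function(cigar, seq) {
    parse_alignments(write_sam_fixture(list(sam_record("r", 1L, cigar, seq)),
                                       ref_len = ref$length), ref)
  }
  # 8M12D8M at POS 1: deletion between 8 and 21
  d <- extract_deletions_from_cigar(
    seg("8M12D8M", paste0(substr(ref$sequence, 1, 8),
                          substr(ref$sequence, 21, 28))), ref)
  expect_equal(d[, c(five, three, deleted_length, insertion_length)],
               c(8L, 21L, 12L, 0L))

  # 5-nt deletion is below the length threshold
  d5 <- extract_deletions_from_cigar(
    seg("8M5D15M", paste0(substr(ref$sequence, 1, 8),
                          substr(ref$sequence, 14, 28))), ref)
  expect_equal(nrow(d5), 0L)

  # insertion adjacent to the deletion joins the junction record
  di <- extract_deletions_from_cigar(
    seg("8M3I12D8M", paste0(substr(ref$sequence, 1, 8), "AAA",
                            substr(ref$sequence, 21, 28))), ref)
  expect_equal(di[, c(five, three, insertion_length)], c(8L, 21L, 3L))

  # two qualifying deletions in one read are both reported
  d2 <- extract_deletions_from_cigar(
    seg("10M10D10M10D10M",
        paste0(substr(ref$sequence, 1, 10), substr(ref$sequence, 21, 30),
               substr(ref$sequence, 41, 50))), ref)
  expect_equal(nrow(d2), 2L)
  expect_equal(d2$five, c(10L, 30L))

  # walking past the reference end is an error
  expect_error(
    extract_deletions_from_cigar(
      seg("8M390D8M", random_seq(16)), ref),
    "past the reference end")
})

test_that("split alignments are joined by query order with the gap as deletion", {
  ref <- make_ref()
  segs <- parse_alignments(write_sam_fixture(list(
    sam_record("r", 1L, "40M40S", paste0(substr(ref$sequence, 1, 40),
                                         substr(ref$sequence, 141, 180))),
    sam_record("r", 141L, "40H40M", substr(ref$sequence, 141, 180),
               flag = 2048L)
  ), ref_len = ref$length), ref)
  d <- join_split_alignments(segs, ref)
  expect_equal(d[, c(five, three, deleted_length, insertion_length)],
               c(40L, 141L, 100L, 0L))

  # unaligned query between segments becomes the junction insertion
  segs2 <- parse_alignments(write_sam_fixture(list(
    sam_record("r", 1L, "40M45S", paste0(substr(ref$sequence, 1, 40), "CCCCC",
                                         substr(ref$sequence, 141, 180))),
    sam_record("r", 141L, "45H40M", substr(ref$sequence, 141, 180),
               flag = 2048L)
  ), ref_len = ref$length), ref)
  d2 <- join_split_alignments(segs2, ref)
  expect_equal(d2$insertion_length, 5L)
  expect_equal(d2$five, 40L)

  # a 5-nt reference gap is below the deletion length rule
  segs3 <- parse_alignments(write_sam_fixture(list(
    sam_record("r", 1L, "40M40S", random_seq(80)),
    sam_record("r", 46L, "40H40M", substr(ref$sequence, 46, 85),
               flag = 2048L)
  ), ref_len = ref$length), ref)
  expect_equal(nrow(join_split_alignments(segs3, ref)), 0L)
})

test_that("ambiguity test agrees with brute-force placement enumeration", {
  # worked examples
  expect_false(is_ambiguous_deletion(2L, 6L, "CTAAAG"))
  expect_true(is_ambiguous_deletion(2L, 5L, "CAAAG"))
  expect_equal(count_deletion_placements("CTAAAG", 2L, 6L), 1L)
  expect_equal(count_deletion_placements("CAAAG", 2L, 5L), 2L)

  # exhaustive over all 4^n references at n = 6
  combos <- expand.grid(rep(list(BASES), 6), stringsAsFactors = FALSE)
  refs <- apply(combos, 1, paste, collapse = "")
  for (sq in refs[seq(1, length(refs), by = 7)]) {
    for (f in 1:3) {
      for (t in (f + 2):6) {
        expect_equal(is_ambiguous_deletion(f, t, sq),
                     count_deletion_placements(sq, f, t) > 1L,
                     info = sprintf("%s del (%d,%d)", sq, f, t))
      }
    }
  }

  # randomized longer references
  set.seed(99)
  for (i in 1:300) {
    sq <- random_seq(sample(8:15, 1))
    L <- nchar(sq)
    f <- sample(1:(L - 3), 1)
    t <- sample((f + 2):L, 1)
    expect_equal(is_ambiguous_deletion(f, t, sq),
                 count_deletion_placements(sq, f, t) > 1L,
                 info = sprintf("%s del (%d,%d)", sq, f, t))
  }
})

test_that("edge matching leaves exact flanks unchanged and shifts mismatches outward", {
  ref <- make_ref()
  mk_seg <- function(cigar, seq) {
    parse_alignments(write_sam_fixture(list(sam_record("r", 1L, cigar, seq)),
                                       ref_len = ref$length), ref)
  }
  clean <- mk_seg("20M100D20M", read_with_deletion(ref$sequence, 20L, 121L) |>
                    substr(1, 40))
  r <- enforce_edge_matching(20L, 121L, clean, clean, ref)
  expect_true(r$ok)
  expect_equal(c(r$five, r$three, r$ins), c(20L, 121L, 0L))

  # mismatch at the base aligned to the 5' site: boundary moves out one,
  # the displaced base becomes junction insertion
  sq <- read_with_deletion(ref$sequence, 20L, 121L)
  v <- strsplit(substr(sq, 1, 40), "")[[1]]
  v[20] <- setdiff(BASES, c(v[20], substr(ref$sequence, 19, 19)))[1]
  # ensure the new 5' flank (18,19,20->ref 17,18,19) matches by construction
  mut <- mk_seg("20M100D20M", paste(v, collapse = ""))
  r2 <- enforce_edge_matching(20L, 121L, mut, mut, ref)
  expect_true(r2$ok)
  expect_equal(r2$five, 19L)
  expect_equal(r2$ins, 1L)
  expect_equal(r2$three, 121L)

  # adversarial read: flanks never match within the shift budget
  bad <- mk_seg("20M100D20M", random_seq(40))
  r3 <- enforce_edge_matching(20L, 121L, bad, bad, ref)
  expect_false(r3$ok)
})

test_that("emitted deletions always satisfy the exact-flank postcondition", {
  ref <- benchmark_reference()
  res <- run_benchmark(mode = "deletion_insertion", n_reads = 400L,
                       seed = 42L, detect = detect_config())
  dels <- res$calls$deletions
  expect_gt(nrow(dels), 100L)
  # regenerate the identical read set to check junctions against raw reads
  sim <- generate_dataset(ref, sim_config(mode = "deletion_insertion",
                                          n_reads = 400L),
                          mutation_model(), seed = 42L)
  reads <- as.character(parse_reads(sim$fastq))
  for (i in seq_len(nrow(dels))) {
    d <- dels[i]
    pat <- paste0(substr(ref$sequence, d$five - 2L, d$five),
                  sprintf(".{%d}", d$insertion_length),
                  substr(ref$sequence, d$three, d$three + 2L))
    expect_true(grepl(pat, reads[[d$read_id]]),
                info = paste("junction flanks must match the reference:",
                             d$read_id))
  }
})

test_that("edge matching never shrinks a deletion and respects the shift budget", {
  set.seed(31)
  ref <- make_ref(seed = 31L)
  for (i in 1:60) {
    f <- sample(30:150, 1)
    gap <- sample(20:120, 1)
    t <- f + gap + 1L
    v <- strsplit(paste0(substr(ref$sequence, 1, f),
                         substr(ref$sequence, t, t + 59L)), "")[[1]]
    # sprinkle mismatches near (and away from) the junction
    for (p in sample(seq_along(v), sample(0:4, 1))) {
      v[p] <- setdiff(BASES, v[p])[1]
    }
    seg <- parse_alignments(write_sam_fixture(list(
      sam_record("r", 1L, sprintf("%dM%dD%dM", f, gap, 60L),
                 paste(v, collapse = ""))
    ), ref_len = ref$length), ref)
    r <- enforce_edge_matching(f, t, seg, seg, ref)
    if (r$ok) {
      expect_gte(r$three - r$five - 1L, gap)            # never shrinks
      expect_lte((r$three - r$five - 1L) + r$ins - gap, 2L * 10L)
      expect_lte(r$shifts, 10L)
    }
  }
})

test_that("the detection pipeline stages apply in a fixed order", {
  # a deletion whose raw junction is ambiguous AND carries a long insertion:
  # edge matching first corrects the junction, then the ambiguity filter and
  # insertion filter see the corrected record
  ref <- make_ref(seed = 5L)
  pair <- pick_unambiguous_pair(ref, 100L)
  f <- pair[1]
  t <- pair[2]
  seq <- paste0(substr(ref$sequence, 1, f), substr(ref$sequence, t, t + 39L))
  sam <- write_sam_fixture(list(
    sam_record("r", 1L, sprintf("%dM%dD%dM", f, t - f - 1L, 40L), seq)
  ), ref_len = ref$length)
  keep_all <- detect_deletions(sam, ref,
                               detect_config(remove_ambiguous = FALSE,
                                             edge_matching = FALSE))
  expect_equal(nrow(keep_all$deletions), 1L)
  with_ambig <- detect_deletions(sam, ref, detect_config())
  expect_equal(nrow(with_ambig$deletions), 1L)  # unambiguous: retained

  # insertion-length filter: junction insertion of 12 nt is removed
  seq_ins <- paste0(substr(ref$sequence, 1, f), random_seq(12),
                    substr(ref$sequence, t, t + 39L))
  sam_ins <- write_sam_fixture(list(
    sam_record("r", 1L, sprintf("%dM12I%dD%dM", f, t - f - 1L, 40L), seq_ins)
  ), ref_len = ref$length)
  res_ins <- detect_deletions(sam_ins, ref,
                              detect_config(edge_matching = FALSE,
                                            remove_ambiguous = FALSE))
  expect_equal(nrow(res_ins$deletions), 0L)
  expect_equal(res_ins$diagnostics$insertion_removed, 1L)

  # duplicate records from two alignment sets are counted once
  res_dup <- detect_deletions(list(sam, sam), ref,
                              detect_config(remove_ambiguous = FALSE,
                                            edge_matching = FALSE))
  expect_equal(nrow(res_dup$deletions), 1L)
  expect_equal(res_dup$diagnostics$duplicates_removed, 1L)
})

test_that("ambiguous detections are removed when configured, kept otherwise", {
  ref2 <- make_ref(seed = 77L)
  # pick an ambiguous pair on the big reference
  amb <- NULL
  for (ff in 20:300) {
    tt <- ff + 41L
    if (is_ambiguous_deletion(ff, tt, ref2)) {
      amb <- c(ff, tt)
      break
    }
  }
  seq <- paste0(substr(ref2$sequence, 1, amb[1]),
                substr(ref2$sequence, amb[2], amb[2] + 39L))
  sam <- write_sam_fixture(list(
    sam_record("r", 1L, sprintf("%dM%dD%dM", amb[1], amb[2] - amb[1] - 1L, 40L),
               seq)
  ), ref_len = ref2$length)
  on_cfg <- detect_deletions(sam, ref2, detect_config(edge_matching = FALSE))
  off_cfg <- detect_deletions(sam, ref2,
                              detect_config(remove_ambiguous = FALSE,
                                            edge_matching = FALSE))
  expect_equal(nrow(on_cfg$deletions), 0L)
  expect_equal(on_cfg$diagnostics$ambiguous_removed, 1L)
  expect_equal(nrow(off_cfg$deletions), 1L)
})

test_that("reverse-strand segments are discarded and tallied", {
  ref <- make_ref()
  sam <- write_sam_fixture(list(
    sam_record("r", 1L, "20M100D20M",
               read_with_deletion(ref$sequence, 20L, 121L) |> substr(1, 40),
               flag = 16L)
  ), ref_len = ref$length)
  res <- detect_deletions(sam, ref, detect_config())
  expect_equal(nrow(res$deletions), 0L)
  expect_equal(res$diagnostics$reverse_strand, 1L)
})
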