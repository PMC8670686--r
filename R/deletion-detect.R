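#' Deletion-detection configuration
#'
#' @param min_deletion_length Deletions shorter than this are ignored.
#' @param max_insertion_length Deletions carrying a junction insertion
#'   longer than this are removed.
#' @param edge_match_flank Number of nucleotides on each side of the
#'   junction required to exactly match the reference.
#' @param max_edge_shift_total A deletion whose edge-matching boundary
#'   moves exceed this many nucleotides in total is not reported.
#' @param remove_ambiguous Drop deletions whose placement is not unique
#'   (identical nucleotides flank both sides, letting the block slide).
#' @param edge_matching Enforce exact junction flanks with outward boundary
#'   shifting. Both toggles exist so benchmark ladders can stage the
#'   optimizations.
#' @return A `detect_config` list.
#' @export
detect_config <- function(min_deletion_length = 10L,
                          max_insertion_length = 10L,
                          edge_match_flank = 3L,
                          max_edge_shift_total = 10L,
                          remove_ambiguous = TRUE,
                          edge_matching = TRUE) {
  stopifnot(min_deletion_length >= 0, max_insertion_length >= 0,
            edge_match_flank >= 0, max_edge_shift_total >= 0)
  structure(list(min_deletion_length = as.integer(min_deletion_length),
                 max_insertion_length = as.integer(max_insertion_length),
                 edge_match_flank = as.integer(edge_match_flank),
                 max_edge_shift_total = as.integer(max_edge_shift_total),
                 remove_ambiguous = isTRUE(remove_ambiguous),
                 edge_matching = isTRUE(edge_matching)),
            class = "detect_config")
}

#' Test whether a deletion placement is ambiguous
#'
#' A deleted block can slide one position 5' when the base at the 5' site
#' equals the last deleted base (`ref[five] == ref[three - 1]`), and one
#' position 3' when the first deleted base equals the base at the 3' site
#' (`ref[five + 1] == ref[three]`). Either slide reproduces the identical
#' read, so the placement is not unique. For contiguous deleted blocks this
#' two-sided single-slide test is equivalent to full placement enumeration.
#'
#' @param five,three Integer vectors of 5'/3' deletion sites (1-based; the
#'   last aligned base before and first aligned base after the block).
#' @param ref A `reference_sequence` or character scalar.
#' @return Logical vector.
#' @export
is_ambiguous_deletion <- function(five, three, ref) {
  sq <- if (inherits(ref, "reference_sequence")) ref$sequence else ref
  stopifnot(all(three > five + 1L), all(five >= 1L), all(three <= nchar(sq)))
  substring(sq, five, five) == substring(sq, three - 1L, three - 1L) |
    substring(sq, five + 1L, five + 1L) == substring(sq, three, three)
}

# ---- candidate collection ------------------------------------------------

# Gather raw deletion candidates (before any correction/filtering) from an
# alignment table, together with the per-segment context edge matching
# needs. Internal engine shared by the exported wrappers.
collect_deletion_candidates <- function(aln, ref, cfg = detect_config()) {
  diag <- list(records = nrow(aln), reverse_strand = 0L, secondary = 0L,
               split_diff_ref = 0L, split_overlap = 0L, split_short_gap = 0L)
  if (!nrow(aln)) {
    return(list(cands = .empty_cands_full(), aln = aln, ops = NULL, diag = diag))
  }
  diag$reverse_strand <- sum(aln$strand == "-")
  diag$secondary <- sum(aln$is_secondary)
  aln <- aln[strand == "+" & !is_secondary & ref_name == ref$name]
  aln <- copy(aln)[, rec := .I]
  if (!nrow(aln)) {
    return(list(cands = .empty_cands_full(), aln = aln, ops = NULL, diag = diag))
  }
  if (any(aln$ref_end > ref$length)) {
    stop("CIGAR walks past the reference end (reference '", ref$name,
         "' has ", ref$length, " nt)")
  }

  ops <- cigar_op_table(aln$cigar)
  ops[, qc := len * (op %chin% .q_ops_seq)]
  ops[, rc := len * (op %chin% .r_ops)]
  ops[, q_off := cumsum(qc) - qc, by = rec]
  ops[, r_off := cumsum(rc) - rc, by = rec]
  aln_ops <- ops[op %chin% .aln_ops,
                 .(first_aln = idx[1], last_aln = idx[.N],
                   first_aln_len = len[1], last_aln_len = len[.N]), by = rec]

  # intra-segment candidates: maximal runs of D/I ops flanked by aligned ops
  ops[, indel := op %chin% c("D", "I")]
  ops[, runid := rleid(indel), by = rec]
  runs <- ops[indel == TRUE,
              .(sumD = sum(len[op == "D"]), sumI = sum(len[op == "I"]),
                idx1 = idx[1], idx2 = idx[.N],
                r_off1 = r_off[1], q_off1 = q_off[1]),
              by = .(rec, runid)]
  runs <- aln_ops[runs, on = "rec"]
  runs <- runs[idx1 > first_aln & idx2 < last_aln &
                 sumD >= cfg$min_deletion_length]
  prevop <- ops[runs[, .(rec, idx = idx1 - 1L)], on = c("rec", "idx")]
  nextop <- ops[runs[, .(rec, idx = idx2 + 1L)], on = c("rec", "idx")]
  intra <- if (nrow(runs)) {
    data.table(
      up_rec = runs$rec, down_rec = runs$rec,
      five = aln$ref_start[runs$rec] + runs$r_off1 - 1L,
      ins = runs$sumI,
      q5_seq = runs$q_off1,
      up_M = ifelse(prevop$op %chin% .aln_ops, prevop$len, 0L),
      down_M = ifelse(nextop$op %chin% .aln_ops, nextop$len, 0L)
    )[, `:=`(three = five + runs$sumD + 1L, q3_seq = q5_seq + runs$sumI + 1L)]
  } else .empty_cands()

  # inter-segment candidates: reference gap between query-adjacent segments
  segs <- aln[, .(rec, read_id, ref_start, ref_end, query_start, query_end,
                  leadH)]
  setorder(segs, read_id, query_start, ref_start)
  segs[, n_seg := .N, by = read_id]
  split_cands <- .empty_cands()
  multi <- segs[n_seg >= 2L]
  if (nrow(multi)) {
    multi[, `:=`(nx_rec = shift(rec, -1L), nx_qs = shift(query_start, -1L),
                 nx_rs = shift(ref_start, -1L), nx_leadH = shift(leadH, -1L)),
          by = read_id]
    pr <- multi[!is.na(nx_rec)]
    pr[, ins := nx_qs - query_end - 1L]
    pr[, ovl := pmax(0L, -ins)]
    diag$split_overlap <- sum(pr$ins < 0L)
    # disjoint segments: junction is simply the reference gap
    disj <- pr[ovl == 0L & nx_rs - ref_end - 1L >= cfg$min_deletion_length]
    if (nrow(disj)) {
      split_cands <- data.table(
        up_rec = disj$rec, down_rec = disj$nx_rec,
        five = disj$ref_end, three = disj$nx_rs, ins = disj$ins,
        q5_seq = disj$query_end - aln$leadH[disj$rec],
        q3_seq = disj$nx_qs - disj$nx_leadH,
        up_M = aln_ops$last_aln_len[match(disj$rec, aln_ops$rec)],
        down_M = aln_ops$first_aln_len[match(disj$nx_rec, aln_ops$rec)]
      )
    }
    diag$split_short_gap <- sum(pr$ovl == 0L &
                                  pr$nx_rs - pr$ref_end - 1L <
                                    cfg$min_deletion_length)
    # Overlapping query spans: the aligner extended one or both segments
    # through the junction (homology, or short sloppy blocks past it).
    # Overlap bases are assigned to the upstream segment, consistent with
    # the aligner's bias of aligning ambiguous bases before the gap: the
    # junction is (upstream segment end, downstream segment's reference
    # position at the next read base). The edge-matching stage re-derives
    # the split point exactly (see .refine_split_junction) using the pair
    # context carried here.
    ovp <- pr[ovl > 0L]
    if (nrow(ovp)) {
      need <- unique(ovp$nx_rec)
      olist <- split(ops[rec %in% need, .(rec, len, op)], by = "rec",
                     keep.by = FALSE)
      three_ov <- integer(nrow(ovp))
      for (ii in seq_len(nrow(ovp))) {
        o <- olist[[as.character(ovp$nx_rec[ii])]]
        q <- ovp$query_end[ii] + 1L
        three_ov[ii] <- query_to_ref_window(o$len, o$op,
                                            aln$ref_start[ovp$nx_rec[ii]],
                                            q, q)[1L]
      }
      ov_cands <- data.table(
        up_rec = ovp$rec, down_rec = ovp$nx_rec,
        five = ovp$ref_end, three = three_ov, ins = 0L,
        q5_seq = ovp$query_end - aln$leadH[ovp$rec],
        q3_seq = ovp$query_end + 1L - ovp$nx_leadH,
        up_M = 0L, down_M = 0L,
        ovl_qe = ovp$query_end, ovl_qs = ovp$nx_qs)
      # read base after the overlap unaligned in B (insert op): fall back
      # to shifting the downstream start by the overlap length
      ov_cands[is.na(three), three := pmin(ovp$nx_rs[is.na(three_ov)] +
                                             ovp$ovl[is.na(three_ov)],
                                           ref$length)]
      split_cands <- rbind(split_cands, ov_cands, use.names = TRUE,
                           fill = TRUE)
    }
  }

  cands <- rbind(intra, split_cands, use.names = TRUE, fill = TRUE)
  if (!"ovl_qe" %in% names(cands)) {
    cands[, `:=`(ovl_qe = NA_integer_, ovl_qs = NA_integer_)]
  }
  if (nrow(cands)) {
    cands[, read_id := aln$read_id[up_rec]]
    cands[, deleted_length := three - five - 1L]
  } else {
    cands[, `:=`(read_id = character(), deleted_length = integer())]
  }
  list(cands = cands, aln = aln, ops = ops, diag = diag)
}

.empty_cands <- function() {
  data.table(up_rec = integer(), down_rec = integer(), five = integer(),
             ins = integer(), q5_seq = integer(), up_M = integer(),
             down_M = integer(), three = integer(), q3_seq = integer(),
             ovl_qe = integer(), ovl_qs = integer())
}

.empty_cands_full <- function() {
  .empty_cands()[, `:=`(read_id = character(), deleted_length = integer())][]
}

# Resolve one query-overlapping split pair: try every split point q* in the
# overlap window (read bases <= q* assigned upstream). A split is valid
# when at least `fl` junction-flank bases on each side lie on the segment
# diagonal and exactly match the reference; among valid splits the one
# with the longest exact diagonal support around the junction wins (a
# sloppy chance-matching extension breaks at its indels within a few
# bases, the true junction does not), ties to the most 3'-extended split,
# consistent with the aligner's bias of aligning ambiguous bases before
# the gap. Falls back to the upstream segment end (flanks unverified; edge
# matching decides). NULL when the junction cannot be placed at all.
.refine_split_junction <- function(up, dn, qe_up, qs_dn, ref_sq, L,
                                   min_del, fl, reach = 12L) {
  reach <- max(reach, fl)
  dA <- .main_diagonal(up)
  dB <- .main_diagonal(dn)
  ubase <- function(q) {
    i <- q - up$leadH
    if (i < 1L || i > nchar(up$seq)) NA_character_ else substr(up$seq, i, i)
  }
  dbase <- function(q) {
    i <- q - dn$leadH
    if (i < 1L || i > nchar(dn$seq)) NA_character_ else substr(dn$seq, i, i)
  }
  best <- NULL
  best_support <- -1L
  for (qs in seq(qe_up, qs_dn - 1L)) {
    f <- qs + dA
    t3 <- qs + 1L + dB
    if (t3 - f - 1L < min_del) next
    if (f - fl + 1L < 1L || t3 + fl - 1L > L) next
    sup_up <- 0L
    for (k in 0:(reach - 1L)) {
      if (f - k < 1L) break
      b <- ubase(qs - k)
      if (is.na(b) || b != substr(ref_sq, f - k, f - k)) break
      sup_up <- sup_up + 1L
    }
    if (sup_up < fl) next
    sup_dn <- 0L
    for (k in 0:(reach - 1L)) {
      if (t3 + k > L) break
      b <- dbase(qs + 1L + k)
      if (is.na(b) || b != substr(ref_sq, t3 + k, t3 + k)) break
      sup_dn <- sup_dn + 1L
    }
    if (sup_dn < fl) next
    if (sup_up + sup_dn > best_support) {
      best_support <- sup_up + sup_dn
      best <- list(found = TRUE, five = f, three = t3, q5 = qs)
    }
  }
  if (!is.null(best)) return(best)
  # no exact split: keep the upstream segment end per the alignment maps
  mapU <- query_to_ref_window(up$len, up$op, up$pos, qe_up, qe_up)
  mapD <- query_to_ref_window(dn$len, dn$op, dn$pos, qe_up + 1L, qe_up + 1L)
  f <- mapU[1L]
  t3 <- mapD[1L]
  if (is.na(f) || is.na(t3) || t3 - f - 1L < min_del || t3 <= f + 1L) {
    return(NULL)
  }
  list(found = FALSE, five = f, three = t3, q5 = qe_up)
}

# diagonal (ref - query offset) of a segment's longest aligned block, in
# original-read query coordinates
.main_diagonal <- function(seg) {
  q <- 0L
  r <- seg$pos - 1L
  best_len <- -1L
  diag <- 0L
  for (k in seq_along(seg$op)) {
    o <- seg$op[k]
    ln <- seg$len[k]
    if (o == "M" || o == "=" || o == "X") {
      if (ln > best_len) {
        best_len <- ln
        diag <- r - q
      }
      q <- q + ln
      r <- r + ln
    } else if (o == "D" || o == "N") {
      r <- r + ln
    } else if (o == "I" || o == "S" || o == "H") {
      q <- q + ln
    }
  }
  diag
}

# ---- edge matching -------------------------------------------------------

# Enforce exact junction flanks for one candidate, shifting boundaries
# outward; returns list(ok, five, three, ins, shifts).
.edge_match_one <- function(five, three, up, down, ref_chars, flank,
                            max_shift) {
  L <- length(ref_chars)
  win <- max_shift + flank
  lo5 <- max(1L, five - win)
  hi3 <- min(L, three + win)
  qU <- ref_to_query_window(up$len, up$op, up$pos, lo5, five)
  qD <- ref_to_query_window(down$len, down$op, down$pos, three, hi3)
  f <- five
  t <- three
  s5 <- 0L
  s3 <- 0L
  repeat {
    if (s5 + s3 > max_shift) return(list(ok = FALSE, reason = "edge_shift"))
    if (f - flank + 1L < 1L || t + flank - 1L > L) {
      return(list(ok = FALSE, reason = "edge_bounds"))
    }
    ok5 <- TRUE
    for (p in (f - flank + 1L):f) {
      q <- qU[p - lo5 + 1L]
      if (is.na(q) || substr(up$seq, q, q) != ref_chars[p]) {
        ok5 <- FALSE
        break
      }
    }
    if (!ok5) {
      f <- f - 1L
      s5 <- s5 + 1L
      next
    }
    ok3 <- TRUE
    for (p in t:(t + flank - 1L)) {
      q <- qD[p - three + 1L]
      if (is.na(q) || substr(down$seq, q, q) != ref_chars[p]) {
        ok3 <- FALSE
        break
      }
    }
    if (!ok3) {
      t <- t + 1L
      s3 <- s3 + 1L
      next
    }
    break
  }
  q5o <- qU[f - lo5 + 1L] + up$leadH
  q3o <- qD[t - three + 1L] + down$leadH
  list(ok = TRUE, five = f, three = t, ins = q3o - q5o - 1L,
       shifts = s5 + s3)
}

#' Enforce exact edge matching on one deletion
#'
#' The `edge_match_flank` read bases aligned immediately 5' of the junction
#' (reference positions `five - flank + 1 .. five`) and 3' of it
#' (`three .. three + flank - 1`) must exactly match the reference. While
#' any flank base mismatches (or is missing from the read), that boundary
#' moves one nucleotide to the exterior and the displaced read base is
#' reclassified as junction insertion. Deletions whose cumulative boundary
#' moves exceed `max_edge_shift_total`, or whose flank runs past the
#' reference, are dropped.
#'
#' @param five,three Candidate junction sites.
#' @param up_segment,down_segment Single-row alignment tables (as from
#'   [parse_alignments()]) holding the segments aligned upstream and
#'   downstream of the junction; the same row for an intra-segment deletion.
#' @param ref A `reference_sequence`.
#' @param cfg A [detect_config()].
#' @return `list(ok, five, three, ins, shifts)`; `ok = FALSE` with a
#'   `reason` when the deletion is dropped.
#' @export
enforce_edge_matching <- function(five, three, up_segment,
                                  down_segment = up_segment, ref,
                                  cfg = detect_config()) {
  seg_ctx <- function(seg) {
    o <- cigar_op_table(seg$cigar)
    list(len = o$len, op = o$op, pos = seg$ref_start, seq = seg$seq,
         leadH = if (!is.null(seg$leadH)) seg$leadH else 0L)
  }
  .edge_match_one(five, three, seg_ctx(up_segment), seg_ctx(down_segment),
                  strsplit(ref$sequence, "")[[1]],
                  cfg$edge_match_flank, cfg$max_edge_shift_total)
}

# Apply edge matching to a candidate table (vectorized fast path for
# candidates whose flanks lie in long aligned blocks and already match).
.apply_edge_matching <- function(cands, collected, ref, cfg) {
  if (!nrow(cands)) return(list(cands = cands, dropped = 0L))
  aln <- collected$aln
  fl <- cfg$edge_match_flank
  L <- ref$length
  sq <- ref$sequence
  seqs <- aln$seq
  # re-derive the split point of query-overlapping segment pairs exactly
  ov_idx <- which(!is.na(cands$ovl_qe))
  ov_dropped <- 0L
  if (length(ov_idx)) {
    need <- unique(c(cands$up_rec[ov_idx], cands$down_rec[ov_idx]))
    olist0 <- split(collected$ops[rec %in% need, .(rec, len, op)],
                    by = "rec", keep.by = FALSE)
    ctx0 <- function(r) {
      o <- olist0[[as.character(r)]]
      list(len = o$len, op = o$op, pos = aln$ref_start[r], seq = seqs[r],
           leadH = aln$leadH[r])
    }
    ok <- logical(length(ov_idx))
    for (k in seq_along(ov_idx)) {
      i <- ov_idx[k]
      r <- .refine_split_junction(ctx0(cands$up_rec[i]),
                                  ctx0(cands$down_rec[i]),
                                  cands$ovl_qe[i], cands$ovl_qs[i],
                                  sq, L, cfg$min_deletion_length,
                                  max(1L, fl))
      if (is.null(r)) next
      ok[k] <- TRUE
      set(cands, i, "five", r$five)
      set(cands, i, "three", r$three)
      set(cands, i, "ins", 0L)
      set(cands, i, "q5_seq", r$q5 - aln$leadH[cands$up_rec[i]])
      set(cands, i, "q3_seq", r$q5 + 1L - aln$leadH[cands$down_rec[i]])
      set(cands, i, "up_M", if (r$found) fl else 0L)
      set(cands, i, "down_M", if (r$found) fl else 0L)
    }
    ov_dropped <- sum(!ok)
    if (ov_dropped) cands <- cands[-ov_idx[!ok]]
  }
  in_bounds <- cands$five - fl + 1L >= 1L & cands$three + fl - 1L <= L
  fastable <- in_bounds & cands$up_M >= fl & cands$down_M >= fl
  up_read <- substr(seqs[cands$up_rec], cands$q5_seq - fl + 1L, cands$q5_seq)
  dn_read <- substr(seqs[cands$down_rec], cands$q3_seq, cands$q3_seq + fl - 1L)
  up_ref <- substring(sq, cands$five - fl + 1L, cands$five)
  dn_ref <- substring(sq, cands$three, cands$three + fl - 1L)
  clean <- fastable & up_read == up_ref & dn_read == dn_ref
  slow_idx <- which(!clean)
  if (length(slow_idx)) {
    need <- unique(c(cands$up_rec[slow_idx], cands$down_rec[slow_idx]))
    ops_need <- collected$ops[rec %in% need, .(rec, len, op)]
    olist <- split(ops_need, by = "rec", keep.by = FALSE)
    ref_chars <- strsplit(sq, "")[[1]]
    ctx <- function(r) {
      o <- olist[[as.character(r)]]
      list(len = o$len, op = o$op, pos = aln$ref_start[r], seq = seqs[r],
           leadH = aln$leadH[r])
    }
    res_five <- cands$five[slow_idx]
    res_three <- cands$three[slow_idx]
    res_ins <- cands$ins[slow_idx]
    res_ok <- logical(length(slow_idx))
    for (k in seq_along(slow_idx)) {
      i <- slow_idx[k]
      r <- .edge_match_one(cands$five[i], cands$three[i],
                           ctx(cands$up_rec[i]), ctx(cands$down_rec[i]),
                           ref_chars, fl, cfg$max_edge_shift_total)
      res_ok[k] <- r$ok
      if (r$ok) {
        res_five[k] <- r$five
        res_three[k] <- r$three
        res_ins[k] <- r$ins
      }
    }
    cands[slow_idx, `:=`(five = res_five, three = res_three, ins = res_ins)]
    keep <- rep(TRUE, nrow(cands))
    keep[slow_idx] <- res_ok
    dropped <- sum(!keep)
    cands <- cands[keep]
  } else {
    dropped <- 0L
  }
  cands[, deleted_length := three - five - 1L]
  cands <- cands[deleted_length >= cfg$min_deletion_length]
  list(cands = cands, dropped = dropped + ov_dropped)
}

# ---- finalization --------------------------------------------------------

# Fixed pipeline order: edge matching -> ambiguity removal -> insertion
# length filter -> dedupe.
finalize_deletions <- function(collected, ref, cfg = detect_config()) {
  cands <- copy(collected$cands)
  diag <- collected$diag
  diag$candidates <- nrow(cands)
  diag$edge_dropped <- 0L
  if (cfg$edge_matching && nrow(cands)) {
    em <- .apply_edge_matching(cands, collected, ref, cfg)
    cands <- em$cands
    diag$edge_dropped <- em$dropped
  } else if (nrow(cands)) {
    # raw junctions of query-overlapping split pairs can fall below the
    # length rule; without edge matching they are simply length-filtered
    cands <- cands[three - five - 1L >= cfg$min_deletion_length]
  }
  diag$ambiguous_removed <- 0L
  if (cfg$remove_ambiguous && nrow(cands)) {
    amb <- is_ambiguous_deletion(cands$five, cands$three, ref)
    diag$ambiguous_removed <- sum(amb)
    cands <- cands[!amb]
  }
  diag$insertion_removed <- if (nrow(cands)) sum(cands$ins > cfg$max_insertion_length) else 0L
  cands <- cands[ins <= cfg$max_insertion_length]
  dels <- cands[, .(read_id, ref_name = ref$name, five, three,
                    deleted_length = three - five - 1L,
                    insertion_length = ins)]
  n0 <- nrow(dels)
  dels <- unique(dels, by = c("read_id", "five", "three"))
  diag$duplicates_removed <- n0 - nrow(dels)
  diag$deletions <- nrow(dels)
  list(deletions = dels[], diagnostics = diag)
}

#' Extract deletions encoded in a single alignment's CIGAR
#'
#' Every maximal run of D (with any interleaved I) ops whose deleted length
#' reaches `min_deletion_length` yields one deletion; insertions adjacent to
#' the run contribute to its junction insertion length. Multiple deletions
#' per read are allowed. No correction or filtering beyond the length rule
#' is applied here (see [detect_deletions()] for the full pipeline).
#'
#' @param segment One-row alignment table (see [parse_alignments()]).
#' @param ref A `reference_sequence`.
#' @param cfg A [detect_config()].
#' @return `data.table` of deletions (`read_id`, `ref_name`, `five`,
#'   `three`, `deleted_length`, `insertion_length`).
#' @export
extract_deletions_from_cigar <- function(segment, ref, cfg = detect_config()) {
  col <- collect_deletion_candidates(as.data.table(segment), ref, cfg)
  col$cands[, .(read_id, ref_name = ref$name, five, three,
                deleted_length = three - five - 1L, insertion_length = ins)]
}

#' Infer deletions from split alignments of one read
#'
#' Segments are ordered by query position; for each adjacent pair, the
#' reference sequence skipped between them defines a candidate deletion,
#' with unaligned query nucleotides between the segments as the junction
#' insertion. Pairs with overlapping query spans or reference gaps shorter
#' than `min_deletion_length` are discarded.
#'
#' @param segments Alignment table holding all segments of one (or more)
#'   reads.
#' @inheritParams extract_deletions_from_cigar
#' @return `data.table` of deletions, as in [extract_deletions_from_cigar()].
#' @export
join_split_alignments <- function(segments, ref, cfg = detect_config()) {
  col <- collect_deletion_candidates(as.data.table(segments), ref, cfg)
  cands <- col$cands[up_rec != down_rec]
  cands[, .(read_id, ref_name = ref$name, five, three,
            deleted_length = three - five - 1L, insertion_length = ins)]
}

#' Detect deletions from aligned reads
#'
#' Runs CIGAR extraction and split-alignment joining on every read, then
#' applies, in fixed order: exact edge matching, ambiguous-deletion
#' removal, the junction-insertion length filter, and deduplication of
#' identical `(read_id, five, three)` records (the same molecular event
#' seen via mate overlap or merged/unmerged double counting).
#'
#' Reverse-strand and secondary records are discarded with a tally: the
#' assay is amplicon-directional.
#'
#' @param alignments One or more alignment inputs: SAM/BAM paths or
#'   alignment tables from [parse_alignments()] (e.g. merged and unmerged
#'   read sets), as a list or a single object.
#' @param ref A `reference_sequence`.
#' @param cfg A [detect_config()].
#' @return List of class `deletion_calls`: `deletions` (`data.table`) and
#'   `diagnostics` (drop tallies by cause).
#' @export
detect_deletions <- function(alignments, ref, cfg = detect_config()) {
  if (!is.list(alignments) || is.data.frame(alignments)) {
    alignments <- list(alignments)
  }
  parts <- lapply(alignments, function(a) {
    if (is.character(a)) a <- parse_alignments(a, ref)
    finalize_deletions(collect_deletion_candidates(as.data.table(a), ref, cfg),
                       ref, cfg)
  })
  dels <- rbindlist(lapply(parts, `[[`, "deletions"))
  n0 <- nrow(dels)
  dels <- unique(dels, by = c("read_id", "five", "three"))
  diags <- lapply(parts, `[[`, "diagnostics")
  diag <- Reduce(function(a, b) Map(`+`, a, b), diags)
  diag$duplicates_removed <- diag$duplicates_removed + n0 - nrow(dels)
  diag$deletions <- nrow(dels)
  structure(list(deletions = dels[], diagnostics = diag),
            class = "deletion_calls")
}

#' @export
print.deletion_calls <- function(x, ...) {
  cat("deletion_calls: ", nrow(x$deletions), " deletions in ",
      length(unique(x$deletions$read_id)), " reads\n", sep = "")
  invisible(x)
}
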