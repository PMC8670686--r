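# CIGAR arithmetic. Deletion parsing from alignments is the core of this
# package, so the op walking is implemented here rather than delegated.

# Explode CIGAR strings into a long op table.
# Returns data.table(rec, idx, len, op) where rec indexes the input vector.
cigar_op_table <- function(cigars) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigars, perl = TRUE)
  toks <- regmatches(cigars, m)
  nop <- lengths(toks)
  toks <- unlist(toks, use.names = FALSE)
  dt <- data.table(
    rec = rep(seq_along(cigars), nop),
    len = as.integer(sub("[A-Z=]$", "", toks)),
    op  = sub("^\\d+", "", toks)
  )
  dt[, idx := seq_len(.N), by = rec]
  dt
}

# which ops consume query (original read) / reference
.q_ops_seq  <- c("M", "I", "S", "=", "X")        # consume SEQ-local bases
.q_ops_all  <- c("M", "I", "S", "H", "=", "X")   # consume original-read bases
.r_ops      <- c("M", "D", "N", "=", "X")
.aln_ops    <- c("M", "=", "X")

# Per-record summaries used throughout: reference span, query span in
# original-read coordinates (hard clips included), and clip bookkeeping.
# `ops` is a cigar_op_table(); returns data.table keyed by rec.
cigar_summaries <- function(ops) {
  first_real <- ops[!(op %in% c("S", "H")), .(first = min(idx), last = max(idx)),
                    by = rec]
  lead <- ops[first_real, on = "rec"][idx < first,
              .(lead_clip = sum(len),
                leadH = sum(len[op == "H"])), by = rec]
  tails <- ops[first_real, on = "rec"][idx > last,
               .(tail_clip = sum(len)), by = rec]
  out <- ops[, .(
    ref_len  = sum(len[op %in% .r_ops]),
    read_len = sum(len[op %in% .q_ops_all])
  ), by = rec]
  out <- lead[out, on = "rec"]
  out <- tails[out, on = "rec"]
  for (cl in c("lead_clip", "leadH", "tail_clip")) {
    set(out, which(is.na(out[[cl]])), cl, 0L)
  }
  out[, query_start := lead_clip + 1L]
  out[, query_end := read_len - tail_clip]
  setkey(out, rec)
  out[]
}

# Reference and query spans of a single CIGAR (1-based, inclusive), as used
# by alignment-segment consumers. Exposed for tests.
cigar_spans <- function(cigar, pos = 1L) {
  ops <- cigar_op_table(cigar)
  s <- cigar_summaries(ops)
  list(ref = c(pos, pos + s$ref_len - 1L),
       query = c(s$query_start, s$query_end),
       read_len = s$read_len)
}

# Map original-read query positions [qlo, qhi] of one segment onto
# reference positions. NA where the read base is unaligned (clip/insert) or
# outside the segment. Hard clips count as query-consuming here.
query_to_ref_window <- function(ops_len, ops_op, pos, qlo, qhi) {
  out <- rep(NA_integer_, qhi - qlo + 1L)
  q <- 0L
  r <- pos - 1L
  for (k in seq_along(ops_op)) {
    o <- ops_op[k]
    ln <- ops_len[k]
    if (o == "M" || o == "=" || o == "X") {
      s <- max(q + 1L, qlo)
      e <- min(q + ln, qhi)
      if (s <= e) out[(s - qlo + 1L):(e - qlo + 1L)] <- r + (s - q):(e - q)
      q <- q + ln
      r <- r + ln
    } else if (o == "D" || o == "N") {
      r <- r + ln
    } else if (o == "I" || o == "S" || o == "H") {
      q <- q + ln
    }
    if (q >= qhi) break
  }
  out
}

# Map reference positions [lo, hi] of one aligned segment onto SEQ-local
# query indices. NA where the reference base is deleted or not covered.
# ops_len/ops_op: this record's cigar ops in order; pos: 1-based POS.
ref_to_query_window <- function(ops_len, ops_op, pos, lo, hi) {
  out <- rep(NA_integer_, hi - lo + 1L)
  q <- 0L
  r <- pos - 1L
  for (k in seq_along(ops_op)) {
    o <- ops_op[k]
    ln <- ops_len[k]
    if (o == "M" || o == "=" || o == "X") {
      s <- max(r + 1L, lo)
      e <- min(r + ln, hi)
      if (s <= e) out[(s - lo + 1L):(e - lo + 1L)] <- q + (s - r):(e - r)
      r <- r + ln
      q <- q + ln
    } else if (o == "D" || o == "N") {
      r <- r + ln
    } else if (o == "I" || o == "S") {
      q <- q + ln
    } # H consumes nothing SEQ-local
    if (r >= hi) break
  }
  out
}
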