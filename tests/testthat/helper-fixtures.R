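library(data.table)

BASES <- c("A", "C", "G", "T")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

# write a minimal single-reference SAM file and return its path
write_sam_fixture <- function(records, ref_name = "ref", ref_len = 400L,
                              path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", ref_name, ref_len))
  lines <- vapply(records, function(r) {
    paste(r$qname, r$flag, ref_name, r$pos, if (is.null(r$mapq)) 60L else r$mapq,
          r$cigar, "*", 0L, 0L, r$seq,
          paste(rep("I", nchar(r$seq)), collapse = ""), sep = "\t")
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

sam_record <- function(qname, pos, cigar, seq, flag = 0L, mapq = 60L) {
  list(qname = qname, pos = pos, cigar = cigar, seq = seq, flag = flag,
       mapq = mapq)
}

# read implied by a reference and a deletion (five, three) with insertion
read_with_deletion <- function(ref_seq, five, three, ins = "") {
  paste0(substr(ref_seq, 1, five), ins,
         substr(ref_seq, three, nchar(ref_seq)))
}

# brute-force oracle: number of placements of a deleted block of length
# `dl` that reproduce the identical read
count_deletion_placements <- function(ref_seq, five, three) {
  L <- nchar(ref_seq)
  dl <- three - five - 1L
  read <- read_with_deletion(ref_seq, five, three)
  hits <- 0L
  for (f in 0:(L - dl)) {
    if (read_with_deletion(ref_seq, f, f + dl + 1L) == read) hits <- hits + 1L
  }
  hits
}

# independent sliding-window trimmer used as oracle
trim_oracle <- function(q, window = 5L, thr = 20) {
  n <- length(q)
  if (n >= window) {
    for (i in 1:(n - window + 1L)) {
      if (mean(q[i:(i + window - 1L)]) < thr) return(i - 1L)
    }
  }
  n
}

# pick an unambiguous (five, three) pair with the requested gap
pick_unambiguous_pair <- function(ref, gap, from = 20L) {
  sq <- ref$sequence
  for (f in from:(ref$length - gap - 20L)) {
    t <- f + gap + 1L
    if (!is_ambiguous_deletion(f, t, ref)) return(c(f, t))
  }
  stop("no unambiguous pair found")
}

# toy folded RNA: O2' coordinates on a confined random walk (so that
# sequence-distant residues come close in space) plus a hairpin-rich
# secondary structure; written as a PDB fixture and re-read through the
# package parser
make_toy_structure <- function(n = 100L, seed = 7L) {
  set.seed(seed)
  xyz <- matrix(0, n, 3)
  for (i in 2:n) {
    repeat {
      step <- rnorm(3)
      cand <- xyz[i - 1, ] + 5.8 * step / sqrt(sum(step^2))
      if (sqrt(sum(cand^2)) < 26) break
    }
    xyz[i, ] <- cand
  }
  pairs <- NULL
  h <- 1L
  while (h + 19L <= n) {
    pairs <- rbind(pairs, cbind(h:(h + 4L), (h + 19L):(h + 15L)))
    h <- h + 25L
  }
  ss <- secondary_structure(pairs, n)
  pdb <- write_pdb_fixture(seq_len(n), xyz,
                           resid = sample(c("A", "C", "G", "U"), n,
                                          replace = TRUE))
  coords <- parse_tertiary_coordinates(pdb, chain = "A")
  list(ss = ss, coords = coords, n = n)
}

# concordant-pair (Mann-Whitney) AUC oracle
roc_oracle <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

# fixed-column PDB ATOM records (one atom name per residue by default)
write_pdb_fixture <- function(resno, xyz, atom = "O2'", resid = "A",
                              chain = "A", path = tempfile(fileext = ".pdb")) {
  n <- length(resno)
  atom <- rep_len(atom, n)
  resid <- rep_len(resid, n)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), atom, resid, chain, resno,
    xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
    toupper(substr(atom, 1, 1)))
  writeLines(c(lines, "END"), path)
  path
}
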