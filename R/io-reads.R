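#' Read sequencing reads from a FASTQ file
#'
#' Reads a (possibly gzip-compressed) Phred+33 FASTQ file into a
#' [Biostrings::QualityScaledDNAStringSet]. Record names are the read ids
#' (text up to the first whitespace after `@`).
#'
#' @param path Path to a FASTQ file; `.gz` is handled transparently.
#' @return A [Biostrings::QualityScaledDNAStringSet]; zero-length for an
#'   empty file.
#' @details A record whose quality string length differs from its sequence
#'   length is a hard error naming the 1-based record index.
#' @export
parse_reads <- function(path) {
  stopifnot(file.exists(path))
  .validate_fastq(path)
  reads <- suppressWarnings(
    Biostrings::readQualityScaledDNAStringSet(path, quality.scoring = "phred"))
  if (length(reads)) names(reads) <- sub("\\s.*$", "", names(reads))
  reads
}

# structural check; Biostrings silently pads short quality strings, so
# sequence/quality length agreement must be verified up front
.validate_fastq <- function(path, chunk_records = 100000L) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    lines <- readLines(con, n = 4L * chunk_records)
    if (!length(lines)) break
    if (length(lines) %% 4L != 0L) {
      stop("FASTQ record ", i + length(lines) %/% 4L + 1L,
           ": truncated record")
    }
    idx <- seq(1L, length(lines), by = 4L)
    if (!all(startsWith(lines[idx], "@")) ||
        !all(startsWith(lines[idx + 2L], "+"))) {
      bad <- which(!startsWith(lines[idx], "@") |
                     !startsWith(lines[idx + 2L], "+"))[1]
      stop("FASTQ record ", i + bad, ": malformed record markers")
    }
    mism <- which(nchar(lines[idx + 1L]) != nchar(lines[idx + 3L]))
    if (length(mism)) {
      stop("FASTQ record ", i + mism[1],
           ": quality length does not match sequence length")
    }
    i <- i + length(idx)
  }
  invisible(TRUE)
}

#' Write reads to a FASTQ file
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @param path Output path (plain text; `.gz` compresses).
#' @return `path`, invisibly.
#' @export
write_reads <- function(reads, path) {
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              compress = grepl("\\.gz$", path),
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Per-read Phred qualities as an integer list
#'
#' @param reads A [Biostrings::QualityScaledDNAStringSet].
#' @return A list of integer vectors, one per read.
#' @export
read_qualities <- function(reads) {
  as(Biostrings::quality(reads), "IntegerList")
}

#' Construct a quality-scaled read set from character vectors
#'
#' Convenience constructor used by the simulator and in tests.
#'
#' @param sequences Character vector of ACGTN sequences.
#' @param qualities Either a single integer (constant Phred score for every
#'   base) or a list of integer vectors matching `sequences` in shape.
#' @param ids Read identifiers; defaults to `read1, read2, ...`.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
make_reads <- function(sequences, qualities = 38L,
                       ids = paste0("read", seq_along(sequences))) {
  stopifnot(all(nchar(sequences) > 0L))
  if (is.numeric(qualities) && length(qualities) == 1L) {
    qchar <- strrep(rawToChar(as.raw(qualities + 33L)), nchar(sequences))
  } else {
    stopifnot(length(qualities) == length(sequences))
    qchar <- vapply(qualities, function(q) {
      rawToChar(as.raw(as.integer(q) + 33L))
    }, character(1))
  }
  Biostrings::QualityScaledDNAStringSet(
    stats::setNames(Biostrings::DNAStringSet(sequences), ids),
    Biostrings::PhredQuality(qchar)
  )
}

#' Read a reference sequence from FASTA
#'
#' Loads one reference sequence, uppercases it and applies U -> T
#' normalization (cDNA reads are DNA), and attaches structure-cassette
#' intervals.
#'
#' @param path FASTA file.
#' @param target Sequence name to select when the file holds several
#'   records; with `NULL` the file must contain exactly one record.
#' @param cassette_5p,cassette_3p Closed 1-based intervals
#'   (`c(start, end)`) of the flanking structure cassettes, or `NULL` when
#'   absent. Cassette sites are excluded from simulated deletion placement.
#' @return An object of class `reference_sequence`: a list with `name`,
#'   `sequence` (character), `length`, `cassette_5p`, `cassette_3p`.
#' @export
parse_reference <- function(path, target = NULL,
                            cassette_5p = NULL, cassette_3p = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.null(target)) {
    if (length(seqs) != 1L) {
      stop("FASTA contains ", length(seqs),
           " sequences; supply `target` to pick one")
    }
    idx <- 1L
  } else {
    idx <- match(target, names(seqs))
    if (is.na(idx)) stop("sequence '", target, "' not found in ", path)
  }
  sq <- chartr("u", "t", toupper(as.character(seqs[[idx]])))
  sq <- chartr("U", "T", sq)
  reference_sequence(sq, name = names(seqs)[idx],
                     cassette_5p = cassette_5p, cassette_3p = cassette_3p)
}

#' Construct a reference sequence object
#'
#' @param sequence Character scalar (ACGT; U is normalized to T).
#' @param name Sequence name.
#' @inheritParams parse_reference
#' @return A `reference_sequence` object.
#' @export
reference_sequence <- function(sequence, name = "ref",
                               cassette_5p = NULL, cassette_3p = NULL) {
  sequence <- chartr("Uu", "Tt", toupper(sequence))
  n <- nchar(sequence)
  chk <- function(iv, lab) {
    if (is.null(iv)) return(NULL)
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2]) {
      stop(lab, " cassette interval [", paste(iv, collapse = ","),
           "] outside reference [1,", n, "]")
    }
    iv
  }
  cassette_5p <- chk(cassette_5p, "5'")
  cassette_3p <- chk(cassette_3p, "3'")
  if (!is.null(cassette_5p) && !is.null(cassette_3p) &&
      cassette_5p[2] >= cassette_3p[1] && cassette_3p[2] >= cassette_5p[1]) {
    stop("cassette intervals overlap")
  }
  structure(list(name = name, sequence = sequence, length = n,
                 cassette_5p = cassette_5p, cassette_3p = cassette_3p),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("reference_sequence '", x$name, "' (", x$length, " nt)\n", sep = "")
  fmt <- function(iv) if (is.null(iv)) "none" else paste(iv, collapse = "-")
  cat("  5' cassette: ", fmt(x$cassette_5p),
      "   3' cassette: ", fmt(x$cassette_3p), "\n", sep = "")
  invisible(x)
}

#' Write a reference sequence to FASTA
#'
#' @param ref A `reference_sequence`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  Biostrings::writeXStringSet(
    stats::setNames(Biostrings::DNAStringSet(ref$sequence), ref$name), path)
  invisible(path)
}
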