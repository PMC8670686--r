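#' Construct a secondary-structure pair table
#'
#' @param pairs Two-column matrix (or data.frame) of 1-based paired
#'   positions, one row per base pair; may be empty.
#' @param length Number of nucleotides in the structure.
#' @return An object of class `secondary_structure`: list with `length` and
#'   `pair_of`, an integer vector mapping position -> partner (`NA` when
#'   unpaired).
#' @export
secondary_structure <- function(pairs, length) {
  length <- as.integer(length)
  pair_of <- rep(NA_integer_, length)
  if (NROW(pairs)) {
    pairs <- matrix(as.integer(as.matrix(pairs)), ncol = 2L)
    if (any(pairs < 1L | pairs > length)) stop("pair outside [1, length]")
    if (any(pairs[, 1] == pairs[, 2])) stop("position paired with itself")
    pair_of[pairs[, 1]] <- pairs[, 2]
    pair_of[pairs[, 2]] <- pairs[, 1]
    j <- which(!is.na(pair_of))
    if (!all(pair_of[pair_of[j]] == j)) stop("pair table is not symmetric")
  }
  structure(list(length = length, pair_of = pair_of),
            class = "secondary_structure")
}

#' Parse a secondary structure from CT or dot-bracket text
#'
#' @param path Structure file. Format is chosen by `format`, or guessed:
#'   files whose first data line has six whitespace-separated fields are CT.
#' @param format `"auto"`, `"ct"` or `"dotbracket"`. Dot-bracket input
#'   supports nested `()` pairs only; pseudoknot symbols (`[]{}<>`, letters)
#'   are rejected with a clear message.
#' @return A `secondary_structure`.
#' @export
parse_secondary_structure <- function(path, format = c("auto", "ct", "dotbracket")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty structure file")
  if (format == "auto") {
    probe <- if (length(lines) > 1L) lines[2] else lines[1]
    format <- if (length(strsplit(trimws(probe), "\\s+")[[1]]) >= 6L)
      "ct" else "dotbracket"
  }
  if (format == "ct") .parse_ct(lines) else .parse_dotbracket(lines)
}

.parse_ct <- function(lines) {
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(header[1]))
  if (is.na(n)) stop("CT header does not start with the sequence length")
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  if (length(rows) < n) stop("CT file truncated: expected ", n, " rows")
  rows <- rows[seq_len(n)]
  idx <- vapply(rows, function(r) as.integer(r[1]), integer(1))
  prt <- vapply(rows, function(r) as.integer(r[5]), integer(1))
  if (!identical(idx, seq_len(n))) stop("CT rows are not 1..n in order")
  pair_of <- rep(NA_integer_, n)
  pair_of[idx[prt > 0L]] <- prt[prt > 0L]
  j <- which(!is.na(pair_of))
  if (any(pair_of[j] < 1L | pair_of[j] > n) ||
      !all(pair_of[pair_of[j]] == j, na.rm = FALSE)) {
    stop("asymmetric CT pairing: row i -> j without j -> i")
  }
  if (any(pair_of[j] == j)) stop("CT position paired with itself")
  structure(list(length = n, pair_of = pair_of),
            class = "secondary_structure")
}

.parse_dotbracket <- function(lines) {
  lines <- lines[!startsWith(lines, ">")]
  is_struct <- grepl("^[.()\\[\\]{}<>A-Za-z]+$", lines, perl = TRUE) &
    grepl("[.()]", lines) & !grepl("^[ACGTUNacgtun]+$", lines)
  db <- lines[is_struct]
  if (!length(db)) stop("no dot-bracket line found")
  db <- db[length(db)]
  if (grepl("[^.()]", db)) {
    stop("unsupported symbol '", sub("^[.()]*", "", db) |> substr(1, 1),
         "' in dot-bracket: only nested '()' pairs are supported ",
         "(pseudoknot notation is not)")
  }
  chars <- strsplit(db, "")[[1]]
  n <- length(chars)
  pair_of <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (chars[i] == "(") {
      stack <- c(stack, i)
    } else if (chars[i] == ")") {
      if (!length(stack)) stop("unbalanced ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pair_of[i] <- j
      pair_of[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced '(' at position ", stack[1])
  structure(list(length = n, pair_of = pair_of),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat("secondary_structure: ", x$length, " nt, ",
      sum(!is.na(x$pair_of)) %/% 2L, " base pairs\n", sep = "")
  invisible(x)
}

#' Parse per-nucleotide 3D coordinates from a PDB file
#'
#' Extracts ATOM records for one chain and renumbers residues by an explicit
#' offset so that residue numbers align with reference positions. An explicit
#' offset (rather than heuristic mapping) is required because silent
#' misalignment corrupts every downstream distance.
#'
#' @param path PDB file.
#' @param chain Chain identifier; `NULL` uses all chains (single-chain files).
#' @param residue_offset Integer added to every PDB residue number.
#' @return An object of class `tertiary_coordinates`: a `data.table` with
#'   columns `resno` (offset applied), `resid`, `atom`, `x`, `y`, `z`.
#'   Residues missing particular atoms are kept; distance functions handle
#'   absence.
#' @export
parse_tertiary_coordinates <- function(path, chain = NULL, residue_offset = 0L) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% at$chain) stop("chain '", chain, "' not present in ", path)
    at <- at[at$chain == chain, , drop = FALSE]
  }
  dt <- data.table(
    resno = as.integer(at$resno) + as.integer(residue_offset),
    resid = as.character(at$resid),
    atom  = as.character(at$elety),
    x = at$x, y = at$y, z = at$z
  )
  setkey(dt, resno, atom)
  structure(list(atoms = dt), class = "tertiary_coordinates")
}

#' @export
print.tertiary_coordinates <- function(x, ...) {
  cat("tertiary_coordinates: ", length(unique(x$atoms$resno)),
      " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  invisible(x)
}

#' Residue numbers resolved in a coordinate set
#' @param coords A `tertiary_coordinates` object.
#' @return Sorted integer vector of residue numbers.
#' @export
resolved_residues <- function(coords) {
  sort(unique(coords$atoms$resno))
}
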