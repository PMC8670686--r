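#' Classify one detected deletion against its encoded truth
#'
#' `exact` when both sites equal the encoded sites; `close` when both sites
#' are within `tol` nucleotides of the encoded sites (and not exact);
#' `incorrect` otherwise.
#'
#' @param five,three Detected sites (vectors).
#' @param truth_five,truth_three Encoded sites.
#' @param tol Close-match tolerance in nucleotides.
#' @return Character vector in `{"exact", "close", "incorrect"}`.
#' @export
classify_deletion_accuracy <- function(five, three, truth_five, truth_three,
                                       tol = 3L) {
  exact <- five == truth_five & three == truth_three
  close <- !exact & abs(five - truth_five) <= tol &
    abs(three - truth_three) <= tol
  ifelse(exact, "exact", ifelse(close, "close", "incorrect"))
}

#' Score detected deletions against a truth table
#'
#' Each truth read contributes its best detection (exact beats close beats
#' incorrect); reads with no detection are tallied as undetected.
#' Percentages are over all truth reads. A per-site positive-predictive
#' value map (fraction of detections at each `(five, three)` that are
#' exact) is included for interaction-map export.
#'
#' @param detections Deletion table (`read_id`, `five`, `three`) or a
#'   `deletion_calls` object.
#' @param truth Truth table with `read_id`, `encoded_five`, `encoded_three`.
#' @param tol Close-match tolerance.
#' @return An `accuracy_report`: counts and percentages for
#'   exact/close/incorrect/undetected, plus the `ppv` table.
#' @export
score_dataset <- function(detections, truth, tol = 3L) {
  if (inherits(detections, "deletion_calls")) detections <- detections$deletions
  det <- as.data.table(detections)
  truth <- as.data.table(truth)
  n_reads <- nrow(truth)
  if (nrow(det)) {
    unknown <- setdiff(det$read_id, truth$read_id)
    if (length(unknown)) {
      stop("detection for read '", unknown[1], "' absent from the truth table")
    }
    det <- truth[det, on = "read_id"]
    det[, category := classify_deletion_accuracy(five, three, encoded_five,
                                                 encoded_three, tol)]
    rank <- c(exact = 1L, close = 2L, incorrect = 3L)
    best <- det[, .(category = category[which.min(rank[category])]),
                by = read_id]
    counts <- c(exact = sum(best$category == "exact"),
                close = sum(best$category == "close"),
                incorrect = sum(best$category == "incorrect"))
    ppv <- det[, .(n = .N, ppv = mean(category == "exact")),
               by = .(five, three)]
  } else {
    counts <- c(exact = 0L, close = 0L, incorrect = 0L)
    ppv <- data.table(five = integer(), three = integer(), n = integer(),
                      ppv = numeric())
  }
  n_detected <- sum(counts)
  counts <- c(counts, undetected = n_reads - n_detected)
  structure(list(n_reads = n_reads, n_detected = n_detected,
                 counts = counts,
                 percentages = 100 * counts / n_reads,
                 ppv = ppv[]),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("accuracy_report over ", x$n_reads, " reads (",
      x$n_detected, " detected)\n", sep = "")
  print(round(x$percentages, 2))
  invisible(x)
}

# adjacency of the secondary-structure graph: backbone + base-pair edges
.ss_adjacency <- function(ss) {
  n <- ss$length
  adj <- vector("list", n)
  for (k in seq_len(n)) {
    nb <- c(if (k > 1L) k - 1L, if (k < n) k + 1L, ss$pair_of[k])
    adj[[k]] <- nb[!is.na(nb)]
  }
  adj
}

.bfs_dist <- function(adj, src) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[src] <- 0L
  queue <- src
  while (length(queue)) {
    nxt <- integer(0)
    for (v in queue) {
      for (w in adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    queue <- nxt
  }
  dist
}

#' Contact distance between nucleotides in a secondary structure
#'
#' The length of the shortest path between two nucleotides in the graph
#' whose unit edges connect backbone neighbors (`k`, `k+1`) and base pairs
#' (`k`, `pair_of[k]`) — the sequence distance "after omitting nested
#' helices", since a helix is traversed in about one step via its pair
#' edges. Symmetric; zero only for `i == j`.
#'
#' @param i,j Integer position vectors (recycled).
#' @param ss A `secondary_structure`.
#' @return Integer vector of shortest-path lengths.
#' @export
contact_distance <- function(i, j, ss) {
  stopifnot(all(i >= 1L), all(j >= 1L), all(i <= ss$length),
            all(j <= ss$length))
  pp <- data.table(i = as.integer(i), j = as.integer(j))
  adj <- .ss_adjacency(ss)
  out <- integer(nrow(pp))
  for (src in unique(pp$i)) {
    d <- .bfs_dist(adj, src)
    sel <- pp$i == src
    out[sel] <- d[pp$j[sel]]
  }
  out
}

#' Tertiary-contact classifier thresholds
#'
#' A nucleotide pair counts as a tertiary contact when its
#' three-dimensional distance is below `max_angstroms` and its contact
#' distance exceeds `min_contact_distance` — close in space but not merely
#' adjacent in the secondary structure.
#'
#' @param max_angstroms Three-dimensional distance threshold (Angstrom).
#' @param min_contact_distance Minimum contact distance.
#' @param anchor Distance anchor: ribose `"O2'"` or `"base_center"`.
#' @return A `contact_classifier` list.
#' @export
contact_classifier <- function(max_angstroms = 15, min_contact_distance = 10L,
                               anchor = c("O2'", "base_center")) {
  stopifnot(max_angstroms > 0, min_contact_distance > 0)
  structure(list(max_angstroms = max_angstroms,
                 min_contact_distance = as.integer(min_contact_distance),
                 anchor = match.arg(anchor)),
            class = "contact_classifier")
}

.PURINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6", "N7", "C8", "N9")
.PYRIMIDINE_RING <- c("N1", "C2", "N3", "C4", "C5", "C6")

# one (x, y, z) anchor point per residue; NA rows where unresolvable
anchor_points <- function(coords, anchor = "O2'") {
  at <- coords$atoms
  if (anchor == "O2'") {
    pts <- at[atom %in% c("O2'", "O2*"), .(x = x[1], y = y[1], z = z[1]),
              by = resno]
  } else {
    base1 <- toupper(substr(at$resid, 1, 1))
    at2 <- copy(at)[, purine := base1 %in% c("A", "G")]
    ring <- at2[(purine & atom %in% .PURINE_RING) |
                  (!purine & atom %in% .PYRIMIDINE_RING)]
    pts <- ring[, {
      need <- if (purine[1]) .PURINE_RING else .PYRIMIDINE_RING
      if (all(need %in% atom)) {
        .(x = mean(x), y = mean(y), z = mean(z))
      } else {
        .(x = NA_real_, y = NA_real_, z = NA_real_)
      }
    }, by = resno]
  }
  setkey(pts, resno)
  pts
}

#' Three-dimensional distance between two nucleotides
#'
#' Euclidean distance between per-residue anchor points: ribose 2'-hydroxyl
#' oxygens (`"O2'"`), or the centroid of the base-ring heavy atoms
#' (`"base_center"`: N1,C2,N3,C4,C5,C6 plus N7,C8,N9 for purines). `NA`
#' when a residue or a required atom is missing; such pairs are excluded
#' from downstream statistics.
#'
#' @param i,j Residue numbers (vectors, recycled).
#' @param coords A `tertiary_coordinates`.
#' @param anchor `"O2'"` or `"base_center"`.
#' @return Numeric vector of distances in Angstrom (`NA` where absent).
#' @export
spatial_distance <- function(i, j, coords, anchor = "O2'") {
  pts <- anchor_points(coords, anchor)
  a <- pts[data.table(resno = as.integer(i)), on = "resno"]
  b <- pts[data.table(resno = as.integer(j)), on = "resno"]
  sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
}

#' Observed vs background three-dimensional distance distributions
#'
#' @param profile A `deletion_profile`.
#' @param coords A `tertiary_coordinates` aligned to the reference.
#' @param anchor `"O2'"` or `"base_center"`.
#' @param fraction Top fraction of deletions (by rate) to observe.
#' @return List with `observed` (distances of the selected deletions;
#'   unresolvable pairs dropped, count in `n_unresolved`) and `background`
#'   (distances over all resolved position pairs).
#' @export
distance_distribution <- function(profile, coords, anchor = "O2'",
                                  fraction = 0.03) {
  top <- select_top_fraction(profile, fraction)
  obs <- spatial_distance(top$entries$five, top$entries$three, coords, anchor)
  pts <- anchor_points(coords, anchor)
  pts <- pts[!is.na(x)]
  bg <- if (nrow(pts) >= 2L) {
    as.numeric(stats::dist(as.matrix(pts[, .(x, y, z)])))
  } else {
    numeric(0)
  }
  list(observed = obs[!is.na(obs)], n_unresolved = sum(is.na(obs)),
       background = bg)
}

#' ROC curve and AUC for tertiary-contact recovery
#'
#' Profile entries are labeled positive when they satisfy the
#' tertiary-contact classifier (3D distance below `max_angstroms` AND
#' contact distance above `min_contact_distance`), ranked by `net_rate`
#' (falling back to `normalized_rate` when net rates are absent), and the
#' true/false positive rates are swept over all distinct rate thresholds.
#' Tied rates enter together, so a profile with one constant rate scores
#' exactly 0.5. Entries whose 3D distance is unresolvable are excluded.
#'
#' @param profile A `deletion_profile`.
#' @param ss A `secondary_structure`.
#' @param coords A `tertiary_coordinates`.
#' @param classifier A [contact_classifier()].
#' @return List with `points` (`data.table` of threshold, fpr, tpr), `auc`
#'   (trapezoidal; `NA` with a `reason` when only one class is present),
#'   `n_pos`, `n_neg`, `n_excluded`.
#' @export
roc_auc <- function(profile, ss, coords, classifier = contact_classifier()) {
  e <- copy(profile$entries)
  score <- if (all(is.na(e$net_rate))) e$normalized_rate else e$net_rate
  sd3 <- spatial_distance(e$five, e$three, coords, classifier$anchor)
  keep <- !is.na(sd3) & !is.na(score)
  n_excluded <- sum(!keep)
  e <- e[keep]
  score <- score[keep]
  sd3 <- sd3[keep]
  if (!nrow(e)) {
    return(list(points = NULL, auc = NA_real_, reason = "no scorable entries",
                n_pos = 0L, n_neg = 0L, n_excluded = n_excluded))
  }
  cd <- contact_distance(e$five, e$three, ss)
  pos <- sd3 < classifier$max_angstroms & cd > classifier$min_contact_distance
  P <- sum(pos)
  N <- sum(!pos)
  if (P == 0L || N == 0L) {
    return(list(points = NULL, auc = NA_real_,
                reason = "need both positive and negative entries",
                n_pos = P, n_neg = N, n_excluded = n_excluded))
  }
  thr <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(thr, function(s) sum(pos & score >= s) / P, numeric(1))
  fpr <- vapply(thr, function(s) sum(!pos & score >= s) / N, numeric(1))
  fpr <- c(0, fpr)
  tpr <- c(0, tpr)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(points = data.table(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auc = auc, n_pos = P, n_neg = N, n_excluded = n_excluded)
}

#' AUC grid over 5'/3' site shifts
#'
#' Applies every combination of 5' shift (3' direction) and 3' shift
#' (5' direction) in `shifts` to an unshifted profile and scores
#' tertiary-contact recovery; used to read off the reverse-transcriptase
#' landing offset as the argmax of the grid.
#'
#' @param profile An unshifted `deletion_profile`.
#' @inheritParams roc_auc
#' @param shifts Integer shift values (default 0-5 in each direction).
#' @return List with `grid` (matrix, rows = 5' shift, cols = 3' shift) and
#'   `best` (named vector `shift_5p`, `shift_3p` of the argmax; earliest in
#'   row-major order on ties).
#' @export
shift_grid_auc <- function(profile, ss, coords,
                           classifier = contact_classifier(),
                           shifts = 0:5) {
  grid <- matrix(NA_real_, length(shifts), length(shifts),
                 dimnames = list(shift_5p = shifts, shift_3p = shifts))
  for (a in seq_along(shifts)) {
    for (b in seq_along(shifts)) {
      sh <- shift_sites(profile, shift_config(shifts[a], shifts[b]))
      grid[a, b] <- roc_auc(sh, ss, coords, classifier)$auc
    }
  }
  best_idx <- which(grid == max(grid, na.rm = TRUE), arr.ind = TRUE)[1, ]
  list(grid = grid,
       best = c(shift_5p = shifts[best_idx[1]], shift_3p = shifts[best_idx[2]]))
}

#' Summary statistics of a deletion profile
#'
#' @param profile A `deletion_profile`.
#' @param deletions Optional per-read deletion table (adds the
#'   insertion-length histogram).
#' @param top_n Rows in the top-deletion table.
#' @param path Optional path prefix; writes `<prefix>.length_hist.tsv`,
#'   `<prefix>.rate_hist.tsv`, `<prefix>.top.tsv` (and
#'   `<prefix>.insertion_hist.tsv` when available).
#' @return List of summary `data.table`s.
#' @export
summary_stats <- function(profile, deletions = NULL, top_n = 20L,
                          path = NULL) {
  e <- profile$entries
  length_hist <- e[, .(n = sum(count)), by = .(length = three - five - 1L)]
  setorder(length_hist, length)
  rate <- if (all(is.na(e$net_rate))) e$normalized_rate else e$net_rate
  rate_hist <- if (nrow(e)) {
    h <- graphics::hist(rate, breaks = "Sturges", plot = FALSE)
    data.table(bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
               n = h$counts)
  } else {
    data.table(bin_lo = numeric(), bin_hi = numeric(), n = integer())
  }
  top <- copy(e)
  top[, rate := rate]
  setorder(top, -rate, five, three)
  top <- head(top, top_n)
  out <- list(length_hist = length_hist, rate_hist = rate_hist, top = top)
  if (!is.null(deletions)) {
    if (inherits(deletions, "deletion_calls")) deletions <- deletions$deletions
    ih <- as.data.table(deletions)[, .N, by = .(insertion_length)]
    setorder(ih, insertion_length)
    out$insertion_hist <- ih
  }
  if (!is.null(path)) {
    for (nm in names(out)) {
      fwrite(out[[nm]], paste0(path, ".", sub("_hist", "_hist", nm), ".tsv"),
             sep = "\t")
    }
  }
  out
}
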