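test_that("accuracy classification distinguishes exact, close and incorrect", {
  expect_equal(classify_deletion_accuracy(50L, 120L, 50L, 120L), "exact")
  expect_equal(classify_deletion_accuracy(48L, 123L, 50L, 120L), "close")
  expect_equal(classify_deletion_accuracy(45L, 120L, 50L, 120L), "incorrect")
  expect_equal(classify_deletion_accuracy(c(50L, 47L), c(120L, 120L),
                                          50L, 120L),
               c("exact", "close"))
})

test_that("dataset scoring takes each read's best detection and tallies undetected", {
  truth <- data.table::data.table(
    read_id = sprintf("r%d", 1:10),
    encoded_five = rep(50L, 10), encoded_three = rep(120L, 10))
  det <- data.table::data.table(
    read_id = c("r1", "r2", "r2", "r3", "r4", "r5", "r6", "r7"),
    five = c(50L, 45L, 50L, 52L, 50L, 49L, 40L, 50L),
    three = c(120L, 120L, 120L, 121L, 120L, 126L, 100L, 120L))
  rep <- score_dataset(det, truth)
  # by hand: r1 exact; r2 best = exact; r3 close; r4 exact; r5 incorrect
  # (|d3| = 6); r6 incorrect; r7 exact; r8-r10 undetected
  expect_equal(unname(rep$counts),
               c(4L, 1L, 2L, 3L))
  expect_equal(sum(rep$percentages), 100)
  expect_equal(rep$n_detected, 7L)
  # ppv map: site (50,120) has 4 detections, all exact
  ppv <- rep$ppv[rep$ppv$five == 50L & rep$ppv$three == 120L]
  expect_equal(ppv$n, 4L)
  expect_equal(ppv$ppv, 1)

  expect_error(score_dataset(
    data.table::data.table(read_id = "zz", five = 1L, three = 20L), truth),
    "absent from the truth")

  none <- score_dataset(det[0], truth)
  expect_equal(unname(none$counts), c(0L, 0L, 0L, 10L))
})

test_that("contact distance follows backbone and pair edges", {
  # hairpin: pairs (1,20)...(5,16)
  ss <- secondary_structure(cbind(1:5, 20:16), 20L)
  expect_equal(contact_distance(3L, 4L, ss), 1L)      # backbone
  expect_equal(contact_distance(1L, 20L, ss), 1L)     # direct pair edge
  expect_equal(contact_distance(6L, 15L, ss), 3L)     # 6-5, 5-16, 16-15
  expect_equal(contact_distance(7L, 7L, ss), 0L)
  expect_equal(contact_distance(6L, 15L, ss), contact_distance(15L, 6L, ss))
})

test_that("contact distance equals the independent graph shortest path", {
  set.seed(8)
  for (trial in 1:10) {
    n <- sample(50:200, 1)
    # random nested structure: repeatedly pair an enclosing interval
    pair_of <- rep(NA_integer_, n)
    for (k in 1:40) {
      i <- sample(1:(n - 3), 1)
      j <- sample((i + 2):min(n, i + 40), 1)
      if (is.na(pair_of[i]) && is.na(pair_of[j])) {
        pair_of[i] <- j
        pair_of[j] <- i
      }
    }
    pairs <- cbind(which(!is.na(pair_of) & seq_len(n) < pair_of),
                   pair_of[!is.na(pair_of) & seq_len(n) < pair_of])
    ss <- secondary_structure(pairs, n)
    # igraph oracle
    edges <- rbind(cbind(1:(n - 1), 2:n), pairs)
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    probe <- data.table::data.table(i = sample(n, 30, replace = TRUE),
                                    j = sample(n, 30, replace = TRUE))
    got <- contact_distance(probe$i, probe$j, ss)
    want <- vapply(seq_len(30), function(k) {
      as.integer(igraph::distances(g, probe$i[k], probe$j[k]))
    }, integer(1))
    expect_equal(got, want)
  }
})

test_that("spatial distances use the requested anchor and handle missing atoms", {
  p <- write_pdb_fixture(c(1L, 2L), matrix(c(0, 0, 0, 3, 4, 0), 2,
                                           byrow = TRUE))
  co <- parse_tertiary_coordinates(p)
  expect_equal(spatial_distance(1L, 2L, co), 5)
  expect_equal(spatial_distance(1L, 1L, co), 0)
  expect_true(is.na(spatial_distance(1L, 3L, co)))  # residue absent

  # base-center anchor: centroid of the pyrimidine ring atoms
  ring <- c("N1", "C2", "N3", "C4", "C5", "C6")
  xyz <- cbind(seq(0, 5), 0, 0)
  p2 <- write_pdb_fixture(rep(1L, 6), xyz, atom = ring, resid = "C")
  co2 <- parse_tertiary_coordinates(p2)
  pts <- jumpdel:::anchor_points(co2, "base_center")
  expect_equal(pts$x, 2.5)
  # incomplete ring: anchor unresolvable
  p3 <- write_pdb_fixture(rep(1L, 5), xyz[1:5, , drop = FALSE],
                          atom = ring[1:5], resid = "C")
  expect_true(is.na(jumpdel:::anchor_points(
    parse_tertiary_coordinates(p3), "base_center")$x))
})

test_that("distance distributions report observed vs all-pairs background", {
  toy <- make_toy_structure(60L, seed = 12L)
  prof <- deletion_profile(data.table::data.table(
    five = c(5L, 10L), three = c(40L, 50L), count = c(5L, 1L), depth = 100,
    normalized_rate = c(0.05, 0.01), net_rate = c(0.05, 0.01)),
    ref_name = "ref", ref_length = 60L)
  dd <- distance_distribution(prof, toy$coords, fraction = 1)
  expect_length(dd$observed, 2L)
  expect_length(dd$background, choose(60, 2))
  dd1 <- distance_distribution(prof, toy$coords, fraction = 0.5)
  expect_length(dd1$observed, 1L)
})

test_that("ROC AUC equals the concordant-pair formulation and handles ties", {
  toy <- make_toy_structure(100L, seed = 5L)
  ss <- toy$ss
  co <- toy$coords
  set.seed(10)
  for (trial in 1:20) {
    n <- sample(10:60, 1)
    five <- sample(1:80, n, replace = TRUE)
    three <- five + sample(12:19, n, replace = TRUE)
    keep <- three <= 100
    five <- five[keep]
    three <- three[keep]
    if (length(five) < 4) next
    rates <- sample(seq(0.01, 0.2, by = 0.01), length(five), replace = TRUE)
    prof <- deletion_profile(data.table::data.table(
      five = five, three = three, count = 1L, depth = 100,
      normalized_rate = rates, net_rate = rates)[!duplicated(
        paste(five, three))],
      ref_name = "ref", ref_length = 100L)
    r <- roc_auc(prof, ss, co)
    e <- prof$entries
    sd3 <- spatial_distance(e$five, e$three, co)
    cd <- contact_distance(e$five, e$three, ss)
    label <- sd3 < 15 & cd > 10
    if (is.na(r$auc)) {
      expect_true(sum(label) == 0 || sum(!label) == 0)
    } else {
      expect_equal(r$auc, roc_oracle(e$net_rate, label), tolerance = 1e-12)
      # invariance under strictly monotone transforms of the rate
      prof2 <- prof
      prof2$entries <- data.table::copy(prof$entries)
      prof2$entries[, net_rate := exp(3 * net_rate)]
      expect_equal(roc_auc(prof2, ss, co)$auc, r$auc, tolerance = 1e-12)
    }
  }
})

test_that("ROC degenerate cases: perfect ranking gives 1, constant rates give 0.5", {
  toy <- make_toy_structure(100L, seed = 6L)
  e <- data.table::data.table(five = sample(1:70, 40), count = 1L, depth = 100)
  e[, three := five + 15L]
  sd3 <- spatial_distance(e$five, e$three, toy$coords)
  cd <- contact_distance(e$five, e$three, toy$ss)
  label <- sd3 < 15 & cd > 10
  if (sum(label) >= 1 && sum(!label) >= 1) {
    e[, normalized_rate := ifelse(label, 0.2, 0.01)]
    e[, net_rate := normalized_rate]
    prof <- deletion_profile(e, ref_name = "ref", ref_length = 100L)
    expect_equal(roc_auc(prof, toy$ss, toy$coords)$auc, 1)
    e2 <- data.table::copy(e)[, net_rate := 0.05][, normalized_rate := 0.05]
    prof2 <- deletion_profile(e2, ref_name = "ref", ref_length = 100L)
    expect_equal(roc_auc(prof2, toy$ss, toy$coords)$auc, 0.5)
  }
  # explicit concordant-pair worked example: scores .9 .8 .7 .6,
  # labels + - + -  ->  AUC 0.75
  expect_equal(roc_oracle(c(0.9, 0.8, 0.7, 0.6), c(TRUE, FALSE, TRUE, FALSE)),
               0.75)
})

test_that("shift grid recovers a planted -2 offset of the 5' sites", {
  toy <- make_toy_structure(120L, seed = 20L)
  ss <- toy$ss
  co <- toy$coords
  # true contacts: pairs satisfying the classifier
  cand <- data.table::CJ(five = 5:110, three = 5:110)
  cand <- cand[three - five > 11]
  sd3 <- spatial_distance(cand$five, cand$three, co)
  cd <- contact_distance(cand$five, cand$three, ss)
  pos <- which(sd3 < 15 & cd > 10)
  neg <- which(!(sd3 < 15 & cd > 10))
  expect_gt(length(pos), 20L)
  set.seed(21)
  take_p <- sample(pos, min(40, length(pos)))
  take_n <- sample(neg, 60)
  e <- cand[c(take_p, take_n)]
  e[, count := 1L]
  e[, depth := 100]
  e[, normalized_rate := c(runif(length(take_p), 0.1, 0.2),
                           runif(length(take_n), 0.001, 0.02))]
  e[, net_rate := normalized_rate]
  # encode the RT landing offset: reported 5' sites sit 2 nt upstream
  e[, five := five - 2L]
  e <- e[!duplicated(paste(five, three))]
  prof <- deletion_profile(e, ref_name = "ref", ref_length = 120L)
  grid <- shift_grid_auc(prof, ss, co)
  expect_equal(dim(grid$grid), c(6L, 6L))
  expect_equal(unname(grid$best), c(2L, 0L))
})

test_that("profile summaries histogram lengths, rates and insertions", {
  prof <- deletion_profile(data.table::data.table(
    five = c(10L, 30L, 60L), three = c(111L, 131L, 161L),
    count = c(1L, 2L, 3L), depth = 100,
    normalized_rate = c(0.01, 0.02, 0.03), net_rate = c(0.01, 0.02, 0.03)),
    ref_name = "ref", ref_length = 400L)
  s <- summary_stats(prof, deletions = data.table::data.table(
    insertion_length = c(0L, 0L, 4L)))
  expect_equal(s$length_hist$length, 100L)
  expect_equal(s$length_hist$n, 6L)
  expect_equal(s$insertion_hist$N, c(2L, 1L))
  expect_equal(nrow(s$top), 3L)
  expect_equal(s$top$rate[1], 0.03)
})
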