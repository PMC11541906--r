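# brute-force oracles used below
naive_moving_average <- function(x, window) {
  half <- (window - 1) / 2
  vapply(seq_along(x), function(i) {
    lo <- max(1, i - half)
    hi <- min(length(x), i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

naive_cnv_scores <- function(states, cluster_of) {
  gene_scores <- abs(states - 3)
  spot <- rowSums(gene_scores)
  clusters <- sort(unique(cluster_of))
  d <- vapply(clusters, function(k) {
    member <- cluster_of == k
    total <- 0
    for (g in seq_len(ncol(states))) {
      total <- total + mean(gene_scores[member, g])
    }
    total
  }, numeric(1))
  list(spot = spot, cluster = setNames(d, clusters))
}

test_that("relative expression is reference-centered, filtered and clipped", {
  nm <- tiny_nm(seed = 1)
  ref <- nm$barcodes[1:40]
  rel <- compute_relative_expression(nm, ref)
  # centering check before clipping: recompute directly
  keep <- nm$mean_counts >= 0.1
  v <- as.matrix(nm$values[, keep])
  centered <- sweep(v, 2, colMeans(v[nm$barcodes %in% ref, ]))
  expect_true(max(abs(colMeans(centered[nm$barcodes %in% ref, , drop = FALSE]))) <
                1e-9)
  expect_true(all(rel >= -0.3 & rel <= 0.3))
  # gene filter: a gene below the cutoff disappears
  expect_true(all(colnames(rel) %in% nm$genes[keep]))
  expect_error(compute_relative_expression(nm, ref, cutoff = 1e9),
               "cutoff")
  expect_error(compute_relative_expression(nm, character()), "non-empty")
})

test_that("chromosome smoothing matches the brute-force moving average", {
  gp <- gene_position_table(data.frame(
    gene = sprintf("g%02d", 1:30),
    chrom = rep(c("chr1", "chr2"), c(20, 10)),
    start = c(1:20, 1:10) * 100, end = c(1:20, 1:10) * 100 + 50))
  set.seed(8)
  rel <- matrix(rnorm(5 * 30), 5, 30,
                dimnames = list(sprintf("s%d", 1:5), sprintf("g%02d", 1:30)))
  for (w in c(1, 5, 11)) {
    sm <- smooth_along_chromosome(rel, gp, window = w)
    for (i in 1:5) {
      expect_equal(sm[i, sprintf("g%02d", 1:20)],
                   setNames(naive_moving_average(rel[i, 1:20], w),
                            sprintf("g%02d", 1:20)))
      expect_equal(sm[i, sprintf("g%02d", 21:30)],
                   setNames(naive_moving_average(rel[i, 21:30], w),
                            sprintf("g%02d", 21:30)))
    }
  }
  # constant row unchanged; single-gene chromosome untouched
  flat <- matrix(0.2, 2, 30, dimnames = dimnames(rel[1:2, ]))
  expect_equal(unname(smooth_along_chromosome(flat, gp, 11)),
               unname(flat))
  expect_error(smooth_along_chromosome(rel, gp, window = 4), "odd")
})

test_that("a step profile is recovered as a plateau near the breakpoints", {
  gp <- gene_position_table(data.frame(
    gene = sprintf("g%03d", 1:100), chrom = "chr1",
    start = 1:100 * 10, end = 1:100 * 10 + 5))
  x <- rep(0, 100)
  x[40:70] <- 0.3
  sm <- smooth_along_chromosome(matrix(x, 1, 100,
                                       dimnames = list("s1",
                                                       sprintf("g%03d", 1:100))),
                                gp, window = 11)
  # inside the segment, away from breakpoints by window/2: full plateau
  expect_true(all(abs(sm[1, 46:65] - 0.3) < 1e-12))
  expect_true(all(abs(sm[1, 1:34]) < 1e-12))
})

test_that("state discretization anchors neutral at 3 with ordered bins", {
  m <- matrix(c(0, 0.05, -0.05, 0.1, -0.1, 0.15, 0.2, 0.25, 0.3, -0.2,
                -0.25, -0.3), 1)
  s <- discretize_states(m)
  expect_identical(as.integer(s),
                   c(3L, 3L, 3L, 4L, 2L, 4L, 5L, 5L, 6L, 1L, 1L, 1L))
  expect_identical(discretize_states(matrix(0, 1, 1))[1, 1], 3L)
  expect_identical(discretize_states(matrix(99, 1, 1))[1, 1], 6L)
  expect_error(discretize_states(m, thresholds = c(1, 2, 3, 2, 5)),
               "increasing")
})

test_that("CNV scores match the brute-force implementation exactly", {
  one <- matrix(c(1L, 6L, 3L), 1, dimnames = list("s1", c("a", "b", "c")))
  lab <- tibble::tibble(barcode = "s1", cnv_cluster = "1")
  sc <- cnv_scores(one, lab)
  expect_equal(sc$gene$mean_score, c(2, 3, 0))
  expect_equal(sc$spot$cnv_score, 5)

  set.seed(11)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    g <- sample(3:9, 1)
    states <- matrix(sample(1:6, n * g, TRUE), n, g,
                     dimnames = list(sprintf("s%d", 1:n),
                                     sprintf("g%d", 1:g)))
    cluster_of <- sample(c("1", "2"), n, TRUE)
    cluster_of[1:2] <- c("1", "2")
    labels <- tibble::tibble(barcode = rownames(states),
                             cnv_cluster = cluster_of)
    got <- cnv_scores(states, labels)
    want <- naive_cnv_scores(states, cluster_of)
    expect_equal(got$spot$cnv_score, unname(want$spot))
    expect_equal(setNames(got$cluster$cnv_score, got$cluster$cnv_cluster),
                 want$cluster)
    # duplicating every spot leaves cluster scores unchanged
    dup <- rbind(states, states)
    rownames(dup) <- c(rownames(states), paste0(rownames(states), "b"))
    dlab <- tibble::tibble(barcode = rownames(dup),
                           cnv_cluster = rep(cluster_of, 2))
    got2 <- cnv_scores(dup, dlab)
    expect_equal(got2$cluster$cnv_score, got$cluster$cnv_score)
  }

  allneutral <- cnv_scores(matrix(3L, 4, 5,
                                  dimnames = list(sprintf("s%d", 1:4),
                                                  sprintf("g%d", 1:5))),
                           tibble::tibble(barcode = sprintf("s%d", 1:4),
                                          cnv_cluster = "1"))
  expect_true(all(allneutral$spot$cnv_score == 0))
})

test_that("subclustering separates planted CNV groups and honors k", {
  set.seed(4)
  prof <- rbind(matrix(rnorm(20 * 10, 0, 0.02), 20, 10),
                matrix(rnorm(20 * 10, 0.25, 0.02), 20, 10))
  rownames(prof) <- sprintf("s%02d", 1:40)
  colnames(prof) <- sprintf("g%d", 1:10)
  lab <- subcluster_spots(prof, k = 2)
  expect_equal(ari(lab$cnv_cluster, rep(1:2, each = 20)), 1.0)

  singletons <- subcluster_spots(prof, k = 40)
  expect_identical(length(unique(singletons$cnv_cluster)), 40L)

  withref <- subcluster_spots(prof, k = 2,
                              reference_barcodes = sprintf("s%02d", 1:5))
  expect_identical(sum(withref$cnv_cluster == "reference"), 5L)
  expect_identical(formals(subcluster_spots)$k, 8)
  expect_error(subcluster_spots(prof, k = 0), "positive")
})

test_that("tumor-cluster calling follows the theta rule and its fallback", {
  sc <- tibble::tibble(cnv_cluster = c("1", "2", "3"),
                       cnv_score = c(0, 0, 10))
  expect_identical(call_tumor_clusters(sc)$malignant, c(FALSE, FALSE, TRUE))

  equal <- tibble::tibble(cnv_cluster = c("1", "2", "3"),
                          cnv_score = c(4, 4, 4))
  expect_warning(res <- call_tumor_clusters(equal), "tied")
  expect_false(any(res$malignant))

  zeros <- tibble::tibble(cnv_cluster = c("1", "2"), cnv_score = c(0, 0))
  expect_warning(resz <- call_tumor_clusters(zeros), "zero")
  expect_false(any(resz$malignant))

  # unique top cluster below theta x median still flagged by the fallback
  mild <- tibble::tibble(cnv_cluster = c("1", "2"), cnv_score = c(1, 1.5))
  expect_identical(call_tumor_clusters(mild)$malignant, c(FALSE, TRUE))

  # reference never malignant
  withref <- tibble::tibble(cnv_cluster = c("reference", "1", "2"),
                            cnv_score = c(50, 0, 10))
  expect_identical(call_tumor_clusters(withref)$malignant,
                   c(FALSE, FALSE, TRUE))
})

test_that("planted gains drive states above neutral in tumor spots", {
  sim <- tiny_sim(seed = 9)
  nm <- tiny_nm(seed = 9)
  cl <- cluster_spots(nm)
  imm <- score_signature(nm, bundled_signature("immune_panel"))
  refb <- cl$barcode[cl$cluster == select_reference_cluster(imm, cl)]
  rel <- compute_relative_expression(nm, refb)
  lab <- sim$truth$spot_labels
  tumor_b <- lab$barcode[lab$label == "tumor"]
  gain <- names(sim$truth$gene_multiplier)[sim$truth$gene_multiplier == 2]
  gain <- intersect(gain, colnames(rel))
  # positive mean relative expression over the gained segment in tumor spots
  expect_gt(mean(rel[rownames(rel) %in% tumor_b, gain]), 0.05)
  # window chosen at the fixture's chromosome scale (50 genes/chromosome)
  sm <- smooth_along_chromosome(rel, sim$gene_positions, window = 21)
  st <- discretize_states(sm)
  frac_gain <- mean(st[rownames(st) %in% tumor_b,
                       intersect(gain, colnames(st))] > 3)
  expect_gt(frac_gain, 0.7)
})

test_that("end-to-end malignant-spot recovery succeeds on one sample", {
  res <- malignant_recovery_study(n_seeds = 2, seed = 7)
  expect_true(all(res$sensitivity >= 0.9))
  expect_true(all(res$specificity >= 0.9))
})
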