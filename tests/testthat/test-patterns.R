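test_that("boundary rings follow lattice adjacency", {
  df <- lattice_df(7, 7)
  df$malignant <- FALSE
  expect_identical(nrow(tumor_boundary(df)), 0L)

  # single malignant spot: inner ring = itself, outer ring = its 4 neighbors
  df1 <- df
  df1$malignant <- df1$array_row == 3 & df1$array_col == 3
  b <- tumor_boundary(df1)
  expect_identical(sum(b$ring == "inner"), 1L)
  expect_identical(sum(b$ring == "outer"), 4L)

  # solid 3x4 rectangle: inner ring = full perimeter 2r + 2c - 4 = 10
  df2 <- df
  df2$malignant <- df2$array_row %in% 2:4 & df2$array_col %in% 1:4
  b2 <- tumor_boundary(df2)
  expect_identical(sum(b2$ring == "inner"), 10L)  # 2r + 2c - 4 for 3 x 4

  # 4-neighborhood boundary is a subset of the 6-neighborhood boundary
  b6 <- tumor_boundary(df2, neighborhood = 6)
  expect_true(all(b2$barcode %in% b6$barcode))
})

test_that("infiltration is classified from the interior high-immune fraction", {
  df <- lattice_df(11, 11)
  center <- df$array_row %in% 3:7 & df$array_col %in% 3:7
  df$malignant <- center
  # all interior tumor spots high -> activation
  df$immune_score <- ifelse(center, 10, 0)
  act <- classify_infiltration(df)
  expect_identical(act$pattern, "activation")
  expect_identical(act$f_intra, 1)

  # immune score only on the outer boundary ring -> exclusion
  b <- tumor_boundary(df)
  outer <- b$barcode[b$ring == "outer"]
  df$immune_score <- ifelse(df$barcode %in% outer, 10, 0)
  exc <- classify_infiltration(df)
  expect_identical(exc$pattern, "exclusion")
  expect_identical(exc$f_intra, 0)
  expect_gt(exc$f_boundary, 0)

  # enclosed non-malignant spots count as tumor area (hole filling)
  hole <- df$array_row == 5 & df$array_col == 5
  df$malignant <- center & !hole
  df$immune_score <- ifelse(hole, 10, 0)
  holed <- classify_infiltration(df, f_min = 0.05)
  expect_identical(holed$pattern, "activation")

  # a tumor that is all boundary has no interior
  df3 <- lattice_df(5, 5)
  df3$malignant <- df3$array_row == 2 & df3$array_col == 2
  df3$immune_score <- 1
  expect_error(classify_infiltration(df3), "interior")
})

test_that("raising interior immune scores never flips activation to exclusion", {
  set.seed(21)
  for (rep in 1:20) {
    df <- lattice_df(9, 9)
    df$malignant <- df$array_row %in% 2:6 & df$array_col %in% 2:6
    df$immune_score <- runif(nrow(df))
    before <- classify_infiltration(df)
    # raise every interior score
    area_inner <- tumor_boundary(df)$barcode
    interior <- df$malignant & !(df$barcode %in% area_inner)
    df2 <- df
    df2$immune_score[interior] <- df2$immune_score[interior] + runif(1, 0, 5)
    after <- classify_infiltration(df2)
    if (before$pattern == "activation") {
      expect_identical(after$pattern, "activation")
    }
    expect_gte(after$f_intra, before$f_intra - 1e-12)
  }
})

test_that("co-localization reproduces exact rank correlations", {
  df <- tibble::tibble(a = c(1, 3, 7, 9, 15), b = c(1, 3, 7, 9, 15)^3)
  expect_equal(colocalization(df, a, b)$rho, 1)
  df$b <- -df$a
  expect_equal(colocalization(df, a, b)$rho, -1)

  # invariance under strictly monotone transforms
  set.seed(5)
  big <- tibble::tibble(a = rnorm(50), b = rnorm(50))
  raw <- colocalization(big, a, b)
  tf <- dplyr::mutate(big, a = exp(a), b = b^3)
  expect_equal(colocalization(tf, a, b)$rho, raw$rho, tolerance = 1e-12)
  expect_equal(colocalization(tf, a, b)$p_value, raw$p_value,
               tolerance = 1e-12)

  expect_error(colocalization(tibble::tibble(a = c(1, 1, 1), b = 1:3), a, b),
               "constant")
  expect_error(colocalization(big[1:2, ], a, b), "at least 3")
})

test_that("exact permutation p-value matches the reference distribution", {
  set.seed(6)
  x <- rnorm(7)
  y <- rnorm(7)
  got <- colocalization(tibble::tibble(a = x, b = y), a, b)
  expect_identical(got$method, "exact permutation")
  # independent oracle: AS 89 exact Spearman p from cor.test (no ties, n = 7)
  want <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = TRUE)$p.value)
  expect_equal(got$p_value, want, tolerance = 1e-10)
  expect_gte(got$p_value, 1 / factorial(7))  # attainable resolution
})

test_that("pattern report is complete and byte-stable", {
  sim <- tiny_sim(seed = 2)
  df <- sim$truth$spot_labels
  df$malignant <- df$label == "tumor"
  df$immune_score <- as.numeric(df$label %in% c("boundary_immune",
                                                "intratumor_immune"))
  pr <- classify_infiltration(df)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  rep1 <- pattern_report(df, pr, d1)
  rep2 <- pattern_report(df, pr, d2)
  expect_identical(nrow(rep1$spots), nrow(df))
  expect_identical(rep1$summary$pattern, pr$pattern)
  for (f in c("spot_annotations.tsv", "summary.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})
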