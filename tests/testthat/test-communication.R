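# hand-built normalized matrix: 3 clusters x 4 spots, controlled expression
fake_nm <- function(values, genes) {
  n <- nrow(values)
  structure(list(
    values = Matrix::Matrix(values, sparse = TRUE,
                            dimnames = list(sprintf("s%02d", seq_len(n)),
                                            genes)),
    scale_target = 100, lib_sizes = rep(100, n),
    mean_counts = colMeans(values),
    barcodes = sprintf("s%02d", seq_len(n)), genes = genes,
    positions = NULL
  ), class = "NormalizedMatrix")
}

fake_pairs <- function() {
  tibble::tibble(ligand = c("L1", "L2"),
                 receptor_subunits = list("R1", c("R2a", "R2b")),
                 pathway = c("P1", "P2"))
}

test_that("scores are mass-action products with the min.pct gate", {
  genes <- c("L1", "R1", "L2", "R2a", "R2b")
  v <- matrix(0, 12, 5, dimnames = list(NULL, genes))
  cl <- rep(c("A", "B", "C"), each = 4)
  v[cl == "A", "L1"] <- 2            # ligand in A
  v[cl == "B", "R1"] <- 3            # receptor in B
  v[cl == "B", c("R2a", "R2b")] <- c(1, 1, 1, 1, 4, 4, 4, 4)
  nm <- fake_nm(v, genes)
  labels <- tibble::tibble(barcode = nm$barcodes, cluster = cl)
  it <- lr_scores(nm, labels, fake_pairs())

  expect_equal(it$score[it$sender == "A" & it$receiver == "B" &
                          it$ligand == "L1"], 2 * 3)
  # ligand absent in sender -> 0
  expect_equal(it$score[it$sender == "B" & it$receiver == "B" &
                          it$ligand == "L1"], 0)
  # doubling ligand expression doubles the score (bilinearity)
  v2 <- v
  v2[cl == "A", "L1"] <- 4
  it2 <- lr_scores(fake_nm(v2, genes), labels, fake_pairs())
  expect_equal(it2$score[it2$sender == "A" & it2$receiver == "B" &
                           it2$ligand == "L1"], 2 * 2 * 3)
  # multi-subunit receptor combines by geometric mean: sqrt(1 * 4) = 2
  v3 <- v
  v3[cl == "A", "L2"] <- 1
  it3 <- lr_scores(fake_nm(v3, genes), labels, fake_pairs())
  expect_equal(it3$score[it3$sender == "A" & it3$receiver == "B" &
                           it3$ligand == "L2"], 1 * 2)
  # a zero subunit zeroes the interaction
  expect_equal(it3$score[it3$sender == "A" & it3$receiver == "A" &
                           it3$ligand == "L2"], 0)
})

test_that("min.pct gates rarely detected ligands to zero", {
  genes <- c("L1", "R1")
  v <- matrix(0, 40, 2, dimnames = list(NULL, genes))
  cl <- rep(c("A", "B"), each = 20)
  v[1, "L1"] <- 50                 # 5% of sender spots
  v[cl == "B", "R1"] <- 2
  nm <- fake_nm(v, genes)
  labels <- tibble::tibble(barcode = nm$barcodes, cluster = cl)
  it <- lr_scores(nm, labels, fake_pairs()[1, ])
  expect_equal(it$score[it$sender == "A" & it$receiver == "B"], 0)
  # raising detection above the gate turns the score on
  v[1:10, "L1"] <- 50
  it2 <- lr_scores(fake_nm(v, genes), labels, fake_pairs()[1, ])
  expect_gt(it2$score[it2$sender == "A" & it2$receiver == "B"], 0)
})

test_that("pairs with absent genes are skipped and scores ignore renaming", {
  nm <- tiny_nm(seed = 1)
  labels <- tibble::tibble(barcode = nm$barcodes,
                           cluster = rep(c("x", "y"),
                                         length.out = length(nm$barcodes)))
  pairs <- dplyr::bind_rows(read_lr_pairs(),
                            tibble::tibble(ligand = "NOPE",
                                           receptor_subunits = list("NADA"),
                                           pathway = "Z"))
  expect_message(it <- lr_scores(nm, labels, pairs), "skipped")
  expect_false("NOPE" %in% it$ligand)

  relab <- labels
  relab$cluster <- ifelse(labels$cluster == "x", "cl_1", "cl_2")
  it2 <- lr_scores(nm, relab, read_lr_pairs())
  expect_equal(sort(it$score), sort(it2$score))
})

test_that("permutation p-values respect the add-one floor and determinism", {
  nm <- tiny_nm(seed = 1)
  labels <- tibble::tibble(barcode = nm$barcodes,
                           cluster = rep(c("x", "y"),
                                         length.out = length(nm$barcodes)))
  it1 <- lr_permutation_test(nm, labels, n_permutations = 19, seed = 1)
  expect_true(all(it1$p_value >= 1 / 20))
  expect_true(all(it1$p_value <= 1))
  it2 <- lr_permutation_test(nm, labels, n_permutations = 19, seed = 1)
  expect_identical(it1$p_value, it2$p_value)
  expect_error(lr_permutation_test(nm, labels, n_permutations = 5),
               "19")
})

test_that("signaling roles conserve total mass and track single edges", {
  single <- tibble::tibble(sender = "A", receiver = "B", ligand = "L",
                           receptor = "R", pathway = "P", score = 2.5)
  roles <- signaling_roles(single)
  expect_equal(roles$outgoing[roles$cluster == "A"], 2.5)
  expect_equal(roles$incoming[roles$cluster == "B"], 2.5)
  expect_equal(sum(roles$outgoing), sum(roles$incoming))

  set.seed(9)
  rnd <- tibble::tibble(
    sender = sample(LETTERS[1:4], 30, TRUE),
    receiver = sample(LETTERS[1:4], 30, TRUE),
    ligand = "L", receptor = "R", pathway = "P",
    score = runif(30))
  r2 <- signaling_roles(rnd)
  expect_equal(sum(r2$outgoing), sum(r2$incoming), tolerance = 1e-12)
})

test_that("tumor clusters dominate outgoing signaling on generated tissue", {
  sim <- tiny_sim(seed = 4)
  nm <- tiny_nm(seed = 4)
  lab <- sim$truth$spot_labels
  labels <- tibble::tibble(
    barcode = lab$barcode,
    cluster = dplyr::case_when(
      lab$label == "tumor" ~ "tumor",
      lab$label %in% c("boundary_immune", "intratumor_immune") ~ "immune",
      TRUE ~ "normal"))
  it <- lr_scores(nm, labels)
  roles <- signaling_roles(it)
  expect_identical(roles$cluster[which.max(roles$outgoing)], "tumor")
  # the SPP1-like axis points tumor -> immune among directed cluster pairs
  spp1 <- it[it$ligand == "SPP1" & it$sender != it$receiver, ]
  top <- spp1[which.max(spp1$score), ]
  expect_identical(top$sender, "tumor")
  expect_identical(top$receiver, "immune")
})
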