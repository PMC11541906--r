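# Reproducible simulation studies quantifying how well each pipeline stage
# recovers the generator's planted structure, and how well the statistical
# machinery is calibrated under null models. These back the package's
# headline recovery/calibration claims and the acceptance script.

study_config <- function(seed, pattern = "exclusion", n_rows = 30,
                         n_cols = 30, ...) {
  sim_config(n_rows = n_rows, n_cols = n_cols, pattern = pattern,
             seed = seed, ...)
}

run_sample <- function(cfg, config = pipeline_config()) {
  sim <- simulate_visium(cfg)
  run <- run_pipeline(sim$spots, sim$gene_positions, config,
                      lr_pairs = NULL)
  list(sim = sim, run = run)
}

#' Malignant-spot recovery study
#'
#' For each seed, generates a 30 x 30 sample (alternating activation /
#' exclusion patterns), runs the full pipeline and compares the called
#' malignant spots with the ground-truth tumor labels.
#'
#' @param n_seeds number of simulated samples.
#' @param seed base seed; sample s uses `seed * 1000 + s`.
#' @param config a [pipeline_config()].
#' @return tibble: seed, pattern, sensitivity, specificity, n_tumor.
#' @export
malignant_recovery_study <- function(n_seeds = 50, seed = 1,
                                     config = pipeline_config()) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    pat <- if (s %% 2 == 0) "activation" else "exclusion"
    cfg <- study_config(seed * 1000 + s, pattern = pat)
    res <- run_sample(cfg, config)
    truth <- res$sim$truth$spot_labels
    called <- res$run$scores$malignant[match(truth$barcode,
                                             res$run$scores$barcode)]
    tumor <- truth$label == "tumor"
    tibble::tibble(seed = cfg$seed, pattern = pat,
                   sensitivity = mean(called[tumor]),
                   specificity = mean(!called[!tumor]),
                   n_tumor = sum(tumor))
  })
}

#' Immune activation/exclusion classification study
#'
#' Generates `n_samples` samples split evenly between the two generating
#' patterns and scores [classify_infiltration()]'s calls against the truth.
#'
#' @param n_samples number of samples (half per pattern).
#' @param seed base seed.
#' @param config a [pipeline_config()].
#' @return tibble: seed, truth_pattern, called_pattern, f_intra, correct.
#' @export
pattern_classification_study <- function(n_samples = 100, seed = 1,
                                         config = pipeline_config()) {
  purrr::map_dfr(seq_len(n_samples), function(s) {
    pat <- if (s <= n_samples / 2) "activation" else "exclusion"
    cfg <- study_config(seed * 2000 + s, pattern = pat)
    # a sample whose called malignant area is too fragmented to classify
    # (zero interior spots) counts as a misclassification, not an abort
    res <- tryCatch(run_sample(cfg, config), error = function(e) NULL)
    if (is.null(res)) {
      return(tibble::tibble(seed = cfg$seed, truth_pattern = pat,
                            called_pattern = NA_character_,
                            f_intra = NA_real_, correct = FALSE))
    }
    tibble::tibble(seed = cfg$seed, truth_pattern = pat,
                   called_pattern = res$run$pattern$pattern,
                   f_intra = res$run$pattern$f_intra,
                   correct = res$run$pattern$pattern == pat)
  })
}

#' Reference-cluster selection study
#'
#' Fraction of seeds in which the immune-score-selected reference cluster is
#' composed of at least `purity` truth-labeled immune spots.
#'
#' @param n_seeds number of simulated samples.
#' @param seed base seed.
#' @param purity required immune fraction (default 0.9).
#' @return tibble: seed, immune_fraction, pure.
#' @export
reference_selection_study <- function(n_seeds = 20, seed = 1, purity = 0.9) {
  purrr::map_dfr(seq_len(n_seeds), function(s) {
    cfg <- study_config(seed * 3000 + s,
                        pattern = if (s %% 2 == 0) "activation" else
                          "exclusion")
    sim <- simulate_visium(cfg)
    nm <- normalize_counts(sim$spots)
    cl <- cluster_spots(nm)
    immune <- score_signature(nm, bundled_signature("immune_panel"))
    ref <- select_reference_cluster(immune, cl)
    ref_b <- cl$barcode[cl$cluster == ref]
    lab <- sim$truth$spot_labels
    frac <- mean(lab$label[lab$barcode %in% ref_b] %in%
                   c("boundary_immune", "intratumor_immune"))
    tibble::tibble(seed = cfg$seed, immune_fraction = frac,
                   pure = frac >= purity)
  })
}

#' Co-localization recovery study
#'
#' Estimates the spot-level Spearman correlation between the two designated
#' co-localized panels on one generated sample (~1000 spots, panel region
#' elevation switched off so the correlation is purely latent-driven), and
#' computes the count-attenuated target by an independent Monte-Carlo
#' rendering of the generative model at large n.
#'
#' @param seed seed for the sample.
#' @param rho latent correlation of the generating model.
#' @param n_mc Monte-Carlo spots for the attenuated target.
#' @return One-row tibble: rho_latent, rho_estimated, rho_target, error,
#'   n_spots.
#' @export
coloc_recovery_study <- function(seed = 1, rho = 0.5, n_mc = 20000) {
  base <- sim_config(n_rows = 32, n_cols = 32)
  panels <- base$marker_panels
  # decouple the co-localized panels from the immune-region architecture
  panels$fibro_chemokine$fold <- 1
  panels$plasma$fold <- 1
  co <- base$coloc
  co$rho <- rho
  cfg <- sim_config(n_rows = 32, n_cols = 32, marker_panels = panels,
                    coloc = co, seed = seed)
  sim <- simulate_visium(cfg)
  nm <- normalize_counts(sim$spots)
  sa <- score_signature(nm, gene_signature("panel_a",
                                           panels$fibro_chemokine$symbols))
  sb <- score_signature(nm, gene_signature("panel_b",
                                           panels$plasma$symbols))
  est <- colocalization(tibble::tibble(a = sa$score, b = sb$score), a, b)

  target <- coloc_mc_target(cfg, n_mc = n_mc, seed = seed + 1)
  tibble::tibble(rho_latent = rho, rho_estimated = est$rho,
                 rho_target = target, error = est$rho - target,
                 n_spots = est$n_spots)
}

# Independent Monte-Carlo rendering of the generative model for two panels
# with no region elevation: plain NB draws + rank correlation of mean
# log1p-normalized panel scores. Deliberately written as a direct loop-free
# restatement of the model, not via the simulator or scoring code paths.
coloc_mc_target <- function(cfg, n_mc, seed) {
  co <- cfg$coloc
  ga <- cfg$marker_panels[[co$panel_a]]$genes
  gb <- cfg$marker_panels[[co$panel_b]]$genes
  with_seed(stream_seed(seed, "subsample"), {
    base <- rgamma(cfg$n_genes, shape = 2, rate = 2) + 0.05
    total_base <- sum(base)
    lib <- rlnorm(n_mc, log(cfg$depth_mean) - 0.02, 0.2)
    z1 <- rnorm(n_mc)
    z2 <- rnorm(n_mc)
    u <- z1
    v <- co$rho * z1 + sqrt(1 - co$rho^2) * z2
    fa <- exp(co$sigma * u - co$sigma^2 / 2)
    fb <- exp(co$sigma * v - co$sigma^2 / 2)
    score_of <- function(gidx, f) {
      mu <- outer(f, base[gidx]) * lib / total_base
      cnt <- matrix(rnbinom(length(mu), size = cfg$nb_dispersion,
                            mu = as.vector(mu)), nrow = n_mc)
      rowMeans(log1p(cnt * (cfg$depth_mean / lib)))
    }
    a <- score_of(ga, fa)
    b <- score_of(gb, fb)
    cor(rank(a), rank(b))
  })
}

#' Log-rank type-I error under the null survival generator
#'
#' Simulates cohorts with `hazard_ratio = 1`, splits each at the median of
#' the effect gene's expression and records the two-sided log-rank
#' rejection rate at `alpha`.
#'
#' @param n_reps number of simulated cohorts.
#' @param n_patients cohort size.
#' @param seed base seed.
#' @param alpha significance level.
#' @return One-row tibble: rejection_rate, n_reps.
#' @export
logrank_type1_study <- function(n_reps = 500, n_patients = 100, seed = 1,
                                alpha = 0.05) {
  rej <- vapply(seq_len(n_reps), function(s) {
    coh <- simulate_survival_cohort(n_patients, hazard_ratio = 1,
                                    censor_rate = 0.2,
                                    seed = seed * 5000 + s)
    st <- coh$survival
    st$group <- ifelse(st$CCL19 > median(st$CCL19), "high", "low")
    logrank_test(st)$p_value <= alpha
  }, logical(1))
  tibble::tibble(rejection_rate = mean(rej), n_reps = n_reps)
}

#' Permutation ligand-receptor test calibration under the null
#'
#' Generates structure-free samples (no CNV segments, all panel folds 1),
#' assigns random spot clusters and runs [lr_permutation_test()];
#' exchangeable labels should give p-values that are (super-)uniform, so the
#' fraction at or below `alpha` should not exceed it materially.
#'
#' @param n_datasets number of null datasets (each contributes 36 pair-tests).
#' @param n_permutations permutations per test.
#' @param seed base seed.
#' @param alpha significance level.
#' @return One-row tibble: rejection_rate, n_tests.
#' @export
lr_type1_study <- function(n_datasets = 28, n_permutations = 99, seed = 1,
                           alpha = 0.05) {
  pvals <- purrr::map(seq_len(n_datasets), function(s) {
    cfg <- null_sim_config(seed * 7000 + s)
    sim <- simulate_visium(cfg)
    nm <- normalize_counts(sim$spots)
    labels <- with_seed(stream_seed(cfg$seed, "cluster"), {
      tibble::tibble(barcode = nm$barcodes,
                     cluster = sample(c("A", "B"), length(nm$barcodes),
                                      replace = TRUE))
    })
    lr_permutation_test(nm, labels, n_permutations = n_permutations,
                        seed = cfg$seed)$p_value
  })
  pvals <- unlist(pvals)
  tibble::tibble(rejection_rate = mean(pvals <= alpha),
                 n_tests = length(pvals))
}

# structure-free generator configuration: no CNV, no panel elevation, no
# latent co-localization
null_sim_config <- function(seed) {
  base <- sim_config(n_rows = 18, n_cols = 18, n_genes = 300,
                     ring_width = 2, stroma_width = 1, seed = seed)
  panels <- base$marker_panels
  for (p in names(panels)) panels[[p]]$fold <- 1
  co <- base$coloc
  co$rho <- 0
  co$sigma <- 0
  sim_config(n_rows = 18, n_cols = 18, n_genes = 300, ring_width = 2,
             stroma_width = 1, marker_panels = panels, coloc = co,
             seed = seed)
}
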