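# End-to-end orchestration: cluster -> score -> CNV -> patterns ->
# (optional) communication -> report, with validated parameters, a global
# seed and a reproducibility manifest.

pipeline_defaults <- function() {
  list(
    resolution = 0.8, n_pcs = 30, k_neighbors = 15, n_hvg = 2000,
    min_pct = 0.1, logfc_threshold = 0.25,
    cnv_cutoff = 0.1, window = 101, clip = 0.3, k = 8, theta = 2.0,
    q = 75, f_min = 0.10, neighborhood = 4,
    n_permutations = 100, alpha = 0.05, min_prop = 0.1,
    coloc_gene_a = "CCL19", coloc_gene_b = "IGHG1",
    seed = 0
  )
}

#' Pipeline configuration
#'
#' Validated parameter set for [run_pipeline()]. Unknown keys are rejected;
#' every parameter is checked against its documented domain.
#'
#' @param ... named overrides of the defaults: `resolution` (0.8), `n_pcs`
#'   (30), `k_neighbors` (15), `n_hvg` (2000), `min_pct` (0.1),
#'   `logfc_threshold` (0.25), `cnv_cutoff` (0.1), `window` (101), `clip`
#'   (0.3), `k` (8), `theta` (2.0), `q` (75), `f_min` (0.10),
#'   `neighborhood` (4), `n_permutations` (100), `alpha` (0.05),
#'   `min_prop` (0.1), `coloc_gene_a` ("CCL19"), `coloc_gene_b` ("IGHG1"),
#'   `seed` (0).
#' @param file optional YAML file of overrides (flags in `...` win).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  cfg <- pipeline_defaults()
  from_file <- if (!is.null(file)) yaml::read_yaml(file) else list()
  overrides <- c(from_file[setdiff(names(from_file), names(list(...)))],
                 list(...))
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(paste("unknown configuration key(s):",
                paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  with(cfg, {
    assert_that(resolution > 0, "resolution must be > 0")
    assert_that(is_count(n_pcs) && n_pcs >= 1, "n_pcs must be >= 1")
    assert_that(is_count(k_neighbors) && k_neighbors >= 2,
                "k_neighbors must be >= 2")
    assert_that(min_pct >= 0 && min_pct <= 1, "min_pct must be in [0, 1]")
    assert_that(logfc_threshold >= 0, "logfc_threshold must be >= 0")
    assert_that(cnv_cutoff >= 0, "cnv_cutoff must be >= 0")
    assert_that(is_count(window) && window %% 2 == 1 && window >= 1,
                "window must be odd and >= 1")
    assert_that(clip > 0, "clip must be > 0")
    assert_that(is_count(k) && k >= 1, "k must be >= 1")
    assert_that(theta > 0, "theta must be > 0")
    assert_that(q > 0 && q < 100, "q must be in (0, 100)")
    assert_that(f_min >= 0 && f_min <= 1, "f_min must be in [0, 1]")
    assert_that(neighborhood %in% c(4, 6), "neighborhood must be 4 or 6")
    assert_that(is_count(n_permutations) && n_permutations >= 19,
                "n_permutations must be >= 19")
    assert_that(alpha > 0 && alpha <= 1, "alpha must be in (0, 1]")
    assert_that(min_prop > 0 && min_prop < 0.5 + 1e-9,
                "min_prop must be in (0, 0.5]")
  })
  structure(cfg, class = "pipeline_config")
}

#' Run the full spatial TME pipeline on one sample
#'
#' Executes normalization, clustering, immune scoring, reference selection,
#' CNV inference with malignant-spot calling, boundary extraction,
#' activation/exclusion classification, TLS and activation-signature
#' scoring, co-localization and (optionally) ligand-receptor communication,
#' then assembles the per-spot report. Fully deterministic for fixed inputs
#' and config.
#'
#' @param spots a [spot_matrix()].
#' @param gene_positions tibble from [gene_position_table()] /
#'   [read_gene_positions()].
#' @param config a [pipeline_config()].
#' @param out_dir optional run directory: writes the spot annotation TSV,
#'   summary JSON, interaction TSV and a manifest.
#' @param lr_pairs ligand-receptor table for the communication stage;
#'   `NULL` skips it.
#' @return list of class `tme_run`: `normalized`, `clusters`, `immune_score`,
#'   `reference_cluster`, `cnv`, `boundary`, `pattern`, `scores` (per-spot
#'   annotation tibble), `interactions`, `roles`, `coloc`, `config`.
#' @export
run_pipeline <- function(spots, gene_positions, config = pipeline_config(),
                         out_dir = NULL, lr_pairs = read_lr_pairs()) {
  assert_that(inherits(config, "pipeline_config"),
              "config must be a pipeline_config()")
  nm <- normalize_counts(spots)
  hvg <- select_hvg(nm, config$n_hvg)
  clusters <- cluster_spots(nm, resolution = config$resolution,
                            n_pcs = config$n_pcs,
                            k_neighbors = config$k_neighbors,
                            hvg = hvg, seed = config$seed)
  immune <- score_signature(nm, bundled_signature("immune_panel"))
  ref_cluster <- select_reference_cluster(immune, clusters)
  ref_barcodes <- clusters$barcode[clusters$cluster == ref_cluster]
  cnv <- infer_cnv(nm, ref_barcodes, gene_positions,
                   window = config$window, clip = config$clip,
                   cutoff = config$cnv_cutoff, k = config$k,
                   theta = config$theta)

  spot_df <- dplyr::left_join(
    spots$positions[, c("barcode", "array_row", "array_col")],
    dplyr::rename(clusters, expr_cluster = "cluster"), by = "barcode")
  spot_df <- dplyr::left_join(spot_df, cnv$spot_calls, by = "barcode")
  spot_df$immune_score <- immune$score[match(spot_df$barcode,
                                             immune$barcode)]
  boundary <- tumor_boundary(spot_df, config$neighborhood)
  pattern <- classify_infiltration(spot_df, q = config$q,
                                   f_min = config$f_min,
                                   neighborhood = config$neighborhood)
  spot_df$boundary_ring <- boundary$ring[match(spot_df$barcode,
                                               boundary$barcode)]
  tls <- try(score_signature(nm, bundled_signature("tls_29gene")),
             silent = TRUE)
  if (!inherits(tls, "try-error")) {
    spot_df$tls_score <- tls$score[match(spot_df$barcode, tls$barcode)]
  }
  act <- try(score_signature(nm, bundled_signature("activation_5gene")),
             silent = TRUE)
  if (!inherits(act, "try-error")) {
    spot_df$activation_score <- act$score[match(spot_df$barcode,
                                                act$barcode)]
  }
  spot_df$pattern <- pattern$pattern

  coloc <- NULL
  if (all(c(config$coloc_gene_a, config$coloc_gene_b) %in% nm$genes)) {
    cd <- tibble::tibble(
      a = as.numeric(nm$values[, config$coloc_gene_a]),
      b = as.numeric(nm$values[, config$coloc_gene_b])
    )
    coloc <- colocalization(cd, a, b)
    coloc$gene_a <- config$coloc_gene_a
    coloc$gene_b <- config$coloc_gene_b
  }

  interactions <- NULL
  roles <- NULL
  if (!is.null(lr_pairs)) {
    ok <- vapply(seq_len(nrow(lr_pairs)), function(i) {
      all(c(lr_pairs$ligand[i], lr_pairs$receptor_subunits[[i]]) %in%
            nm$genes)
    }, logical(1))
    if (any(ok)) {
      comm_labels <- tibble::tibble(
        barcode = spot_df$barcode,
        cluster = ifelse(spot_df$malignant, "tumor",
                         ifelse(spot_df$barcode %in% ref_barcodes, "immune",
                                "other"))
      )
      interactions <- lr_permutation_test(
        nm, comm_labels, lr_pairs[ok, ],
        n_permutations = config$n_permutations, seed = config$seed,
        min_pct = config$min_pct)
      roles <- signaling_roles(interactions)
    }
  }

  report <- pattern_report(spot_df, pattern, out_dir)
  if (!is.null(out_dir)) {
    if (!is.null(interactions)) {
      tab <- interactions
      readr::write_tsv(tab, file.path(out_dir, "interactions.tsv"))
    }
    manifest <- list(
      package = "spatialtme",
      version = as.character(utils::packageVersion("spatialtme")),
      parameters = unclass(config),
      n_spots = nrow(spot_df), n_genes = length(nm$genes),
      reference_cluster = ref_cluster,
      parameter_hash = rlang::hash(unclass(config))
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  structure(list(
    normalized = nm, clusters = clusters, immune_score = immune,
    reference_cluster = ref_cluster, cnv = cnv, boundary = boundary,
    pattern = pattern, scores = report$spots, interactions = interactions,
    roles = roles, coloc = coloc, config = config
  ), class = "tme_run")
}

#' @export
print.tme_run <- function(x, ...) {
  cat("<tme_run> ", nrow(x$scores), " spots; pattern: ",
      x$pattern$pattern, " (f_intra = ",
      format(x$pattern$f_intra, digits = 3), ")\n", sep = "")
  invisible(x)
}
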