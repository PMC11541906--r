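# Synthetic Visium-like generator.
#
# Emulates a square-lattice tissue with a central tumor core, an immune ring
# along the tumor boundary, a stromal band, surrounding normal tissue and --
# for the "activation" pattern -- intra-tumor immune aggregates. Counts are
# negative binomial (gamma-Poisson) around a per-spot library size, with
# planted chromosomal copy-number segments acting as count multipliers in
# tumor spots, marker-panel fold-elevation in immune spots, and a shared
# latent log-normal factor inducing tunable co-localization between two
# designated panels.

#' Configuration for the synthetic Visium-like generator
#'
#' Defaults describe the study conditions used throughout the package's
#' recovery tests: a 40 x 40 lattice, a central tumor core covering 25% of the
#' area, 900 genes on 6 chromosomes, three planted copy-number segments of 60
#' genes (multipliers 2.0, 0.5 and 1.75), an 8-fold elevated 10-gene immune
#' marker panel in immune regions, and latent co-localization rho = 0.5
#' between a fibroblast-chemokine panel and a plasma-cell panel.
#'
#' @param n_rows,n_cols lattice dimensions in spots.
#' @param pattern `"activation"` (intra-tumor immune aggregates present) or
#'   `"exclusion"` (immune spots confined to the boundary ring).
#' @param tumor_fraction fraction of the lattice area inside the tumor core
#'   (0 < f < 1).
#' @param n_genes,n_chromosomes total genes and chromosome count.
#' @param cnv_segments data frame (chrom, start, end, multiplier) with
#'   1-based within-chromosome gene indices; multiplier > 0 scales the
#'   expected counts of segment genes in tumor spots.
#' @param marker_panels named list; each element is a list with `genes`
#'   (global gene indices), `symbols` (gene names to assign), `fold`
#'   (mean elevation) and `regions` (spot labels receiving the elevation).
#'   `NULL` uses the built-in immune / fibroblast-chemokine / plasma /
#'   tumor-ligand / immune-receptor panels.
#' @param coloc list: `panel_a`, `panel_b` (panel names), `rho` latent
#'   correlation in \[-1, 1\], `sigma` log-normal scale of the latent factor.
#' @param nb_dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param depth_mean mean library size per spot.
#' @param ring_width,stroma_width widths (lattice steps) of the boundary
#'   immune ring and the stromal band outside it.
#' @param n_aggregates,aggregate_radius intra-tumor immune aggregates
#'   (activation pattern only): number and radius in lattice steps.
#' @param neighborhood 4 (square) or 6 (hex-like) lattice adjacency used by
#'   downstream boundary logic; stored for provenance.
#' @param seed integer master seed; all randomness is derived from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_rows = 40, n_cols = 40,
                       pattern = c("exclusion", "activation"),
                       tumor_fraction = 0.25,
                       n_genes = 900, n_chromosomes = 6,
                       cnv_segments = NULL,
                       marker_panels = NULL,
                       coloc = list(panel_a = "fibro_chemokine",
                                    panel_b = "plasma",
                                    rho = 0.5, sigma = 0.6),
                       nb_dispersion = 2, depth_mean = 5000,
                       ring_width = 4, stroma_width = 2,
                       n_aggregates = 3, aggregate_radius = 2.5,
                       neighborhood = 4, seed = 1) {
  pattern <- match.arg(pattern)
  assert_that(is_count(n_rows) && n_rows >= 4 && is_count(n_cols) &&
                n_cols >= 4, "lattice must be at least 4 x 4")
  assert_that(tumor_fraction > 0 && tumor_fraction < 1,
              "tumor_fraction must be in (0, 1)")
  assert_that(is_count(n_genes) && n_genes >= n_chromosomes,
              "need at least one gene per chromosome")
  assert_that(is_count(n_chromosomes) && n_chromosomes >= 1,
              "n_chromosomes must be a positive integer")
  assert_that(nb_dispersion > 0, "nb_dispersion must be > 0")
  assert_that(depth_mean > 0, "depth_mean must be > 0")
  assert_that(neighborhood %in% c(4, 6), "neighborhood must be 4 or 6")

  sizes <- chrom_sizes(n_genes, n_chromosomes)
  if (is.null(cnv_segments)) cnv_segments <- default_segments(sizes)
  cnv_segments <- tibble::as_tibble(cnv_segments)
  assert_that(all(c("chrom", "start", "end", "multiplier") %in%
                    names(cnv_segments)),
              "cnv_segments needs chrom, start, end, multiplier")
  assert_that(all(cnv_segments$multiplier > 0),
              "CNV multipliers must be > 0")
  for (ch in unique(cnv_segments$chrom)) {
    seg <- cnv_segments[cnv_segments$chrom == ch, ]
    assert_that(ch >= 1 && ch <= n_chromosomes, "segment chromosome out of range")
    assert_that(all(seg$start >= 1) && all(seg$end <= sizes[ch]) &&
                  all(seg$start <= seg$end),
                "segment outside its chromosome's gene range")
    seg <- seg[order(seg$start), ]
    if (nrow(seg) > 1 &&
        any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      abort("overlapping CNV segments on one chromosome")
    }
  }

  if (is.null(marker_panels)) marker_panels <- default_panels(sizes)
  cnv_genes <- segment_gene_indices(cnv_segments, sizes)
  panel_genes <- unlist(lapply(marker_panels, `[[`, "genes"))
  assert_that(!anyDuplicated(panel_genes),
              "marker panels must not share genes")
  assert_that(length(intersect(panel_genes, cnv_genes)) == 0,
              "marker panels must be disjoint from CNV-segment genes")
  assert_that(all(panel_genes >= 1 & panel_genes <= n_genes),
              "panel gene index out of range")
  assert_that(is.numeric(coloc$rho) && abs(coloc$rho) <= 1,
              "coloc rho must be in [-1, 1]")
  assert_that(all(c(coloc$panel_a, coloc$panel_b) %in% names(marker_panels)),
              "coloc panels must name marker panels")

  # the tumor core plus the immune ring and stromal band must fit on the
  # lattice with at least one row of normal tissue outside
  radius <- sqrt(tumor_fraction * n_rows * n_cols / pi)
  half_min <- (min(n_rows, n_cols) - 1) / 2
  if (radius + ring_width + stroma_width >= half_min) {
    abort("lattice too small to host tumor_fraction with the boundary ring")
  }

  structure(list(
    n_rows = n_rows, n_cols = n_cols, pattern = pattern,
    tumor_fraction = tumor_fraction, n_genes = n_genes,
    n_chromosomes = n_chromosomes, chrom_sizes = sizes,
    cnv_segments = cnv_segments, marker_panels = marker_panels,
    coloc = coloc, nb_dispersion = nb_dispersion, depth_mean = depth_mean,
    ring_width = ring_width, stroma_width = stroma_width,
    n_aggregates = n_aggregates, aggregate_radius = aggregate_radius,
    neighborhood = neighborhood, seed = as.integer(seed)
  ), class = "sim_config")
}

chrom_sizes <- function(n_genes, n_chromosomes) {
  base <- n_genes %/% n_chromosomes
  sizes <- rep(base, n_chromosomes)
  extra <- n_genes - base * n_chromosomes
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  sizes
}

chrom_starts <- function(sizes) cumsum(c(0L, sizes[-length(sizes)])) + 1L

default_segments <- function(sizes) {
  seg <- tibble::tibble(
    chrom = c(1L, 3L, 5L),
    start_frac = c(0.13, 0.26, 0.40),
    multiplier = c(2.0, 0.5, 1.75)
  )
  seg <- seg[seg$chrom <= length(sizes), ]
  len <- pmax(1L, round(0.4 * sizes[seg$chrom]))
  start <- pmax(1L, floor(seg$start_frac * sizes[seg$chrom]) + 1L)
  end <- pmin(sizes[seg$chrom], start + len - 1L)
  tibble::tibble(chrom = seg$chrom, start = start, end = end,
                 multiplier = seg$multiplier)
}

segment_gene_indices <- function(segments, sizes) {
  starts <- chrom_starts(sizes)
  unlist(lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    (starts[s$chrom] - 1L) + seq.int(s$start, s$end)
  }))
}

panel_at <- function(sizes, chrom, fracs, symbols, fold, regions) {
  start <- chrom_starts(sizes)[chrom]
  idx <- start - 1L + pmin(sizes[chrom], floor(fracs * sizes[chrom]) + 1L)
  list(genes = as.integer(idx), symbols = symbols, fold = fold,
       regions = regions)
}

default_panels <- function(sizes) {
  immune_regions <- c("boundary_immune", "intratumor_immune")
  list(
    immune = panel_at(
      sizes, 2L, seq(0.06, 0.60, length.out = 10),
      c("PTPRC", "CD2", "CD3D", "CD3E", "CD3G", "CD79A", "MS4A1", "CD79B",
        "CD68", "CD14"),
      fold = 8, regions = immune_regions),
    immune_receptor = panel_at(
      sizes, 2L, seq(0.68, 0.92, length.out = 8),
      c("CD44", "CD74", "CXCR4", "CCR7", "ITGAV", "ITGA5", "ITGB1", "ITGB5"),
      fold = 4, regions = immune_regions),
    fibro_chemokine = panel_at(
      sizes, 4L, seq(0.06, 0.34, length.out = 5),
      c("CCL19", "CCL21", "DCN", "CXCL12", "LUM"),
      fold = 6, regions = immune_regions),
    tumor_ligand = panel_at(
      sizes, 4L, seq(0.45, 0.60, length.out = 3),
      c("SPP1", "MIF", "DKK1"),
      fold = 6, regions = "tumor"),
    plasma = panel_at(
      sizes, 6L, seq(0.06, 0.45, length.out = 7),
      c("IGHG1", "IGHG2", "IGHG3", "IGHA1", "JCHAIN", "IGKC", "MZB1"),
      fold = 6, regions = immune_regions)
  )
}

sim_gene_names <- function(config) {
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  for (panel in config$marker_panels) {
    genes[panel$genes] <- panel$symbols
  }
  genes
}

sim_gene_positions <- function(config) {
  starts <- chrom_starts(config$chrom_sizes)
  chrom <- rep(paste0("chr", seq_len(config$n_chromosomes)),
               config$chrom_sizes)
  within <- unlist(lapply(config$chrom_sizes, seq_len))
  gene_position_table(tibble::tibble(
    gene = sim_gene_names(config), chrom = chrom,
    start = (within - 1L) * 10000L + 1L,
    end = (within - 1L) * 10000L + 1000L
  ))
}

sim_layout <- function(config) {
  r0 <- (config$n_rows - 1) / 2
  c0 <- (config$n_cols - 1) / 2
  grid <- expand.grid(array_col = seq_len(config$n_cols) - 1L,
                      array_row = seq_len(config$n_rows) - 1L)
  grid <- grid[, c("array_row", "array_col")]
  d <- sqrt((grid$array_row - r0)^2 + (grid$array_col - c0)^2)
  radius <- sqrt(config$tumor_fraction * config$n_rows * config$n_cols / pi)
  label <- rep("normal", nrow(grid))
  label[d <= radius + config$ring_width + config$stroma_width] <- "stroma"
  label[d <= radius + config$ring_width] <- "boundary_immune"
  label[d <= radius] <- "tumor"

  if (config$pattern == "activation") {
    tumor_core <- which(label == "tumor" & d <= 0.5 * radius)
    centers <- sample(tumor_core, min(config$n_aggregates, length(tumor_core)))
    for (ct in centers) {
      da <- sqrt((grid$array_row - grid$array_row[ct])^2 +
                   (grid$array_col - grid$array_col[ct])^2)
      label[label %in% c("tumor", "intratumor_immune") &
              da <= config$aggregate_radius] <- "intratumor_immune"
    }
  }
  tibble::tibble(
    barcode = sprintf("spot_r%03d_c%03d", grid$array_row, grid$array_col),
    array_row = grid$array_row, array_col = grid$array_col,
    label = label
  )
}

#' Generate a synthetic Visium-like sample
#'
#' Draws a full spot x gene count matrix plus ground-truth labels from the
#' generative model described in [sim_config()]. Deterministic for a fixed
#' config (the config's `seed` drives named RNG streams for layout, counts
#' and the co-localization latent, so each stage is independently
#' reproducible).
#'
#' @param config a [sim_config()].
#' @return A list of class `tme_sim`:
#'   * `spots`: a [spot_matrix()];
#'   * `truth`: list with `spot_labels` (tibble barcode, array_row,
#'     array_col, label), `gene_multiplier` (per-gene expected copy ratio in
#'     tumor spots), `segments`, `pattern`, `coloc`;
#'   * `gene_positions`: the matching gene-position tibble;
#'   * `config`.
#' @examples
#' sim <- simulate_visium(sim_config(n_rows = 20, n_cols = 20, n_genes = 300,
#'                                   ring_width = 2, stroma_width = 1,
#'                                   seed = 7))
#' table(sim$truth$spot_labels$label)
#' @export
simulate_visium <- function(config = sim_config()) {
  assert_that(inherits(config, "sim_config"), "config must be a sim_config()")
  layout <- with_seed(stream_seed(config$seed, "layout"), sim_layout(config))
  n_spots <- nrow(layout)
  n_genes <- config$n_genes
  genes <- sim_gene_names(config)

  # per-gene tumor copy ratio from the planted segments
  gene_mult <- rep(1, n_genes)
  idx <- segment_gene_indices(config$cnv_segments, config$chrom_sizes)
  gene_mult[idx] <- rep(config$cnv_segments$multiplier,
                        config$cnv_segments$end - config$cnv_segments$start + 1L)

  # mean multiplier matrix: CNV in tumor spots, panel folds in their regions
  mult <- matrix(1, n_spots, n_genes)
  tumor <- layout$label == "tumor"
  mult[tumor, ] <- rep(gene_mult, each = sum(tumor))
  for (panel in config$marker_panels) {
    in_region <- layout$label %in% panel$regions
    mult[in_region, panel$genes] <- mult[in_region, panel$genes] * panel$fold
  }

  # shared latent factor inducing co-localization between the two designated
  # panels (log-normal, unit mean)
  co <- config$coloc
  latent <- with_seed(stream_seed(config$seed, "coloc"), {
    z1 <- rnorm(n_spots)
    z2 <- rnorm(n_spots)
    cbind(z1, co$rho * z1 + sqrt(1 - co$rho^2) * z2)
  })
  fa <- exp(co$sigma * latent[, 1] - co$sigma^2 / 2)
  fb <- exp(co$sigma * latent[, 2] - co$sigma^2 / 2)
  ga <- config$marker_panels[[co$panel_a]]$genes
  gb <- config$marker_panels[[co$panel_b]]$genes
  mult[, ga] <- mult[, ga] * fa
  mult[, gb] <- mult[, gb] * fb

  counts <- with_seed(stream_seed(config$seed, "counts"), {
    base <- rgamma(n_genes, shape = 2, rate = 2) + 0.05
    lib <- rlnorm(n_spots, meanlog = log(config$depth_mean) - 0.02,
                  sdlog = 0.2)
    w <- sweep(mult, 2, base, `*`)
    mu <- (w / rowSums(w)) * lib
    matrix(rnbinom(n_spots * n_genes, size = config$nb_dispersion,
                   mu = as.vector(mu)),
           n_spots, n_genes)
  })

  positions <- tibble::tibble(
    barcode = layout$barcode, in_tissue = 1L,
    array_row = layout$array_row, array_col = layout$array_col,
    pxl_row = layout$array_row * 100L, pxl_col = layout$array_col * 100L
  )
  spots <- spot_matrix(counts, layout$barcode, genes, positions)
  truth <- structure(list(
    spot_labels = layout,
    gene_multiplier = setNames(gene_mult, genes),
    segments = config$cnv_segments,
    pattern = config$pattern,
    coloc = co
  ), class = "tme_truth")
  structure(list(spots = spots, truth = truth,
                 gene_positions = sim_gene_positions(config),
                 config = config),
            class = "tme_sim")
}

#' Expected copy-ratio matrix implied by the ground truth
#'
#' @param truth the `truth` element of a [simulate_visium()] result.
#' @return spots x genes matrix of expected copy ratios (1 outside tumor
#'   spots).
#' @export
truth_copy_ratio <- function(truth) {
  tumor <- truth$spot_labels$label == "tumor"
  m <- matrix(1, nrow(truth$spot_labels), length(truth$gene_multiplier),
              dimnames = list(truth$spot_labels$barcode,
                              names(truth$gene_multiplier)))
  m[tumor, ] <- rep(truth$gene_multiplier, each = sum(tumor))
  m
}

#' Write a simulated sample to disk
#'
#' Writes the spot matrix via [write_spot_matrix()], the gene positions and
#' ground-truth labels as TSV, and a JSON manifest of segments and
#' parameters.
#'
#' @param sim a [simulate_visium()] result.
#' @param out_dir output directory.
#' @return Invisibly, the output directory.
#' @export
write_sim <- function(sim, out_dir) {
  write_spot_matrix(sim$spots, out_dir)
  readr::write_tsv(sim$gene_positions,
                   file.path(out_dir, "gene_positions.tsv"))
  readr::write_tsv(sim$truth$spot_labels[, c("barcode", "label")],
                   file.path(out_dir, "truth_labels.tsv"))
  cfg <- sim$config
  manifest <- list(
    pattern = cfg$pattern, seed = cfg$seed,
    n_rows = cfg$n_rows, n_cols = cfg$n_cols,
    tumor_fraction = cfg$tumor_fraction,
    n_genes = cfg$n_genes, n_chromosomes = cfg$n_chromosomes,
    nb_dispersion = cfg$nb_dispersion, depth_mean = cfg$depth_mean,
    coloc_rho = cfg$coloc$rho, coloc_sigma = cfg$coloc$sigma,
    cnv_segments = cfg$cnv_segments
  )
  jsonlite::write_json(manifest, file.path(out_dir, "sim_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a bulk expression cohort with expression-dependent survival
#'
#' Event times are exponential with rate `base_hazard * hazard_ratio^z`,
#' where `z` is the standardized log-expression of `effect_gene`; censoring
#' is independent exponential calibrated so that roughly `censor_rate` of
#' records are censored.
#'
#' @param n_patients cohort size (>= 2).
#' @param effect_gene name of the gene driving survival.
#' @param hazard_ratio hazard multiplier per SD of expression (> 0); 1 means
#'   no association.
#' @param censor_rate target censoring fraction in \[0, 1).
#' @param n_genes number of genes in the expression table.
#' @param base_hazard baseline event rate (arbitrary time unit).
#' @param seed integer seed.
#' @return list with `expression` (tibble patient x genes) and `survival`
#'   (tibble patient, time, event, plus a column named after `effect_gene`).
#' @export
simulate_survival_cohort <- function(n_patients, effect_gene = "CCL19",
                                     hazard_ratio = 1, censor_rate = 0.2,
                                     n_genes = 20, base_hazard = 0.1,
                                     seed = 1) {
  assert_that(is_count(n_patients) && n_patients >= 2,
              "n_patients must be at least 2")
  assert_that(hazard_ratio > 0, "hazard_ratio must be > 0")
  assert_that(censor_rate >= 0 && censor_rate < 1,
              "censor_rate must be in [0, 1)")
  with_seed(stream_seed(seed, "survival"), {
    genes <- c(effect_gene, sprintf("bg%03d", seq_len(max(0, n_genes - 1))))
    expr <- matrix(rlnorm(n_patients * length(genes), 2, 0.8),
                   n_patients, length(genes), dimnames = list(NULL, genes))
    z <- as.numeric(scale(log(expr[, effect_gene])))
    rate <- base_hazard * hazard_ratio^z
    t_event <- rexp(n_patients, rate = rate)
    if (censor_rate > 0) {
      t_cens <- rexp(n_patients,
                     rate = base_hazard * censor_rate / (1 - censor_rate))
      event <- as.integer(t_event <= t_cens)
      time <- pmin(t_event, t_cens)
    } else {
      event <- rep(1L, n_patients)
      time <- t_event
    }
    patient <- sprintf("pt%04d", seq_len(n_patients))
    survival <- tibble::tibble(patient = patient, time = time, event = event)
    survival[[effect_gene]] <- expr[, effect_gene]
    list(
      expression = dplyr::bind_cols(tibble::tibble(patient = patient),
                                    tibble::as_tibble(expr)),
      survival = survival
    )
  })
}

#' Simulate an IHC scoring table
#'
#' Staining intensity (0-3) and positive-area (0-4) categories are drawn
#' from group-shifted latent-normal categorical distributions; the composite
#' is their product via [ihc_composite()].
#'
#' @param n_samples total samples (>= 2), split evenly between groups
#'   `"exclusion"` and `"activation"`.
#' @param group_effect latent-mean shift of the activation group (0 = no
#'   group difference).
#' @param seed integer seed.
#' @return tibble: sample_id, group, intensity, area, composite.
#' @export
simulate_ihc_table <- function(n_samples, group_effect = 0, seed = 1) {
  assert_that(is_count(n_samples) && n_samples >= 2,
              "n_samples must be at least 2")
  with_seed(stream_seed(seed, "ihc"), {
    group <- rep(c("exclusion", "activation"), length.out = n_samples)
    shift <- ifelse(group == "activation", group_effect, 0)
    cut_int <- c(-Inf, -0.8, 0, 0.8, Inf)
    cut_area <- c(-Inf, -1, -0.3, 0.4, 1.1, Inf)
    intensity <- as.integer(cut(rnorm(n_samples) + shift, cut_int)) - 1L
    area <- as.integer(cut(rnorm(n_samples) + shift, cut_area)) - 1L
    tibble::tibble(
      sample_id = sprintf("ihc%04d", seq_len(n_samples)),
      group = group, intensity = intensity, area = area,
      composite = ihc_composite(intensity, area)
    )
  })
}
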