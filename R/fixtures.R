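# Seeded synthetic-data generator: count matrices with the statistical
# structure the screening pipeline assumes (regime-corner genes, planted
# filter violations, low-depth cells, replicate "animals" sharing gene-level
# ground truth), so the whole workflow is testable without any downloads.

#' Fixture specification
#'
#' @param n_genes_per_regime Genes per regime category (jump-driven bursty
#'   corner, diffusion-driven heavy-tail corner, slow-reversion mixture
#'   corner).
#' @param n_cells Cells per replicate dataset; one dataset ("animal") is
#'   generated per entry.  Defaults to four replicates of about five
#'   thousand cells, the magnitude of typical single-animal 10x datasets.
#' @param n_subtypes Number of (label-only) cell subtypes per dataset.
#' @param mean_rate_range Range of per-gene mean transcription rates.
#' @param beta,gamma Splicing and degradation rates shared by all simulated
#'   genes.
#' @param corner_half_width Half-width of the regime-coordinate boxes around
#'   the corners used to draw gene parameters.
#' @param planted_filter_genes Add one gene violating each expression-filter
#'   rule (low mean, low max, high max) plus a fraction of low-depth cells.
#' @param low_depth_fraction Fraction of cells binomially thinned to emulate
#'   low-quality barcodes.
#' @param seed Integer seed: fixed seed, byte-identical fixture.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_genes_per_regime = 4,
                         n_cells = c(5343, 6604, 5892, 4497),
                         n_subtypes = 3,
                         mean_rate_range = c(4, 12),
                         beta = 1.2, gamma = 0.7,
                         corner_half_width = 0.05,
                         planted_filter_genes = TRUE,
                         low_depth_fraction = 0.05,
                         seed = 1L) {
  stopifnot(n_genes_per_regime >= 1, all(n_cells >= 1), n_subtypes >= 1,
            mean_rate_range[1] > 0, diff(mean_rate_range) >= 0)
  structure(list(n_genes_per_regime = n_genes_per_regime, n_cells = n_cells,
                 n_subtypes = n_subtypes, mean_rate_range = mean_rate_range,
                 beta = beta, gamma = gamma,
                 corner_half_width = corner_half_width,
                 planted_filter_genes = planted_filter_genes,
                 low_depth_fraction = low_depth_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

fixture_regimes <- function() {
  # centers of the regime boxes each category is drawn from
  list("gou-like" = list(model = "gou", reversion = 0.9, gain = 0.9),
       "cir-like" = list(model = "cir", reversion = 0.9, gain = 0.9),
       "mixture-like" = list(model = "gou", reversion = 0.08, gain = 0.9))
}

#' Generate a synthetic multi-replicate fixture
#'
#' Draws per-gene kinetic parameters from the regime corners, simulates
#' paired counts for each replicate dataset with the hybrid stochastic
#' simulator (replicates share gene-level ground truth and differ only by
#' RNG stream), optionally plants genes violating each expression-filter
#' rule (sampled from their exact constitutive law) and thins a fraction of
#' cells to exercise the depth filter, and writes everything to `dir` as
#' Matrix Market pairs with TSV sidecars plus a `ground_truth.csv`.
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory; one subdirectory per replicate
#'   (`animal_1`, ...) plus `ground_truth.csv`.
#' @return Invisibly, a list with `ground_truth` (data frame) and `dirs`.
#' @export
generate_fixture <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  regs <- fixture_regimes()
  hw <- spec$corner_half_width
  genes <- list()
  for (lab in names(regs)) {
    for (i in seq_len(spec$n_genes_per_regime)) {
      r <- regs[[lab]]$reversion + stats::runif(1, -hw, hw)
      g <- regs[[lab]]$gain + stats::runif(1, -hw, hw)
      r <- min(max(r, 0.01), 0.99); g <- min(max(g, 0.01), 0.99)
      K <- stats::runif(1, spec$mean_rate_range[1], spec$mean_rate_range[2])
      p <- params_from_regime(r, g, K, spec$beta, spec$gamma)
      genes[[length(genes) + 1L]] <- list(
        gene = sprintf("%s_%d", gsub("-like", "", lab), i),
        model = regs[[lab]]$model, label = lab, params = p)
    }
  }
  if (spec$planted_filter_genes) {
    planted <- list(
      list(gene = "planted_low_mean", mu_N = 0.004, mu_M = 0.004),
      list(gene = "planted_low_max", mu_N = 0.03, mu_M = 0.03),
      list(gene = "planted_high_max", mu_N = 450, mu_M = 500))
  } else planted <- list()
  gt_rows <- lapply(genes, function(ge) {
    data.frame(gene = ge$gene, model = ge$model, regime_label = ge$label,
               kappa = ge$params$kappa, theta = ge$params$theta,
               a = ge$params$a, beta = ge$params$beta, gamma = ge$params$gamma,
               stringsAsFactors = FALSE)
  })
  for (pl in planted) {
    gt_rows[[length(gt_rows) + 1L]] <- data.frame(
      gene = pl$gene, model = "constitutive", regime_label = "planted_filter",
      kappa = NA, theta = NA, a = NA, beta = NA, gamma = NA,
      stringsAsFactors = FALSE)
  }
  ground_truth <- do.call(rbind, gt_rows)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character(0)
  for (d in seq_along(spec$n_cells)) {
    nc <- spec$n_cells[d]
    mats <- lapply(genes, function(ge) simulate_cells(ge$model, ge$params, nc))
    nas <- do.call(rbind, lapply(mats, function(m) m$nascent))
    mat <- do.call(rbind, lapply(mats, function(m) m$mature))
    for (pl in planted) {
      nas <- rbind(nas, stats::rpois(nc, pl$mu_N))
      mat <- rbind(mat, stats::rpois(nc, pl$mu_M))
    }
    low <- stats::runif(nc) < spec$low_depth_fraction
    if (any(low)) {
      for (j in which(low)) {
        nas[, j] <- stats::rbinom(nrow(nas), nas[, j], 0.02)
        mat[, j] <- stats::rbinom(nrow(mat), mat[, j], 0.02)
      }
    }
    cells <- data.frame(
      cell_id = sprintf("a%d_cell%05d", d, seq_len(nc)),
      subtype = sprintf("subtype%d", 1 + (seq_len(nc) %% spec$n_subtypes)),
      low_depth = low, stringsAsFactors = FALSE)
    tab <- gene_table(nas, mat, ground_truth$gene, cells)
    sub <- file.path(dir, sprintf("animal_%d", d))
    write_count_matrices(tab, sub)
    dirs <- c(dirs, sub)
  }
  utils::write.csv(ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(list(ground_truth = ground_truth, dirs = dirs))
}

#' Synthetic datasets for the Bayes-factor lattice experiment
#'
#' Draws paired-count datasets from the exact stationary PMF of the
#' ground-truth model at every lattice point: the inputs of the in-silico
#' distinguishability experiment at configurable scale.
#'
#' @param lattice A data frame from [regime_lattice()].
#' @param model Ground-truth model tag.
#' @param cells Cells per dataset (must be positive).
#' @param n_datasets Datasets per lattice point.
#' @param seed Optional seed.
#' @return A list with one element per lattice row: `reversion`, `gain`,
#'   `params`, and `datasets` (list of [count_data]).
#' @export
generate_insilico_bayes_data <- function(lattice, model = "cir", cells = 1000,
                                         n_datasets = 3, seed = NULL) {
  model <- match_model(model)
  if (cells < 1) stop("'cells' must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nrow(lattice)), function(i) {
    p <- lattice$params[[i]]
    pmf <- joint_pmf(model, p)
    list(reversion = lattice$reversion[i], gain = lattice$gain[i], params = p,
         datasets = lapply(seq_len(n_datasets), function(k)
           sample_joint_pmf(pmf, cells)))
  })
}
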