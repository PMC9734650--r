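test_that("fixtures are byte-identical under a fixed seed", {
  spec <- fixture_spec(n_genes_per_regime = 1, n_cells = c(120),
                       n_subtypes = 2, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  generate_fixture(spec, d1)
  generate_fixture(spec, d2)
  for (f in c("animal_1/nascent.mtx", "animal_1/mature.mtx",
              "animal_1/cells.tsv", "ground_truth.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted filter-violating genes are exactly the ones removed", {
  spec <- fixture_spec(n_genes_per_regime = 1, n_cells = c(800),
                       n_subtypes = 1, planted_filter_genes = TRUE,
                       low_depth_fraction = 0, seed = 8)
  dir <- tempfile()
  fx <- generate_fixture(spec, dir)
  gt <- read_count_matrices(fx$dirs[1])
  out <- filter_genes(gt)
  planted <- fx$ground_truth$gene[fx$ground_truth$regime_label == "planted_filter"]
  expect_setequal(out$report$gene[out$report$removed], planted)
})

test_that("fixture gene moments match their recorded ground truth", {
  spec <- fixture_spec(n_genes_per_regime = 1, n_cells = c(900),
                       n_subtypes = 1, planted_filter_genes = FALSE,
                       low_depth_fraction = 0, seed = 9)
  dir <- tempfile()
  fx <- generate_fixture(spec, dir)
  gt <- read_count_matrices(fx$dirs[1])
  for (i in seq_len(nrow(fx$ground_truth))) {
    row <- fx$ground_truth[i, ]
    p <- sde_params(row$kappa, row$theta, row$a, row$beta, row$gamma)
    z <- moment_z_scores(gene_counts(gt, row$gene), steady_state_moments(p))
    expect_true(all(abs(z) < 4), info = row$gene)
  }
})

test_that("low-depth cells are planted and caught by the depth filter", {
  spec <- fixture_spec(n_genes_per_regime = 2, n_cells = c(400),
                       n_subtypes = 1, planted_filter_genes = FALSE,
                       low_depth_fraction = 0.1, seed = 10)
  dir <- tempfile()
  fx <- generate_fixture(spec, dir)
  gt <- read_count_matrices(fx$dirs[1])
  tot <- Matrix::colSums(gt$nascent) + Matrix::colSums(gt$mature)
  thresh <- stats::median(tot[!gt$cells$low_depth]) / 4
  f <- filter_cells(gt, min_total = thresh)
  expect_equal(attr(f, "n_cells_removed"), sum(gt$cells$low_depth))
  expect_true(all(!f$cells$low_depth))
})

test_that("lattice dataset generator reproduces the requested conditions", {
  expect_error(generate_insilico_bayes_data(regime_lattice(1), cells = 0),
               "positive")
  lat <- regime_lattice(2, bounds = c(0.2, 0.8), mean_rate = 10,
                        beta = 1.2, gamma = 0.7)
  sets <- generate_insilico_bayes_data(lat, "cir", cells = 1500,
                                       n_datasets = 2, seed = 12)
  expect_length(sets, 4)
  for (s in sets) {
    m <- steady_state_moments(s$params)
    for (d in s$datasets) {
      expect_lt(abs(mean(d$nascent) - m$mu_N) / m$mu_N, 0.1)
      expect_lt(abs(mean(d$mature) - m$mu_M) / m$mu_M, 0.1)
    }
  }
  # dispersion contrast between the Poisson-like and overdispersed corners
  lowg <- sample_joint_pmf(joint_pmf("cir", params_from_regime(0.8, 0.05, 10, 1.2, 0.7)), 1500)
  highg <- sample_joint_pmf(joint_pmf("cir", params_from_regime(0.8, 0.9, 10, 1.2, 0.7)), 1500)
  expect_lt(var(lowg$nascent) / mean(lowg$nascent), 1.3)
  expect_gt(var(highg$nascent) / mean(highg$nascent), 2)
})
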