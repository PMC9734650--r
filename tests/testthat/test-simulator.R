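test_that("jump-driver paths have the stationary gamma law and correct time average", {
  p <- test_params()
  set.seed(51)
  vals <- replicate(2000, {
    path <- sample_gou_path(p, 3)
    rate_at(path, 3)
  })
  ks <- suppressWarnings(ks.test(vals, pgamma, shape = p$a / p$kappa,
                                 scale = p$theta))
  expect_gt(ks$p.value, 0.01)
  # long-run time average equals a*theta/kappa
  path <- sample_gou_path(p, 400)
  avg <- mean(rate_at(path, seq(1, 400, by = 0.05)))
  expect_lt(abs(avg - p$mean_rate) / p$mean_rate, 0.1)
})

test_that("diffusion-driver paths are nonnegative with the same stationary law", {
  p <- test_params()
  set.seed(52)
  vals <- replicate(2000, sample_cir_path(p, 1.5, dt = 0.05)$values[31])
  expect_true(all(vals >= 0))
  ks <- suppressWarnings(ks.test(vals, pgamma, shape = p$a / p$kappa,
                                 scale = p$theta))
  expect_gt(ks$p.value, 0.01)
  # autocovariance of the rate decays as exp(-kappa tau)
  long <- sample_cir_path(p, 600, dt = 0.02)
  x <- long$values[-(1:250)]
  lag1 <- as.integer(round(0.25 / 0.02))
  emp <- cor(x[seq_len(length(x) - lag1)], x[seq_len(length(x) - lag1) + lag1])
  expect_lt(abs(emp - exp(-p$kappa * 0.25)), 0.05)
})

test_that("cell simulation is deterministic under a fixed seed", {
  p <- test_params()
  a <- simulate_cells("gou", p, 50, fast_protocol(p), seed = 7)
  b <- simulate_cells("gou", p, 50, fast_protocol(p), seed = 7)
  expect_identical(a$nascent, b$nascent)
  expect_identical(a$mature, b$mature)
  c1 <- simulate_cells("cir", p, 20, fast_protocol(p), seed = 9)
  c2 <- simulate_cells("cir", p, 20, fast_protocol(p), seed = 9)
  expect_identical(c1$nascent, c2$nascent)
})

test_that("a vanishing arrival frequency yields empty cells", {
  p <- sde_params(1, 1, 1e-9, 1.2, 0.7)
  s <- simulate_cells("gou", p, 30, fast_protocol(p), seed = 3)
  expect_true(all(s$nascent == 0) && all(s$mature == 0))
})

test_that("every mature molecule was previously nascent (event audit)", {
  p <- test_params()
  for (model in c("gou", "cir")) {
    s <- simulate_cells(model, p, 3, fast_protocol(p), seed = 13,
                        record_events = TRUE)
    ev <- attr(s, "events")
    expect_gt(nrow(ev), 0)
    for (cl in unique(ev$cell)) {
      e <- ev[ev$cell == cl, ]
      e <- e[order(e$time), ]
      xN <- cumsum(e$reaction == 0) - cumsum(e$reaction == 1)
      xM <- cumsum(e$reaction == 1) - cumsum(e$reaction == 2)
      expect_true(all(xN >= 0))        # splicing never outruns transcription
      expect_true(all(xM >= 0))        # degradation never outruns splicing
    }
  }
})

test_that("simulated moments match the closed forms for both drivers", {
  p <- test_params()
  m <- steady_state_moments(p)
  sg <- simulate_cells("gou", p, 3000, fast_protocol(p), seed = 61)
  expect_true(all(abs(moment_z_scores(sg, m)) < 3.5))
  sc <- simulate_cells("cir", p, 2000, fast_protocol(p), seed = 62)
  expect_true(all(abs(moment_z_scores(sc, m)) < 3.5))
})

test_that("event-driven counts agree with the independent Poisson-representation oracle", {
  p <- test_params()
  set.seed(71)
  oracle <- sample_gou_poisson_rep(p, 3000)
  pmf <- joint_pmf("gou", p)
  expect_gt(chi2_gof_p(oracle, pmf), 0.01)   # oracle vs analytic solver
  sim <- simulate_cells("gou", p, 3000, fast_protocol(p), seed = 72)
  expect_gt(chi2_gof_p(sim, pmf), 0.01)      # event loop vs analytic solver
  z <- moment_diff_z(sim, oracle)            # event loop vs oracle directly
  expect_true(all(abs(z) < 3.5))
})

test_that("diffusion counts are insensitive to halving the path grid step", {
  p <- test_params()
  dt0 <- 0.01 / max(p$kappa, p$mean_rate)
  a <- simulate_cells("cir", p, 1500, fast_protocol(p, dt_cir = dt0), seed = 81)
  b <- simulate_cells("cir", p, 1500, fast_protocol(p, dt_cir = dt0 / 2), seed = 82)
  expect_true(all(abs(moment_diff_z(a, b)) < 3))
})

test_that("trajectory recording supports autocorrelation estimation", {
  p <- test_params()
  pr <- fast_protocol(p, t_r = 6, sample_dt = 0.3)
  s <- simulate_cells("gou", p, 1500, pr, seed = 91)
  lags <- c(0, 0.6, 1.2, 2.4)
  rn <- empirical_autocorrelation(s, "nascent", lags)
  expect_equal(rn[1], 1, tolerance = 1e-12)
  expect_lt(max(abs(rn - autocorrelation(p, "nascent", lags))), 0.05)
  rm_ <- empirical_autocorrelation(s, "mature", lags)
  expect_lt(max(abs(rm_ - autocorrelation(p, "mature", lags))), 0.05)
  expect_error(empirical_autocorrelation(s, "nascent", 100), "within")
  # jump- and diffusion-driver estimates agree with each other
  s2 <- simulate_cells("cir", p, 1500, pr, seed = 92)
  rn2 <- empirical_autocorrelation(s2, "nascent", lags)
  expect_lt(max(abs(rn - rn2)), 0.08)
})

test_that("short equilibration triggers the advisory warning", {
  p <- test_params()
  expect_warning(sim_protocol(p, t_ss = 1), "equilibration")
})
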