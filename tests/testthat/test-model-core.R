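test_that("mean transcription rate is a*theta/kappa and validation names offenders", {
  expect_equal(mean_transcription_rate(sde_params(1, 1, 1, 1, 1)), 1)
  expect_equal(mean_transcription_rate(sde_params(2, 3, 4, 1.2, 0.7)), 6)
  expect_error(sde_params(1, 1, 0, 1, 1), "'a'")
  expect_error(sde_params(-1, 1, 1, 1, 1), "'kappa'")
  expect_error(sde_params(1, Inf, 1, 1, 1), "'theta'")
})

test_that("regime coordinates match their defining ratios", {
  rc <- regime_coords(sde_params(1, 1, 1, 1, 1))
  expect_equal(unname(rc), c(1 / 3, 1 / 2))
  # reversion coordinate approaches 1 as kappa dominates
  expect_gt(regime_coords(sde_params(1e4, 1, 1, 1, 1))[["reversion"]], 0.999)
  # theta = a gives gain exactly 1/2
  expect_equal(regime_coords(sde_params(2, 7, 7, 1, 3))[["gain"]], 0.5)
})

test_that("params_from_regime inverts the coordinate map", {
  p <- params_from_regime(1 / 3, 1 / 2, mean_rate = 1, beta = 1, gamma = 1)
  expect_equal(p$kappa, 1); expect_equal(p$theta, 1); expect_equal(p$a, 1)
  expect_error(params_from_regime(1, 0.5, 1, 1, 1), "inside")
  expect_error(params_from_regime(0.5, 0, 1, 1, 1), "inside")
  # round-trip property on random interior points
  set.seed(11)
  for (i in 1:25) {
    r <- runif(1, 0.02, 0.98); g <- runif(1, 0.02, 0.98)
    K <- runif(1, 0.5, 50); be <- runif(1, 0.2, 5); ga <- runif(1, 0.2, 5)
    p <- params_from_regime(r, g, K, be, ga)
    rc <- regime_coords(p)
    expect_equal(rc[["reversion"]], r, tolerance = 1e-12)
    expect_equal(rc[["gain"]], g, tolerance = 1e-12)
    expect_equal(mean_transcription_rate(p), K, tolerance = 1e-12)
  }
})

test_that("regime coordinates are monotone in kappa and theta", {
  base <- list(theta = 2, a = 3, beta = 1.2, gamma = 0.7)
  rev_at <- function(k) regime_coords(sde_params(k, base$theta, base$a,
                                                 base$beta, base$gamma))[["reversion"]]
  kv <- c(0.1, 0.5, 1, 5, 20)
  expect_true(all(diff(vapply(kv, rev_at, 0)) > 0))
  gain_at <- function(th) regime_coords(sde_params(1, th, base$a,
                                                   base$beta, base$gamma))[["gain"]]
  expect_true(all(diff(vapply(kv, gain_at, 0)) > 0))
})

test_that("regime lattice covers the requested square", {
  lat <- regime_lattice(4, bounds = c(0.1, 0.9), mean_rate = 5, beta = 1, gamma = 1)
  expect_equal(nrow(lat), 16)
  expect_equal(range(lat$reversion), c(0.1, 0.9))
  expect_true(all(vapply(lat$params, inherits, TRUE, "sde_params")))
})

test_that("JSON parameter files round-trip both input forms", {
  f <- tempfile(fileext = ".json")
  writeLines('{"model": "gou", "kappa": 2, "theta": 3, "a": 4, "beta": 1.2, "gamma": 0.7}', f)
  p <- read_params_json(f)
  expect_equal(p$mean_rate, 6)
  expect_equal(attr(p, "model"), "gou")
  writeLines('{"reversion": 0.5, "gain": 0.5, "mean_rate": 10, "beta": 1.2, "gamma": 0.7}', f)
  p2 <- read_params_json(f)
  expect_equal(unname(regime_coords(p2)), c(0.5, 0.5), tolerance = 1e-12)
})
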