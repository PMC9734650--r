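test_that("closed-form moments match direct substitution at unit rates", {
  m <- steady_state_moments(sde_params(1, 1, 1, 1, 1))
  expect_equal(m$mu_N, 1)
  expect_equal(m$var_N, 1.5)          # Poisson part 1 + extrinsic 1/2
  expect_equal(m$cov_NK, 0.5)
  expect_equal(m$cov_MK, 0.25)
  expect_equal(m$cov_NM, 3 / 8)       # 1/(2*2) * 3/2
})

test_that("vanishing gain recovers Poisson statistics", {
  m <- steady_state_moments(sde_params(1, 1e-10, 1e10, 1.2, 0.7))
  expect_equal(m$var_N, m$mu_N, tolerance = 1e-8)
  expect_equal(m$var_M, m$mu_M, tolerance = 1e-8)
  nd <- noise_decomposition(sde_params(1, 1e-10, 1e10, 1.2, 0.7))
  expect_lt(nd$extrinsic_fraction_N, 1e-9)
})

test_that("noise decomposition is algebraically consistent with the moments", {
  nd <- noise_decomposition(sde_params(1, 1, 1, 1, 1))
  expect_equal(nd$extrinsic_fraction_N, 1 / 3)
  set.seed(21)
  for (i in 1:20) {
    p <- sde_params(runif(1, .1, 10), runif(1, .1, 10), runif(1, .1, 10),
                    runif(1, .1, 10), runif(1, .1, 10))
    m <- steady_state_moments(p)
    nd <- noise_decomposition(p)
    expect_equal(nd$eta2_N, m$var_N / m$mu_N^2, tolerance = 1e-12)
    expect_equal(nd$eta2_M, m$var_M / m$mu_M^2, tolerance = 1e-12)
    expect_equal(nd$intrinsic_N, 1 / m$mu_N, tolerance = 1e-12)
    expect_equal(nd$extrinsic_fraction_N,
                 p$theta / (p$theta + p$kappa + p$beta), tolerance = 1e-12)
  }
})

test_that("extrinsic fraction is monotone in theta, kappa and beta", {
  f <- function(th, k, b) noise_decomposition(sde_params(k, th, 1, b, 0.7))$extrinsic_fraction_N
  expect_true(all(diff(vapply(c(.1, 1, 5, 20), f, 0, k = 1, b = 1)) > 0))
  expect_true(all(diff(vapply(c(.1, 1, 5, 20), function(k) f(1, k, 1), 0)) < 0))
  expect_true(all(diff(vapply(c(.1, 1, 5, 20), function(b) f(1, 1, b), 0)) < 0))
})

test_that("autocorrelations are 1 at lag zero and decay to zero", {
  p <- test_params()
  expect_equal(autocorrelation(p, "nascent", 0), 1)
  expect_equal(autocorrelation(p, "mature", 0), 1)
  expect_lt(abs(autocorrelation(p, "nascent", 100)), 1e-10)
  expect_lt(abs(autocorrelation(p, "mature", 100)), 1e-10)
  rn <- autocorrelation(p, "nascent", c(0, .5, 1, 2, 4))
  expect_true(all(diff(rn) < 0))
  expect_error(autocorrelation(p, "nascent", -1), "nonnegative")
})

test_that("mature autocorrelation normalizes exactly at lag zero for any rates", {
  # the three-exponential bracket vanishes at tau = 0 (partial fractions),
  # so no additive constant is needed
  set.seed(31)
  for (i in 1:10) {
    p <- sde_params(runif(1, .1, 10), runif(1, .1, 10), runif(1, .1, 10),
                    runif(1, .1, 10), runif(1, .1, 10))
    expect_equal(autocorrelation(p, "mature", 0), 1, tolerance = 1e-9)
  }
})

test_that("degenerate rate pairs are handled without blow-up", {
  p <- sde_params(1, 2, 3, 1, 1)           # beta == gamma == kappa
  r <- autocorrelation(p, "mature", c(0, 1, 2))
  expect_true(all(is.finite(r)))
  # accuracy is limited by the documented O(delta) rate perturbation
  expect_equal(r[1], 1, tolerance = 1e-4)
})
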