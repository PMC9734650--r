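test_that("closed-form characteristic coefficients match direct substitution", {
  # u_M = 1, beta = 2, gamma = 1, kappa = 3, u_N = 0:
  # A2 = 1 * (2/1) * (3/2) = 3
  co <- gou_u0_coeffs(0 + 0i, 1 + 0i, sde_params(3, 1, 1, 2, 1))
  expect_equal(co$A2, 3 + 0i, tolerance = 1e-10)
  expect_equal(co$A0, -co$A1 - co$A2)
  # zero boundary data gives the zero solution
  co0 <- gou_u0_coeffs(0 + 0i, 0 + 0i, sde_params(3, 1, 1, 2, 1))
  expect_equal(Mod(co0$A0) + Mod(co0$A1) + Mod(co0$A2), 0)
})

test_that("closed-form U0 agrees with numerical integration of the characteristic ODEs", {
  # independent oracle: integrate the linear U2 -> U1 -> U0 cascade with a
  # general-purpose complex ODE solver and compare along s
  set.seed(41)
  svals <- c(0.05, 0.3, 1, 3, 8)
  for (i in 1:5) {
    p <- sde_params(runif(1, .3, 5), runif(1, .3, 5), runif(1, .3, 5),
                    runif(1, .3, 5), runif(1, .3, 5))
    th <- runif(2, 0, 2 * pi)
    uN <- exp(1i * th[1]) - 1; uM <- exp(1i * th[2]) - 1
    rhs <- function(s, y, parms) {
      list(c(-p$gamma * y[1], p$beta * (y[1] - y[2]), p$kappa * (y[2] - y[3])))
    }
    sol <- deSolve::zvode(y = c(uM, uN, 0 + 0i), times = c(0, svals), func = rhs,
                          parms = NULL, rtol = 1e-12, atol = 1e-14)
    co <- gou_u0_coeffs(uN, uM, p)
    expect_lt(max(Mod(gou_u0_eval(co, svals) - sol[-1, 4])), 1e-8)
    # boundary conditions of the characteristic solution
    expect_equal(gou_u0_eval(co, 0)[1, 1], 0 + 0i, tolerance = 1e-12)
    expect_lt(Mod(gou_u0_eval(co, 200 / min(p$kappa, p$beta, p$gamma))[1, 1]), 1e-10)
  }
})

test_that("log PGF vanishes at the normalization point and encodes the mean", {
  p <- test_params()
  expect_lt(Mod(log_pgf_gou(0 + 0i, 0 + 0i, p)), 1e-12)
  expect_lt(Mod(log_pgf_cir(0 + 0i, 0 + 0i, p)), 1e-10)
  # d phi / d u_N at 0 equals mu_N = <K>/beta (finite differences)
  h <- 1e-6
  m <- steady_state_moments(p)
  dN <- Re(log_pgf_gou(-h + 0i, 0 + 0i, p)) / (-h)
  expect_equal(dN, m$mu_N, tolerance = 1e-4)
  dNc <- Re(log_pgf_cir(-h + 0i, 0 + 0i, p)) / (-h)
  expect_equal(dNc, m$mu_N, tolerance = 1e-4)
})

test_that("cross-derivative of the diffusion-model PGF reproduces the covariance", {
  p <- test_params()
  m <- steady_state_moments(p)
  h <- 1e-4
  f <- function(uN, uM) Re(log_pgf_cir(uN + 0i, uM + 0i, p))
  d2 <- (f(h, h) - f(h, -h) - f(-h, h) + f(-h, -h)) / (4 * h^2)
  expect_equal(d2, m$cov_NM, tolerance = 1e-3)
})

test_that("constitutive PMF is the exact product of Poissons", {
  p <- sde_params(1, 1, 1, 1, 1)  # <K> = 1
  j <- joint_pmf("constitutive", p, grid_spec(n_max = 12, m_max = 12))
  expect_equal(unname(j$probs[1, 1]), exp(-2))
  expect_equal(j$probs, outer(dpois(0:12, 1), dpois(0:12, 1)),
               ignore_attr = TRUE)
})

test_that("solver PMFs are normalized, real and moment-consistent", {
  p <- test_params()
  m <- steady_state_moments(p)
  for (model in c("gou", "cir")) {
    j <- joint_pmf(model, p)
    expect_lt(abs(sum(j$probs) - 1), 1e-6)
    expect_lt(j$im_max, 1e-10)
    pm <- pmf_moments(j)
    expect_equal(pm$mu_N, m$mu_N, tolerance = 1e-4)
    expect_equal(pm$mu_M, m$mu_M, tolerance = 1e-4)
    expect_equal(pm$var_N, m$var_N, tolerance = 1e-4)
    expect_equal(pm$var_M, m$var_M, tolerance = 1e-4)
    expect_equal(pm$cov_NM, m$cov_NM, tolerance = 1e-3)
  }
})

test_that("mixture marginals are negative binomial", {
  p <- test_params()
  j <- joint_pmf("mixture", p)
  alpha <- p$a / p$kappa
  nbN <- dnbinom(0:(nrow(j$probs) - 1), size = alpha, mu = alpha * p$theta / p$beta)
  nbM <- dnbinom(0:(ncol(j$probs) - 1), size = alpha, mu = alpha * p$theta / p$gamma)
  expect_lt(max(abs(marginal_pmf(j, "nascent") - nbN)), 1e-6)
  expect_lt(max(abs(marginal_pmf(j, "mature") - nbM)), 1e-6)
})

test_that("mixture collapses to constitutive as the gamma sharpens", {
  # alpha -> infinity, theta -> 0 with alpha*theta fixed
  be <- 1.2; ga <- 0.7
  pc <- sde_params(1, 1, 5, be, ga)   # <K> = 5 constitutive reference
  jc <- joint_pmf("constitutive", pc, grid_spec(n_max = 30, m_max = 40))
  p_sharp <- sde_params(1, 5 / 4000, 4000, be, ga)  # alpha = 4000
  jm <- joint_pmf("mixture", p_sharp, grid_spec(n_max = 30, m_max = 40))
  expect_lt(tv_distance(jm, jc), 2e-3)
})

test_that("the jump model converges to geometric bursts at fast reversion, the diffusion model does not", {
  be <- 1.2; ga <- 0.7; b <- 5; K <- 10
  kap <- 1000 * max(be, ga)
  p <- sde_params(kap, b * kap, K / b, be, ga)
  g <- grid_spec(n_max = 120, m_max = 150)
  jb <- joint_pmf("bursty", p, g)
  expect_lt(tv_distance(joint_pmf("gou", p, g), jb), 1e-3)
  expect_gt(tv_distance(joint_pmf("cir", p, g), jb), 0.05)
})

test_that("diffusion solution reduces to the jump solution at small gain", {
  # both tend to the constitutive PGF as theta -> 0
  p <- sde_params(2, 0.01, 2000, 1.2, 0.7)
  th <- seq(0.3, 1.8, length.out = 4)
  u <- exp(1i * th) - 1
  d <- Mod(log_pgf_gou(u, rev(u), p) - log_pgf_cir(u, rev(u), p))
  expect_lt(max(d), 1e-3)
})

test_that("marginals sum the joint correctly", {
  j <- joint_pmf("mixture", test_params())
  expect_equal(sum(marginal_pmf(j, "nascent")), sum(j$probs))
  expect_equal(unname(marginal_pmf(j, "nascent")), unname(rowSums(j$probs)))
  u <- matrix(0.25, 2, 2)
  expect_equal(tv_distance(u, u), 0)
})

test_that("a too-small grid is refused with a size suggestion", {
  p <- test_params()
  expect_error(joint_pmf("gou", p, grid_spec(n_max = 5, m_max = 5)),
               "grid too small")
})

test_that("the compiled Riccati integrator matches the BDF reference solver", {
  p <- test_params()
  j1 <- joint_pmf("cir", p, grid_spec(n_max = 40, m_max = 50))
  j2 <- joint_pmf("cir", p, grid_spec(n_max = 40, m_max = 50, ode_solver = "zvode"))
  expect_lt(max(abs(j1$probs - j2$probs)), 1e-9)
})

test_that("PMF CSV export writes the dense matrix with mature-count header", {
  j <- joint_pmf("constitutive", sde_params(1, 1, 1, 1, 1),
                 grid_spec(n_max = 4, m_max = 5))
  f <- tempfile(fileext = ".csv")
  write_pmf_csv(j, f)
  df <- utils::read.csv(f, check.names = FALSE)
  expect_equal(dim(df), c(5, 7))   # x_N column + 6 mature columns
  expect_equal(df[1, "0"], exp(-2), tolerance = 1e-12)
})
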