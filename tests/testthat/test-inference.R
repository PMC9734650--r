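test_that("log-likelihood matches hand computation and is additive", {
  # single cell (0,0) under the unit-rate constitutive model: log e^{-2}
  d <- count_data(0, 0)
  expect_equal(as.numeric(sde_loglik(d, "constitutive",
                                     list(mean_rate = 1, beta = 1, gamma = 1))), -2)
  p <- test_params()
  d1 <- count_data(c(3, 7, 12), c(10, 15, 2))
  d2 <- count_data(rep(d1$nascent, 2), rep(d1$mature, 2))
  ll1 <- sde_loglik(d1, "gou", p)
  ll2 <- sde_loglik(d2, "gou", p)
  expect_equal(as.numeric(ll2), 2 * as.numeric(ll1), tolerance = 1e-10)
})

test_that("likelihood at slow reversion matches quadrature over the frozen-rate mixture", {
  # brute-force oracle: P(x_N, x_M) = E_K[Pois(K/beta) Pois(K/gamma)] with
  # K ~ Gamma(a/kappa, theta), by adaptive quadrature per state
  p <- params_from_regime(1e-4, 0.7, 8, 1.2, 0.7)
  states <- rbind(c(0, 0), c(3, 5), c(8, 14), c(15, 25))
  alpha <- p$a / p$kappa
  orc <- apply(states, 1, function(s) {
    f <- function(K) dgamma(K, shape = alpha, scale = p$theta) *
      dpois(s[1], K / p$beta) * dpois(s[2], K / p$gamma)
    integrate(f, 0, Inf, rel.tol = 1e-10)$value
  })
  j <- joint_pmf("gou", p)
  got <- j$probs[cbind(states[, 1] + 1, states[, 2] + 1)]
  expect_lt(max(abs(got - orc)), 1e-6)
})

test_that("constitutive MLE recovers the closed-form rate estimator", {
  set.seed(101)
  truth <- sde_params(1, 1, 10, 1, 1.7)
  d <- sample_joint_pmf(joint_pmf("constitutive", truth), 5000)
  fit <- sde_fit(d, "constitutive", fixed = list(beta = 1, gamma = 1.7),
                 n_restarts = 2, seed = 1)
  khat_oracle <- 1 * mean(d$nascent)      # beta * mean nascent
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)["mean_rate"]), khat_oracle, tolerance = 5e-3)
  se <- sqrt(10 / 5000 + 10 / 5000)       # both marginals inform the rate
  expect_lt(abs(coef(fit)["mean_rate"] - 10), 3 * se * 3)
})

test_that("fixing all parameters evaluates without optimization", {
  d <- count_data(c(1, 2), c(3, 4))
  fit <- sde_fit(d, "constitutive",
                 fixed = list(mean_rate = 2, beta = 1, gamma = 1))
  expect_equal(fit$k, 0)
  expect_equal(fit$logLik,
               as.numeric(sde_loglik(d, "constitutive",
                                     list(mean_rate = 2, beta = 1, gamma = 1))))
})

test_that("the fit object supports the standard modelling generics", {
  set.seed(103)
  p <- test_params()
  d <- sample_joint_pmf(joint_pmf("mixture", p), 600)
  fit <- sde_fit(d, "mixture", fixed = list(beta = 1), n_restarts = 2, seed = 2)
  expect_s3_class(fit, "sde_fit")
  expect_true(all(c("alpha", "theta", "beta", "gamma") %in% names(coef(fit))))
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3)
  expect_equal(AIC(fit), 2 * 3 - 2 * as.numeric(ll))
  pr <- predict(fit, "joint")
  expect_s3_class(pr, "joint_pmf")
  expect_equal(length(predict(fit, "nascent")), nrow(pr$probs))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.sde_fit")
  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_s3_class(sim, "count_data")
  expect_length(sim$nascent, 50)
  res <- residuals(fit)
  expect_true(all(is.finite(res$nascent)))
  expect_output(print(fit), "mixture")
})

test_that("Akaike weights follow the definition and flag non-convergence", {
  mk <- function(ll, k, conv = TRUE) {
    structure(list(model = "constitutive", logLik = ll, k = k, converged = conv,
                   data = count_data(0, 0)), class = "sde_fit")
  }
  w <- akaike_weights(list(a = mk(-10, 2), b = mk(-10, 2), c = mk(-10, 2)))
  expect_equal(unname(w), rep(1 / 3, 3))
  # Delta AIC of +20 gives weight < 1e-4
  w2 <- akaike_weights(list(good = mk(-10, 2), bad = mk(-20, 2)))
  expect_lt(w2[["bad"]], 1e-4)
  expect_equal(sum(w2), 1)
  expect_warning(w3 <- akaike_weights(list(a = mk(-10, 2), b = mk(-5, 2, FALSE))),
                 "non-converged")
  expect_true(is.na(w3[["b"]]))
})

test_that("grid evidence matches a hand-computed enumeration oracle", {
  set.seed(104)
  d <- sample_joint_pmf(joint_pmf("constitutive", sde_params(1, 1, 6, 1, 1.4)), 80)
  pri <- prior_spec(bounds = list(mean_rate = c(2, 20)),
                    fixed = list(beta = 1, gamma = 1.4))
  post <- posterior_grid(d, "constitutive", pri, n_grid = 41)
  # oracle: same trapezoid quadrature computed directly from Poisson products
  ax <- seq(log10(2), log10(20), length.out = 41)
  ll <- vapply(ax, function(lk) {
    K <- 10^lk
    sum(dpois(d$nascent, K / 1, log = TRUE) + dpois(d$mature, K / 1.4, log = TRUE))
  }, 0)
  h <- diff(ax[1:2]); w <- rep(h, 41); w[c(1, 41)] <- h / 2
  m <- max(ll)
  l10ev <- (m + log(sum(w * exp(ll - m)))) / log(10) - log10(diff(range(ax)))
  expect_equal(post$log10_evidence, l10ev, tolerance = 1e-6)
  # posterior mode sits at the best enumerated node
  expect_equal(10^post$mode[["mean_rate"]], 10^ax[which.max(ll)],
               tolerance = 1e-9)
})

test_that("Bayes factors are zero for self-comparison and antisymmetric", {
  set.seed(105)
  p <- test_params()
  d <- sample_joint_pmf(joint_pmf("cir", p), 300)
  pri <- prior_spec(fixed = list(beta = p$beta, gamma = p$gamma,
                                 mean_rate = p$mean_rate))
  self <- log10_bayes_factor(d, "gou", "gou", pri, n_grid = 5)
  expect_equal(self$log10_bf, 0)
  ab <- log10_bayes_factor(d, "cir", "gou", pri, n_grid = 5)
  ba <- log10_bayes_factor(d, "gou", "cir", pri, n_grid = 5)
  expect_equal(ab$log10_bf, -ba$log10_bf)
})

test_that("the DE-Metropolis sampler concentrates on the rate of constitutive data", {
  set.seed(106)
  d <- sample_joint_pmf(joint_pmf("constitutive", sde_params(1, 1, 8, 1, 1.4)), 400)
  pri <- prior_spec(bounds = list(mean_rate = c(4, 16)),
                    fixed = list(beta = 1, gamma = 1.4))
  ch <- posterior_sample(d, "constitutive", pri, n_chains = 3, n_burn = 150,
                         n_iter = 350, seed = 3)
  draws <- 10^as.vector(ch$draws[, , "mean_rate"])
  expect_lt(abs(mean(draws) - 8), 0.5)
  expect_true(all(ch$rhat < 1.1))
  # agrees with the deterministic grid posterior (fine grid resolves the CI)
  post <- posterior_grid(d, "constitutive", pri, n_grid = 81)
  ci <- marginal_interval(post, "mean_rate", 0.95)
  expect_gt(ci[2] / ci[1], 1.01)
  expect_gt(mean(draws >= ci[1] & draws <= ci[2]), 0.85)
})

test_that("marginal-channel likelihoods drop information but stay consistent", {
  p <- test_params()
  set.seed(107)
  d <- sample_joint_pmf(joint_pmf("gou", p), 200)
  llj <- as.numeric(sde_loglik(d, "gou", p, data_mode = "joint"))
  lln <- as.numeric(sde_loglik(d, "gou", p, data_mode = "nascent"))
  llm <- as.numeric(sde_loglik(d, "gou", p, data_mode = "mature"))
  expect_true(lln > llj && llm > llj)  # marginals are higher-probability events
})
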