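# Shared test fixtures and independent oracles.

# A moderate overdispersed parameter set used across tests.
test_params <- function() params_from_regime(0.5, 0.5, 10, 1.2, 0.7)

# Independent exact sampler of stationary counts for the jump-driven model,
# by the Poisson representation: conditional on the rate path K(t), the
# counts at time T are independent Poissons with means given by
# exponentially weighted path integrals (each decaying pulse contributes in
# closed form).  Shares no code with the event-driven simulator.
sample_gou_poisson_rep <- function(p, n_cells, t_end = NULL) {
  if (is.null(t_end)) t_end <- 15 / min(p$beta, p$gamma)
  kap <- p$kappa; be <- p$beta; ga <- p$gamma
  wN <- function(d) (exp(-kap * d) - exp(-be * d)) / (be - kap)
  wM <- function(d) be / (be - ga) *
    ((exp(-ga * d) - exp(-kap * d)) / (kap - ga) -
     (exp(-be * d) - exp(-kap * d)) / (kap - be))
  xN <- integer(n_cells); xM <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    path <- sample_gou_path(p, t_end)
    amps <- c(path$K0, path$jump_sizes)
    d <- t_end - c(0, path$jump_times)
    lamN <- sum(amps * wN(d)); lamM <- sum(amps * wM(d))
    xN[i] <- stats::rpois(1, lamN); xM[i] <- stats::rpois(1, lamM)
  }
  count_data(xN, xM)
}

# Pearson chi-squared goodness-of-fit p-value of paired counts against a
# joint PMF, pooling cells with expected count below `pool`.
chi2_gof_p <- function(data, pmf, pool = 5) {
  n <- length(data$nascent)
  Np <- nrow(pmf$probs); Mp <- ncol(pmf$probs)
  obs <- table(factor(pmin(data$nascent, Np - 1L), levels = 0:(Np - 1L)),
               factor(pmin(data$mature, Mp - 1L), levels = 0:(Mp - 1L)))
  expd <- pmf$probs * n
  main <- expd >= pool
  stat <- sum((obs[main] - expd[main])^2 / expd[main])
  o_rest <- sum(obs[!main]); e_rest <- max(sum(expd[!main]), 1e-12)
  stat <- stat + (o_rest - e_rest)^2 / e_rest
  df <- sum(main)  # pooled cell adds 1, normalization removes 1
  stats::pchisq(stat, df, lower.tail = FALSE)
}

# z-scores of empirical moments against closed-form values, with
# moment-based standard errors estimated from the sample itself.
moment_z_scores <- function(data, m) {
  xN <- data$nascent; xM <- data$mature; n <- length(xN)
  se_mean <- function(x) stats::sd(x) / sqrt(n)
  se_var <- function(x) {
    mu <- mean(x); m4 <- mean((x - mu)^4); v <- stats::var(x)
    sqrt(max(m4 - v^2, 0) / n)
  }
  se_cov <- function(x, y) {
    cx <- x - mean(x); cy <- y - mean(y)
    sqrt(max(mean(cx^2 * cy^2) - mean(cx * cy)^2, 0) / n)
  }
  c(mu_N = (mean(xN) - m$mu_N) / se_mean(xN),
    mu_M = (mean(xM) - m$mu_M) / se_mean(xM),
    var_N = (stats::var(xN) - m$var_N) / se_var(xN),
    var_M = (stats::var(xM) - m$var_M) / se_var(xM),
    cov_NM = (stats::cov(xN, xM) - m$cov_NM) / se_cov(xN, xM))
}

# z-scores for the difference of two samples' moments (shared closed form).
moment_diff_z <- function(a, b) {
  se2_mean <- function(x) stats::var(x) / length(x)
  se2_var <- function(x) {
    mu <- mean(x); v <- stats::var(x)
    max(mean((x - mu)^4) - v^2, 0) / length(x)
  }
  c(mu_N = (mean(a$nascent) - mean(b$nascent)) /
      sqrt(se2_mean(a$nascent) + se2_mean(b$nascent)),
    mu_M = (mean(a$mature) - mean(b$mature)) /
      sqrt(se2_mean(a$mature) + se2_mean(b$mature)),
    var_N = (stats::var(a$nascent) - stats::var(b$nascent)) /
      sqrt(se2_var(a$nascent) + se2_var(b$nascent)),
    var_M = (stats::var(a$mature) - stats::var(b$mature)) /
      sqrt(se2_var(a$mature) + se2_var(b$mature)))
}

# fast-equilibration protocol: the rate process starts in its exact
# stationary law, so only the count transient (time scale 1/min(beta,gamma))
# must be burned in.
fast_protocol <- function(p, ...) {
  suppressWarnings(sim_protocol(p, t_ss = 15 / min(p$beta, p$gamma), ...))
}

# One small multi-replicate fixture shared by the pipeline tests (generated
# once per test run).
.fixture_cache <- new.env()
pipeline_fixture <- function() {
  if (is.null(.fixture_cache$fx)) {
    spec <- fixture_spec(n_genes_per_regime = 1, n_cells = c(500, 400),
                         n_subtypes = 2, planted_filter_genes = FALSE,
                         low_depth_fraction = 0, seed = 43,
                         mean_rate_range = c(6, 9))
    dir <- tempfile()
    fx <- generate_fixture(spec, dir)
    tables <- lapply(fx$dirs, read_count_matrices)
    .fixture_cache$fx <- list(ground_truth = fx$ground_truth, dirs = fx$dirs,
                              tables = tables,
                              regimes = assign_regimes(tables[[1]]))
  }
  .fixture_cache$fx
}
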