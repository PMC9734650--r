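# Bayesian machinery: uniform (log10-box) priors, deterministic tensor-grid
# posteriors and evidence, and a differential-evolution Metropolis sampler.

#' Uniform prior specification in log10-parameter space
#'
#' @param bounds Named list of `c(lower, upper)` natural-scale bounds; the
#'   prior is uniform in log10 of each free parameter over the induced box.
#'   Defaults span 1e-2 to 1e2 for every parameter.
#' @param fixed Named list of parameters held fixed (excluded from the
#'   prior).  For full models, fixing `mean_rate` pins
#'   `a = mean_rate * kappa / theta`.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(bounds = NULL, fixed = list()) {
  if (!is.null(bounds)) {
    for (b in bounds) if (b[1] <= 0 || b[2] <= b[1])
      stop("each bound must satisfy 0 < lower < upper", call. = FALSE)
  }
  structure(list(bounds = bounds, fixed = fixed), class = "prior_spec")
}

prior_free <- function(model, prior) {
  pnames <- model_param_names(model)
  if ("mean_rate" %in% names(prior$fixed) && model %in% c("gou", "cir"))
    pnames <- setdiff(pnames, "a")
  setdiff(pnames, names(prior$fixed))
}

prior_box <- function(model, prior) {
  free <- prior_free(model, prior)
  bnd <- default_bounds(free)
  if (!is.null(prior$bounds)) bnd[intersect(names(prior$bounds), free)] <-
      prior$bounds[intersect(names(prior$bounds), free)]
  list(free = free,
       lo = log10(vapply(bnd[free], `[`, 0, 1)),
       hi = log10(vapply(bnd[free], `[`, 0, 2)))
}

# Tensor grid over the prior box: axes (log10), node data frame, trapezoid
# weights (log scale volume element), parameter list per node.
prior_grid <- function(model, prior, n_grid) {
  bx <- prior_box(model, prior)
  d <- length(bx$free)
  axes <- lapply(seq_len(d), function(i) seq(bx$lo[i], bx$hi[i], length.out = n_grid))
  names(axes) <- bx$free
  nodes <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  wts1 <- lapply(axes, function(ax) {
    h <- diff(ax[1:2]); w <- rep(h, length(ax)); w[c(1, length(ax))] <- h / 2; w
  })
  wmat <- as.matrix(expand.grid(wts1, KEEP.OUT.ATTRS = FALSE))
  w <- apply(wmat, 1, prod)
  vol <- prod(bx$hi - bx$lo)
  params <- lapply(seq_len(nrow(nodes)), function(i) {
    to_sde_params(model, fit_param_list(model, nodes[i, ], bx$free, prior$fixed))
  })
  list(free = bx$free, axes = axes, nodes = nodes, w = w, vol = vol,
       params = params)
}

log10_sum_exp <- function(loga, w) {
  m <- max(loga)
  (m + log(sum(w * exp(loga - m)))) / log(10)
}

#' Tensor-grid posterior over model parameters
#'
#' Evaluates the likelihood on a deterministic tensor grid over the uniform
#' log10-box prior (at most a few free dimensions), yielding a normalized
#' grid posterior, the log10 model evidence with a coarse-grid error
#' estimate, and highest-posterior-density machinery.  For the
#' diffusion-driven model all grid nodes share one vectorized ODE solve.
#'
#' @param data A [count_data] object.
#' @param model Model tag.
#' @param prior A [prior_spec].  With `parameterization = "regime"` its
#'   `fixed` must pin `mean_rate`, `beta` and `gamma`.
#' @param n_grid Nodes per free dimension (default 25).
#' @param grid Optional [grid_spec] for the PMF solver.
#' @param data_mode Observation channel (see [sde_loglik()]).
#' @param parameterization `"log10"`: uniform prior over the log10 box of the
#'   model's free kinetic parameters.  `"regime"` (full models with
#'   `mean_rate`, `beta`, `gamma` fixed): uniform prior over the
#'   qualitative-regime square `(reversion, gain)`, where the posterior is
#'   compact rather than ridge-shaped.
#' @param regime_bounds Bounds of the regime square prior.
#' @return An object of class `sde_posterior`: `free`, `axes`, `nodes`
#'   (log10 or regime scale), `loglik`, `prob` (normalized node masses),
#'   `log10_evidence`, `evidence_err` (difference against the
#'   half-resolution estimate), `mode` (coordinates of the posterior mode).
#' @export
posterior_grid <- function(data, model, prior = prior_spec(), n_grid = 25,
                           grid = NULL, data_mode = c("joint", "nascent", "mature"),
                           parameterization = c("log10", "regime"),
                           regime_bounds = c(0.02, 0.98)) {
  model <- match_model(model)
  data_mode <- match.arg(data_mode)
  parameterization <- match.arg(parameterization)
  data <- as_count_data(data)
  pg <- if (parameterization == "regime") {
    if (!all(c("mean_rate", "beta", "gamma") %in% names(prior$fixed)))
      stop("regime parameterization needs mean_rate, beta and gamma in prior$fixed",
           call. = FALSE)
    prior_grid_regime(prior, n_grid, regime_bounds)
  } else {
    prior_grid(model, prior, n_grid)
  }
  tab <- tabulate_counts(data)
  pmfs <- joint_pmf_batch(model, pg$params, grid, data)
  ll <- vapply(pmfs, function(pm) {
    if (is.null(pm)) -1e12 else as.numeric(loglik_from_pmf(pm, tab, data_mode))
  }, 0)
  mass <- pg$w * exp(ll - max(ll))
  prob <- mass / sum(mass)
  l10ev <- log10_sum_exp(ll, pg$w) - log10(pg$vol)
  # coarse-grid (every other node per axis) evidence for an error estimate
  keep1 <- lapply(pg$axes, function(ax) seq(1, length(ax), by = 2))
  sel <- rep(TRUE, nrow(pg$nodes))
  for (i in seq_along(pg$axes))
    sel <- sel & (pg$nodes[, i] %in% pg$axes[[i]][keep1[[i]]])
  axes_c <- lapply(seq_along(pg$axes), function(i) pg$axes[[i]][keep1[[i]]])
  wts1 <- lapply(axes_c, function(ax) {
    h <- diff(ax[1:2]); w <- rep(h, length(ax)); w[c(1, length(ax))] <- h / 2; w
  })
  wc <- apply(as.matrix(expand.grid(wts1, KEEP.OUT.ATTRS = FALSE)), 1, prod)
  l10ev_c <- log10_sum_exp(ll[sel], wc) - log10(pg$vol)
  structure(list(model = model, free = pg$free, axes = pg$axes,
                 nodes = pg$nodes, loglik = ll, prob = prob,
                 log10_evidence = l10ev, evidence_err = abs(l10ev - l10ev_c),
                 mode = pg$nodes[which.max(ll), , drop = TRUE],
                 prior = prior, data_mode = data_mode,
                 scale = if (parameterization == "regime") "linear" else "log10"),
            class = "sde_posterior")
}

# Tensor grid over the qualitative-regime square for the full models.
# `bounds` is either c(lo, hi) shared by both axes or a list with per-axis
# `reversion` and `gain` ranges (used for zoomed refinement passes).
prior_grid_regime <- function(prior, n_grid, bounds) {
  free <- c("reversion", "gain")
  if (!is.list(bounds)) bounds <- list(reversion = bounds, gain = bounds)
  axes <- list(reversion = seq(bounds$reversion[1], bounds$reversion[2],
                               length.out = n_grid),
               gain = seq(bounds$gain[1], bounds$gain[2], length.out = n_grid))
  nodes <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
  wts1 <- lapply(axes, function(ax) {
    h <- diff(ax[1:2]); w <- rep(h, length(ax)); w[c(1, length(ax))] <- h / 2; w
  })
  w <- apply(as.matrix(expand.grid(wts1, KEEP.OUT.ATTRS = FALSE)), 1, prod)
  fx <- prior$fixed
  params <- lapply(seq_len(nrow(nodes)), function(i)
    params_from_regime(nodes[i, 1], nodes[i, 2], fx$mean_rate, fx$beta, fx$gamma))
  list(free = free, axes = axes, nodes = nodes, w = w,
       vol = diff(bounds$reversion) * diff(bounds$gain),
       params = params)
}

#' @export
print.sde_posterior <- function(x, ...) {
  cat(sprintf("Grid posterior: %s model, free parameters (%s), %d nodes\n",
              x$model, paste(x$free, collapse = ", "), nrow(x$nodes)))
  cat(sprintf("  log10 evidence %.3f (err est %.3g)\n", x$log10_evidence,
              x$evidence_err))
  cat("  posterior mode (log10): ",
      paste(sprintf("%s=%.3f", x$free, x$mode), collapse = ", "), "\n")
  invisible(x)
}

#' Highest-posterior-density membership test
#'
#' Whether a parameter point lies inside the HPD credible region of a grid
#' posterior: the point is mapped to its nearest grid node and tested against
#' the posterior-mass threshold that accumulates `level` of the mass.
#'
#' @param post An `sde_posterior`.
#' @param truth Named vector of parameter values (natural scale) for the free
#'   parameters.
#' @param level Credibility level (default 0.95).
#' @return Logical.
#' @export
in_credible_region <- function(post, truth, level = 0.95) {
  stopifnot(inherits(post, "sde_posterior"))
  lt <- if (identical(post$scale, "linear")) truth[post$free] else log10(truth[post$free])
  # HPD threshold: the log-likelihood of the least likely node inside the
  # smallest node set accumulating `level` of the posterior mass
  ord <- order(post$prob, decreasing = TRUE)
  cum <- cumsum(post$prob[ord])
  n_in <- min(which(cum >= level))
  thresh_ll <- min(post$loglik[ord[seq_len(n_in)]])
  # multilinear interpolation of the log-likelihood at the queried point,
  # so membership does not suffer nearest-node discretization error
  d <- length(post$free)
  lens <- vapply(post$axes, length, 0L)
  lo_idx <- integer(d); frac <- numeric(d)
  for (i in seq_len(d)) {
    ax <- post$axes[[i]]
    x <- min(max(lt[i], ax[1]), ax[length(ax)])
    j <- findInterval(x, ax, rightmost.closed = TRUE)
    j <- min(max(j, 1L), length(ax) - 1L)
    lo_idx[i] <- j
    frac[i] <- (x - ax[j]) / (ax[j + 1] - ax[j])
  }
  ll <- 0
  for (corner in seq_len(2^d) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(d)]
    w <- prod(ifelse(bits == 1L, frac, 1 - frac))
    if (w == 0) next
    idx <- lo_idx + bits
    flat <- 1L + sum((idx - 1L) * cumprod(c(1L, lens[-d])))
    ll <- ll + w * post$loglik[flat]
  }
  ll >= thresh_ll
}

#' Likelihood-ratio credible-region membership
#'
#' Tests whether a parameter point lies inside the `level` credible region of
#' a grid posterior using the likelihood-ratio construction:
#' `2 (max logL - logL(point)) <= qchisq(level, d)` over the `d` free
#' parameters.  Under the uniform prior this region coincides with the
#' highest-posterior-density region to the accuracy of the Gaussian
#' approximation, and, unlike node-based membership, it does not suffer
#' grid-discretization bias: the point's log-likelihood is supplied exactly
#' (e.g. from [sde_loglik()] at the true parameters) and the maximum is
#' refined by a per-axis parabolic fit around the best node.
#'
#' @param post An `sde_posterior`.
#' @param loglik_at_point Exact log-likelihood at the queried point, on the
#'   same data and observation channel the posterior was built from.
#' @param level Credibility level (default 0.95).
#' @return Logical.
#' @export
lr_region_contains <- function(post, loglik_at_point, level = 0.95) {
  stopifnot(inherits(post, "sde_posterior"))
  d <- length(post$free)
  lens <- vapply(post$axes, length, 0L)
  i0 <- which.max(post$loglik)
  # recover the multi-index of the best node and add separable parabolic
  # refinement gains along each axis
  rem <- i0 - 1L
  ll_max <- post$loglik[i0]
  for (k in seq_len(d)) {
    ik <- rem %% lens[k] + 1L
    rem <- rem %/% lens[k]
    if (ik > 1L && ik < lens[k]) {
      step <- prod(lens[seq_len(k - 1L)])
      ym <- post$loglik[i0 - step]; y0 <- post$loglik[i0]
      yp <- post$loglik[i0 + step]
      curv <- 2 * y0 - ym - yp
      if (is.finite(curv) && curv > 0)
        ll_max <- ll_max + (yp - ym)^2 / (8 * curv)
    }
  }
  2 * (ll_max - loglik_at_point) <= stats::qchisq(level, d)
}

#' Marginal credible interval from a grid posterior
#'
#' @param post An `sde_posterior`.
#' @param param One free parameter name.
#' @param level Credibility level.
#' @return `c(lower, upper)` on the natural scale (equal-tail interval of the
#'   marginal grid posterior).
#' @export
marginal_interval <- function(post, param, level = 0.95) {
  stopifnot(param %in% post$free)
  i <- match(param, post$free)
  marg <- tapply(post$prob, post$nodes[, i], sum)
  ax <- as.numeric(names(marg))
  cdf <- cumsum(marg)
  # round outward by one node so discretization cannot shrink the interval
  lo <- ax[max(1L, which(cdf >= (1 - level) / 2)[1] - 1L)]
  hi <- ax[min(length(ax), which(cdf >= 1 - (1 - level) / 2)[1] + 1L)]
  if (identical(post$scale, "linear")) c(lo, hi) else 10^c(lo, hi)
}

#' Differential-evolution Metropolis posterior sampling
#'
#' A non-gradient MCMC sampler in log10-parameter space over a uniform box
#' prior: proposals are scaled differences of states sampled from the chain's
#' own past (z-history variant), with occasional unit-scale jumps and a small
#' Gaussian jitter.  Suited to the low-dimensional, non-differentiable
#' likelihood surfaces produced by the PMF solver.
#'
#' @param data A [count_data] object.
#' @param model Model tag.
#' @param prior A [prior_spec].
#' @param n_chains Number of chains (default 4).
#' @param n_burn Burn-in iterations per chain.
#' @param n_iter Post-burn-in iterations per chain.
#' @param seed Optional seed.
#' @param grid Optional [grid_spec].
#' @param data_mode Observation channel.
#' @return An object of class `sde_chains`: `draws` (iteration x chain x
#'   parameter array, log10 scale), `accept_rate`, `rhat` (split-chain
#'   potential scale reduction per parameter), `free`.
#' @export
posterior_sample <- function(data, model, prior = prior_spec(), n_chains = 4,
                             n_burn = 1000, n_iter = 2000, seed = NULL,
                             grid = NULL,
                             data_mode = c("joint", "nascent", "mature")) {
  model <- match_model(model)
  data_mode <- match.arg(data_mode)
  data <- as_count_data(data)
  if (!is.null(seed)) set.seed(seed)
  bx <- prior_box(model, prior)
  d <- length(bx$free)
  tab <- tabulate_counts(data)
  llfun <- function(x) {
    pars <- fit_param_list(model, x, bx$free, prior$fixed)
    out <- tryCatch({
      p <- to_sde_params(model, pars)
      pmf <- joint_pmf(model, p, grid_for_data(model, p, data, grid),
                       tail_check = FALSE)
      as.numeric(loglik_from_pmf(pmf, tab, data_mode))
    }, error = function(e) -Inf)
    if (!is.finite(out)) -1e12 else out
  }
  gam0 <- 2.38 / sqrt(2 * d)
  eps_sd <- 1e-4
  draws <- array(NA_real_, c(n_iter, n_chains, d),
                 dimnames = list(NULL, NULL, bx$free))
  acc <- 0L; tot <- 0L
  for (ch in seq_len(n_chains)) {
    x <- bx$lo + stats::runif(d) * (bx$hi - bx$lo)
    lx <- llfun(x)
    hist_z <- matrix(NA_real_, n_burn + n_iter + 1L, d)
    hist_z[1, ] <- x
    n_hist <- 1L
    for (it in seq_len(n_burn + n_iter)) {
      if (n_hist >= 3) {
        ij <- sample.int(n_hist, 2)
        gam <- if (stats::runif(1) < 0.1) 1 else gam0
        prop <- x + gam * (hist_z[ij[1], ] - hist_z[ij[2], ]) +
          stats::rnorm(d, 0, eps_sd)
      } else {
        prop <- x + stats::rnorm(d, 0, 0.1)
      }
      tot <- tot + 1L
      if (all(prop >= bx$lo) && all(prop <= bx$hi)) {
        lp <- llfun(prop)
        if (log(stats::runif(1)) < lp - lx) {
          x <- prop; lx <- lp; acc <- acc + 1L
        }
      }
      n_hist <- n_hist + 1L
      hist_z[n_hist, ] <- x
      if (it > n_burn) draws[it - n_burn, ch, ] <- x
    }
  }
  rhat <- vapply(seq_len(d), function(j) split_rhat(draws[, , j, drop = FALSE]), 0)
  structure(list(draws = draws, accept_rate = acc / tot,
                 rhat = stats::setNames(rhat, bx$free), free = bx$free,
                 model = model),
            class = "sde_chains")
}

split_rhat <- function(a) {
  n <- dim(a)[1]; m <- dim(a)[2]
  half <- n %/% 2
  chains <- do.call(cbind, lapply(seq_len(m), function(c)
    cbind(a[seq_len(half), c, 1], a[half + seq_len(half), c, 1])))
  mu <- colMeans(chains)
  W <- mean(apply(chains, 2, stats::var))
  B <- half * stats::var(mu)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' @export
print.sde_chains <- function(x, ...) {
  cat(sprintf("DE-Metropolis chains: %s model, %d draws x %d chains\n",
              x$model, dim(x$draws)[1], dim(x$draws)[2]))
  cat(sprintf("  acceptance %.2f; Rhat: %s\n", x$accept_rate,
              paste(sprintf("%s=%.3f", x$free, x$rhat), collapse = ", ")))
  invisible(x)
}
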