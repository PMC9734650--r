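# Maximum-likelihood fitting of the SDE-driven and limiting models to paired
# nascent/mature counts: box-constrained quasi-Newton optimization in
# log10-parameter space with multi-start (moment-matched initial plus Latin
# hypercube restarts).

default_bounds <- function(free) {
  b <- list(kappa = c(1e-2, 1e2), theta = c(1e-2, 1e2), a = c(1e-2, 1e2),
            beta = c(1e-2, 1e2), gamma = c(1e-2, 1e2),
            alpha = c(1e-2, 1e2), b = c(1e-2, 1e2), mean_rate = c(1e-2, 1e3))
  b[free]
}

# Crude method-of-moments starting values; clamped into bounds.
moment_init <- function(model, data, fixed, free, bounds) {
  muN <- max(mean(data$nascent), 1e-3)
  muM <- max(mean(data$mature), 1e-3)
  dN <- max(stats::var(data$nascent) / muN - 1, 0.05)   # overdispersion theta/(kappa+beta)
  est <- list(beta = 1, gamma = muN / muM, kappa = 1)
  est$gamma <- max(est$gamma, 1e-2)
  be <- if (!is.null(fixed$beta)) fixed$beta else est$beta
  K <- if (!is.null(fixed$mean_rate)) fixed$mean_rate else muN * be
  est$mean_rate <- K
  est$theta <- dN * (est$kappa + be)
  est$a <- K * est$kappa / est$theta
  est$alpha <- max(muN^2 / max(stats::var(data$nascent) - muN, muN * 0.05), 0.05)
  est$b <- dN
  init <- unlist(est[free])
  for (nm in free) init[nm] <- min(max(init[nm], bounds[[nm]][1] * 1.01),
                                   bounds[[nm]][2] * 0.99)
  init
}

fit_param_list <- function(model, x_free, free, fixed) {
  pars <- as.list(fixed)
  pars[free] <- as.list(10^x_free)
  pars
}

#' Fit an SDE-driven transcription model by maximum likelihood
#'
#' The central model-fitting entry point.  Fits any of the five model kinds
#' to paired nascent/mature counts for one gene by box-constrained L-BFGS-B
#' in log10-parameter space, with a moment-matched starting point plus Latin
#' hypercube restarts.  Full models (`"gou"`, `"cir"`) are parameterized by
#' `(kappa, theta, a, beta, gamma)`; since the stationary distribution is
#' invariant under a joint rescaling of time, one rate (conventionally
#' `beta = 1`) should be fixed, leaving the four identifiable parameters.
#' Limiting models use their natural parameters: mixture `(alpha, theta,
#' beta, gamma)`, bursty `(a, b, beta, gamma)` with `b` the mean burst size,
#' constitutive `(mean_rate, beta, gamma)`.  Supplying `mean_rate` in
#' `fixed` for a full model pins `a = mean_rate * kappa / theta`.
#'
#' @param data A [count_data] object (or list with `nascent`/`mature`).
#' @param model Model tag.
#' @param fixed Named list of parameters held fixed (default `beta = 1` for
#'   full models, empty otherwise).
#' @param bounds Named list of `c(lower, upper)` bounds (natural scale) for
#'   free parameters; sensible defaults span 1e-2 to 1e2.
#' @param n_restarts Number of optimizer starts (first is moment-matched).
#' @param seed Optional seed for the restart design.
#' @param grid Optional [grid_spec] forwarded to the likelihood.
#' @param data_mode Observation channel for the likelihood (see
#'   [sde_loglik()]).
#' @param control Passed to [stats::optim()].
#' @return An object of class `sde_fit` with methods `print`, `summary`,
#'   `coef`, `logLik`, `predict`, `simulate`, `plot` and `residuals`.
#' @examples
#' \donttest{
#' p <- params_from_regime(0.5, 0.5, 10, 1.2, 0.7)
#' dat <- simulate_cells("gou", p, 400, seed = 1)
#' fit <- sde_fit(dat, "mixture", n_restarts = 2, seed = 1)
#' coef(fit); logLik(fit)
#' }
#' @export
sde_fit <- function(data, model, fixed = NULL, bounds = NULL,
                    n_restarts = 5, seed = NULL, grid = NULL,
                    data_mode = c("joint", "nascent", "mature"),
                    control = list(maxit = 300)) {
  model <- match_model(model)
  data_mode <- match.arg(data_mode)
  data <- as_count_data(data)
  if (!length(data$nascent)) stop("empty count data", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pnames <- model_param_names(model)
  if (is.null(fixed)) fixed <- if (model %in% c("gou", "cir")) list(beta = 1) else list()
  if ("mean_rate" %in% names(fixed) && model %in% c("gou", "cir"))
    pnames <- setdiff(pnames, "a")
  free <- setdiff(pnames, names(fixed))
  if (!length(free)) {  # everything fixed: just evaluate
    ll <- as.numeric(sde_loglik(data, model, to_sde_params(model, fixed), grid,
                                data_mode))
    return(new_sde_fit(model, fixed, character(0), fixed, ll, TRUE, 0L, data,
                       data_mode, grid))
  }
  bnd <- default_bounds(free)
  if (!is.null(bounds)) bnd[names(bounds)] <- bounds
  lo <- log10(vapply(bnd[free], `[`, 0, 1))
  hi <- log10(vapply(bnd[free], `[`, 0, 2))
  tab <- tabulate_counts(data)
  negll <- function(x) {
    pars <- fit_param_list(model, x, free, fixed)
    out <- tryCatch({
      p <- to_sde_params(model, pars)
      pmf <- joint_pmf(model, p, grid_for_data(model, p, data, grid),
                       tail_check = FALSE)
      -as.numeric(loglik_from_pmf(pmf, tab, data_mode))
    }, error = function(e) NA_real_)
    if (!is.finite(out)) 1e10 else out
  }
  starts <- matrix(moment_init(model, data, fixed, free, bnd), nrow = 1,
                   dimnames = list(NULL, free))
  starts <- log10(starts)
  if (n_restarts > 1) {
    u <- lhs::randomLHS(n_restarts - 1, length(free))
    more <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
    colnames(more) <- free
    starts <- rbind(starts, more)
  }
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    n_used <- n_used + 1L
    opt <- tryCatch(
      stats::optim(pmin(pmax(starts[i, ], lo), hi), negll, method = "L-BFGS-B",
                   lower = lo, upper = hi, control = control),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) {
    return(new_sde_fit(model, fixed, free, NULL, -Inf, FALSE, n_used, data,
                       data_mode, grid))
  }
  pars <- fit_param_list(model, best$par, free, fixed)
  new_sde_fit(model, fixed, free, pars, -best$value,
              best$convergence %in% c(0L, 1L), n_used, data, data_mode, grid,
              optim = best)
}

new_sde_fit <- function(model, fixed, free, pars, loglik, converged, n_used,
                        data, data_mode, grid, optim = NULL) {
  coefs <- if (is.null(pars)) NULL else unlist(pars[model_param_names(model)[
    model_param_names(model) %in% names(pars)]])
  structure(list(model = model, coef = coefs, free = free,
                 fixed = fixed, logLik = loglik, k = length(free),
                 converged = converged, n_restarts_used = n_used,
                 data = data, data_mode = data_mode, grid = grid,
                 optim = optim),
            class = "sde_fit")
}

#' @export
print.sde_fit <- function(x, ...) {
  cat(sprintf("Maximum-likelihood fit: %s model (%d cells, %s likelihood)\n",
              x$model, length(x$data$nascent), x$data_mode))
  if (!x$converged) {
    cat("  ** did not converge **\n")
  }
  if (!is.null(x$coef)) {
    lab <- ifelse(names(x$coef) %in% x$free, "", " (fixed)")
    cat(paste0(sprintf("  %-9s %.5g%s", names(x$coef), x$coef, lab),
               collapse = "\n"), "\n")
  }
  cat(sprintf("  logLik %.3f  (k = %d free parameters)\n", x$logLik, x$k))
  invisible(x)
}

#' @export
coef.sde_fit <- function(object, ...) object$coef

#' @export
logLik.sde_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = length(object$data$nascent),
            class = "logLik")
}

#' @export
summary.sde_fit <- function(object, ...) {
  out <- list(fit = object,
              aic = 2 * object$k - 2 * object$logLik,
              mu_N = mean(object$data$nascent), mu_M = mean(object$data$mature))
  if (object$model %in% c("gou", "cir") && !is.null(object$coef)) {
    p <- to_sde_params(object$model, as.list(object$coef))
    out$regime <- regime_coords(p)
    out$moments <- steady_state_moments(p)
  }
  structure(out, class = "summary.sde_fit")
}

#' @export
print.summary.sde_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC %.3f\n", x$aic))
  if (!is.null(x$regime))
    cat(sprintf("  regime coordinates: reversion %.3f, gain %.3f\n",
                x$regime[["reversion"]], x$regime[["gain"]]))
  invisible(x)
}

#' Fitted joint or marginal PMF
#'
#' @param object An `sde_fit`.
#' @param type `"joint"` for the full `joint_pmf`, `"nascent"`/`"mature"` for
#'   a marginal vector.
#' @param ... Unused.
#' @export
predict.sde_fit <- function(object, type = c("joint", "nascent", "mature"), ...) {
  type <- match.arg(type)
  if (is.null(object$coef)) stop("fit did not converge; no parameters", call. = FALSE)
  p <- to_sde_params(object$model, as.list(object$coef))
  pmf <- joint_pmf(object$model, p, grid_for_data(object$model, p, object$data,
                                                  object$grid), tail_check = FALSE)
  if (type == "joint") pmf else marginal_pmf(pmf, type)
}

#' Simulate new cells from a fitted model
#'
#' Full models are re-simulated with the hybrid stochastic simulator;
#' limiting models are sampled from their exact PMF.
#'
#' @param object An `sde_fit`.
#' @param nsim Number of cells.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A [count_data] object.
#' @export
simulate.sde_fit <- function(object, nsim = length(object$data$nascent),
                             seed = NULL, ...) {
  if (is.null(object$coef)) stop("fit did not converge; no parameters", call. = FALSE)
  p <- to_sde_params(object$model, as.list(object$coef))
  if (object$model %in% c("gou", "cir")) {
    simulate_cells(object$model, p, nsim, seed = seed)
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample_joint_pmf(joint_pmf(object$model, p), nsim)
  }
}

#' Pearson residuals of the fitted marginals
#'
#' Residuals `(observed - expected) / sqrt(expected)` of the pooled marginal
#' count histograms under the fitted PMF, for both species.
#'
#' @param object An `sde_fit`.
#' @param ... Unused.
#' @return A list with `nascent` and `mature` residual vectors (one entry per
#'   count value on the fitted grid).
#' @export
residuals.sde_fit <- function(object, ...) {
  pmf <- predict(object, "joint")
  n <- length(object$data$nascent)
  res <- function(x, marg) {
    obs <- tabulate(x + 1L, nbins = length(marg))
    expd <- pmin(pmax(marg * n, 1e-12), n)
    (obs - expd) / sqrt(expd)
  }
  list(nascent = res(object$data$nascent, marginal_pmf(pmf, "nascent")),
       mature = res(object$data$mature, marginal_pmf(pmf, "mature")))
}

#' Plot observed marginals against the fitted model
#'
#' @param x An `sde_fit`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.sde_fit <- function(x, ...) {
  pmf <- predict(x, "joint")
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  for (sp in c("nascent", "mature")) {
    marg <- marginal_pmf(pmf, sp)
    obs <- tabulate(x$data[[sp]] + 1L, nbins = length(marg)) /
      length(x$data[[sp]])
    bp <- graphics::barplot(obs, names.arg = seq_along(marg) - 1,
                            main = sp, xlab = "count", ylab = "probability",
                            border = NA, col = "grey80", ...)
    graphics::lines(bp, marg, lwd = 2, col = "firebrick")
  }
  invisible(x)
}

#' Akaike weights across candidate model fits
#'
#' `w_i` proportional to `exp(-(AIC_i - min AIC)/2)`, normalized over the
#' supplied fits (which must be fits of the same data).  Non-converged fits
#' are excluded with a warning and receive weight `NA`.
#'
#' @param fits A list of `sde_fit` objects (named or not).
#' @return Named numeric vector of weights summing to 1 over converged fits.
#' @export
akaike_weights <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  nm <- names(fits)
  if (is.null(nm)) nm <- vapply(fits, function(f) f$model, "")
  ok <- vapply(fits, function(f) isTRUE(f$converged) && is.finite(f$logLik), TRUE)
  if (any(!ok)) warning("excluding non-converged fits: ", paste(nm[!ok], collapse = ", "))
  aic <- vapply(fits, function(f) 2 * f$k - 2 * f$logLik, 0)
  w <- rep(NA_real_, length(fits))
  d <- aic[ok] - min(aic[ok])
  w[ok] <- exp(-d / 2) / sum(exp(-d / 2))
  stats::setNames(w, nm)
}

#' Sample paired counts from an exact joint PMF
#'
#' @param j A `joint_pmf` object.
#' @param n Number of cells to draw.
#' @return A [count_data] object.
#' @export
sample_joint_pmf <- function(j, n) {
  stopifnot(inherits(j, "joint_pmf"), n >= 1)
  pr <- pmax(as.vector(j$probs), 0)
  idx <- sample.int(length(pr), n, replace = TRUE, prob = pr) - 1L
  count_data(idx %% nrow(j$probs), idx %/% nrow(j$probs))
}
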