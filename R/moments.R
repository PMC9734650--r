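# Closed-form steady-state moments, noise decomposition and autocorrelation
# functions. These are identical for the jump-driven (gamma OU) and
# diffusion-driven (CIR) transcription models, which is why summary statistics
# cannot discriminate between them.

#' Steady-state moments of nascent/mature RNA counts
#'
#' Exact stationary means, variances and covariances of the joint
#' nascent/mature count distribution under an SDE-driven transcription rate.
#' The same closed forms hold for both the jump-driven and diffusion-driven
#' models.
#'
#' @param p An [sde_params] object.
#' @return An object of class `sde_moments`: list with `mean_K`, `mu_N`,
#'   `mu_M`, `var_N`, `var_M`, `cov_NK`, `cov_MK`, `cov_NM`.
#' @examples
#' m <- steady_state_moments(sde_params(1, 1, 1, 1, 1))
#' m$var_N  # 3/2: Poisson part 1 plus extrinsic part 1/2
#' @export
steady_state_moments <- function(p) {
  stopifnot(inherits(p, "sde_params"))
  kap <- p$kappa; th <- p$theta; be <- p$beta; ga <- p$gamma
  K <- p$mean_rate
  mu_N <- K / be
  mu_M <- K / ga
  var_N <- mu_N + mu_N * th / (kap + be)
  var_M <- mu_M + mu_M * th / (kap + ga) * be / (kap + be) *
    (kap + be + ga) / (be + ga)
  cov_NK <- K * th / (kap + be)
  cov_MK <- K * th / (kap + ga) * be / (kap + be)
  cov_NM <- K * th / ((kap + be) * (kap + ga)) * (kap + be + ga) / (be + ga)
  structure(list(mean_K = K, mu_N = mu_N, mu_M = mu_M,
                 var_N = var_N, var_M = var_M,
                 cov_NK = cov_NK, cov_MK = cov_MK, cov_NM = cov_NM),
            class = "sde_moments")
}

#' @export
print.sde_moments <- function(x, ...) {
  cat("Stationary moments (identical for both SDE drivers)\n")
  cat(sprintf("  <K>   = %g\n  mu_N  = %g   var_N = %g\n  mu_M  = %g   var_M = %g\n",
              x$mean_K, x$mu_N, x$var_N, x$mu_M, x$var_M))
  cat(sprintf("  Cov(N,K) = %g   Cov(M,K) = %g   Cov(N,M) = %g\n",
              x$cov_NK, x$cov_MK, x$cov_NM))
  invisible(x)
}

#' Intrinsic/extrinsic noise decomposition
#'
#' Splits the squared coefficient of variation of each RNA species into an
#' intrinsic component (`1/mu`, reaction-timing noise present even for a
#' constant rate) and an extrinsic component (transcription-rate variation).
#' The nascent extrinsic fraction has the compact form
#' `theta / (theta + kappa + beta)`.
#'
#' @param p An [sde_params] object.
#' @return A list of class `sde_noise`: `eta2_N`, `eta2_M` (squared CVs),
#'   `intrinsic_N`, `extrinsic_N`, `intrinsic_M`, `extrinsic_M`,
#'   `extrinsic_fraction_N`, `extrinsic_fraction_M`.
#' @export
noise_decomposition <- function(p) {
  stopifnot(inherits(p, "sde_params"))
  kap <- p$kappa; th <- p$theta; be <- p$beta; ga <- p$gamma
  K <- p$mean_rate
  mu_N <- K / be; mu_M <- K / ga
  intrinsic_N <- 1 / mu_N
  intrinsic_M <- 1 / mu_M
  extrinsic_N <- (th / K) * (1 / kap) / (1 / kap + 1 / be)
  extrinsic_M <- (th / K) * ((1 / kap) / (1 / kap + 1 / be)) *
    ((1 / kap) / (1 / kap + 1 / ga)) *
    ((1 / kap + 1 / (be + ga)) / (1 / kap))
  eta2_N <- intrinsic_N + extrinsic_N
  eta2_M <- intrinsic_M + extrinsic_M
  structure(list(eta2_N = eta2_N, eta2_M = eta2_M,
                 intrinsic_N = intrinsic_N, extrinsic_N = extrinsic_N,
                 intrinsic_M = intrinsic_M, extrinsic_M = extrinsic_M,
                 extrinsic_fraction_N = extrinsic_N / eta2_N,
                 extrinsic_fraction_M = extrinsic_M / eta2_M),
            class = "sde_noise")
}

#' @export
print.sde_noise <- function(x, ...) {
  cat("Noise decomposition (squared CV = intrinsic + extrinsic)\n")
  cat(sprintf("  nascent: eta2 = %.4g = %.4g + %.4g (extrinsic fraction %.3f)\n",
              x$eta2_N, x$intrinsic_N, x$extrinsic_N, x$extrinsic_fraction_N))
  cat(sprintf("  mature:  eta2 = %.4g = %.4g + %.4g (extrinsic fraction %.3f)\n",
              x$eta2_M, x$intrinsic_M, x$extrinsic_M, x$extrinsic_fraction_M))
  invisible(x)
}

# Deterministically separate nearly equal rates so that the removable
# singularities in the closed forms (factors like 1/(beta-gamma)) stay
# well-conditioned. Below a relative gap of delta the smaller rate of the
# offending pair is shrunk by delta; this perturbs results by O(delta).
# delta balances the perturbation bias (O(delta)) against floating-point
# cancellation in the near-singular partial fractions (O(eps/delta^2)).
split_degenerate_rates <- function(kappa, beta, gamma, delta = 1e-5) {
  r <- c(kappa = kappa, beta = beta, gamma = gamma)
  for (iter in 1:8) {
    moved <- FALSE
    pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
    for (pr in pairs) {
      gap <- abs(r[pr[1]] - r[pr[2]]) / max(r[pr])
      if (gap < delta) {
        i <- pr[which.min(r[pr])]
        r[i] <- r[i] * (1 - delta)
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  as.list(r)
}

#' Stationary autocorrelation of RNA counts
#'
#' Normalized stationary autocovariance of the nascent or mature count
#' process at lag `tau` (value 1 at lag 0).  Identical for both SDE drivers.
#' Nearly equal rate pairs among (kappa, beta, gamma) are deterministically
#' perturbed by 1e-6 relative to keep the removable singularities
#' well-conditioned.
#'
#' @param p An [sde_params] object.
#' @param species `"nascent"` or `"mature"`.
#' @param tau Vector of nonnegative lags (time units).
#' @return Numeric vector of autocorrelations, one per lag.
#' @export
autocorrelation <- function(p, species = c("nascent", "mature"), tau) {
  stopifnot(inherits(p, "sde_params"))
  species <- match.arg(species)
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("lags 'tau' must be finite and nonnegative", call. = FALSE)
  r <- split_degenerate_rates(p$kappa, p$beta, p$gamma)
  kap <- r$kappa; be <- r$beta; ga <- r$gamma
  pp <- sde_params(kap, p$theta, p$a, be, ga)
  m <- steady_state_moments(pp)
  if (species == "nascent") {
    exp(-be * tau) + (m$cov_NK / m$var_N) * (exp(-kap * tau) - exp(-be * tau)) / (be - kap)
  } else {
    exp(-ga * tau) +
      be * (m$cov_NM / m$var_M) * (exp(-be * tau) - exp(-ga * tau)) / (ga - be) +
      be * (m$cov_MK / m$var_M) * (
        exp(-be * tau) / ((be - ga) * (be - kap)) +
        exp(-ga * tau) / ((ga - be) * (ga - kap)) +
        exp(-kap * tau) / ((kap - be) * (kap - ga)))
  }
}
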