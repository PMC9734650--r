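#' Kinetic parameters of an SDE-driven transcription model
#'
#' Bundles the five kinetic parameters shared by the gamma Ornstein-Uhlenbeck
#' (jump-driven) and Cox-Ingersoll-Ross (diffusion-driven) transcription
#' models: the mean-reversion rate of the transcription-rate process, the gain
#' parameter linking driver fluctuations to transcription, the driver
#' arrival/production frequency, the splicing rate and the mature-RNA
#' degradation rate.  Both drivers share the stationary transcription-rate law
#' Gamma(a/kappa, theta) and hence the mean rate a*theta/kappa.
#'
#' @param kappa Mean-reversion rate of the transcription-rate process (1/time).
#' @param theta Gain parameter (transcription-rate units): mean jump size for
#'   the jump driver, Langevin gain for the diffusion driver.  Large `theta`
#'   relative to `a` gives overdispersed RNA counts.
#' @param a Driver arrival (jump) or regulator production frequency (1/time).
#' @param beta Splicing rate: nascent RNA converts to mature RNA at this
#'   per-molecule rate (1/time).
#' @param gamma Degradation rate of mature RNA (1/time).
#'
#' @return An object of class `sde_params`: a named list with the five rates
#'   and the derived `mean_rate = a*theta/kappa`.
#' @examples
#' p <- sde_params(kappa = 2, theta = 3, a = 4, beta = 1.2, gamma = 0.7)
#' mean_transcription_rate(p)  # 6
#' @export
sde_params <- function(kappa, theta, a, beta, gamma) {
  vals <- list(kappa = kappa, theta = theta, a = a, beta = beta, gamma = gamma)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("parameter '%s' must be a strictly positive finite scalar (got %s)",
                   nm, paste(format(v), collapse = ",")), call. = FALSE)
    }
  }
  structure(c(vals, list(mean_rate = a * theta / kappa)), class = "sde_params")
}

#' @export
print.sde_params <- function(x, ...) {
  cat("SDE-CME kinetic parameters\n")
  cat(sprintf("  kappa (mean reversion): %g\n  theta (gain):           %g\n", x$kappa, x$theta))
  cat(sprintf("  a     (arrival freq.):  %g\n  beta  (splicing):       %g\n", x$a, x$beta))
  cat(sprintf("  gamma (degradation):    %g\n  <K> = a*theta/kappa:    %g\n", x$gamma, x$mean_rate))
  rc <- regime_coords(x)
  cat(sprintf("  regime: reversion %.3f, gain %.3f\n", rc[["reversion"]], rc[["gain"]]))
  invisible(x)
}

#' @export
as.list.sde_params <- function(x, ...) unclass(x)[c("kappa", "theta", "a", "beta", "gamma")]

#' Mean transcription rate
#'
#' The stationary mean of the driving transcription-rate process,
#' `a * theta / kappa`, identical for both drivers.
#'
#' @param p An [sde_params] object.
#' @return The mean transcription rate (rate units).
#' @export
mean_transcription_rate <- function(p) {
  stopifnot(inherits(p, "sde_params"))
  p$a * p$theta / p$kappa
}

#' Qualitative-regime coordinates
#'
#' Maps a parameter set to the two-dimensional unit square whose corners are
#' the limiting models: the reversion coordinate `kappa/(kappa+beta+gamma)`
#' (fast reversion to the right) and the gain ratio `theta/(theta+a)` (high
#' gain at the top).  Fast reversion and low gain give Poisson-like
#' (constitutive) behaviour; slow reversion gives the mixture model; fast
#' reversion with high gain gives bursty (jump driver) or heavy-tailed
#' (diffusion driver) behaviour.
#'
#' @param p An [sde_params] object.
#' @return Named numeric vector `c(reversion =, gain =)`, both in (0, 1).
#' @export
regime_coords <- function(p) {
  stopifnot(inherits(p, "sde_params"))
  c(reversion = p$kappa / (p$kappa + p$beta + p$gamma),
    gain = p$theta / (p$theta + p$a))
}

#' Parameters from regime coordinates
#'
#' Inverts [regime_coords()]: given a point of the qualitative-regime square,
#' the mean transcription rate and the two RNA rates, reconstructs the unique
#' parameter set mapping to that point.  Useful for laying out parameter
#' lattices that uniformly cover the regime space while holding the
#' distribution-scale parameters fixed.
#'
#' @param reversion Reversion coordinate, strictly inside (0, 1).
#' @param gain Gain coordinate, strictly inside (0, 1).
#' @param mean_rate Mean transcription rate `a*theta/kappa` to impose.
#' @param beta Splicing rate.
#' @param gamma Degradation rate.
#' @return An [sde_params] object with `regime_coords()` equal to
#'   `(reversion, gain)` and the requested mean rate.
#' @examples
#' p <- params_from_regime(1/3, 1/2, mean_rate = 1, beta = 1, gamma = 1)
#' unlist(as.list(p))  # kappa = theta = a = 1
#' @export
params_from_regime <- function(reversion, gain, mean_rate, beta, gamma) {
  for (nm in c("reversion", "gain")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      stop(sprintf("'%s' must lie strictly inside (0, 1)", nm), call. = FALSE)
  }
  if (mean_rate <= 0 || beta <= 0 || gamma <= 0)
    stop("'mean_rate', 'beta' and 'gamma' must be positive", call. = FALSE)
  kappa <- (beta + gamma) * reversion / (1 - reversion)
  # gain = theta/(theta+a) and a*theta = mean_rate*kappa jointly give:
  a <- sqrt(mean_rate * kappa * (1 - gain) / gain)
  theta <- mean_rate * kappa / a
  sde_params(kappa = kappa, theta = theta, a = a, beta = beta, gamma = gamma)
}

#' Even lattice over the qualitative-regime square
#'
#' Lays out an `n x n` lattice of regime coordinates evenly spanning
#' `bounds[1]` to `bounds[2]` on both axes, the configurable stand-in for a
#' set of parameter sets that uniformly cover the regime space.
#'
#' @param n Number of lattice points per axis (default 10).
#' @param bounds Lower/upper coordinate bounds (default `c(0.05, 0.95)`).
#' @param mean_rate,beta,gamma Passed to [params_from_regime()].
#' @return A data frame with columns `reversion`, `gain` and a list column
#'   `params` of [sde_params] objects.
#' @export
regime_lattice <- function(n = 10, bounds = c(0.05, 0.95),
                           mean_rate = 10, beta = 1.2, gamma = 0.7) {
  stopifnot(n >= 1, length(bounds) == 2, bounds[1] > 0, bounds[2] < 1,
            bounds[1] <= bounds[2])
  ax <- if (n == 1) mean(bounds) else seq(bounds[1], bounds[2], length.out = n)
  grid <- expand.grid(reversion = ax, gain = ax, KEEP.OUT.ATTRS = FALSE)
  grid$params <- lapply(seq_len(nrow(grid)), function(i) {
    params_from_regime(grid$reversion[i], grid$gain[i], mean_rate, beta, gamma)
  })
  grid
}

#' Read model parameters from a JSON file
#'
#' Accepts either explicit parameters
#' (`{"kappa":..., "theta":..., "a":..., "beta":..., "gamma":...}`) or regime
#' coordinates plus scales
#' (`{"reversion":..., "gain":..., "mean_rate":..., "beta":..., "gamma":...}`).
#' An optional `"model"` field is returned as an attribute.
#'
#' @param path Path to a JSON file.
#' @return An [sde_params] object; the JSON `model` tag, if present, is
#'   attached as attribute `"model"`.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  p <- if (all(c("kappa", "theta", "a", "beta", "gamma") %in% names(x))) {
    sde_params(x$kappa, x$theta, x$a, x$beta, x$gamma)
  } else if (all(c("reversion", "gain", "mean_rate", "beta", "gamma") %in% names(x))) {
    params_from_regime(x$reversion, x$gain, x$mean_rate, x$beta, x$gamma)
  } else {
    stop("JSON must give either {kappa,theta,a,beta,gamma} or {reversion,gain,mean_rate,beta,gamma}",
         call. = FALSE)
  }
  if (!is.null(x$model)) attr(p, "model") <- match.arg(tolower(x$model), sde_model_kinds())
  p
}

#' Model kinds
#'
#' The closed enumeration of model tags: the two SDE-driven models and the
#' three limiting models (constant rate, gamma-frozen rate, geometric bursts).
#'
#' @return Character vector of valid model tags.
#' @export
sde_model_kinds <- function() c("gou", "cir", "constitutive", "mixture", "bursty")

match_model <- function(model) {
  match.arg(tolower(model), sde_model_kinds())
}

#' Validation parameter sets
#'
#' Six parameter sets used throughout the package's simulator/solver
#' validation: four near the corners of the qualitative-regime square and two
#' intermediate, all with splicing rate 1.2, degradation rate 0.7 and mean
#' transcription rate 10.
#'
#' @return A data frame with `reversion`, `gain`, list column `params` and a
#'   `label` column.
#' @export
validation_parameter_sets <- function() {
  coords <- data.frame(
    reversion = c(0.9, 0.9, 0.1, 0.1, 0.5, 0.3),
    gain      = c(0.1, 0.9, 0.1, 0.9, 0.5, 0.7),
    label = c("constitutive-corner", "bursty-corner", "slow-poisson",
              "mixture-corner", "central", "intermediate-overdispersed"),
    stringsAsFactors = FALSE
  )
  coords$params <- lapply(seq_len(nrow(coords)), function(i) {
    params_from_regime(coords$reversion[i], coords$gain[i],
                       mean_rate = 10, beta = 1.2, gamma = 0.7)
  })
  coords
}
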