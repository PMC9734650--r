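# Rate-path sampling (R level) and hybrid cell simulation (Rcpp event loop).

#' Paired nascent/mature count data for one gene
#'
#' @param nascent,mature Equal-length vectors of nonnegative integer counts,
#'   one entry per cell.
#' @return An object of class `count_data`.
#' @export
count_data <- function(nascent, mature) {
  nascent <- as.integer(nascent); mature <- as.integer(mature)
  if (length(nascent) != length(mature))
    stop("nascent and mature count vectors must be paired (equal length)", call. = FALSE)
  if (length(nascent) && (min(nascent) < 0 || min(mature) < 0))
    stop("counts must be nonnegative integers", call. = FALSE)
  structure(list(nascent = nascent, mature = mature), class = "count_data")
}

#' @export
print.count_data <- function(x, ...) {
  cat(sprintf("count_data: %d cells; mean nascent %.3f, mean mature %.3f\n",
              length(x$nascent), mean(x$nascent), mean(x$mature)))
  invisible(x)
}

#' Simulation protocol
#'
#' Equilibration and recording settings for [simulate_cells()].  Defaults:
#' the equilibration horizon is 15 relaxation times of the slowest rate and
#' the recording horizon (used only when autocorrelation trajectories are
#' requested) is 5.
#'
#' @param p An [sde_params] object (used for time-scale defaults).
#' @param t_ss Equilibration time before counts are recorded.
#' @param t_r Recording horizon past `t_ss` for trajectory sampling (0 = only
#'   record the steady-state snapshot).
#' @param sample_dt Spacing of trajectory sample times within the recording
#'   window; default `t_r / 50` when `t_r > 0`.
#' @param dt_cir Uniform path grid step for the diffusion driver; default
#'   `0.01 / max(kappa, mean_rate)`, below which counts are insensitive to
#'   the discretization.
#' @return A list of class `sim_protocol`.
#' @export
sim_protocol <- function(p, t_ss = NULL, t_r = 0, sample_dt = NULL, dt_cir = NULL) {
  stopifnot(inherits(p, "sde_params"))
  slowest <- min(p$kappa, p$beta, p$gamma)
  if (is.null(t_ss)) t_ss <- 15 / slowest
  if (t_ss <= 0 || t_r < 0) stop("t_ss must be > 0 and t_r >= 0", call. = FALSE)
  if (t_ss < 10 / slowest)
    warning("t_ss shorter than 10 relaxation times of the slowest rate; equilibration suspect")
  if (is.null(sample_dt)) sample_dt <- if (t_r > 0) t_r / 50 else 0
  if (is.null(dt_cir)) dt_cir <- 0.01 / max(p$kappa, p$mean_rate)
  structure(list(t_ss = t_ss, t_r = t_r, sample_dt = sample_dt, dt_cir = dt_cir),
            class = "sim_protocol")
}

#' Sample a jump-driven transcription-rate path
#'
#' Realizes the jump-decay (gamma OU) rate process: exponential decay at rate
#' `kappa` between compound-Poisson jumps arriving at frequency `a` with
#' exponential sizes of mean `theta`; the initial value is drawn from the
#' stationary Gamma(a/kappa, theta) law.
#'
#' @param p An [sde_params] object.
#' @param horizon Path length (time units).
#' @param K0 Optional fixed initial rate (default: stationary draw).
#' @return An object of class `rate_path` with fields `model`, `horizon`,
#'   `K0`, `jump_times`, `jump_sizes`, `kappa`.
#' @export
sample_gou_path <- function(p, horizon, K0 = NULL) {
  stopifnot(inherits(p, "sde_params"), horizon > 0)
  if (is.null(K0)) K0 <- stats::rgamma(1, shape = p$a / p$kappa, scale = p$theta)
  n_jumps <- stats::rpois(1, p$a * horizon)
  jt <- sort(stats::runif(n_jumps, 0, horizon))
  js <- stats::rexp(n_jumps, rate = 1 / p$theta)
  structure(list(model = "gou", horizon = horizon, K0 = K0,
                 jump_times = jt, jump_sizes = js, kappa = p$kappa),
            class = "rate_path")
}

#' Sample a diffusion-driven transcription-rate path
#'
#' Realizes the square-root diffusion (CIR) rate process on a uniform grid
#' using the exact scaled noncentral chi-squared transition law, so values
#' are nonnegative by construction and the grid marginals carry no
#' discretization error.  The initial value is a stationary
#' Gamma(a/kappa, theta) draw.
#'
#' @inheritParams sample_gou_path
#' @param dt Grid step.
#' @return An object of class `rate_path` with fields `model`, `horizon`,
#'   `dt`, `values` (length `floor(horizon/dt) + 1`).
#' @export
sample_cir_path <- function(p, horizon, dt, K0 = NULL) {
  stopifnot(inherits(p, "sde_params"), horizon > 0, dt > 0)
  n_steps <- floor(horizon / dt)
  if (is.null(K0)) K0 <- stats::rgamma(1, shape = p$a / p$kappa, scale = p$theta)
  vals <- numeric(n_steps + 1)
  vals[1] <- K0
  decay <- exp(-p$kappa * dt)
  cc <- p$theta * (1 - decay) / 2
  df <- 2 * p$a / p$kappa
  for (i in seq_len(n_steps)) {
    vals[i + 1] <- cc * stats::rchisq(1, df = df, ncp = vals[i] * decay / cc)
  }
  structure(list(model = "cir", horizon = n_steps * dt, dt = dt, values = vals),
            class = "rate_path")
}

#' Evaluate a rate path at arbitrary times
#'
#' Jump-decay paths are evaluated exactly; diffusion paths by linear
#' interpolation on their grid.
#'
#' @param path A `rate_path` object.
#' @param t Vector of times within the path horizon.
#' @return Numeric vector of K(t) values.
#' @export
rate_at <- function(path, t) {
  stopifnot(inherits(path, "rate_path"))
  if (any(t < 0 | t > path$horizon + 1e-9))
    stop("times outside the path horizon", call. = FALSE)
  if (path$model == "gou") {
    vapply(t, function(ti) {
      v <- path$K0 * exp(-path$kappa * ti)
      sel <- path$jump_times <= ti
      if (any(sel))
        v <- v + sum(path$jump_sizes[sel] * exp(-path$kappa * (ti - path$jump_times[sel])))
      v
    }, 0)
  } else {
    stats::approx(seq(0, path$horizon, by = path$dt), path$values, xout = t)$y
  }
}

#' Simulate cells under an SDE-driven transcription model
#'
#' Hybrid exact simulation: the transcription-rate path is continuous (jump
#' decay or square-root diffusion) while transcription, splicing and
#' degradation are discrete events generated by inverting the integrated
#' propensity.  Jump-driver transcription waiting times are solved exactly
#' with the Lambert W function on each decay segment; diffusion-driver firing
#' times use trapezoidal flux accumulation on the path grid.  Counts start at
#' (0, 0) and are recorded after the equilibration time.
#'
#' @param model `"gou"` or `"cir"`.
#' @param p An [sde_params] object.
#' @param n_cells Number of independent replicate cells.
#' @param protocol A [sim_protocol] (default constructed from `p`).
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called so
#'   the output is bit-reproducible.
#' @param record_events Keep a per-event audit log (reaction type and time);
#'   intended for small runs.
#' @return A `count_data` object with attributes `trajectory` (list with
#'   `times`, `nascent`, `mature` matrices, present when `protocol$t_r > 0`)
#'   and `events` (when requested).
#' @export
simulate_cells <- function(model, p, n_cells, protocol = NULL, seed = NULL,
                           record_events = FALSE) {
  model <- match_model(model)
  if (!model %in% c("gou", "cir"))
    stop("simulate_cells supports the 'gou' and 'cir' models", call. = FALSE)
  stopifnot(inherits(p, "sde_params"), n_cells >= 1)
  if (is.null(protocol)) protocol <- sim_protocol(p)
  stopifnot(inherits(protocol, "sim_protocol"))
  if (!is.null(seed)) set.seed(seed)
  rec <- protocol$t_ss
  if (protocol$t_r > 0)
    rec <- c(rec, protocol$t_ss + seq(protocol$sample_dt, protocol$t_r,
                                      by = protocol$sample_dt))
  t_end <- max(rec)
  sim <- if (model == "gou") {
    simulate_gou_cells_cpp(p$kappa, p$theta, p$a, p$beta, p$gamma,
                           t_end, rec, as.integer(n_cells), record_events)
  } else {
    simulate_cir_cells_cpp(p$kappa, p$theta, p$a, p$beta, p$gamma,
                           t_end, protocol$dt_cir, rec, as.integer(n_cells),
                           record_events)
  }
  out <- count_data(sim$nascent[, 1], sim$mature[, 1])
  if (protocol$t_r > 0) {
    attr(out, "trajectory") <- list(times = rec, nascent = sim$nascent,
                                    mature = sim$mature)
  }
  if (record_events) attr(out, "events") <- sim$events
  attr(out, "model") <- model
  attr(out, "params") <- p
  out
}

#' Empirical stationary autocorrelation of simulated trajectories
#'
#' Normalized stationary autocovariance estimated from the recorded
#' trajectory window of [simulate_cells()] (requires `t_r > 0`), averaged
#' over cells and time origins.
#'
#' @param sim A `count_data` object carrying a `trajectory` attribute.
#' @param species `"nascent"` or `"mature"`.
#' @param lags Vector of nonnegative lags; must be (near) multiples of the
#'   trajectory sampling interval and within the recording window.
#' @return Numeric vector of autocorrelation estimates, one per lag.
#' @export
empirical_autocorrelation <- function(sim, species = c("nascent", "mature"), lags) {
  species <- match.arg(species)
  traj <- attr(sim, "trajectory")
  if (is.null(traj))
    stop("simulation has no recorded trajectory; rerun with t_r > 0", call. = FALSE)
  x <- traj[[species]]
  times <- traj$times
  dt <- diff(times[1:2])
  idx <- lags / dt
  if (any(lags < 0) || any(abs(idx - round(idx)) > 1e-6) ||
      any(round(idx) > length(times) - 1))
    stop("lags must be nonnegative multiples of the sampling interval within the recording window",
         call. = FALSE)
  idx <- as.integer(round(idx))
  mu <- mean(x); v <- mean((x - mu)^2)
  nT <- ncol(x)
  vapply(idx, function(l) {
    a <- x[, seq_len(nT - l), drop = FALSE]
    b <- x[, seq_len(nT - l) + l, drop = FALSE]
    mean((a - mu) * (b - mu)) / v
  }, 0)
}
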