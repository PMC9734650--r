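# Likelihood evaluation over solver PMFs, including batched evaluation across
# parameter sets (one vectorized Riccati solve serves a whole likelihood
# surface for the diffusion-driven model).

# Parameter names of each model's native parameterization used in fitting.
# Full models carry the five kinetic rates (one of which is usually fixed to
# pin the time scale); limiting models use their own natural parameters.
model_param_names <- function(model) {
  switch(match_model(model),
    gou = ,
    cir = c("kappa", "theta", "a", "beta", "gamma"),
    mixture = c("alpha", "theta", "beta", "gamma"),
    bursty = c("a", "b", "beta", "gamma"),
    constitutive = c("mean_rate", "beta", "gamma"))
}

# Translate a named parameter vector/list in a model's native parameterization
# into the sde_params currency used by the solvers.  For the full models a
# fixed mean_rate may replace 'a' (a = mean_rate * kappa / theta).
to_sde_params <- function(model, pars) {
  pars <- as.list(pars)
  switch(match_model(model),
    gou = ,
    cir = {
      if (is.null(pars$a)) {
        if (is.null(pars$mean_rate))
          stop("full models need either 'a' or 'mean_rate'", call. = FALSE)
        pars$a <- pars$mean_rate * pars$kappa / pars$theta
      }
      sde_params(pars$kappa, pars$theta, pars$a, pars$beta, pars$gamma)
    },
    # mixture: gamma shape alpha = a/kappa, scale theta
    mixture = sde_params(1, pars$theta, pars$alpha, pars$beta, pars$gamma),
    # bursty: burst frequency a, mean burst size b = theta/kappa
    bursty = sde_params(1, pars$b, pars$a, pars$beta, pars$gamma),
    constitutive = sde_params(1, 1, pars$mean_rate, pars$beta, pars$gamma))
}

as_count_data <- function(data) {
  if (inherits(data, "count_data")) return(data)
  if (is.list(data) && all(c("nascent", "mature") %in% names(data)))
    return(count_data(data$nascent, data$mature))
  stop("'data' must be a count_data object or a list with nascent/mature", call. = FALSE)
}

# Tabulated (x_N, x_M) pairs for fast repeated likelihood evaluation.
tabulate_counts <- function(data) {
  key <- paste(data$nascent, data$mature)
  tab <- table(key)
  first <- !duplicated(key)
  list(nascent = data$nascent[first], mature = data$mature[first],
       count = as.numeric(tab[paste(data$nascent[first], data$mature[first])]))
}

loglik_from_pmf <- function(pmf, tab, data_mode = "joint", floor_p = 1e-12) {
  probs <- switch(data_mode,
    joint = pmf$probs[cbind(tab$nascent + 1L, tab$mature + 1L)],
    nascent = marginal_pmf(pmf, "nascent")[tab$nascent + 1L],
    mature = marginal_pmf(pmf, "mature")[tab$mature + 1L])
  n_floored <- sum(probs < floor_p)
  probs[probs < floor_p] <- floor_p
  structure(sum(tab$count * log(probs)), n_floored = n_floored)
}

# Grid spec whose extents cover both the observed counts and the model bulk.
# Extents are capped relative to the data so that parameter sets whose bulk
# lies far beyond the observations (which have negligible likelihood anyway)
# cannot force enormous transforms.
grid_for_data <- function(model, p, data, grid = NULL) {
  n_lo <- max(data$nascent) + 5L; m_lo <- max(data$mature) + 5L
  g <- resolve_grid(match_model(model), p, grid, min_n = n_lo, min_m = m_lo)
  g$n_max <- min(g$n_max, max(ceiling(1.3 * max(data$nascent)) + 20L, n_lo))
  g$m_max <- min(g$m_max, max(ceiling(1.3 * max(data$mature)) + 20L, m_lo))
  g
}

#' Log-likelihood of count data under a model
#'
#' Sum over cells of the log joint stationary probability of the observed
#' (nascent, mature) pair.  PMF entries are floored at `floor_p` before the
#' log so that grid truncation cannot produce infinite penalties; the number
#' of floored entries is attached as an attribute.
#'
#' @param data A [count_data] object (or list with `nascent`, `mature`).
#' @param model One of the five model tags.
#' @param p An [sde_params] object, or a named vector/list in the model's
#'   native parameterization (see [sde_fit()]).
#' @param grid Optional [grid_spec]; extents are enlarged to cover the data.
#' @param data_mode `"joint"` (default), `"nascent"` or `"mature"`: which
#'   observation channel enters the likelihood.
#' @param floor_p Probability floor.
#' @return The log-likelihood (numeric scalar) with attribute `n_floored`.
#' @export
sde_loglik <- function(data, model, p, grid = NULL,
                       data_mode = c("joint", "nascent", "mature"),
                       floor_p = 1e-12) {
  model <- match_model(model)
  data_mode <- match.arg(data_mode)
  data <- as_count_data(data)
  if (!length(data$nascent)) stop("empty count data", call. = FALSE)
  if (!inherits(p, "sde_params")) p <- to_sde_params(model, p)
  pmf <- joint_pmf(model, p, grid_for_data(model, p, data, grid),
                   tail_check = FALSE)
  tab <- tabulate_counts(data)
  loglik_from_pmf(pmf, tab, data_mode, floor_p)
}

# Joint PMFs for many parameter sets of one model on a common grid.
# For the diffusion-driven model all generating-function ODE solves are
# batched into a single vectorized integration.
joint_pmf_batch <- function(model, params_list, grid = NULL, data = NULL) {
  model <- match_model(model)
  n_max <- 8L; m_max <- 8L
  for (p in params_list) {
    g <- resolve_grid(model, p, grid)
    n_max <- max(n_max, g$n_max); m_max <- max(m_max, g$m_max)
  }
  if (!is.null(data)) {
    n_max <- min(max(n_max, max(data$nascent) + 5L),
                 ceiling(1.3 * max(data$nascent)) + 20L)
    m_max <- min(max(m_max, max(data$mature) + 5L),
                 ceiling(1.3 * max(data$mature)) + 20L)
    n_max <- max(n_max, max(data$nascent) + 5L)
    m_max <- max(m_max, max(data$mature) + 5L)
  }
  gg <- if (is.null(grid)) grid_spec() else grid
  gg$n_max <- n_max; gg$m_max <- m_max
  if (model != "cir") {
    return(lapply(params_list, function(p)
      tryCatch(joint_pmf(model, p, gg), error = function(e) NULL)))
  }
  Np <- n_max + 1L; Mp <- m_max + 1L
  gN <- exp(2i * pi * (seq_len(Np) - 1) / Np)
  gM <- exp(2i * pi * (seq_len(Mp) - 1) / Mp)
  uN <- rep(gN - 1, times = Mp)
  uM <- rep(gM - 1, each = Np)
  phi <- log_pgf_cir_batch(uN, uM, params_list, gg)
  lapply(seq_along(params_list), function(i) {
    psi <- matrix(exp(phi[i, ]), nrow = Np, ncol = Mp)
    praw <- stats::fft(psi) / (Np * Mp)
    probs <- Re(praw)
    probs[probs < 0] <- 0
    dimnames(probs) <- list(0:n_max, 0:m_max)
    structure(list(probs = probs, model = model, params = params_list[[i]],
                   grid = gg, im_max = max(abs(Im(praw))), n_clipped = 0L),
              class = "joint_pmf")
  })
}
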