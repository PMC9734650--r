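# Exact steady-state joint PMFs via the log probability-generating function
# phi_ss(u_N, u_M) (u = g - 1), evaluated on the complex unit circle and
# inverted with a 2-D FFT.
#
# Jump-driven (gamma OU) model:  phi_ss = <K> Int_0^inf U0 / (1 - (theta/kappa) U0) ds
# with U0(s) = A0 e^{-kappa s} + A1 e^{-beta s} + A2 e^{-gamma s} in closed form.
# Diffusion-driven (CIR) model:  phi_ss = <K> Int_0^inf U0(s) ds with U0 the
# solution of the Riccati characteristic ODE, integrated numerically.

#' Numerical grid specification for PMF recovery
#'
#' Controls the FFT state-space extents and the quadrature/ODE settings used
#' to evaluate the generating function.  When `n_max`/`m_max` are `NULL` they
#' are sized automatically from the model's closed-form moments as
#' `ceiling(mu + 10*sigma)`, so that truncated tail mass is negligible for all
#' but the most pathological parameter sets.
#'
#' @param n_max Largest nascent count on the grid (state space is `0:n_max`).
#' @param m_max Largest mature count on the grid.
#' @param quad_s_max Truncation point of the semi-infinite characteristic-time
#'   integral; default `max(30/min(kappa, beta, gamma), 50)`, where the
#'   integrand has decayed below 1e-13.
#' @param quad_panels,quad_order Composite Gauss-Legendre quadrature layout:
#'   geometrically graded panels, `quad_order` nodes each.
#' @param tail_tol Tolerance on the estimated off-grid tail mass.
#' @param ode_rtol,ode_atol Tolerances for the Riccati ODE integration.
#' @param ode_solver `"zvode"` (default): stiff-capable complex BDF
#'   integrator, which copes with the nonlinearly stiff high-gain corner;
#'   `"dp45"`: compiled adaptive Dormand-Prince integrator, retained as an
#'   independent cross-validation route.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_max = NULL, m_max = NULL, quad_s_max = NULL,
                      quad_panels = 10, quad_order = 8,
                      tail_tol = 1e-8, ode_rtol = 1e-10, ode_atol = 1e-12,
                      ode_solver = c("zvode", "dp45")) {
  ode_solver <- match.arg(ode_solver)
  if (!is.null(n_max) && n_max < 2) stop("n_max must be >= 2", call. = FALSE)
  if (!is.null(m_max) && m_max < 2) stop("m_max must be >= 2", call. = FALSE)
  if (!is.null(quad_s_max) && quad_s_max <= 0) stop("quad_s_max must be > 0", call. = FALSE)
  structure(list(n_max = n_max, m_max = m_max, quad_s_max = quad_s_max,
                 quad_panels = quad_panels, quad_order = quad_order,
                 tail_tol = tail_tol, ode_rtol = ode_rtol, ode_atol = ode_atol,
                 ode_solver = ode_solver),
            class = "grid_spec")
}

# Moments appropriate to each model tag, used only for automatic grid sizing.
# The limiting models use the corresponding limits of the closed forms.
model_sizing_moments <- function(model, p) {
  kap <- p$kappa; th <- p$theta; be <- p$beta; ga <- p$gamma
  K <- p$mean_rate
  mu_N <- K / be; mu_M <- K / ga
  switch(model,
    gou = ,
    cir = {
      m <- steady_state_moments(p)
      list(mu_N = m$mu_N, mu_M = m$mu_M, var_N = m$var_N, var_M = m$var_M)
    },
    constitutive = list(mu_N = mu_N, mu_M = mu_M, var_N = mu_N, var_M = mu_M),
    mixture = list(mu_N = mu_N, mu_M = mu_M,
                   var_N = mu_N * (1 + th / be), var_M = mu_M * (1 + th / ga)),
    bursty = {
      b <- th / kap
      list(mu_N = mu_N, mu_M = mu_M,
           var_N = mu_N * (1 + b), var_M = mu_M * (1 + b * be / (be + ga)))
    })
}

resolve_grid <- function(model, p, grid, min_n = NULL, min_m = NULL) {
  if (is.null(grid)) grid <- grid_spec()
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(grid$n_max) || is.null(grid$m_max)) {
    mm <- model_sizing_moments(model, p)
    if (is.null(grid$n_max))
      grid$n_max <- max(8, ceiling(mm$mu_N + 10 * sqrt(mm$var_N)))
    if (is.null(grid$m_max))
      grid$m_max <- max(8, ceiling(mm$mu_M + 10 * sqrt(mm$var_M)))
  }
  if (!is.null(min_n)) grid$n_max <- max(grid$n_max, min_n)
  if (!is.null(min_m)) grid$m_max <- max(grid$m_max, min_m)
  if (is.null(grid$quad_s_max))
    grid$quad_s_max <- max(30 / min(p$kappa, p$beta, p$gamma), 50)
  grid
}

# Composite Gauss-Legendre nodes/weights on geometrically graded panels of
# [0, s_max]: resolves both the fast initial transient and the slow tail.
# When `min_panel` is given, panels are added until the innermost one is at
# most that wide, so very long horizons cannot under-resolve the transient.
quad_rule <- function(s_max, n_panels = 14, order = 10, min_panel = NULL) {
  if (!is.null(min_panel) && min_panel > 0) {
    need <- ceiling(log2(s_max / min_panel)) + 1
    n_panels <- max(n_panels, min(need, 40))
  }
  breaks <- c(0, s_max * 2^seq(-(n_panels - 1), 0))
  nodes <- numeric(0); weights <- numeric(0)
  for (i in seq_len(length(breaks) - 1)) {
    gl <- pracma::gaussLegendre(order, breaks[i], breaks[i + 1])
    nodes <- c(nodes, gl$x); weights <- c(weights, gl$w)
  }
  list(nodes = nodes, weights = weights)
}

#' Closed-form characteristic solution for the jump-driven model
#'
#' The innermost characteristic function `U0(s)` of the jump-driven
#' (gamma OU) generating-function solution is a three-exponential closed form
#' `A0 exp(-kappa s) + A1 exp(-beta s) + A2 exp(-gamma s)`.  This returns the
#' coefficients (vectorized over boundary data), after deterministic
#' separation of nearly equal rates.
#'
#' @param u_N,u_M Complex shifted-PGF arguments (`g - 1`), equal-length
#'   vectors with `|1 + u|` at most 1.
#' @param p An [sde_params] object.
#' @return List with complex vectors `A0`, `A1`, `A2` and the (possibly
#'   perturbed) `kappa`, `beta`, `gamma` used.
#' @export
gou_u0_coeffs <- function(u_N, u_M, p) {
  stopifnot(inherits(p, "sde_params"), length(u_N) == length(u_M))
  r <- split_degenerate_rates(p$kappa, p$beta, p$gamma)
  kap <- r$kappa; be <- r$beta; ga <- r$gamma
  A2 <- u_M * (be / (be - ga)) * (kap / (kap - ga))
  A1 <- (kap / (kap - be)) * (u_N - u_M * be / (be - ga))
  A0 <- -A1 - A2
  list(A0 = A0, A1 = A1, A2 = A2, kappa = kap, beta = be, gamma = ga)
}

#' Evaluate the jump-driven characteristic solution
#'
#' Evaluates the three-exponential `U0(s)` from [gou_u0_coeffs()] on an
#' outer (boundary pairs x times) grid.
#'
#' @param coefs Output of [gou_u0_coeffs()].
#' @param s Vector of nonnegative times.
#' @return Complex matrix, boundary pairs in rows, times in columns.
#' @export
gou_u0_eval <- function(coefs, s) {
  outer(coefs$A0, exp(-coefs$kappa * s)) +
    outer(coefs$A1, exp(-coefs$beta * s)) +
    outer(coefs$A2, exp(-coefs$gamma * s))
}

# U1(s) in closed form (shared by the bursty limit and the Riccati forcing):
# U1(s) = u_N e^{-beta s} + u_M beta/(beta-gamma) (e^{-gamma s} - e^{-beta s}).

#' Log generating function, jump-driven model
#'
#' Evaluates `phi_ss(u_N, u_M)`, the log of the shifted-argument PGF of the
#' stationary joint count distribution under the jump-driven (gamma OU)
#' transcription rate, by closed-form characteristics and Gauss-Legendre
#' quadrature.  `phi_ss(0, 0) = 0` (normalization).
#'
#' @inheritParams gou_u0_coeffs
#' @param grid A [grid_spec] (extents are irrelevant here; the quadrature
#'   settings are used). `NULL` for defaults.
#' @return Complex vector of `phi_ss` values, one per boundary pair.
#' @export
log_pgf_gou <- function(u_N, u_M, p, grid = NULL) {
  grid <- resolve_grid("gou", p, grid, min_n = 2, min_m = 2)
  qr <- quad_rule(grid$quad_s_max, grid$quad_panels, grid$quad_order,
                  min_panel = 0.05 / max(p$kappa, p$beta, p$gamma))
  coefs <- gou_u0_coeffs(u_N, u_M, p)
  U0 <- gou_u0_eval(coefs, qr$nodes)
  denom <- 1 - (p$theta / p$kappa) * U0
  bad <- which(Mod(denom) < 1e-10)
  if (length(bad)) {
    stop(sprintf("generating-function pole: 1 - (theta/kappa) U0 vanishes near s = %.4g (diverging distribution)",
                 qr$nodes[((bad[1] - 1) %/% nrow(U0)) + 1]), call. = FALSE)
  }
  p$mean_rate * as.vector((U0 / denom) %*% qr$weights)
}

#' Log generating function, diffusion-driven model
#'
#' Evaluates `phi_ss(u_N, u_M)` for the diffusion-driven (CIR) transcription
#' rate by numerically integrating the Riccati characteristic ODE
#' `dU0/ds = kappa (U1 - U0) + theta U0^2` (complex BDF integrator) and
#' applying the same Gauss-Legendre quadrature in `s`.
#'
#' @inheritParams log_pgf_gou
#' @return Complex vector of `phi_ss` values.
#' @export
log_pgf_cir <- function(u_N, u_M, p, grid = NULL) {
  as.vector(log_pgf_cir_batch(u_N, u_M, list(p), grid))
}

#' Batched diffusion-model generating function over parameter sets
#'
#' Solves the Riccati characteristic system for many parameter sets and one
#' shared `(u_N, u_M)` grid in a single vectorized ODE integration; every
#' (parameter, grid-node) component is independent, so the system is diagonal
#' and solved jointly.  Used to make likelihood-surface and
#' evidence-quadrature evaluations affordable.
#'
#' @inheritParams log_pgf_gou
#' @param params List of [sde_params] objects.
#' @return Complex matrix, `length(params)` rows by `length(u_N)` columns.
#' @export
log_pgf_cir_batch <- function(u_N, u_M, params, grid = NULL) {
  stopifnot(length(u_N) == length(u_M), length(params) >= 1)
  # The shared adaptive step makes mixed batches pay the slowest member's
  # horizon at the stiffest member's step size; group parameter sets by the
  # decade of their mean-reversion rate so each group integrates only as far
  # and as finely as it needs.
  if (length(params) > 1) {
    kv <- vapply(params, `[[`, 0, "kappa")
    grp <- floor(log10(kv))
    if (length(unique(grp)) > 1) {
      out <- matrix(NA_complex_, length(params), length(u_N))
      for (g in unique(grp)) {
        idx <- which(grp == g)
        out[idx, ] <- log_pgf_cir_batch(u_N, u_M, params[idx], grid)
      }
      return(out)
    }
  }
  P <- length(params); G <- length(u_N)
  # widest quadrature horizon across the batch
  smax <- 0; panels <- 10; order <- 8; rtol <- 1e-10; atol <- 1e-12
  solver <- "zvode"
  for (p in params) {
    g <- resolve_grid("cir", p, grid, min_n = 2, min_m = 2)
    smax <- max(smax, g$quad_s_max)
    panels <- g$quad_panels; order <- g$quad_order
    rtol <- g$ode_rtol; atol <- g$ode_atol
    solver <- g$ode_solver
  }
  maxrate <- max(vapply(params, function(p) max(p$kappa, p$beta, p$gamma), 0))
  qr <- quad_rule(smax, panels, order, min_panel = 0.05 / maxrate)
  rr <- lapply(params, function(p) split_degenerate_rates(p$kappa, p$beta, p$gamma))
  kapv <- vapply(rr, `[[`, 0, "kappa")
  bev  <- vapply(rr, `[[`, 0, "beta")
  gav  <- vapply(rr, `[[`, 0, "gamma")
  thv  <- vapply(params, `[[`, 0, "theta")
  cv   <- bev / (bev - gav)
  ord <- order(qr$nodes)
  Kv <- vapply(params, `[[`, 0, "mean_rate")
  if (solver == "dp45") {
    acc <- riccati_quad_cpp(u_N, u_M, kapv, bev, gav, thv,
                            qr$nodes[ord], qr$weights[ord], rtol, atol)
    return(matrix(acc, nrow = P) * Kv)
  }
  # zvode route: flat state of length P*G (params vary fastest); exponentials
  # are computed per parameter set (length P) and index-expanded
  pidx <- rep(seq_len(P), times = G)
  uNE <- rep(u_N, each = P); uME <- rep(u_M, each = P)
  kapE <- kapv[pidx]; thE <- thv[pidx]
  rhs <- function(s, y, parms) {
    eb <- exp(-bev * s); eg <- exp(-gav * s)
    U1 <- uNE * eb[pidx] + uME * (cv * (eg - eb))[pidx]
    list(kapE * (U1 - y) + thE * y * y)
  }
  times <- c(0, qr$nodes[ord])
  sol <- deSolve::zvode(y = complex(P * G), times = times, func = rhs,
                        parms = NULL, rtol = rtol, atol = atol,
                        mf = 23L)
  if (nrow(sol) < length(times))
    stop(sprintf("Riccati integration diverged near s = %.4g (distribution may not exist at these parameters)",
                 max(sol[, 1])), call. = FALSE)
  U0s <- sol[-1, -1, drop = FALSE]            # (sorted s) x (P*G), complex
  w <- qr$weights[ord]
  acc <- as.vector(rbind(w) %*% U0s)          # quadrature along s, length P*G
  matrix(acc, nrow = P) * Kv
}

# log PGF of the three limiting models, vectorized over (u_N, u_M)
log_pgf_limit <- function(model, u_N, u_M, p, grid = NULL) {
  kap <- p$kappa; th <- p$theta; be <- p$beta; ga <- p$gamma
  K <- p$mean_rate
  switch(model,
    constitutive = (K / be) * u_N + (K / ga) * u_M,
    mixture = {
      alpha <- p$a / kap
      -alpha * log(1 - th * (u_N / be + u_M / ga))
    },
    bursty = {
      grid <- resolve_grid("bursty", p, grid, min_n = 2, min_m = 2)
      qr <- quad_rule(grid$quad_s_max, grid$quad_panels, grid$quad_order,
                      min_panel = 0.05 / max(kap, be, ga))
      r <- split_degenerate_rates(kap, be, ga)
      b <- th / kap
      eb <- exp(-r$beta * qr$nodes); eg <- exp(-r$gamma * qr$nodes)
      U1 <- outer(u_N, eb) +
        outer(u_M, (r$beta / (r$beta - r$gamma)) * (eg - eb))
      denom <- 1 - b * U1
      if (any(Mod(denom) < 1e-10))
        stop("generating-function pole in the bursty limit (b U1 reaches 1)", call. = FALSE)
      p$a * as.vector((b * U1 / denom) %*% qr$weights)
    },
    stop("unknown limiting model: ", model, call. = FALSE))
}

#' Steady-state joint PMF of nascent and mature RNA counts
#'
#' Computes the exact stationary joint distribution `P(x_N, x_M)` on the grid
#' `0:n_max` by `0:m_max` for any of the five model kinds, by evaluating the
#' generating function on the product of complex unit-circle roots and taking
#' a two-dimensional inverse FFT.  The constitutive model is returned in its
#' exact product-Poisson form without a transform.
#'
#' @param model One of `"gou"`, `"cir"`, `"constitutive"`, `"mixture"`,
#'   `"bursty"`.
#' @param p An [sde_params] object.  For the mixture model the gamma shape is
#'   `a/kappa` and scale `theta`; for the bursty model the burst frequency is
#'   `a` and mean burst size `theta/kappa`.
#' @param grid A [grid_spec], or `NULL` to size the grid from closed-form
#'   moments.
#' @param tail_check Refuse grids whose boundary mass suggests truncation
#'   (default `TRUE`).  Likelihood evaluations on data-capped grids disable
#'   the check deliberately.
#' @return An object of class `joint_pmf`: list with the probability `probs`
#'   matrix (rows = nascent count 0..n_max, columns = mature count 0..m_max),
#'   `model`, `params`, `grid`, the largest imaginary residual `im_max` and
#'   the number of clipped negative entries `n_clipped`.
#' @examples
#' p <- sde_params(1, 1, 1, 1, 1)
#' j <- joint_pmf("constitutive", p)
#' j$probs[1, 1]  # exp(-2)
#' @export
joint_pmf <- function(model, p, grid = NULL, tail_check = TRUE) {
  model <- match_model(model)
  stopifnot(inherits(p, "sde_params"))
  grid <- resolve_grid(model, p, grid)
  Np <- grid$n_max + 1L; Mp <- grid$m_max + 1L
  if (model == "constitutive") {
    probs <- outer(stats::dpois(0:grid$n_max, p$mean_rate / p$beta),
                   stats::dpois(0:grid$m_max, p$mean_rate / p$gamma))
    dimnames(probs) <- list(0:grid$n_max, 0:grid$m_max)
    return(structure(list(probs = probs, model = model, params = p, grid = grid,
                          im_max = 0, n_clipped = 0L), class = "joint_pmf"))
  }
  gN <- exp(2i * pi * (seq_len(Np) - 1) / Np)
  gM <- exp(2i * pi * (seq_len(Mp) - 1) / Mp)
  uN <- rep(gN - 1, times = Mp)
  uM <- rep(gM - 1, each = Np)
  phi <- switch(model,
    gou = log_pgf_gou(uN, uM, p, grid),
    cir = as.vector(log_pgf_cir_batch(uN, uM, list(p), grid)),
    log_pgf_limit(model, uN, uM, p, grid))
  psi <- matrix(exp(phi), nrow = Np, ncol = Mp)
  praw <- stats::fft(psi) / (Np * Mp)
  im_max <- max(abs(Im(praw)))
  probs <- Re(praw)
  n_clipped <- sum(probs < 0)
  probs[probs < 0] <- 0
  boundary <- sum(probs[Np, ]) + sum(probs[, Mp])
  if (tail_check && boundary > sqrt(grid$tail_tol))
    stop(sprintf(paste0("state-space grid too small: boundary mass %.3g at extents ",
                        "(%d, %d); retry with n_max >= %d, m_max >= %d"),
                 boundary, grid$n_max, grid$m_max,
                 ceiling(1.5 * grid$n_max), ceiling(1.5 * grid$m_max)),
         call. = FALSE)
  dimnames(probs) <- list(0:grid$n_max, 0:grid$m_max)
  structure(list(probs = probs, model = model, params = p, grid = grid,
                 im_max = im_max, n_clipped = n_clipped), class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat(sprintf("Joint stationary PMF (%s model) on 0:%d x 0:%d; total mass %.8f\n",
              x$model, nrow(x$probs) - 1L, ncol(x$probs) - 1L, sum(x$probs)))
  invisible(x)
}

#' Closed-form limiting-model PMF
#'
#' Convenience wrapper around [joint_pmf()] restricted to the three limiting
#' models (constant-rate, gamma-frozen mixture, geometric-burst).
#'
#' @inheritParams joint_pmf
#' @param model One of `"constitutive"`, `"mixture"`, `"bursty"`.
#' @return A `joint_pmf` object.
#' @export
closed_form_pmf <- function(model, p, grid = NULL) {
  model <- match_model(model)
  if (!model %in% c("constitutive", "mixture", "bursty"))
    stop("closed_form_pmf is for the limiting models only", call. = FALSE)
  joint_pmf(model, p, grid)
}

#' Marginal PMF of one species
#'
#' @param j A `joint_pmf` object.
#' @param species `"nascent"` or `"mature"`.
#' @return Named numeric vector of marginal probabilities over counts.
#' @export
marginal_pmf <- function(j, species = c("nascent", "mature")) {
  stopifnot(inherits(j, "joint_pmf"))
  species <- match.arg(species)
  if (species == "nascent") rowSums(j$probs) else colSums(j$probs)
}

#' Total-variation distance between two joint PMFs
#'
#' Grids are zero-padded to common extents before comparison.
#'
#' @param a,b `joint_pmf` objects (or bare probability matrices).
#' @return Total-variation distance in `[0, 1]`.
#' @export
tv_distance <- function(a, b) {
  pa <- if (inherits(a, "joint_pmf")) a$probs else a
  pb <- if (inherits(b, "joint_pmf")) b$probs else b
  nr <- max(nrow(pa), nrow(pb)); nc <- max(ncol(pa), ncol(pb))
  pad <- function(m) {
    out <- matrix(0, nr, nc); out[seq_len(nrow(m)), seq_len(ncol(m))] <- m; out
  }
  0.5 * sum(abs(pad(pa) - pad(pb)))
}

#' Moments of a computed joint PMF
#'
#' Empirical-style means, variances and covariance evaluated directly from a
#' probability matrix; used to cross-check the transform inversion against
#' the closed-form moments.
#'
#' @param j A `joint_pmf` object.
#' @return List with `mu_N`, `mu_M`, `var_N`, `var_M`, `cov_NM`.
#' @export
pmf_moments <- function(j) {
  stopifnot(inherits(j, "joint_pmf"))
  P <- j$probs
  xN <- seq_len(nrow(P)) - 1; xM <- seq_len(ncol(P)) - 1
  pN <- rowSums(P); pM <- colSums(P); tot <- sum(P)
  mu_N <- sum(xN * pN) / tot; mu_M <- sum(xM * pM) / tot
  var_N <- sum(xN^2 * pN) / tot - mu_N^2
  var_M <- sum(xM^2 * pM) / tot - mu_M^2
  exy <- as.numeric(t(xN) %*% P %*% xM) / tot
  list(mu_N = mu_N, mu_M = mu_M, var_N = var_N, var_M = var_M,
       cov_NM = exy - mu_N * mu_M)
}

#' Write a joint PMF as dense CSV
#'
#' Columns are mature counts (header row of `x_M` indices), rows are nascent
#' counts.
#'
#' @param j A `joint_pmf` object.
#' @param path Output file path.
#' @export
write_pmf_csv <- function(j, path) {
  stopifnot(inherits(j, "joint_pmf"))
  df <- as.data.frame(j$probs)
  names(df) <- colnames(j$probs)
  utils::write.csv(cbind(x_N = rownames(j$probs), df), path, row.names = FALSE)
}
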