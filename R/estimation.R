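# Weighted least-squares estimation of the model parameters:
# Controlled Random Search over the bound box, refined with bounded
# Levenberg-Marquardt (minpack.lm), plus Jacobian-based confidence
# intervals.

included_points <- function(dataset) {
  ok <- is.finite(dataset$mean) & is.finite(dataset$sd) & dataset$sd > 0
  dataset[ok, , drop = FALSE]
}

# evaluate the model flux series at the dataset points; NULL on failure
model_at_points <- function(params, dataset, forcing, rtol, atol) {
  times <- sort(unique(dataset$time))
  sim <- tryCatch(
    simulate_adipose(params, forcing, times = times, rtol = rtol,
                     atol = atol),
    error = function(e) NULL)
  if (is.null(sim)) return(NULL)
  mf <- model_fluxes(sim)
  idx <- match(dataset$time, mf$time)
  vapply(seq_len(nrow(dataset)), function(i) {
    mf[[dataset$series[i]]][idx[i]]
  }, numeric(1))
}

# weighted residual vector ((M - mu)/sigma) over included points
flux_residuals <- function(params, dataset, forcing, rtol = 1e-8,
                           atol = 1e-10) {
  pts <- included_points(dataset)
  m <- model_at_points(params, pts, forcing, rtol, atol)
  if (is.null(m) || any(!is.finite(m))) {
    return(rep(1e6, nrow(pts)))
  }
  (m - pts$mean) / pts$sd
}

#' Weighted least-squares cost of a parameter set
#'
#' For each fitted flux series the cost accumulates the squared weighted
#' residuals `((M(p, t_i) - mu_i) / sigma_i)^2` over the sampling times;
#' the total is the unweighted sum over the five series.  Points with zero
#' or missing dispersion are excluded.  A failed simulation yields `Inf`.
#'
#' @param params model parameter vector
#' @param dataset a [flux_dataset()]
#' @param forcing a [build_forcing()] object
#' @param rtol,atol solver tolerances
#' @param breakdown if `TRUE`, also return the per-series costs
#' @return the scalar cost, or a list with `total` and `by_series`
#' @export
flux_cost <- function(params, dataset, forcing, rtol = 1e-8, atol = 1e-10,
                      breakdown = FALSE) {
  pts <- included_points(dataset)
  m <- model_at_points(params, pts, forcing, rtol, atol)
  if (is.null(m) || any(!is.finite(m))) {
    if (breakdown) {
      return(list(total = Inf,
                  by_series = setNames(rep(NA_real_,
                                           length(unique(pts$series))),
                                       unique(pts$series)),
                  failed = TRUE))
    }
    return(Inf)
  }
  r2 <- ((m - pts$mean) / pts$sd)^2
  if (!breakdown) return(sum(r2))
  list(total = sum(r2),
       by_series = tapply(r2, pts$series, sum),
       failed = FALSE)
}

new_fit_result <- function(par, free, cost, breakdown, jac, ci, seed,
                           lower, upper, solver, converged, n_local) {
  structure(list(par = par, free = free, cost = cost,
                 cost_breakdown = breakdown, jacobian = jac, ci95 = ci,
                 seed = seed, lower = lower, upper = upper, solver = solver,
                 converged = converged, n_local_restarts = n_local,
                 config_hash = config_hash(list(lower = lower,
                                                upper = upper,
                                                solver = solver,
                                                seed = seed))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit: cost %.6g (%s), seed %s\n", x$cost,
              if (isTRUE(x$converged)) "converged" else "not converged",
              as.character(x$seed)))
  est <- x$par[x$free]
  ci <- x$ci95
  for (k in names(est)) {
    cat(sprintf("  %-10s %.5g (%.5g, %.5g)\n", k, est[[k]],
                ci[k, "lo"], ci[k, "hi"]))
  }
  invisible(x)
}

#' Local bounded least-squares fit
#'
#' Levenberg-Marquardt minimisation of the weighted residual vector with
#' box constraints (via `minpack.lm::nls.lm`), starting from `init`.
#' Deterministic given the initial value.
#'
#' @param init named initial parameter vector (full, or a subset completed
#'   from [default_parameters()])
#' @param dataset a [flux_dataset()]
#' @param forcing a [build_forcing()] object
#' @param lower,upper named bound vectors over the free parameters
#' @param free names of the parameters to estimate (default: all 14)
#' @param maxiter,ftol,ptol,epsfcn Levenberg-Marquardt controls; `epsfcn`
#'   sets the forward-difference step well above the ODE solver noise
#'   floor
#' @param rtol,atol ODE solver tolerances
#' @param compute_ci compute Jacobian-based confidence intervals
#' @return a `fit_result`
#' @export
fit_local <- function(init, dataset, forcing, lower = NULL, upper = NULL,
                      free = par_names(), maxiter = 200, ftol = 1e-10,
                      ptol = 1e-10, epsfcn = 1e-8, rtol = 1e-8,
                      atol = 1e-10, compute_ci = TRUE) {
  base <- validate_parameters(init)
  cfg <- default_run_config()
  if (is.null(lower)) lower <- cfg$lower[free]
  if (is.null(upper)) upper <- cfg$upper[free]
  lower <- lower[free]
  upper <- upper[free]
  start <- pmin(pmax(base[free], lower), upper)
  resid_fn <- function(x) {
    p <- base
    p[free] <- x
    flux_residuals(p, dataset, forcing, rtol, atol)
  }
  res <- minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = maxiter, ftol = ftol, ptol = ptol,
                              epsfcn = epsfcn))
  par <- base
  par[free] <- res$par
  bd <- flux_cost(par, dataset, forcing, rtol, atol, breakdown = TRUE)
  jac <- residual_jacobian(par, free, dataset, forcing, rtol, atol)
  ci <- if (compute_ci) {
    jacobian_ci(jac, par[free], bd$total,
                n_obs = nrow(included_points(dataset)))
  } else {
    matrix(NA_real_, length(free), 2,
           dimnames = list(free, c("lo", "hi")))
  }
  converged <- res$info %in% 1:4
  new_fit_result(par, free, bd$total, bd$by_series, jac, ci,
                 seed = NA_integer_, lower = lower, upper = upper,
                 solver = list(rtol = rtol, atol = atol,
                               maxiter = maxiter, ftol = ftol, ptol = ptol),
                 converged = converged, n_local = 1L)
}

# Divide-and-conquer start: fit each flux series' dominant parameters
# separately (low-dimensional, robust) from moment-based heuristics, then
# assemble the result as a start for the joint refinement.
dac_start <- function(dataset, forcing, lower, upper, base, rtol, atol,
                      maxiter = 80) {
  p <- base
  fast_mean <- function(series) {
    d <- dataset[dataset$series == series & dataset$time <= 0, ]
    m <- mean(d$mean[is.finite(d$mean)])
    if (is.finite(m)) m else NA_real_
  }
  i_b <- forcing$I_B
  # moment-based heuristics from the fasting data
  tg0 <- fast_mean("tg")
  if (is.finite(tg0) && tg0 > 0) {
    p["k_ad"] <- min(max(tg0 / (forcing$fasting[["tg"]] * i_b), lower[["k_ad"]]),
                     upper[["k_ad"]])
  }
  p["tau_lpl"] <- min(150, upper[["tau_lpl"]])
  p["tau_at"] <- min(30, upper[["tau_at"]])
  glc0 <- fast_mean("glucose")
  if (is.finite(glc0) && glc0 > 0) {
    p["glut1"] <- min(0.5 * glc0 / forcing$fasting[["glucose"]],
                      upper[["glut1"]])
    p["glut4"] <- min(0.5 * glc0 / (forcing$fasting[["glucose"]] * i_b),
                      upper[["glut4"]])
  }
  gly0 <- fast_mean("glycerol")
  lpl_fast <- p[["k_ad"]] * forcing$fasting[["tg"]] * i_b
  atl0 <- max(abs(min(gly0, 0, na.rm = TRUE)) - lpl_fast, 0.01)
  p["b_atl"] <- min(atl0 / 2, upper[["b_atl"]])
  p["atl_max"] <- min(atl0, upper[["atl_max"]])
  p["k_atl"] <- min(i_b, upper[["k_atl"]])
  sp <- dataset[dataset$series == "spill_fraction" & is.finite(dataset$mean), ]
  if (nrow(sp) > 0) {
    p["d_spill"] <- min(100 * max(sp$mean), upper[["d_spill"]])
  }
  p["p_gly"] <- upper[["p_gly"]] / 20
  p["p_nefa"] <- upper[["p_nefa"]] / 20
  p["k_reester"] <- upper[["k_reester"]] / 20
  p["tau_g3p"] <- min(30, upper[["tau_g3p"]])
  p["frac_use"] <- 0.1

  stages <- list(
    list(series = "tg", free = c("k_ad", "tau_lpl")),
    list(series = "spill_fraction", free = "d_spill"),
    list(series = "glucose", free = c("glut1", "glut4", "tau_at")),
    list(series = "glycerol", free = c("p_gly", "b_atl", "atl_max",
                                       "k_atl")),
    list(series = "nefa", free = c("p_nefa", "k_reester", "frac_use",
                                   "tau_g3p")))
  for (st in stages) {
    ds <- dataset[dataset$series == st$series, , drop = FALSE]
    if (nrow(ds[is.finite(ds$sd) & ds$sd > 0, ]) < 2L) next
    best <- NULL
    for (j in 1:3) {
      p_try <- p
      if (j > 1) {
        jit <- p[st$free] * exp(stats::rnorm(length(st$free), 0, log(3)))
        p_try[st$free] <- pmin(pmax(jit, lower[st$free]), upper[st$free])
      }
      ft <- tryCatch(
        fit_local(p_try, ds, forcing, lower = lower[st$free],
                  upper = upper[st$free], free = st$free,
                  maxiter = maxiter, rtol = rtol, atol = atol,
                  compute_ci = FALSE),
        error = function(e) NULL)
      if (!is.null(ft) && (is.null(best) || ft$cost < best$cost)) {
        best <- ft
      }
    }
    if (!is.null(best)) p[st$free] <- best$par[st$free]
  }
  p[names(lower)]
}

# Price-style Controlled Random Search over a box
crs_minimize <- function(fn, lower, upper, n_init = 250, maxeval = 5000,
                         tol = 1e-8) {
  d <- length(lower)
  n_pop <- max(10 * d, n_init)
  pop <- vapply(seq_len(d),
                function(j) stats::runif(n_pop, lower[j], upper[j]),
                numeric(n_pop))
  f <- apply(pop, 1, fn)
  evals <- n_pop
  while (evals < maxeval) {
    iw <- which.max(f)
    ib <- which.min(f)
    if (is.finite(f[iw]) &&
        (f[iw] - f[ib]) <= tol * max(1, abs(f[ib]))) break
    idx <- sample.int(n_pop, d + 1L)
    centroid <- colMeans(pop[idx[seq_len(d)], , drop = FALSE])
    trial <- 2 * centroid - pop[idx[d + 1L], ]
    if (all(trial >= lower & trial <= upper)) {
      ft <- fn(trial)
      evals <- evals + 1L
      if (ft < f[iw]) {
        pop[iw, ] <- trial
        f[iw] <- ft
      }
    }
  }
  o <- order(f)
  list(par = pop[o[1], ], value = f[o[1]], evals = evals,
       population = pop[o, , drop = FALSE], fpop = f[o])
}

#' Global + local parameter estimation
#'
#' Controlled Random Search (Price-style population search seeded with
#' `n_init` uniform draws over the bound box) followed by bounded
#' Levenberg-Marquardt refinement from the best `n_start` population
#' points.  Fully reproducible from `seed`.
#'
#' @param dataset a [flux_dataset()]
#' @param forcing a [build_forcing()] object
#' @param config a [default_run_config()] list (bounds, optimiser and
#'   solver settings)
#' @param seed integer seed; overrides `config$seed`
#' @param free names of parameters to estimate
#' @param base_params values for the non-estimated parameters
#' @return a `fit_result` with seed and provenance recorded
#' @export
fit_global <- function(dataset, forcing, config = NULL, seed = NULL,
                       free = par_names(), base_params = NULL) {
  if (is.null(config)) config <- default_run_config(if (is.null(seed)) 1L else seed)
  config <- validate_run_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  base <- validate_parameters(base_params)
  lower <- config$lower[free]
  upper <- config$upper[free]
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    stop("bounds must be finite for the global search box")
  }
  rtol <- config$solver$rtol
  atol <- config$solver$atol
  cost_fn <- function(x) {
    p <- base
    p[free] <- x
    flux_cost(p, dataset, forcing, rtol, atol)
  }
  n_start <- config$local$n_start
  if (config$crs$n_init <= 1L) {
    # degenerate single-start local fit from the box midpoint
    start <- (lower + upper) / 2
    starts <- matrix(start, nrow = 1, dimnames = list(NULL, free))
    n_start <- 1L
  } else {
    crs <- crs_minimize(cost_fn, lower, upper, n_init = config$crs$n_init,
                        maxeval = config$crs$maxeval, tol = config$crs$tol)
    # cost-ordered population, thinned so local refinements start from
    # distinct basins rather than one valley
    scale <- pmax(upper - lower, 1e-12)
    picked <- 1L
    for (i in seq_len(nrow(crs$population))) {
      if (length(picked) >= n_start) break
      d <- vapply(picked, function(j) {
        sqrt(mean(((crs$population[i, ] - crs$population[j, ]) / scale)^2))
      }, numeric(1))
      if (all(d > 0.05)) picked <- c(picked, i)
    }
    starts <- crs$population[picked, , drop = FALSE]
    colnames(starts) <- free
    if (identical(sort(free), sort(par_names()))) {
      # divide-and-conquer start: per-series low-dimensional fits,
      # assembled into one joint start (robust against the
      # quasi-equilibrium valleys of the full 14-parameter surface)
      dac <- tryCatch(
        dac_start(dataset, forcing, config$lower[free],
                  config$upper[free], base, rtol, atol),
        error = function(e) NULL)
      if (!is.null(dac)) starts <- rbind(starts, dac[free])
    }
  }
  best <- NULL
  n_local <- 0L
  for (i in seq_len(nrow(starts))) {
    p0 <- base
    p0[free] <- starts[i, ]
    fit <- tryCatch(
      fit_local(p0, dataset, forcing, lower = lower, upper = upper,
                free = free, maxiter = config$local$maxiter,
                ftol = config$local$ftol, ptol = config$local$ptol,
                rtol = rtol, atol = atol, compute_ci = FALSE),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_local <- n_local + 1L
    if (is.null(best) || fit$cost < best$cost) best <- fit
  }
  if (is.null(best)) stop("all local refinements failed")
  # basin-hopping polish: lognormal perturbations of the incumbent,
  # re-refined locally, escape the broad quasi-equilibrium valleys of the
  # exchange-rate parameters
  n_hop <- config$local$n_hop
  if (!is.null(n_hop) && n_hop > 0L) {
    for (i in seq_len(n_hop)) {
      if (best$cost < 1e-12) break
      x <- best$par[free] * exp(stats::rnorm(length(free), 0, log(2)))
      # parameters pinned at a bound are resampled log-uniformly over the
      # box, otherwise multiplicative proposals can never escape
      span <- upper - lower
      at_bound <- best$par[free] <= lower + 0.01 * span |
        best$par[free] >= upper - 0.01 * span
      if (any(at_bound)) {
        lo_pos <- pmax(lower[at_bound], 1e-4 * upper[at_bound])
        x[at_bound] <- exp(stats::runif(sum(at_bound), log(lo_pos),
                                        log(upper[at_bound])))
      }
      x <- pmin(pmax(x, lower), upper)
      p0 <- base
      p0[free] <- x
      ft <- tryCatch(
        fit_local(p0, dataset, forcing, lower = lower, upper = upper,
                  free = free, maxiter = config$local$maxiter,
                  ftol = config$local$ftol, ptol = config$local$ptol,
                  rtol = rtol, atol = atol, compute_ci = FALSE),
        error = function(e) NULL)
      if (is.null(ft)) next
      n_local <- n_local + 1L
      if (ft$cost < best$cost) best <- ft
    }
  }
  ci <- jacobian_ci(best$jacobian, best$par[free], best$cost,
                    n_obs = nrow(included_points(dataset)))
  best$ci95 <- ci
  best$seed <- config$seed
  best$n_local_restarts <- n_local
  best$config_hash <- config_hash(config)
  best
}

# central-difference Jacobian of the weighted residuals w.r.t. free params
residual_jacobian <- function(par, free, dataset, forcing, rtol = 1e-8,
                              atol = 1e-10, rel_step = 1e-4) {
  base <- validate_parameters(par)
  r0 <- flux_residuals(base, dataset, forcing, rtol, atol)
  J <- matrix(0, nrow = length(r0), ncol = length(free),
              dimnames = list(NULL, free))
  for (k in free) {
    h <- rel_step * max(abs(base[[k]]), 1e-6)
    pp <- base; pp[k] <- base[[k]] + h
    pm <- base; pm[k] <- max(base[[k]] - h, 0)
    rp <- flux_residuals(pp, dataset, forcing, rtol, atol)
    rm <- flux_residuals(pm, dataset, forcing, rtol, atol)
    J[, k] <- (rp - rm) / (pp[[k]] - pm[[k]])
  }
  J
}

#' Jacobian-based 95% confidence intervals
#'
#' Linearised intervals `estimate +/- 1.96 * SE` with the covariance
#' approximated as `s^2 (J^T J)^{-1}`, `s^2 = cost / (n_obs - k)`.  The
#' linearisation ignores the bound constraints, so intervals may extend
#' below zero.  Parameters with (numerically) zero sensitivity get
#' infinite intervals with a warning; a singular `J^T J` falls back to the
#' Moore-Penrose pseudo-inverse with a non-identifiability warning.
#'
#' @param J residual Jacobian (n_obs x k)
#' @param par_free the point estimates (length k)
#' @param cost weighted residual sum of squares at the optimum
#' @param n_obs number of fitted observations
#' @return matrix with columns `lo`, `hi`, rownames the parameter names
#' @export
jacobian_ci <- function(J, par_free, cost, n_obs) {
  k <- ncol(J)
  dof <- n_obs - k
  s2 <- if (dof > 0) cost / dof else NA_real_
  col_norm <- sqrt(colSums(J^2))
  zero_col <- col_norm < 1e-12 * max(col_norm, 1)
  if (any(zero_col)) {
    warning("zero-sensitivity parameter(s): ",
            paste(colnames(J)[zero_col], collapse = ", "),
            "; confidence interval set to infinite")
  }
  JtJ <- crossprod(J)
  cov <- tryCatch(s2 * solve(JtJ), error = function(e) {
    warning("J^T J is singular; using pseudo-inverse ",
            "(some parameters are not identifiable)")
    s2 * MASS::ginv(JtJ)
  })
  se <- sqrt(pmax(diag(cov), 0))
  se[zero_col] <- Inf
  out <- cbind(lo = par_free - 1.96 * se, hi = par_free + 1.96 * se)
  rownames(out) <- colnames(J)
  out
}
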