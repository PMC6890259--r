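# Profile-likelihood identifiability, AICc model-term selection, and
# local parameter sensitivities.

#' Solve a three-compartment insulin delay chain
#'
#' Integrates the linear cascade driven by an arbitrary insulin input
#' function and returns the final (delayed) compartment.
#'
#' @param i_fun function of time returning the input insulin (uU/ml)
#' @param tau delay constant (min), > 0
#' @param times output times (min)
#' @param init initial value of all three compartments (default: input at
#'   the first time)
#' @return data frame with `time` and `i_delay`
#' @export
delay_chain_solve <- function(i_fun, tau, times, init = i_fun(times[1])) {
  if (tau <= 0) stop("tau must be > 0")
  rhs <- function(t, y, parms) list(delay_chain_rhs(y, i_fun(t), tau))
  out <- deSolve::ode(y = rep(init, 3), times = sort(unique(times)),
                      func = rhs, parms = NULL, rtol = 1e-10, atol = 1e-12)
  data.frame(time = out[, 1], i_delay = out[, 4])
}

#' Profile likelihood of one parameter
#'
#' The parameter is fixed on a grid around its optimum and all remaining
#' free parameters are re-estimated locally, warm-started from the
#' previous grid point, walking outward from the optimum in both
#' directions.  A parameter is classified `identifiable` if the profiled
#' cost exceeds `min + threshold` on both sides within the grid,
#' `bounded_above`/`bounded_below` if on one side only (the data impose
#' only an upper/lower bound), and `non_identifiable` otherwise.
#'
#' @param fit a converged `fit_result`
#' @param param name of the parameter to profile
#' @param dataset,forcing the fitting data
#' @param n_per_side grid points on each side of the optimum
#' @param span multiplicative half-range of the log-spaced grid
#'   (`optimum/span` to `optimum*span`); `frac_use` instead uses a linear
#'   grid on \[0, 1\]
#' @param threshold chi-squared cost increase defining the 95% confidence
#'   region (3.84, 1 d.o.f.)
#' @param maxiter Levenberg-Marquardt iterations per refit
#' @param rtol,atol ODE solver tolerances
#' @return object of class `profile_result`: list with `parameter`,
#'   `grid`, `cost`, `optimum`, `min_cost`, `threshold`, `classification`
#' @export
profile_likelihood <- function(fit, param, dataset, forcing,
                               n_per_side = 21, span = 100,
                               threshold = 3.84, maxiter = 50,
                               rtol = 1e-8, atol = 1e-10) {
  stopifnot(param %in% fit$free)
  opt <- fit$par[[param]]
  free_rest <- setdiff(fit$free, param)
  if (param == "frac_use") {
    left <- seq(0, opt, length.out = n_per_side + 1L)[seq_len(n_per_side)]
    right <- seq(opt, 1, length.out = n_per_side + 1L)[-1L]
  } else if (opt <= 1e-10) {
    # optimum at the zero bound: only an upward grid is meaningful
    up_hi <- max(fit$upper[[param]], 1e-6, na.rm = TRUE)
    left <- numeric(0)
    right <- exp(seq(log(up_hi / 1e4), log(up_hi),
                     length.out = 2L * n_per_side))
  } else {
    left <- rev(exp(seq(log(opt / span), log(opt),
                        length.out = n_per_side + 1L)[seq_len(n_per_side)]))
    right <- exp(seq(log(opt), log(opt * span),
                     length.out = n_per_side + 1L)[-1L])
    if (param %in% c("tau_lpl", "tau_at", "tau_g3p")) {
      left <- left[left > 0]
    }
  }

  refit_cost <- function(value, start) {
    p <- start
    p[param] <- value
    ft <- tryCatch(
      fit_local(p, dataset, forcing, free = free_rest, maxiter = maxiter,
                rtol = rtol, atol = atol, compute_ci = FALSE),
      error = function(e) NULL)
    if (is.null(ft)) return(list(cost = NA_real_, par = start))
    list(cost = ft$cost, par = ft$par)
  }

  walk <- function(values) {
    costs <- numeric(length(values))
    start <- fit$par
    for (i in seq_along(values)) {
      res <- refit_cost(values[i], start)
      costs[i] <- res$cost
      if (is.finite(res$cost)) start <- res$par
    }
    costs
  }
  cost_left <- walk(left)    # walking away from the optimum (descending)
  cost_right <- walk(right)

  grid <- c(rev(left), opt, right)
  cost <- c(rev(cost_left), fit$cost, cost_right)
  min_cost <- min(cost, na.rm = TRUE)
  crosses_low <- any(cost_left > min_cost + threshold, na.rm = TRUE)
  crosses_high <- any(cost_right > min_cost + threshold, na.rm = TRUE)
  classification <- if (crosses_low && crosses_high) {
    "identifiable"
  } else if (crosses_high) {
    "bounded_above"
  } else if (crosses_low) {
    "bounded_below"
  } else {
    "non_identifiable"
  }
  structure(list(parameter = param, grid = grid, cost = cost,
                 optimum = opt, min_cost = min_cost, threshold = threshold,
                 classification = classification),
            class = "profile_result")
}

#' @export
print.profile_result <- function(x, ...) {
  cat(sprintf("Profile likelihood for %s: %s (min cost %.4g over %d points)\n",
              x$parameter, x$classification, x$min_cost, length(x$grid)))
  invisible(x)
}

#' Profile all free parameters of a fit
#'
#' Convenience wrapper running [profile_likelihood()] for every free
#' parameter with a coarse default grid suitable for whole-model
#' identifiability classification.
#'
#' @inheritParams profile_likelihood
#' @param params parameters to profile (default: all free parameters)
#' @param ... passed to [profile_likelihood()]
#' @return named list of `profile_result` objects
#' @export
profile_all_parameters <- function(fit, dataset, forcing,
                                   params = fit$free, n_per_side = 6,
                                   span = 100, maxiter = 30, ...) {
  out <- lapply(params, function(p) {
    profile_likelihood(fit, p, dataset, forcing, n_per_side = n_per_side,
                       span = span, maxiter = maxiter, ...)
  })
  names(out) <- params
  out
}

#' Summarise identifiability classes
#'
#' @param profiles a list of `profile_result` objects
#' @return list with `table` (data frame parameter/class) and `counts`
#'   (named vector over the four classes)
#' @export
classify_identifiability <- function(profiles) {
  classes <- vapply(profiles, function(p) p$classification, character(1))
  params <- vapply(profiles, function(p) p$parameter, character(1))
  lev <- c("identifiable", "bounded_above", "bounded_below",
           "non_identifiable")
  counts <- table(factor(classes, levels = lev))
  list(table = data.frame(parameter = params, class = classes,
                          row.names = NULL),
       counts = setNames(as.integer(counts), lev))
}

#' Small-sample corrected Akaike Information Criterion
#'
#' `AICc = n ln(RSS/n) + 2k + 2k(k+1)/(n - k - 1)`, with RSS the weighted
#' residual sum of squares (the fitting cost).
#'
#' @param rss weighted residual sum of squares, >= 0
#' @param n_obs number of observations
#' @param k_params number of estimated parameters
#' @return the AICc score
#' @export
aicc <- function(rss, n_obs, k_params) {
  if (n_obs - k_params - 1 <= 0) {
    stop("AICc undefined: n - k - 1 must be positive (n = ", n_obs,
         ", k = ", k_params, ")")
  }
  if (rss < 0) stop("rss must be non-negative")
  n_obs * log(rss / n_obs) + 2 * k_params +
    2 * k_params * (k_params + 1) / (n_obs - k_params - 1)
}

#' Candidate flux-term variants
#'
#' Construct a candidate rate expression for the divide-and-conquer term
#' comparison.  Built-in families are returned by [spill_term_variants()]
#' (constant spill, basal+insulin spill, insulin-only spill) and
#' [lpl_term_variants()] (undelayed linear, delayed linear, delayed
#' Michaelis-Menten LPL lipolysis).
#'
#' @param name variant name
#' @param series flux series the variant targets
#' @param pars named default parameter vector
#' @param lower,upper named bound vectors
#' @param predict `function(par, forcing, times)` returning the predicted
#'   series
#' @return a `term_variant`
#' @export
term_variant <- function(name, series, pars, lower, upper, predict) {
  stopifnot(identical(names(pars), names(lower)),
            identical(names(pars), names(upper)))
  structure(list(name = name, series = series, pars = pars,
                 lower = lower, upper = upper, predict = predict),
            class = "term_variant")
}

#' @rdname term_variant
#' @export
spill_term_variants <- function() {
  clamp01 <- function(x) pmin(1, pmax(0, x))
  list(
    term_variant(
      "spill_insulin_only", "spill_fraction",
      pars = c(d_spill = 30), lower = c(d_spill = 0),
      upper = c(d_spill = 300),
      predict = function(par, forcing, times) {
        spill_fraction(par[["d_spill"]], forcing$I_B,
                       forcing$insulin(times))
      }),
    term_variant(
      "spill_basal_insulin", "spill_fraction",
      pars = c(b_spill = 10, d_spill = 30),
      lower = c(b_spill = 0, d_spill = 0),
      upper = c(b_spill = 100, d_spill = 300),
      predict = function(par, forcing, times) {
        clamp01(0.01 * (par[["b_spill"]] +
                          par[["d_spill"]] * forcing$I_B /
                            forcing$insulin(times)))
      }),
    term_variant(
      "spill_constant", "spill_fraction",
      pars = c(c_spill = 0.25), lower = c(c_spill = 0),
      upper = c(c_spill = 1),
      predict = function(par, forcing, times) {
        rep(par[["c_spill"]], length(times))
      }))
}

#' @rdname term_variant
#' @export
lpl_term_variants <- function() {
  list(
    term_variant(
      "lpl_linear_delayed", "tg",
      pars = c(k_ad = 0.01, tau_lpl = 120),
      lower = c(k_ad = 0, tau_lpl = 1),
      upper = c(k_ad = 0.1, tau_lpl = 600),
      predict = function(par, forcing, times) {
        del <- delay_chain_solve(forcing$insulin, par[["tau_lpl"]],
                                 c(-30, times), init = forcing$I_B)
        i_lpl <- del$i_delay[match(times, del$time)]
        tg_flux(par[["k_ad"]], forcing$tg(times), i_lpl)
      }),
    term_variant(
      "lpl_linear_undelayed", "tg",
      pars = c(k_ad = 0.01), lower = c(k_ad = 0),
      upper = c(k_ad = 0.1),
      predict = function(par, forcing, times) {
        tg_flux(par[["k_ad"]], forcing$tg(times), forcing$insulin(times))
      }),
    term_variant(
      "lpl_mm_delayed", "tg",
      pars = c(vmax = 0.5, km = 2, tau_lpl = 120),
      lower = c(vmax = 0, km = 0.01, tau_lpl = 1),
      upper = c(vmax = 50, km = 50, tau_lpl = 600),
      predict = function(par, forcing, times) {
        del <- delay_chain_solve(forcing$insulin, par[["tau_lpl"]],
                                 c(-30, times), init = forcing$I_B)
        i_lpl <- del$i_delay[match(times, del$time)]
        tg <- forcing$tg(times)
        par[["vmax"]] * tg / (par[["km"]] + tg) * i_lpl
      }))
}

# multi-start bounded LM fit of one term variant against one series
fit_term_variant <- function(variant, series_df, forcing, n_start = 20) {
  pts <- series_df[is.finite(series_df$mean) & is.finite(series_df$sd) &
                     series_df$sd > 0, , drop = FALSE]
  if (nrow(pts) == 0L) stop("no usable points for variant ", variant$name)
  resid_fn <- function(x) {
    pred <- tryCatch(variant$predict(setNames(x, names(variant$pars)),
                                     forcing, pts$time),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) {
      return(rep(1e6, nrow(pts)))
    }
    (pred - pts$mean) / pts$sd
  }
  d <- length(variant$pars)
  rand <- matrix(0, nrow = max(n_start - 1L, 0L), ncol = d)
  for (j in seq_len(d)) {
    rand[, j] <- stats::runif(nrow(rand), variant$lower[j],
                              variant$upper[j])
  }
  starts <- rbind(matrix(variant$pars, nrow = 1), rand)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = setNames(starts[i, ], names(variant$pars)),
                         lower = variant$lower, upper = variant$upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 100)),
      error = function(e) NULL)
    if (is.null(res)) next
    rss <- sum(res$fvec^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(par = res$par, rss = rss)
    }
  }
  if (is.null(best)) stop("all starts failed for variant ", variant$name)
  best$n_obs <- nrow(pts)
  best$k <- d
  best
}

#' AICc ranking of candidate flux terms
#'
#' Fits each candidate term variant to the given flux series by weighted
#' least squares (multi-start bounded Levenberg-Marquardt, seeded) and
#' ranks the variants by AICc, ascending.  Ties are broken by variant
#' name so the ranking is deterministic.
#'
#' @param variants list of [term_variant()] objects targeting one series
#' @param series_df data frame with columns `time`, `mean`, `sd` for the
#'   target series
#' @param forcing a [build_forcing()] object
#' @param seed integer seed for the random starts
#' @param n_start number of starts per variant
#' @return data frame `name`, `k`, `rss`, `aicc`, `delta_aicc`, `rank`,
#'   with the fitted parameter vectors in `attr(, "fits")`
#' @export
select_term <- function(variants, series_df, forcing, seed = 1L,
                        n_start = 20) {
  if (length(variants) < 2L) stop("need at least two variants to compare")
  set.seed(seed)
  fits <- list()
  rows <- list()
  for (v in variants) {
    ft <- tryCatch(fit_term_variant(v, series_df, forcing, n_start),
                   error = function(e) NULL)
    if (is.null(ft)) {
      warning("variant ", v$name, " failed to fit; excluded")
      next
    }
    fits[[v$name]] <- ft
    rows[[v$name]] <- data.frame(name = v$name, k = ft$k, rss = ft$rss,
                                 aicc = aicc(ft$rss, ft$n_obs, ft$k))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc, out$name), , drop = FALSE]
  out$delta_aicc <- out$aicc - out$aicc[1]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Local sensitivity coefficients of the model fluxes
#'
#' Central finite differences of each flux series with respect to the
#' log-parameters (relative step 1e-4), giving `d flux_j(t_i) / d log p_k`.
#' Parameters at zero cannot be perturbed multiplicatively; their columns
#' are zero and flagged in `attr(, "at_zero")`.
#'
#' @param params model parameter vector
#' @param forcing a [build_forcing()] object
#' @param times evaluation times (min)
#' @param free parameters to perturb (default all 14)
#' @param rel_step relative log-step
#' @return matrix with one row per series/time pair (rownames
#'   `"series@time"`) and one column per parameter
#' @export
local_sensitivities <- function(params, forcing, times = canonical_times(),
                                free = par_names(), rel_step = 1e-4) {
  base <- validate_parameters(params)
  series <- c("tg", "spill_fraction", "glucose", "glycerol", "nefa")
  flux_vec <- function(p) {
    mf <- model_fluxes(simulate_adipose(p, forcing, times = times))
    unlist(mf[series], use.names = FALSE)
  }
  f0 <- flux_vec(base)
  rn <- as.vector(outer(times, series,
                        function(t, s) paste0(s, "@", t)))
  S <- matrix(0, nrow = length(f0), ncol = length(free),
              dimnames = list(rn, free))
  at_zero <- logical(length(free))
  names(at_zero) <- free
  for (k in free) {
    if (base[[k]] == 0) {
      at_zero[k] <- TRUE
      next
    }
    pp <- base; pp[k] <- base[[k]] * exp(rel_step)
    pm <- base; pm[k] <- base[[k]] * exp(-rel_step)
    S[, k] <- (flux_vec(pp) - flux_vec(pm)) / (2 * rel_step)
  }
  if (any(at_zero)) {
    warning("parameter(s) at zero not perturbed: ",
            paste(free[at_zero], collapse = ", "))
  }
  attr(S, "at_zero") <- at_zero
  S
}
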