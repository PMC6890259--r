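# Decomposition of simulated glycerol and NEFA fluxes into constituent
# reaction time courses, and postprandial summary descriptors.

#' Decompose simulated fluxes into constituent reactions
#'
#' Extracts the constituent reaction rate curves (LPL glycerol/NEFA
#' release, stored-TG lipolysis, plasma-adipose diffusion, spill-over,
#' re-esterification, G-3-P production) and the compartment concentration
#' curves from a simulation, and verifies the closure identities that tie
#' the constituents to the net model fluxes: for glycerol, net flux =
#' -(LPL release + adipose-to-plasma diffusion); for NEFA, net flux =
#' plasma-to-adipose diffusion - spill-over; at the LPL node, spill +
#' adipose influx = 3 x TG hydrolysis.
#'
#' @param sim an `adipose_sim` object (use a dense time grid, e.g. 1-min)
#' @param tol closure tolerance (absolute)
#' @return object of class `flux_decomposition`: data frame of time,
#'   constituent rates, net fluxes, and compartment concentrations
#' @export
decompose <- function(sim, tol = 1e-9) {
  tr <- sim$trajectory
  out <- data.frame(
    time = tr$time,
    lpl_rate = tr$lpl_rate,
    atl_rate = tr$atl_rate,
    spill_rate = tr$spill_rate,
    adipose_influx = tr$adipose_influx,
    gly_diffusion = tr$gly_diffusion,
    nefa_diffusion = tr$nefa_diffusion,
    reester_rate = tr$reester_rate,
    g3p_production = tr$g3p_production,
    glycerol_flux = tr$glycerol_flux,
    nefa_flux = tr$nefa_flux,
    tg_flux = tr$tg_flux,
    glucose_flux = tr$glucose_flux,
    spill_fraction = tr$spill_fraction,
    gly_adipose = tr$gly_at,
    nefa_adipose = tr$nefa_at,
    nefa_plasma_local = tr$nefa_pl,
    g3p_adipose = tr$g3p_at)
  err_gly <- max(abs(out$glycerol_flux + out$lpl_rate + out$gly_diffusion))
  err_nefa <- max(abs(out$nefa_flux -
                        (out$nefa_diffusion - out$spill_rate)))
  err_fa <- max(abs(out$spill_rate + out$adipose_influx -
                      3 * out$lpl_rate))
  if (max(err_gly, err_nefa, err_fa) > tol) {
    stop(sprintf(paste0("flux decomposition closure violated: glycerol ",
                        "%.3g, NEFA %.3g, LPL node %.3g (tol %.1g)"),
                 err_gly, err_nefa, err_fa, tol))
  }
  structure(out, closure_error = c(glycerol = err_gly, nefa = err_nefa,
                                   lpl_node = err_fa),
            class = c("flux_decomposition", "data.frame"))
}

#' Time of the curve maximum
#'
#' Argmax of a sampled curve over a window; ties break to the earliest
#' time.
#'
#' @param times sampling times (min)
#' @param values curve values
#' @param window length-2 window in minutes (default the postprandial
#'   phase, 0 to 300)
#' @return peak time (min)
#' @export
peak_time <- function(times, values, window = c(0, 300)) {
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("empty window")
  t_w <- times[keep]
  v_w <- values[keep]
  t_w[which.max(v_w)]
}

#' Magnitude of the postprandial response slope
#'
#' Ordinary least-squares slope of the curve over the stated window,
#' reported as a magnitude.  Defaults to the onset phase (0 to 120 min)
#' where insulin-driven inhibition and stimulation act.
#'
#' @param times sampling times (min)
#' @param values curve values
#' @param window length-2 window in minutes
#' @return |slope| (curve units per min)
#' @export
response_slope <- function(times, values, window = c(0, 120)) {
  keep <- times >= window[1] & times <= window[2]
  if (sum(keep) < 2L) stop("need at least two points in the window")
  abs(unname(stats::coef(stats::lm(values[keep] ~ times[keep]))[2]))
}

#' Fasting (baseline) rate of a curve
#'
#' Mean of the curve over the fasting window \[-30, 0\] min.
#'
#' @param times sampling times (min)
#' @param values curve values
#' @return the fasting mean rate
#' @export
fasting_rate <- function(times, values) {
  keep <- times >= -30 & times <= 0
  if (!any(keep)) stop("curve not defined on the fasting window")
  mean(values[keep])
}
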