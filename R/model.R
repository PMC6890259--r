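#' @keywords internal
par_names <- function() {
  c("k_ad", "tau_lpl", "tau_at", "d_spill", "glut1", "glut4", "p_gly",
    "b_atl", "atl_max", "k_atl", "p_nefa", "k_reester", "frac_use",
    "tau_g3p")
}

#' Default model parameters
#'
#' The 14 estimable parameters of the refined adipose tissue model, plus the
#' optional glycerol sink constant `k_sink` (disabled, 0, by default).  The
#' five rate/delay constants for which published baseline estimates exist
#' (`k_ad`, `tau_lpl`, `tau_at`, `p_gly`, `p_nefa`) default to those
#' estimates; the remaining nine are synthetic placeholder values chosen to
#' give physiologically plausible flux magnitudes (fasting stored-TG
#' lipolysis ~0.22 umol/100 ml/min, postprandial TG uptake below ~1
#' umol/100 ml/min) and are also the default "truth" of the synthetic
#' cohort generator.
#'
#' Units: `k_ad` per (uU/ml)/min acting on mmol/l TG; `tau_lpl`, `tau_at`,
#' `tau_g3p` minutes; `d_spill` percent-scale (spill fraction at basal
#' insulin = `d_spill`/100); `glut1` per min, `glut4` per (uU/ml)/min;
#' `p_gly`, `p_nefa` per min; `b_atl`, `atl_max` umol/100 ml/min; `k_atl`
#' uU/ml; `frac_use` dimensionless in \[0,1\].
#'
#' @return named numeric vector of length 15 (14 parameters + `k_sink`)
#' @export
default_parameters <- function() {
  c(k_ad      = 0.0096,
    tau_lpl   = 156.92,
    tau_at    = 21.19,
    d_spill   = 35,
    glut1     = 0.02,
    glut4     = 0.008,
    p_gly     = 0.249,
    b_atl     = 0.05,
    atl_max   = 0.35,
    k_atl     = 10,
    p_nefa    = 0.0444,
    k_reester = 0.001,
    frac_use  = 0.2,
    tau_g3p   = 30,
    k_sink    = 0)
}

#' Validate a model parameter vector
#'
#' Checks non-negativity of all parameters, `frac_use` <= 1, strictly
#' positive delay constants, and the `k_atl` > 0 requirement whenever
#' `atl_max` > 0.  Missing entries are filled from [default_parameters()].
#'
#' @param params named numeric vector (any subset of the parameter names)
#' @return the completed, validated parameter vector
#' @export
validate_parameters <- function(params) {
  full <- default_parameters()
  if (!is.null(params)) {
    unknown <- setdiff(names(params), names(full))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    full[names(params)] <- params
  }
  if (any(!is.finite(full))) stop("non-finite parameter value")
  if (any(full < 0)) {
    stop("parameters must be non-negative; offending: ",
         paste(names(full)[full < 0], collapse = ", "))
  }
  if (full[["frac_use"]] > 1) stop("frac_use must lie in [0, 1]")
  for (tau in c("tau_lpl", "tau_at", "tau_g3p")) {
    if (full[[tau]] <= 0) {
      stop(tau, " must be strictly positive (a zero delay must be ",
           "modelled with an explicit undelayed term, not tau = 0)")
    }
  }
  if (full[["atl_max"]] > 0 && full[["k_atl"]] <= 0) {
    stop("k_atl must be positive when atl_max > 0")
  }
  full
}

#' Three-compartment insulin delay chain: right-hand side
#'
#' The damped insulin signal used for LPL lipolysis and for the adipose
#' interstitial space is a linear cascade of three first-order compartments
#' with a common time constant `tau`:
#' dI1/dt = (I_art - I1)/tau, dI2/dt = (I1 - I2)/tau,
#' dI_delay/dt = (I2 - I_delay)/tau.
#'
#' @param chain numeric length-3 state (I1, I2, I_delay)
#' @param i_art arterial insulin (uU/ml)
#' @param tau delay time constant (min), must be > 0
#' @return numeric length-3 derivative
#' @export
delay_chain_rhs <- function(chain, i_art, tau) {
  stopifnot(length(chain) == 3L)
  if (tau <= 0) {
    stop("tau must be > 0; a zero delay requires bypassing the chain, ",
         "never dividing by tau = 0")
  }
  c((i_art - chain[1]) / tau,
    (chain[1] - chain[2]) / tau,
    (chain[2] - chain[3]) / tau)
}

#' Closed-form step response of the delay chain
#'
#' For a chain at rest subjected to a constant input `i0` from t = 0, the
#' final compartment follows the Erlang(3) cumulative response
#' `i0 * (1 - exp(-t/tau) * (1 + t/tau + t^2/(2 tau^2)))`.  Used as the
#' analytic oracle for the numerical integrator.
#'
#' @param t time (min)
#' @param i0 step amplitude (uU/ml)
#' @param tau delay constant (min)
#' @return value of the delayed signal at `t`
#' @export
delay_chain_step_response <- function(t, i0, tau) {
  x <- t / tau
  i0 * (1 - exp(-x) * (1 + x + x^2 / 2))
}

#' LPL lipolysis flux of circulating triglyceride
#'
#' Linear kinetics in the arterial TG concentration, stimulated by the
#' delayed insulin signal: `k_ad * TG_art * I_LPL`.  Positive values are
#' uptake (TG removed from plasma) under the measured-flux convention.
#'
#' @param k_ad rate constant
#' @param tg_art arterial TG (mmol/l)
#' @param i_lpl delayed insulin signal (uU/ml)
#' @return flux (umol/100 ml tissue/min)
#' @export
tg_flux <- function(k_ad, tg_art, i_lpl) {
  stopifnot(k_ad >= 0, all(tg_art >= 0), all(i_lpl >= 0))
  k_ad * tg_art * i_lpl
}

#' Fractional spill-over of LPL-derived NEFA
#'
#' `f = (1/100) * d_spill * I_B / I_art`, clamped to \[0, 1\].  The spill
#' fraction is inversely proportional to arterial insulin, equalling
#' `d_spill`/100 at basal insulin and falling as insulin rises after the
#' meal.
#'
#' @param d_spill spill constant (percent-scale)
#' @param i_basal basal insulin (uU/ml)
#' @param i_art arterial insulin (uU/ml), must be > 0
#' @return spill fraction in \[0, 1\]
#' @export
spill_fraction <- function(d_spill, i_basal, i_art) {
  stopifnot(d_spill >= 0, i_basal >= 0)
  if (any(i_art <= 0)) {
    stop("arterial insulin must be positive to evaluate the spill fraction")
  }
  pmin(1, pmax(0, 0.01 * d_spill * i_basal / i_art))
}

#' Adipose glucose uptake flux
#'
#' Insulin-independent (GLUT1) plus insulin-dependent (GLUT4) transport:
#' `glut1 * G_art + glut4 * G_art * I_AT`, reported uptake-positive.
#'
#' @param glut1,glut4 transport rate constants
#' @param g_art arterial glucose (mmol/l)
#' @param i_at delayed adipose insulin signal (uU/ml)
#' @return flux (umol/100 ml tissue/min), uptake positive
#' @export
glucose_flux <- function(glut1, glut4, g_art, i_at) {
  stopifnot(glut1 >= 0, glut4 >= 0, all(g_art >= 0), all(i_at >= 0))
  glut1 * g_art + glut4 * g_art * i_at
}

#' Lipolysis rate of stored triglyceride (ATL)
#'
#' Basal plus saturable insulin-inhibited rate:
#' `b_atl + atl_max / (1 + I_AT / k_atl)`; strictly decreasing in the
#' delayed adipose insulin signal.
#'
#' @param b_atl basal rate (umol/100 ml/min)
#' @param atl_max maximal insulin-suppressible rate (umol/100 ml/min)
#' @param k_atl insulin half-inhibition constant (uU/ml)
#' @param i_at delayed adipose insulin signal (uU/ml)
#' @return lipolysis rate (umol TG-equivalent/100 ml/min)
#' @export
atl_rate <- function(b_atl, atl_max, k_atl, i_at) {
  stopifnot(b_atl >= 0, atl_max >= 0, all(i_at >= 0))
  if (atl_max > 0 && k_atl <= 0) {
    stop("k_atl must be positive when atl_max > 0")
  }
  if (atl_max == 0) return(rep(b_atl, length(i_at)))
  b_atl + atl_max / (1 + i_at / k_atl)
}

#' Glycerol flux terms
#'
#' LPL hydrolysis releases one glycerol per TG; plasma and adipose glycerol
#' exchange along the concentration gradient at rate `p_gly`, with the
#' local plasma concentration elevated by the LPL release.  Returns the
#' measured-convention net glycerol flux (uptake positive, so fasting
#' release is negative) and the adipose glycerol derivative.
#'
#' @param params validated parameter vector
#' @param gly_at adipose glycerol (mmol/l)
#' @param i_lpl,i_at delayed insulin signals (uU/ml)
#' @param tg_art,gly_art arterial TG and glycerol (mmol/l)
#' @return list with `flux` (net glycerol flux), `dgly_at` (d\[GLY_AT\]/dt),
#'   `lpl_release` and `diffusion` (adipose-to-plasma positive)
#' @export
glycerol_terms <- function(params, gly_at, i_lpl, i_at, tg_art, gly_art) {
  p <- validate_parameters(params)
  lpl <- tg_flux(p[["k_ad"]], tg_art, i_lpl)
  diff_out <- p[["p_gly"]] * (gly_at - (gly_art + lpl))
  atl <- atl_rate(p[["b_atl"]], p[["atl_max"]], p[["k_atl"]], i_at)
  list(flux = -(lpl + diff_out),
       dgly_at = -diff_out + atl - p[["k_sink"]] * gly_at,
       lpl_release = lpl,
       diffusion = diff_out)
}

#' NEFA flux terms
#'
#' LPL hydrolysis releases three fatty acids per TG; a fraction `f` (the
#' spill fraction) enters the plasma directly and the remainder enters the
#' adipose space, conserving fatty acids exactly at the LPL node.  Plasma
#' and adipose NEFA exchange at rate `p_nefa` against the local plasma
#' concentration `NEFA_PL = NEFA_art + spill`.  The adipose pool also gains
#' 3 fatty acids per stored TG hydrolysed (ATL) and loses NEFA to
#' insulin-stimulated re-esterification `3 k_reester I_AT NEFA_AT G3P_AT`.
#'
#' @param params validated parameter vector
#' @param nefa_at adipose NEFA (mmol/l)
#' @param g3p_at adipose G-3-P
#' @param i_lpl,i_at delayed insulin signals (uU/ml)
#' @param i_art arterial insulin (uU/ml)
#' @param i_basal basal insulin (uU/ml)
#' @param tg_art,nefa_art arterial TG and NEFA (mmol/l)
#' @return list with `flux` (net NEFA flux, uptake positive), `dnefa_at`,
#'   `spill`, `adipose_influx`, `diffusion` (plasma-to-adipose positive),
#'   `reester` and `nefa_pl`
#' @export
nefa_terms <- function(params, nefa_at, g3p_at, i_lpl, i_at, i_art,
                       i_basal, tg_art, nefa_art) {
  p <- validate_parameters(params)
  lpl <- tg_flux(p[["k_ad"]], tg_art, i_lpl)
  f <- spill_fraction(p[["d_spill"]], i_basal, i_art)
  spill <- 3 * f * lpl
  influx <- 3 * (1 - f) * lpl
  nefa_pl <- nefa_art + spill
  diff_in <- p[["p_nefa"]] * (nefa_pl - nefa_at)
  atl <- atl_rate(p[["b_atl"]], p[["atl_max"]], p[["k_atl"]], i_at)
  reester <- 3 * p[["k_reester"]] * i_at * nefa_at * g3p_at
  list(flux = diff_in - spill,
       dnefa_at = influx + diff_in + 3 * atl - reester,
       spill = spill,
       adipose_influx = influx,
       diffusion = diff_in,
       reester = reester,
       nefa_pl = nefa_pl)
}

#' G-6-P / G-3-P production cascade: right-hand side
#'
#' A portion `frac_use` of adipose glucose uptake is phosphorylated and
#' routed towards glycerol-3-phosphate, yielding two triose units per
#' glucose.  Production is damped by a two-compartment delay with constant
#' `tau_g3p`; the adipose G-3-P pool is consumed by re-esterification.
#'
#' @param params validated parameter vector
#' @param g6p,g3p_pro,g3p_at current cascade states
#' @param uptake glucose uptake flux at time t
#' @param i_at delayed adipose insulin (uU/ml)
#' @param nefa_at adipose NEFA (mmol/l)
#' @return named numeric: `dg6p`, `dg3p_pro`, `dg3p_at`
#' @export
g3p_rhs <- function(params, g6p, g3p_pro, g3p_at, uptake, i_at, nefa_at) {
  p <- validate_parameters(params)
  c(dg6p = (2 * p[["frac_use"]] * uptake - g6p) / p[["tau_g3p"]],
    dg3p_pro = (g6p - g3p_pro) / p[["tau_g3p"]],
    dg3p_at = g3p_pro - p[["k_reester"]] * i_at * nefa_at * g3p_at)
}

#' Fasting fixed-point initial state
#'
#' The simulation starts at t = -30 min with the system at the fasting
#' steady state: delay chains at basal insulin, and the adipose glycerol,
#' NEFA and G-3-P pools at the algebraic fixed point of the right-hand
#' side with forcings frozen at their fasting means.
#'
#' @param params parameter vector (validated internally)
#' @param forcing a [build_forcing()] object
#' @return named state vector of length 11
#' @export
initial_state <- function(params, forcing) {
  p <- validate_parameters(params)
  fast <- forcing$fasting
  i_b <- forcing$I_B
  lpl <- tg_flux(p[["k_ad"]], fast[["tg"]], i_b)
  f <- spill_fraction(p[["d_spill"]], i_b, i_b)
  atl <- atl_rate(p[["b_atl"]], p[["atl_max"]], p[["k_atl"]], i_b)

  # glycerol: 0 = -p_gly (GLY - (GLY_art + lpl)) + atl - k_sink GLY
  denom <- p[["p_gly"]] + p[["k_sink"]]
  if (denom > 0) {
    gly_at <- (p[["p_gly"]] * (fast[["glycerol"]] + lpl) + atl) / denom
  } else if (atl == 0) {
    gly_at <- fast[["glycerol"]]
  } else {
    stop("no fasting fixed point for adipose glycerol: p_gly = 0 with ",
         "nonzero lipolysis")
  }

  # G-3-P cascade: G6P = G3P_pro = 2 frac_use * uptake at steady state
  uptake <- glucose_flux(p[["glut1"]], p[["glut4"]], fast[["glucose"]], i_b)
  g3p_pro <- 2 * p[["frac_use"]] * uptake

  # NEFA: steady re-esterification equals G-3-P production (3 FA per G3P),
  # the remaining imbalance is carried by diffusion
  nefa_pl <- fast[["nefa"]] + 3 * f * lpl
  if (p[["p_nefa"]] > 0) {
    nefa_at <- nefa_pl +
      (3 * (1 - f) * lpl + 3 * atl - 3 * g3p_pro) / p[["p_nefa"]]
  } else if (abs(3 * (1 - f) * lpl + 3 * atl - 3 * g3p_pro) < 1e-12) {
    nefa_at <- nefa_pl
  } else {
    stop("no fasting fixed point for adipose NEFA: p_nefa = 0 with ",
         "unbalanced lipolysis/re-esterification")
  }
  if (nefa_at < 0) {
    stop("fasting fixed point gives negative adipose NEFA (",
         signif(nefa_at, 4), "); G-3-P production exceeds fasting NEFA ",
         "supply -- reduce frac_use/glucose uptake or increase lipolysis")
  }

  if (g3p_pro == 0) {
    g3p_at <- 0
  } else if (p[["k_reester"]] * i_b * nefa_at > 0) {
    g3p_at <- g3p_pro / (p[["k_reester"]] * i_b * nefa_at)
  } else {
    stop("no fasting fixed point for adipose G-3-P: production ",
         signif(g3p_pro, 4), " with zero re-esterification capacity ",
         "(k_reester * I_B * NEFA_AT = 0)")
  }

  c(i1_lpl = i_b, i2_lpl = i_b, i_lpl = i_b,
    i1_at = i_b, i2_at = i_b, i_at = i_b,
    gly_at = unname(gly_at), nefa_at = unname(nefa_at),
    g6p = unname(g3p_pro), g3p_pro = unname(g3p_pro),
    g3p_at = unname(g3p_at))
}

flux_output_names <- function() {
  c("tg_flux", "spill_fraction", "glucose_flux", "glycerol_flux",
    "nefa_flux", "lpl_rate", "atl_rate", "spill_rate", "adipose_influx",
    "gly_diffusion", "nefa_diffusion", "reester_rate", "g3p_production",
    "nefa_pl")
}

#' Reference right-hand side in R
#'
#' Plain-R evaluation of the model derivatives and flux outputs, used to
#' cross-check the compiled solver and for unit tests of individual terms.
#'
#' @param t time (min)
#' @param state named state vector (see [initial_state()])
#' @param params parameter vector
#' @param forcing a [build_forcing()] object
#' @return list(derivatives, outputs)
#' @export
adipose_rhs_r <- function(t, state, params, forcing) {
  p <- validate_parameters(params)
  i_art <- forcing$insulin(t)
  g_art <- forcing$glucose(t)
  tg_art <- forcing$tg(t)
  gly_art <- forcing$glycerol(t)
  nefa_art <- forcing$nefa(t)

  d_lpl <- delay_chain_rhs(state[1:3], i_art, p[["tau_lpl"]])
  d_at <- delay_chain_rhs(state[4:6], i_art, p[["tau_at"]])
  gly <- glycerol_terms(p, state[["gly_at"]], state[["i_lpl"]],
                        state[["i_at"]], tg_art, gly_art)
  nef <- nefa_terms(p, state[["nefa_at"]], state[["g3p_at"]],
                    state[["i_lpl"]], state[["i_at"]], i_art,
                    forcing$I_B, tg_art, nefa_art)
  uptake <- glucose_flux(p[["glut1"]], p[["glut4"]], g_art, state[["i_at"]])
  g3 <- g3p_rhs(p, state[["g6p"]], state[["g3p_pro"]], state[["g3p_at"]],
                uptake, state[["i_at"]], state[["nefa_at"]])

  derivs <- c(d_lpl, d_at, gly$dgly_at, nef$dnefa_at, g3)
  names(derivs) <- names(state)
  outputs <- c(tg_flux = unname(gly$lpl_release),
               spill_fraction = unname(spill_fraction(p[["d_spill"]],
                                                      forcing$I_B, i_art)),
               glucose_flux = unname(uptake),
               glycerol_flux = unname(gly$flux),
               nefa_flux = unname(nef$flux),
               lpl_rate = unname(gly$lpl_release),
               atl_rate = unname(atl_rate(p[["b_atl"]], p[["atl_max"]],
                                          p[["k_atl"]], state[["i_at"]])),
               spill_rate = unname(nef$spill),
               adipose_influx = unname(nef$adipose_influx),
               gly_diffusion = unname(gly$diffusion),
               nefa_diffusion = unname(nef$diffusion),
               reester_rate = unname(nef$reester),
               g3p_production = unname(state[["g3p_pro"]]),
               nefa_pl = unname(nef$nefa_pl))
  list(derivatives = derivs, outputs = outputs)
}

#' Simulate the adipose tissue model over a meal challenge
#'
#' Integrates the 11-state model from t = -30 min (fasting fixed point)
#' with the compiled right-hand side, driven by the piecewise-linear
#' arterial forcings.  Uses `deSolve::lsoda` (adaptive, stiff-capable)
#' with tight default tolerances.
#'
#' @param params parameter vector (validated and completed internally)
#' @param forcing a [build_forcing()] object
#' @param times output times (min); t = -30 is always used as the initial
#'   time and prepended if absent
#' @param rtol,atol solver tolerances
#' @param state0 optional initial state overriding the fasting fixed point
#' @return object of class `adipose_sim`: list with `trajectory` (data
#'   frame of time, states and flux outputs), `params`, `forcing`, `times`
#' @export
simulate_adipose <- function(params, forcing, times = seq(-30, 300, by = 1),
                             rtol = 1e-8, atol = 1e-10, state0 = NULL) {
  p <- validate_parameters(params)
  times <- sort(unique(times))
  solve_times <- if (times[1] > -30) c(-30, times) else times
  if (solve_times[1] < -30) {
    stop("simulation cannot start before t = -30 min")
  }
  y0 <- if (is.null(state0)) initial_state(p, forcing) else state0
  forcings <- unname(forcing$samples[c("insulin", "glucose", "tg",
                                       "glycerol", "nefa")])
  parms <- c(p[par_names()], i_basal = unname(forcing$I_B),
             k_sink = unname(p[["k_sink"]]))
  out <- deSolve::ode(y = y0, times = solve_times, func = "adipose_derivs",
                      parms = parms,
                      dllname = "adipoflux",
                      initfunc = "adipose_init", initforc = "adipose_forc",
                      forcings = forcings,
                      fcontrol = list(method = "linear", rule = 2),
                      nout = 14, outnames = flux_output_names(),
                      rtol = rtol, atol = atol, method = "lsoda")
  attr_diag <- attributes(out)$istate
  if (!is.null(attr_diag) && attr_diag[1] < 0) {
    stop("integration failed at t = ", max(out[, "time"], na.rm = TRUE))
  }
  traj <- as.data.frame(out)
  traj <- traj[traj$time %in% times, , drop = FALSE]
  rownames(traj) <- NULL
  structure(list(trajectory = traj, params = p, forcing = forcing,
                 times = times),
            class = "adipose_sim")
}

#' Extract model flux series from a simulation
#'
#' @param sim an `adipose_sim` object
#' @param series which series to return (default: the five fitted series)
#' @return data frame with `time` and one column per requested series
#' @export
model_fluxes <- function(sim, series = c("tg", "spill_fraction", "glucose",
                                         "glycerol", "nefa")) {
  cols <- c(tg = "tg_flux", spill_fraction = "spill_fraction",
            glucose = "glucose_flux", glycerol = "glycerol_flux",
            nefa = "nefa_flux")
  series <- match.arg(series, names(cols), several.ok = TRUE)
  out <- sim$trajectory[, c("time", unname(cols[series])), drop = FALSE]
  names(out) <- c("time", series)
  out
}

#' @export
print.adipose_sim <- function(x, ...) {
  cat(sprintf("Adipose tissue model simulation: %d time points on [%g, %g] min\n",
              nrow(x$trajectory), min(x$times), max(x$times)))
  cat("States: ", paste(names(x$trajectory)[2:12], collapse = ", "), "\n")
  invisible(x)
}
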