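# Synthetic arteriovenous meal-challenge cohorts with the statistical
# structure the estimation workflow assumes: smooth arterial excursions
# sampled on the canonical 7-point grid, model-generated fluxes with
# additive measurement noise, venous concentrations back-computed for
# exact arteriovenous consistency, and a meal tracer for the spill-over
# series.

#' Default arterial curve shape parameters
#'
#' Cohort-mean fasting levels, postprandial excursion amplitudes, peak
#' times and log-widths for the five arterial analytes.  Insulin and
#' glucose peak early (60 min), triglyceride peaks late (210 min), NEFA
#' dips under insulin suppression and rebounds late, glycerol rises
#' modestly.  Values are synthetic but physiological for an
#' overweight/obese cohort consuming a high-fat mixed meal.
#'
#' @return nested list of shape parameters per analyte
#' @export
default_arterial_shapes <- function() {
  list(
    insulin  = list(fasting = 10,   amp = 50,   peak = 60,  width = 0.55),
    glucose  = list(fasting = 5.0,  amp = 2.5,  peak = 60,  width = 0.50),
    tg       = list(fasting = 1.2,  amp = 0.9,  peak = 210, width = 0.45),
    glycerol = list(fasting = 0.08, amp = 0.05, peak = 120, width = 0.60),
    nefa     = list(fasting = 0.50, dip = 0.35, dip_peak = 90,
                    dip_width = 0.50, rebound = 0.25, rebound_peak = 280,
                    rebound_width = 0.35))
}

# log-normal-shaped postprandial bump: 0 for t <= 0, peaks at t = peak
meal_bump <- function(t, peak, width) {
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-(log(t[pos] / peak))^2 / (2 * width^2))
  out
}

arterial_curve <- function(analyte, shape) {
  if (analyte == "nefa") {
    function(t) {
      pmax(0.02, shape$fasting -
             shape$dip * meal_bump(t, shape$dip_peak, shape$dip_width) +
             shape$rebound * meal_bump(t, shape$rebound_peak,
                                       shape$rebound_width))
    }
  } else {
    function(t) shape$fasting + shape$amp * meal_bump(t, shape$peak,
                                                      shape$width)
  }
}

# multiplicative lognormal factor with unit mean and coefficient of
# variation cv
ln_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

#' Specification of a synthetic meal-challenge cohort
#'
#' @param n_subjects number of subjects (default 16, the study design the
#'   generator emulates)
#' @param times sampling grid (default the canonical 7 points)
#' @param params true model parameters (default [default_parameters()])
#' @param shapes arterial shape parameters ([default_arterial_shapes()])
#' @param cv between-subject lognormal coefficient of variation applied to
#'   every shape parameter and to ATBF (default 0.15)
#' @param noise_frac additive Gaussian measurement noise SD per flux
#'   series, as a fraction of that series' dynamic range (default 0.15);
#'   set 0 for noiseless cohorts
#' @param atbf adipose tissue blood flow level (ml/100 ml tissue/min)
#' @param tracer_enrichment peak fraction of arterial TG carrying the meal
#'   tracer label
#' @param tracer_noise_frac tracer flux noise fraction (inflated 3-fold
#'   after 180 min, emulating label recycling)
#' @param seed mandatory integer seed
#' @return a `cohort_spec` list
#' @export
cohort_spec <- function(n_subjects = 16, times = canonical_times(),
                        params = default_parameters(),
                        shapes = default_arterial_shapes(), cv = 0.15,
                        noise_frac = 0.15, atbf = 3.0,
                        tracer_enrichment = 0.05,
                        tracer_noise_frac = 0.05, seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_subjects >= 1, cv >= 0, noise_frac >= 0, atbf > 0)
  structure(list(n_subjects = as.integer(n_subjects), times = sort(times),
                 params = validate_parameters(params), shapes = shapes,
                 cv = cv, noise_frac = noise_frac, atbf = atbf,
                 tracer_enrichment = tracer_enrichment,
                 tracer_noise_frac = tracer_noise_frac,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

perturb_shapes <- function(shapes, cv) {
  lapply(shapes, function(sh) {
    lapply(sh, function(v) v * ln_factor(1, cv))
  })
}

#' Generate per-subject arterial concentration profiles
#'
#' Draws per-subject shape parameters lognormally around the cohort means
#' and samples the resulting smooth curves at the specified grid.
#' Reproducible from the spec seed.
#'
#' @param spec a [cohort_spec()]
#' @return list with `study` (arterial study-table rows, plus `atbf`),
#'   `subject_shapes`, and `subject_atbf`
#' @export
generate_arterial_profiles <- function(spec) {
  set.seed(spec$seed)
  analytes <- c("insulin", "glucose", "tg", "glycerol", "nefa")
  rows <- list()
  subject_shapes <- list()
  subject_atbf <- numeric(spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    sh <- perturb_shapes(spec$shapes, spec$cv)
    subject_shapes[[s]] <- sh
    subject_atbf[s] <- spec$atbf * ln_factor(1, spec$cv)
    for (a in analytes) {
      vals <- arterial_curve(a, sh[[a]])(spec$times)
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = sprintf("S%02d", s), time = spec$times,
                   site = "arterial", metabolite = a, value = vals,
                   atbf = subject_atbf[s])
    }
  }
  list(study = do.call(rbind, rows), subject_shapes = subject_shapes,
       subject_atbf = subject_atbf)
}

#' Labelled tracer fluxes for one subject
#'
#' The meal tracer labels circulating TG with a log-normal appearance
#' envelope; labelled TG hydrolysis is the model LPL rate times the
#' enrichment, and labelled NEFA efflux is the spill fraction times the
#' labelled fatty-acid hydrolysis, plus noise whose SD is inflated
#' 3-fold after 180 min (label recycling makes late spill-over estimates
#' unreliable).
#'
#' @param spec a [cohort_spec()]
#' @param lpl_rate model LPL hydrolysis rate at `times`
#' @param spill model spill fraction at `times`
#' @param times sampling times
#' @return data frame with `time`, `enrichment`, `hydrolysis_tg` (TG
#'   units), `nefa_efflux` (fatty-acid units, noisy), `sd_inflated`
#' @export
generate_tracer_series <- function(spec, lpl_rate, spill, times) {
  e <- spec$tracer_enrichment * meal_bump(times, 120, 0.5)
  hyd_tg <- lpl_rate * e
  efflux0 <- 3 * spill * hyd_tg
  base_sd <- spec$tracer_noise_frac * max(efflux0, 1e-12)
  sd_vec <- base_sd * ifelse(times > 180, 3, 1)
  efflux <- efflux0 + stats::rnorm(length(times), 0, sd_vec)
  data.frame(time = times, enrichment = e, hydrolysis_tg = hyd_tg,
             nefa_efflux = efflux, sd_inflated = times > 180)
}

#' Generate a complete synthetic arteriovenous cohort
#'
#' For each subject the refined model is simulated at the true parameters
#' with that subject's arterial forcing; the five flux series are
#' evaluated at the sampling grid, Gaussian measurement noise is added,
#' and venous concentrations are back-computed as
#' `venous = arterial - flux / atbf` so that the arteriovenous flux
#' calculation reproduces the stored (noisy) flux exactly.  Tracer TG and
#' NEFA concentration rows encode the labelled fluxes for the spill-over
#' series.  When `n_subjects >= 2` the flux dataset is obtained by
#' [build_flux_dataset()] on the assembled study table; with a single
#' subject the dataset carries the exact per-point fluxes with `sd = NA`.
#'
#' @param spec a [cohort_spec()]
#' @return list with `study` (a validated study table), `dataset` (a
#'   [flux_dataset()]), `truth` (the generating parameters), `forcing`
#'   (cohort-mean forcing), and `spec`
#' @export
generate_cohort_fluxes <- function(spec) {
  prof <- generate_arterial_profiles(spec)
  art <- prof$study
  times <- spec$times
  analytes <- c("tg", "glucose", "glycerol", "nefa")
  flux_cols <- c(tg = "tg", glucose = "glucose", glycerol = "glycerol",
                 nefa = "nefa")
  rows <- list(art)
  for (s in unique(art$subject_id)) {
    sub <- art[art$subject_id == s, , drop = FALSE]
    atbf <- sub$atbf[1]
    forcing_s <- build_forcing(sub)
    sim <- simulate_adipose(spec$params, forcing_s, times = times)
    mf <- model_fluxes(sim)
    noisy <- list()
    for (a in analytes) {
      f0 <- mf[[a]]
      rng <- diff(range(f0))
      sd_a <- spec$noise_frac * max(rng, 1e-12)
      f <- f0 + stats::rnorm(length(times), 0, sd_a)
      arterial <- sub$value[sub$metabolite == a][match(times,
                    sub$time[sub$metabolite == a])]
      f <- pmin(f, arterial * atbf)  # venous concentrations stay >= 0
      noisy[[a]] <- f
      rows[[length(rows) + 1L]] <-
        data.frame(subject_id = s, time = times, site = "venous",
                   metabolite = a, value = arterial - f / atbf,
                   atbf = atbf)
    }
    # tracer rows encoding labelled hydrolysis and labelled NEFA efflux
    tr <- generate_tracer_series(spec, mf$tg, mf$spill_fraction, times)
    art_tg_tr <- 2 * tr$hydrolysis_tg / atbf + 0.02 * tr$enrichment
    ven_tg_tr <- art_tg_tr - tr$hydrolysis_tg / atbf
    art_nf_tr <- 0.05 * tr$enrichment
    efflux <- pmax(tr$nefa_efflux, -art_nf_tr * atbf)
    ven_nf_tr <- art_nf_tr + efflux / atbf
    rows[[length(rows) + 1L]] <-
      data.frame(subject_id = s,
                 time = rep(times, 4),
                 site = rep(c("arterial", "venous", "arterial", "venous"),
                            each = length(times)),
                 metabolite = rep(c("tg_tracer", "tg_tracer",
                                    "nefa_tracer", "nefa_tracer"),
                                  each = length(times)),
                 value = c(art_tg_tr, ven_tg_tr, art_nf_tr, ven_nf_tr),
                 atbf = atbf)
  }
  study <- validate_study_table(do.call(rbind, rows))
  if (spec$n_subjects >= 2L) {
    dataset <- suppressWarnings(build_flux_dataset(study))
  } else {
    # single subject: exact per-point fluxes, no dispersion
    sub <- study[study$subject_id == study$subject_id[1], , drop = FALSE]
    ds <- list()
    for (a in analytes) {
      arterial <- sub$value[sub$site == "arterial" & sub$metabolite == a]
      venous <- sub$value[sub$site == "venous" & sub$metabolite == a]
      ds[[a]] <- data.frame(series = a, time = times,
                            mean = av_flux(arterial, venous, sub$atbf[1]),
                            sd = NA_real_)
    }
    dataset <- flux_dataset(do.call(rbind, ds), n_subjects = 1L)
  }
  list(study = study, dataset = dataset, truth = spec$params,
       forcing = build_forcing(study), spec = spec)
}
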