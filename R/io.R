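#' Canonical meal-challenge sampling grid
#'
#' Fasting samples at -30 and 0 min, postprandial samples at 60, 120,
#' 180, 240 and 300 min after meal ingestion.
#'
#' @return numeric vector of the 7 sampling times (min)
#' @export
canonical_times <- function() c(-30, 0, 60, 120, 180, 240, 300)

insulin_pmol_per_uu <- function() 6.0

study_metabolites <- function() {
  c("insulin", "glucose", "tg", "glycerol", "nefa",
    "tg_tracer", "nefa_tracer")
}

#' Read and validate an arteriovenous study table
#'
#' The single accepted input dialect is a UTF-8 CSV with header columns
#' `subject_id,time,site,metabolite,value,atbf` and an optional `unit`
#' column.  `site` is `arterial` or `venous`; `metabolite` is one of
#' insulin, glucose, tg, glycerol, nefa, tg_tracer, nefa_tracer.  Times
#' must be a subset of the canonical grid (-30, 0, 60, 120, 180, 240, 300
#' min).  Values are stored in the internal convention (insulin uU/ml, all
#' metabolites mmol/l, ATBF ml/100 ml tissue/min); insulin rows tagged
#' `unit = "pmol/l"` are converted with 1 uU/ml = 6.0 pmol/l.
#'
#' @param path CSV file path
#' @return validated study table (data frame of class `study_table`)
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_study_table(df)
}

#' @rdname read_study_table
#' @param df a data frame with the study-table columns
#' @export
validate_study_table <- function(df) {
  required <- c("subject_id", "time", "site", "metabolite", "value", "atbf")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if ("unit" %in% names(df)) {
    conv <- df$metabolite == "insulin" & !is.na(df$unit) &
      df$unit == "pmol/l"
    df$value[conv] <- df$value[conv] / insulin_pmol_per_uu()
    df$unit <- NULL
  }
  bad_site <- !df$site %in% c("arterial", "venous")
  if (any(bad_site)) {
    stop("invalid site in row(s) ", paste(which(bad_site), collapse = ", "))
  }
  bad_met <- !df$metabolite %in% study_metabolites()
  if (any(bad_met)) {
    stop("invalid metabolite in row(s) ",
         paste(which(bad_met), collapse = ", "))
  }
  bad_time <- !df$time %in% canonical_times()
  if (any(bad_time)) {
    stop("time outside the canonical grid in row(s) ",
         paste(which(bad_time), collapse = ", "))
  }
  bad_val <- !is.finite(df$value) | df$value < 0
  if (any(bad_val)) {
    stop("negative or non-finite value in row(s) ",
         paste(which(bad_val), collapse = ", "))
  }
  bad_atbf <- !is.finite(df$atbf) | df$atbf < 0
  if (any(bad_atbf)) {
    stop("negative or non-finite atbf in row(s) ",
         paste(which(bad_atbf), collapse = ", "))
  }
  key <- paste(df$subject_id, df$time, df$site, df$metabolite)
  if (anyDuplicated(key)) {
    stop("duplicate (subject, time, site, metabolite) in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  df <- df[order(df$subject_id, df$time, df$site, df$metabolite), ]
  rownames(df) <- NULL
  class(df) <- c("study_table", "data.frame")
  df
}

#' Write a study table to CSV
#'
#' @param study a study table
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_study_table <- function(study, path) {
  utils::write.csv(as.data.frame(study), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' Bounds, optimiser and solver settings used by the fitting workflow.
#' All lower bounds are zero except the three delay constants, which are
#' kept at a 1-minute floor for solver stability (delays below one minute
#' are indistinguishable on the hour-scale sampling grid).  Upper bounds
#' are ten times the default parameter values, with fraction-valued
#' parameters capped at 1.
#'
#' @param seed integer seed recorded in every output
#' @return a `run_config` list
#' @export
default_run_config <- function(seed = 1L) {
  p <- default_parameters()[par_names()]
  lower <- setNames(rep(0, length(p)), names(p))
  lower[c("tau_lpl", "tau_at", "tau_g3p")] <- 1
  upper <- 10 * p
  upper["frac_use"] <- 1
  cfg <- list(
    seed = as.integer(seed),
    lower = lower,
    upper = upper,
    crs = list(n_init = 250, maxeval = 8000, tol = 1e-8),
    local = list(maxiter = 200, ftol = 1e-10, ptol = 1e-10, n_start = 6,
                 n_hop = 15),
    solver = list(rtol = 1e-8, atol = 1e-10),
    sign_convention = "uptake_positive",
    cost_weights = c(tg = 1, spill_fraction = 1, glucose = 1,
                     glycerol = 1, nefa = 1))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

#' @rdname default_run_config
#' @param cfg a configuration list
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (is.null(cfg$seed)) stop("run config must carry a seed")
  if (any(cfg$lower < 0)) stop("all lower bounds must be >= 0")
  if (cfg$upper[["frac_use"]] > 1) {
    stop("fraction-valued parameters must be bounded above by 1")
  }
  if (any(cfg$upper <= cfg$lower)) stop("upper bounds must exceed lower")
  cfg
}

#' Stable hash of a configuration object
#'
#' Polynomial rolling hash (base 131, modulus 2^31 - 1) over the deparsed
#' object; used to stamp outputs with the exact configuration that
#' produced them.
#'
#' @param x any R object
#' @return hex string
#' @export
config_hash <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "\n")
  bytes <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (b in bytes) {
    h <- (h * 131 + b) %% m
  }
  sprintf("%08x", as.integer(h))
}

#' Write a fit result to disk
#'
#' Writes a parameter table (CSV, estimate plus a parenthesised
#' `"(lo, hi)"` 95% confidence-interval column) and a JSON sidecar with
#' the seed, bounds, solver settings, cost and configuration hash.
#'
#' @param fit a `fit_result` from [fit_global()] or [fit_local()]
#' @param path output stem; writes `<path>_parameters.csv` and
#'   `<path>_run.json`
#' @return named character vector of the written paths, invisibly
#' @export
write_results <- function(fit, path) {
  est <- fit$par
  ci <- fit$ci95
  tab <- data.frame(parameter = names(est),
                    estimate = unname(est),
                    ci95 = sprintf("(%.6g, %.6g)", ci[, "lo"], ci[, "hi"]))
  csv <- paste0(path, "_parameters.csv")
  jsonf <- paste0(path, "_run.json")
  utils::write.csv(tab, csv, row.names = FALSE, quote = TRUE)
  meta <- list(seed = fit$seed,
               cost = fit$cost,
               cost_breakdown = as.list(fit$cost_breakdown),
               lower = as.list(fit$lower),
               upper = as.list(fit$upper),
               solver = fit$solver,
               converged = fit$converged,
               n_local_restarts = fit$n_local_restarts,
               config_hash = fit$config_hash,
               ci95 = list(lo = as.list(setNames(ci[, "lo"], names(est))),
                           hi = as.list(setNames(ci[, "hi"], names(est)))))
  jsonlite::write_json(meta, jsonf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(parameters = csv, run = jsonf))
}

#' Read back a written fit result
#'
#' @param path the stem passed to [write_results()]
#' @return list with `par`, `ci95`, `cost`, `seed`, `lower`, `upper`,
#'   `solver`, `converged`, `n_local_restarts`, `config_hash`
#' @export
read_results <- function(path) {
  tab <- utils::read.csv(paste0(path, "_parameters.csv"),
                         stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, "_run.json"),
                              simplifyVector = TRUE)
  ci <- cbind(lo = unlist(meta$ci95$lo), hi = unlist(meta$ci95$hi))
  rownames(ci) <- tab$parameter
  list(par = setNames(tab$estimate, tab$parameter),
       ci95 = ci,
       cost = meta$cost,
       cost_breakdown = unlist(meta$cost_breakdown),
       seed = meta$seed,
       lower = unlist(meta$lower),
       upper = unlist(meta$upper),
       solver = meta$solver,
       converged = meta$converged,
       n_local_restarts = meta$n_local_restarts,
       config_hash = meta$config_hash)
}
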