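#' Continuous arterial forcing functions
#'
#' Turns sampled arterial concentrations into the continuous forcing
#' functions that drive the adipose tissue model.  Each analyte is
#' interpolated piecewise-linearly through its samples and extrapolated as a
#' constant outside the sampled range, so that the integrator can probe
#' slightly outside \[-30, 300\] min.  The basal insulin concentration
#' `I_B` is the mean of the fasting samples (t <= 0).
#'
#' @param study a study table (see [read_study_table()]) or any data frame
#'   with columns `time`, `site`, `metabolite`, `value`; only rows with
#'   `site == "arterial"` are used.  Values from several subjects at the
#'   same time are averaged (the cohort-mean forcing used for fitting).
#' @return an object of class `forcing_set`: a list with components
#'   `insulin`, `glucose`, `tg`, `glycerol`, `nefa` (each a function of
#'   time in minutes), `I_B` (basal insulin, uU/ml), `fasting` (named
#'   vector of fasting means per analyte) and `samples` (the per-analyte
#'   sample matrices used, for handing to the compiled solver).
#' @examples
#' tab <- expand.grid(time = c(-30, 0, 60, 120, 180, 240, 300),
#'                    metabolite = c("insulin", "glucose", "tg",
#'                                   "glycerol", "nefa"))
#' tab$site <- "arterial"
#' tab$value <- 1 + (tab$time > 0)
#' f <- build_forcing(tab)
#' f$insulin(30)   # midway between 1 and 2
#' @export
build_forcing <- function(study) {
  analytes <- c("insulin", "glucose", "tg", "glycerol", "nefa")
  art <- study[study$site == "arterial" & study$metabolite %in% analytes, ,
               drop = FALSE]
  if (nrow(art) == 0L) {
    stop("no arterial samples found")
  }
  samples <- list()
  funs <- list()
  fasting <- numeric(0)
  for (a in analytes) {
    sub <- art[art$metabolite == a, , drop = FALSE]
    if (nrow(sub) == 0L) {
      stop("no arterial samples for analyte '", a, "'")
    }
    agg <- aggregate_mean(sub$time, sub$value)
    if (nrow(agg) < 4L) {
      stop("insufficient data for analyte '", a,
           "': need at least 4 distinct times, got ", nrow(agg))
    }
    n_fast <- sum(agg$time <= 0)
    n_post <- sum(agg$time > 0)
    if (n_fast < 2L || n_post < 3L) {
      stop("analyte '", a, "' needs >= 2 fasting and >= 3 postprandial ",
           "times (got ", n_fast, " and ", n_post, ")")
    }
    if (any(agg$value < 0)) {
      stop("negative arterial concentration for analyte '", a, "'")
    }
    samples[[a]] <- cbind(time = agg$time, value = agg$value)
    funs[[a]] <- stats::approxfun(agg$time, agg$value, rule = 2)
    fasting[a] <- mean(agg$value[agg$time <= 0])
  }
  out <- c(funs, list(I_B = fasting[["insulin"]], fasting = fasting,
                      samples = samples))
  if (out$I_B <= 0) {
    stop("basal insulin must be positive, got ", out$I_B)
  }
  class(out) <- "forcing_set"
  out
}

#' Basal (fasting) value of a sampled series
#'
#' Arithmetic mean of samples taken at t <= 0 min; a single fasting sample
#' is returned as-is.
#'
#' @param time sampling times (minutes)
#' @param value sampled values
#' @return the fasting mean
#' @examples
#' basal_value(c(-30, 0, 60), c(5.0, 5.2, 40)) # 5.1
#' @export
basal_value <- function(time, value) {
  stopifnot(length(time) == length(value))
  fast <- value[time <= 0]
  if (length(fast) == 0L) {
    stop("no fasting sample (t <= 0) available")
  }
  mean(fast)
}

#' @export
print.forcing_set <- function(x, ...) {
  cat("Arterial forcing set (piecewise linear, constant extrapolation)\n")
  cat(sprintf("  basal insulin I_B = %.3g uU/ml\n", x$I_B))
  cat("  fasting means:",
      paste(sprintf("%s=%.3g", names(x$fasting), x$fasting),
            collapse = ", "), "\n")
  invisible(x)
}

# mean of values per distinct time, times sorted ascending
aggregate_mean <- function(time, value) {
  m <- tapply(value, time, mean)
  t <- as.numeric(names(m))
  o <- order(t)
  data.frame(time = t[o], value = as.numeric(m)[o])
}
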