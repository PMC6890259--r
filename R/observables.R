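#' Arteriovenous metabolite flux
#'
#' Flux across the tissue bed: (arterial - venous) concentration difference
#' multiplied by the adipose tissue blood flow.  Positive values indicate
#' net uptake by the tissue, negative values net release.
#'
#' @param arterial,venous concentrations (mmol/l)
#' @param atbf adipose tissue blood flow (ml/100 ml tissue/min), >= 0
#' @return flux (umol/100 ml tissue/min)
#' @examples
#' av_flux(1.0, 0.8, 2.0)  # +0.4, uptake
#' av_flux(0.5, 0.7, 3.0)  # -0.6, release
#' @export
av_flux <- function(arterial, venous, atbf) {
  if (any(atbf < 0)) stop("atbf must be non-negative")
  (arterial - venous) * atbf
}

#' Tracer-based fractional spill-over
#'
#' Spill-over of LPL-derived NEFA is one minus the fractional extraction:
#' the labelled NEFA efflux divided by the labelled TG fatty-acid
#' hydrolysis rate (both per fatty-acid equivalent), clamped to \[0, 1\].
#'
#' @param labelled_hydrolysis labelled TG-fatty-acid hydrolysis flux (> 0;
#'   non-positive values yield `NA` with a warning so the point can be
#'   excluded from fitting)
#' @param labelled_nefa_release labelled NEFA efflux into plasma
#' @return spill fraction in \[0, 1\], or `NA` where undefined
#' @export
tracer_spill_fraction <- function(labelled_hydrolysis,
                                  labelled_nefa_release) {
  out <- rep(NA_real_, length(labelled_hydrolysis))
  ok <- is.finite(labelled_hydrolysis) & labelled_hydrolysis > 0
  if (any(!ok)) {
    warning("spill-over undefined at ", sum(!ok),
            " point(s) with non-positive labelled hydrolysis; set to NA")
  }
  out[ok] <- pmin(1, pmax(0, labelled_nefa_release[ok] /
                               labelled_hydrolysis[ok]))
  out
}

#' HOMA-IR whole-body insulin resistance index
#'
#' Fasting glucose (mmol/l) times fasting insulin (uU/ml) divided by 22.4.
#' Published cut-offs for flagging insulin resistance range from 1.85 to
#' 2.01 depending on the population; the midpoint band is exposed via
#' `homa_ir_cutoffs()`.
#'
#' @param fasting_glucose mmol/l
#' @param fasting_insulin uU/ml
#' @return the index
#' @examples
#' homa_ir(5.0, 10.0)  # 2.232
#' @export
homa_ir <- function(fasting_glucose, fasting_insulin) {
  stopifnot(all(fasting_glucose >= 0), all(fasting_insulin >= 0))
  fasting_glucose * fasting_insulin / 22.4
}

#' @rdname homa_ir
#' @export
homa_ir_cutoffs <- function() c(low = 1.85, high = 2.01)

#' ADIPO-IR adipose tissue insulin resistance index
#'
#' Fasting NEFA (mmol/l) times fasting insulin in pmol/l.  If insulin is
#' supplied in the package-internal uU/ml convention set
#' `insulin_unit = "uU/ml"` and it is converted with 1 uU/ml = 6.0 pmol/l.
#'
#' @param fasting_nefa mmol/l
#' @param fasting_insulin insulin concentration
#' @param insulin_unit `"pmol/l"` (default) or `"uU/ml"`
#' @return the index
#' @examples
#' adipo_ir(0.5, 60)                       # 30
#' adipo_ir(0.5, 10, insulin_unit = "uU/ml")  # 30
#' @export
adipo_ir <- function(fasting_nefa, fasting_insulin,
                     insulin_unit = c("pmol/l", "uU/ml")) {
  insulin_unit <- match.arg(insulin_unit)
  stopifnot(all(fasting_nefa >= 0), all(fasting_insulin >= 0))
  if (insulin_unit == "uU/ml") {
    fasting_insulin <- fasting_insulin * insulin_pmol_per_uu()
  }
  fasting_nefa * fasting_insulin
}

#' Trapezoidal area under the curve
#'
#' Total (not incremental) AUC over the sampled window by the trapezoid
#' rule.  Times must be strictly increasing.
#'
#' @param times minutes, strictly increasing, length >= 2
#' @param values curve values at `times`
#' @return area (value x min)
#' @examples
#' auc(c(0, 100, 200), c(0, 2, 0))  # 200
#' @export
auc <- function(times, values) {
  if (length(times) < 2L) stop("auc needs at least two points")
  if (length(times) != length(values)) stop("length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  sum(diff(times) * (head(values, -1) + values[-1]) / 2)
}

#' Build the flux dataset fitted by the model
#'
#' Computes per-subject arteriovenous fluxes for triglyceride, glucose,
#' glycerol and NEFA (and, when tracer rows are present, the tracer-derived
#' spill-over fraction), then aggregates across subjects into the
#' mean/standard-deviation dataset used as the weighted fitting target.
#' Points where the cross-subject standard deviation is zero are retained
#' with `sd = 0` and a warning; the cost function excludes them.
#'
#' @param study a study table (see [read_study_table()]) with arterial and
#'   venous rows and an `atbf` column
#' @return object of class `flux_dataset`: data frame with columns
#'   `series`, `time`, `mean`, `sd`, and attribute `n_subjects`
#' @export
build_flux_dataset <- function(study) {
  subjects <- unique(study$subject_id)
  if (length(subjects) < 2L) {
    stop("need at least two subjects to estimate a dispersion")
  }
  mets <- c("tg", "glucose", "glycerol", "nefa")
  has_tracer <- all(c("tg_tracer", "nefa_tracer") %in% study$metabolite)
  rows <- list()
  for (s in subjects) {
    sub <- study[study$subject_id == s, , drop = FALSE]
    for (tm in sort(unique(sub$time))) {
      at <- sub[sub$time == tm, , drop = FALSE]
      atbf <- at$atbf[1]
      for (m in mets) {
        a <- at$value[at$site == "arterial" & at$metabolite == m]
        v <- at$value[at$site == "venous" & at$metabolite == m]
        if (length(a) == 1L && length(v) == 1L) {
          rows[[length(rows) + 1L]] <-
            data.frame(subject_id = s, series = m, time = tm,
                       flux = av_flux(a, v, atbf))
        }
      }
      if (has_tracer) {
        a_tg <- at$value[at$site == "arterial" & at$metabolite == "tg_tracer"]
        v_tg <- at$value[at$site == "venous" & at$metabolite == "tg_tracer"]
        a_nf <- at$value[at$site == "arterial" & at$metabolite == "nefa_tracer"]
        v_nf <- at$value[at$site == "venous" & at$metabolite == "nefa_tracer"]
        if (length(a_tg) == 1L && length(v_tg) == 1L &&
            length(a_nf) == 1L && length(v_nf) == 1L) {
          hyd_fa <- 3 * av_flux(a_tg, v_tg, atbf)   # FA equivalents
          efflux <- -av_flux(a_nf, v_nf, atbf)      # release positive
          sp <- suppressWarnings(tracer_spill_fraction(hyd_fa, efflux))
          rows[[length(rows) + 1L]] <-
            data.frame(subject_id = s, series = "spill_fraction",
                       time = tm, flux = sp)
        }
      }
    }
  }
  long <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(long, list(long$series, long$time),
                                     drop = TRUE), function(d) {
    ok <- is.finite(d$flux)
    data.frame(series = d$series[1], time = d$time[1],
               mean = mean(d$flux[ok]), sd = stats::sd(d$flux[ok]),
               n = sum(ok))
  }))
  agg <- agg[order(agg$series, agg$time), c("series", "time", "mean", "sd")]
  rownames(agg) <- NULL
  if (any(agg$sd == 0, na.rm = TRUE)) {
    warning(sum(agg$sd == 0, na.rm = TRUE),
            " point(s) have zero cross-subject dispersion and will be ",
            "excluded from weighted fitting")
  }
  flux_dataset(agg, n_subjects = length(subjects))
}

#' Construct a flux dataset
#'
#' Low-level constructor for the weighted fitting target, e.g. to supply
#' unit weights for a noiseless recovery experiment.
#'
#' @param df data frame with columns `series`, `time`, `mean`, `sd`
#' @param n_subjects number of subjects behind the means
#' @return a `flux_dataset`
#' @export
flux_dataset <- function(df, n_subjects) {
  stopifnot(all(c("series", "time", "mean", "sd") %in% names(df)))
  structure(as.data.frame(df), n_subjects = n_subjects,
            class = c("flux_dataset", "data.frame"))
}

#' @export
print.flux_dataset <- function(x, ...) {
  cat(sprintf("Flux dataset: %d points, %d series, %s subjects\n",
              nrow(x), length(unique(x$series)),
              as.character(attr(x, "n_subjects"))))
  NextMethod()
}
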