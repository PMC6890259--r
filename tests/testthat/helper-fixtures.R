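# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a deterministic single-subject arterial table on the canonical grid
flat_arterial_table <- function(values = c(insulin = 10, glucose = 5,
                                           tg = 1.2, glycerol = 0.08,
                                           nefa = 0.5)) {
  tab <- expand.grid(time = canonical_times(),
                     metabolite = names(values),
                     stringsAsFactors = FALSE)
  tab$subject_id <- "S01"
  tab$site <- "arterial"
  tab$value <- values[tab$metabolite]
  tab$atbf <- 3
  tab
}

# cohort-style forcing with realistic postprandial excursions
test_forcing <- function() {
  cached("forcing", {
    prof <- generate_arterial_profiles(cohort_spec(n_subjects = 3,
                                                   seed = 11))
    build_forcing(prof$study)
  })
}

# noiseless homogeneous two-subject cohort at the default truth
zero_noise_cohort <- function() {
  cached("zero_noise", {
    generate_cohort_fluxes(cohort_spec(n_subjects = 2, cv = 0,
                                       noise_frac = 0,
                                       tracer_noise_frac = 0, seed = 7))
  })
}

# unit-weight dataset for noiseless recovery experiments
unit_sigma <- function(dataset) {
  dataset$sd <- 1
  dataset
}
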