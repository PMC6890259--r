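test_that("cohort generation is deterministic and respects its spec", {
  spec <- cohort_spec(n_subjects = 4, seed = 31)
  a1 <- generate_arterial_profiles(spec)
  a2 <- generate_arterial_profiles(spec)
  expect_identical(a1$study, a2$study)
  # all curves non-negative, fasting plateau identical at -30 and 0
  s <- a1$study
  expect_true(all(s$value >= 0))
  for (sub in unique(s$subject_id)) {
    for (m in unique(s$metabolite)) {
      v <- s$value[s$subject_id == sub & s$metabolite == m]
      t <- s$time[s$subject_id == sub & s$metabolite == m]
      expect_equal(v[t == -30], v[t == 0])
    }
  }
  # zero between-subject variability collapses the cohort
  spec0 <- cohort_spec(n_subjects = 3, cv = 0, seed = 31)
  a0 <- generate_arterial_profiles(spec0)
  v1 <- a0$study$value[a0$study$subject_id == "S01"]
  v2 <- a0$study$value[a0$study$subject_id == "S02"]
  expect_equal(v1, v2)
  expect_error(cohort_spec(n_subjects = 4), "seed")
})

test_that("venous back-computation reproduces the stored fluxes exactly", {
  coh <- generate_cohort_fluxes(cohort_spec(n_subjects = 5, seed = 13))
  st <- coh$study
  rebuilt <- suppressWarnings(build_flux_dataset(st))
  expect_equal(rebuilt$mean, coh$dataset$mean)
  expect_equal(rebuilt$sd, coh$dataset$sd)
  expect_equal(attr(rebuilt, "n_subjects"), 5L)
  # direct check for one subject/metabolite
  sub <- st[st$subject_id == "S03" & st$metabolite == "nefa", ]
  art <- sub$value[sub$site == "arterial"]
  ven <- sub$value[sub$site == "venous"]
  flux <- av_flux(art, ven, sub$atbf[1])
  expect_true(all(is.finite(flux)))
})

test_that("a noiseless single subject reproduces the model fluxes exactly", {
  spec <- cohort_spec(n_subjects = 1, cv = 0, noise_frac = 0,
                      tracer_noise_frac = 0, seed = 2)
  coh <- generate_cohort_fluxes(spec)
  f <- build_forcing(coh$study)
  sim <- simulate_adipose(coh$truth, f, times = spec$times)
  mf <- model_fluxes(sim)
  for (s in c("tg", "glucose", "glycerol", "nefa")) {
    got <- coh$dataset$mean[coh$dataset$series == s]
    expect_equal(got, mf[[s]], tolerance = 1e-10)
  }
  expect_true(all(is.na(coh$dataset$sd)))
})

test_that("noiseless tracer rows recover the model spill fraction", {
  spec <- cohort_spec(n_subjects = 2, cv = 0, noise_frac = 0,
                      tracer_noise_frac = 0, seed = 5)
  coh <- generate_cohort_fluxes(spec)
  ds <- coh$dataset
  f <- build_forcing(coh$study)
  sim <- simulate_adipose(coh$truth, f, times = spec$times)
  mf <- model_fluxes(sim)
  sp <- ds[ds$series == "spill_fraction", ]
  ok <- is.finite(sp$mean)
  expect_gt(sum(ok), 2)
  expect_equal(sp$mean[ok], mf$spill_fraction[match(sp$time[ok], mf$time)],
               tolerance = 1e-8)
  # the spill series rises late in the postprandial period as arterial
  # insulin falls back towards basal
  late <- sp$mean[ok][sp$time[ok] >= 180]
  early <- sp$mean[ok][sp$time[ok] < 180]
  expect_gt(min(late), max(early) - 1e-9)
})

test_that("tracer noise is inflated after 180 minutes", {
  spec <- cohort_spec(n_subjects = 1, seed = 17)
  set.seed(17)
  tr <- generate_tracer_series(spec, lpl_rate = rep(0.3, 7),
                               spill = rep(0.2, 7),
                               times = canonical_times())
  expect_identical(tr$sd_inflated, canonical_times() > 180)
  expect_true(all(tr$hydrolysis_tg[canonical_times() <= 0] == 0))
})

test_that("measurement noise scales with the series dynamic range", {
  # many-subject homogeneous cohort: the cross-subject SD of each flux
  # series should approach 15% of that series' dynamic range
  coh <- generate_cohort_fluxes(cohort_spec(n_subjects = 60, cv = 0,
                                            seed = 23))
  f <- build_forcing(coh$study)
  sim <- simulate_adipose(coh$truth, f, times = canonical_times())
  mf <- model_fluxes(sim)
  for (s in c("glucose", "nefa")) {
    expected_sd <- 0.15 * diff(range(mf[[s]]))
    got <- coh$dataset$sd[coh$dataset$series == s]
    expect_equal(mean(got), expected_sd, tolerance = 0.35)
  }
})
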