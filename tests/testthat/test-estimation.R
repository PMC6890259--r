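test_that("the weighted cost is zero at a perfect fit and counts unit residuals", {
  f <- test_forcing()
  p <- default_parameters()
  sim <- simulate_adipose(p, f, times = canonical_times())
  mf <- model_fluxes(sim)
  perfect <- flux_dataset(
    do.call(rbind, lapply(c("tg", "glucose", "glycerol", "nefa"),
                          function(s) data.frame(series = s,
                                                 time = mf$time,
                                                 mean = mf[[s]],
                                                 sd = 0.1))),
    n_subjects = 16)
  expect_equal(flux_cost(p, perfect, f), 0, tolerance = 1e-12)
  # shifting one series up by one sigma per point adds 7
  shifted <- perfect
  tg_rows <- shifted$series == "tg"
  shifted$mean[tg_rows] <- shifted$mean[tg_rows] + shifted$sd[tg_rows]
  expect_equal(flux_cost(p, shifted, f), 7, tolerance = 1e-8)
  # zero-sigma points are excluded
  part <- shifted
  part$sd[which(tg_rows)[1]] <- 0
  expect_equal(flux_cost(p, part, f), 6, tolerance = 1e-8)
  # cost invariant under reordering of the points
  perm <- shifted[sample(nrow(shifted)), ]
  expect_equal(flux_cost(p, perm, f), flux_cost(p, shifted, f))
})

test_that("a failed simulation yields infinite cost, not an optimiser crash", {
  f <- test_forcing()
  coh <- zero_noise_cohort()
  ds <- unit_sigma(coh$dataset)
  # frac_use at 1 with high glucose routing starves the NEFA fixed point
  p_bad <- default_parameters()
  p_bad["frac_use"] <- 1
  p_bad["glut4"] <- 0.08
  expect_true(is.infinite(flux_cost(p_bad, ds, f)))
})

test_that("local fitting is a fixed point at an optimum and reduces cost", {
  coh <- zero_noise_cohort()
  ds <- unit_sigma(coh$dataset)
  f <- coh$forcing
  truth <- default_parameters()
  # starting at the optimum (the truth, cost 0) does not move away
  fit0 <- fit_local(truth, ds, f, compute_ci = FALSE)
  expect_lt(fit0$cost, 1e-12)
  expect_equal(fit0$par[fit0$free], truth[fit0$free], tolerance = 1e-6)
  # from a perturbed start the cost at the optimum is below the start
  init <- truth
  init[par_names()] <- truth[par_names()] * 1.25
  fit1 <- fit_local(init, ds, f, compute_ci = FALSE)
  expect_lt(fit1$cost, flux_cost(init, ds, f))
  expect_true(all(fit1$par[fit1$free] >= fit1$lower - 1e-12))
  expect_true(all(fit1$par[fit1$free] <= fit1$upper + 1e-12))
})

test_that("global fitting is reproducible and degenerates cleanly", {
  coh <- zero_noise_cohort()
  ds <- unit_sigma(coh$dataset)
  ds <- ds[ds$series == "tg", ]
  f <- coh$forcing
  cfg <- default_run_config(seed = 9)
  cfg$crs <- list(n_init = 40, maxeval = 300, tol = 1e-8)
  cfg$local <- list(maxiter = 60, ftol = 1e-10, ptol = 1e-10,
                    n_start = 2, n_hop = 2)
  free <- c("k_ad", "tau_lpl")
  fit_a <- fit_global(ds, f, config = cfg, free = free)
  fit_b <- fit_global(ds, f, config = cfg, free = free)
  expect_identical(fit_a$par, fit_b$par)
  expect_identical(fit_a$cost, fit_b$cost)
  expect_equal(fit_a$seed, 9L)
  # the TG series alone pins down its own two parameters
  expect_equal(unname(fit_a$par["k_ad"]), 0.0096, tolerance = 1e-3)
  expect_equal(unname(fit_a$par["tau_lpl"]), 156.92, tolerance = 1e-3)
  # n_init = 1 degenerates to a single midpoint-start local fit
  cfg1 <- cfg
  cfg1$crs$n_init <- 1
  fit_c <- fit_global(ds, f, config = cfg1, free = free)
  expect_s3_class(fit_c, "fit_result")
  expect_gte(fit_c$n_local_restarts, 1L)
})

test_that("Jacobian confidence intervals match the diagonal closed form", {
  # diagonal Jacobian, unit residual variance: half-width 1.96/|J_kk|
  J <- diag(c(2, 0.5))
  colnames(J) <- c("a", "b")
  n_obs <- 6
  k <- 2
  cost <- n_obs - k  # s^2 = 1
  ci <- jacobian_ci(J, c(a = 1, b = 10), cost, n_obs)
  expect_equal(ci["a", "hi"] - ci["a", "lo"], 2 * 1.96 / 2)
  expect_equal(ci["b", "hi"] - ci["b", "lo"], 2 * 1.96 / 0.5)
  expect_true(all(ci[, "lo"] < c(1, 10) & ci[, "hi"] > c(1, 10)))
  # a zero-sensitivity column gets an infinite interval and a warning
  J0 <- cbind(J, c = 0)
  expect_warning(
    expect_warning(ci0 <- jacobian_ci(J0, c(a = 1, b = 10, c = 5), cost,
                                      n_obs),
                   "zero-sensitivity"),
    "singular")
  expect_true(is.infinite(ci0["c", "hi"]))
})

test_that("intervals may extend below zero for weakly constrained delays", {
  # linearisation ignores the non-negativity bound; construct a fit-like
  # Jacobian with weak tau sensitivity and confirm the interval spans 0
  J <- cbind(k_ad = c(5, 4, 6, 5), tau_at = c(0.02, -0.01, 0.015, 0.01))
  ci <- jacobian_ci(J, c(k_ad = 0.01, tau_at = 21), cost = 8, n_obs = 30)
  expect_lt(ci["tau_at", "lo"], 0)
  expect_gt(ci["tau_at", "hi"], 21)
})
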