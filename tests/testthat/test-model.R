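test_that("delay chain derivatives vanish at steady state and reject tau = 0", {
  expect_equal(delay_chain_rhs(c(7, 7, 7), 7, 30), c(0, 0, 0))
  expect_error(delay_chain_rhs(c(1, 1, 1), 1, 0), "tau")
  d <- delay_chain_rhs(c(0, 0, 0), 12, 60)
  expect_equal(d, c(12 / 60, 0, 0))
})

test_that("integrated delay chain matches the analytic step response", {
  i0 <- 50
  for (tau in c(17.13, 21.19, 112.76, 156.92)) {
    sol <- delay_chain_solve(function(t) rep(i0, length(t)), tau,
                             times = seq(0, 300, 10), init = 0)
    ref <- delay_chain_step_response(sol$time, i0, tau)
    err <- abs(sol$i_delay - ref) / pmax(abs(ref), 1e-8)
    expect_lt(max(err[-1]), 1e-6)
  }
})

test_that("flux terms follow their defining algebra", {
  # LPL lipolysis: direct product, linear in TG
  expect_equal(tg_flux(0.0096, 1.0, 20), 0.192)
  expect_equal(tg_flux(0.0096, 2.0, 20), 2 * tg_flux(0.0096, 1.0, 20))
  expect_equal(tg_flux(0.0096, 1.0, 0), 0)
  # spill fraction: D/100 at basal insulin, halved at doubled insulin,
  # clamped at 1
  expect_equal(spill_fraction(35, 10, 10), 0.35)
  expect_equal(spill_fraction(35, 10, 20), 0.175)
  expect_equal(spill_fraction(400, 10, 10), 1)
  expect_error(spill_fraction(35, 10, 0), "positive")
  # monotone decreasing in arterial insulin
  i <- seq(5, 100, 5)
  expect_true(all(diff(spill_fraction(35, 10, i)) < 0))
  # glucose uptake arithmetic
  expect_equal(glucose_flux(0.1, 0.01, 5, 20), 1.5)
  expect_equal(glucose_flux(0.1, 0, 5, 20), 0.5)
  expect_equal(glucose_flux(0.1, 0.01, 0, 20), 0)
  # ATL: no inhibition, half inhibition, high-insulin limit, monotone
  expect_equal(atl_rate(0.05, 0.35, 10, 0), 0.4)
  expect_equal(atl_rate(0.05, 0.35, 10, 10), 0.05 + 0.175)
  expect_equal(atl_rate(0.05, 0.35, 10, 1e9), 0.05, tolerance = 1e-6)
  expect_true(all(diff(atl_rate(0.05, 0.35, 10, i)) < 0))
  expect_error(atl_rate(0.05, 0.35, 0, 10), "k_atl")
})

test_that("glycerol terms satisfy gradient-zero and 1:1 LPL stoichiometry", {
  p <- default_parameters()
  lpl <- tg_flux(p[["k_ad"]], 1.5, 30)
  # gradient zero: adipose glycerol equals local plasma level
  g <- glycerol_terms(p, gly_at = 0.08 + lpl, i_lpl = 30, i_at = 20,
                      tg_art = 1.5, gly_art = 0.08)
  expect_equal(g$diffusion, 0)
  expect_equal(g$flux, -lpl)
  expect_equal(g$lpl_release, lpl)
})

test_that("NEFA terms conserve fatty acids at the LPL node", {
  p <- default_parameters()
  n <- nefa_terms(p, nefa_at = 2, g3p_at = 1, i_lpl = 30, i_at = 20,
                  i_art = 40, i_basal = 10, tg_art = 1.5, nefa_art = 0.4)
  lpl <- tg_flux(p[["k_ad"]], 1.5, 30)
  expect_equal(n$spill + n$adipose_influx, 3 * lpl)
  # equilibrium: no gradient and no spill-over gives zero net flux
  p0 <- p
  p0["d_spill"] <- 0
  n0 <- nefa_terms(p0, nefa_at = 0.4, g3p_at = 1, i_lpl = 30, i_at = 20,
                   i_art = 40, i_basal = 10, tg_art = 1.5, nefa_art = 0.4)
  expect_equal(n0$flux, 0)
})

test_that("G-3-P cascade has the stated fixed point and integral limit", {
  p <- default_parameters()
  u <- 0.6
  g6p_star <- 2 * p[["frac_use"]] * u
  d <- g3p_rhs(p, g6p = g6p_star, g3p_pro = g6p_star, g3p_at = 1,
               uptake = u, i_at = 0, nefa_at = 1)
  expect_equal(unname(d["dg6p"]), 0)
  expect_equal(unname(d["dg3p_pro"]), 0)
  # k_reester = 0: adipose G-3-P integrates the production signal
  p0 <- p
  p0["k_reester"] <- 0
  d0 <- g3p_rhs(p0, g6p = 1, g3p_pro = 0.7, g3p_at = 5, uptake = u,
                i_at = 50, nefa_at = 3)
  expect_equal(unname(d0["dg3p_at"]), 0.7)
})

test_that("parameter validation guards the admissible region", {
  expect_error(validate_parameters(c(frac_use = 1.5)), "frac_use")
  expect_error(validate_parameters(c(k_ad = -1)), "non-negative")
  expect_error(validate_parameters(c(tau_lpl = 0)), "tau_lpl")
  expect_error(validate_parameters(c(atl_max = 1, k_atl = 0)), "k_atl")
  expect_error(validate_parameters(c(bogus = 1)), "unknown")
  full <- validate_parameters(c(k_ad = 0.01))
  expect_equal(length(full), 15)
})

test_that("initial state is the fasting fixed point of the dynamics", {
  f <- test_forcing()
  p <- default_parameters()
  y0 <- initial_state(p, f)
  expect_true(all(y0 >= 0))
  # freeze forcings at fasting values and evaluate the reference RHS
  frozen <- f
  for (a in c("insulin", "glucose", "tg", "glycerol", "nefa")) {
    v <- f$fasting[[a]]
    frozen[[a]] <- local({vv <- v; function(t) rep(vv, length(t))})
  }
  d <- adipose_rhs_r(-30, y0, p, frozen)$derivatives
  expect_lt(max(abs(d)), 1e-8)
  # closed-form fasting adipose glycerol
  lpl <- tg_flux(p[["k_ad"]], f$fasting[["tg"]], f$I_B)
  atl <- atl_rate(p[["b_atl"]], p[["atl_max"]], p[["k_atl"]], f$I_B)
  expect_equal(unname(y0["gly_at"]),
               unname(f$fasting[["glycerol"]] + lpl + atl / p[["p_gly"]]))
  # all lipolysis off: pure diffusion equilibrium at arterial levels
  p0 <- p
  p0[c("k_ad", "b_atl", "atl_max", "glut1", "glut4", "frac_use",
       "k_reester", "d_spill")] <- 0
  y00 <- initial_state(p0, f)
  expect_equal(unname(y00["gly_at"]), unname(f$fasting[["glycerol"]]))
  expect_equal(unname(y00["nefa_at"]), unname(f$fasting[["nefa"]]))
  # G-3-P production with no re-esterification capacity has no fixed point
  pbad <- p
  pbad["k_reester"] <- 0
  expect_error(initial_state(pbad, f), "G-3-P")
})

test_that("compiled right-hand side agrees with the R reference", {
  f <- test_forcing()
  p <- default_parameters()
  sim <- simulate_adipose(p, f, times = seq(-30, 300, 5))
  tr <- sim$trajectory
  for (tt in c(-30, 40, 155, 290)) {
    row <- tr[which.min(abs(tr$time - tt)), ]
    st <- setNames(as.numeric(row[2:12]), names(row)[2:12])
    ref <- adipose_rhs_r(row$time, st, p, f)
    expect_equal(as.numeric(row[13:26]), as.numeric(ref$outputs),
                 tolerance = 1e-10)
  }
})

test_that("null model and constant forcing give invariant trajectories", {
  f <- test_forcing()
  p0 <- default_parameters()
  p0[c("k_ad", "d_spill", "glut1", "glut4", "p_gly", "b_atl", "atl_max",
       "p_nefa", "k_reester", "frac_use")] <- 0
  sim <- simulate_adipose(p0, f, times = canonical_times())
  mf <- model_fluxes(sim)
  for (s in c("tg", "glucose", "glycerol", "nefa")) {
    expect_equal(mf[[s]], rep(0, 7), tolerance = 1e-12)
  }
  # constant forcing: the state stays at the fasting fixed point
  const <- build_forcing(flat_arterial_table())
  simc <- simulate_adipose(default_parameters(), const,
                           times = canonical_times())
  y0 <- initial_state(default_parameters(), const)
  for (k in names(y0)) {
    expect_equal(simc$trajectory[[k]], rep(unname(y0[k]), 7),
                 tolerance = 1e-7)
  }
})

test_that("states stay non-negative and solver tolerances are converged", {
  f <- test_forcing()
  sim <- simulate_adipose(default_parameters(), f)
  states <- sim$trajectory[, 2:12]
  expect_true(all(states >= -1e-10))
  sim2 <- simulate_adipose(default_parameters(), f, rtol = 5e-9,
                           atol = 5e-11)
  for (s in c("tg_flux", "glucose_flux", "glycerol_flux", "nefa_flux")) {
    rel <- abs(sim$trajectory[[s]] - sim2$trajectory[[s]]) /
      pmax(abs(sim$trajectory[[s]]), 1e-6)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("the delayed LPL insulin signal peaks after arterial insulin", {
  f <- test_forcing()
  sim <- simulate_adipose(default_parameters(), f)
  tr <- sim$trajectory
  t_art <- peak_time(tr$time, f$insulin(tr$time))
  t_lpl <- peak_time(tr$time, tr$i_lpl)
  expect_gt(t_lpl, t_art)
  # TG flux rises then falls over the postprandial window
  tg <- tr$tg_flux[tr$time >= 0]
  expect_gt(max(tg), tg[1])
  expect_lt(tg[length(tg)], max(tg))
})
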