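test_that("AICc matches an independent arithmetic evaluation", {
  # independent oracle: spell the formula out term by term
  aicc_oracle <- function(rss, n, k) {
    ll_term <- n * log(rss / n)
    penalty <- 2 * k
    correction <- (2 * k * (k + 1)) / (n - k - 1)
    ll_term + penalty + correction
  }
  for (k in 1:3) {
    expect_equal(aicc(7, 7, k), aicc_oracle(7, 7, k))
    expect_equal(aicc(0.31, 7, k), aicc_oracle(0.31, 7, k))
  }
  # equal RSS: fewer parameters score lower
  expect_lt(aicc(5, 7, 2), aicc(5, 7, 3))
  # guard: n - k - 1 must be positive
  expect_error(aicc(7, 7, 6), "n - k - 1")
})

test_that("term selection prefers the generating spill mechanism", {
  f <- test_forcing()
  times <- canonical_times()[canonical_times() > 0]
  # data generated from the insulin-only spill term
  truth_d <- 35
  spill <- spill_fraction(truth_d, f$I_B, f$insulin(times))
  set.seed(4)
  df <- data.frame(series = "spill_fraction", time = times,
                   mean = pmin(1, pmax(0, spill + rnorm(5, 0, 0.02))),
                   sd = 0.03)
  rank <- select_term(spill_term_variants(), df, f, seed = 21)
  expect_equal(rank$name[1], "spill_insulin_only")
  ins <- which(rank$name == "spill_insulin_only")
  bas <- which(rank$name == "spill_basal_insulin")
  expect_lt(rank$aicc[ins], rank$aicc[bas])
  d_hat <- attr(rank, "fits")$spill_insulin_only$par[["d_spill"]]
  expect_equal(d_hat, truth_d, tolerance = 0.15)
})

test_that("term selection recovers the need for the LPL insulin delay", {
  f <- test_forcing()
  times <- canonical_times()
  tau_true <- 150
  del <- delay_chain_solve(f$insulin, tau_true, c(-30, times),
                           init = f$I_B)
  i_lpl <- del$i_delay[match(times, del$time)]
  flux <- tg_flux(0.0096, f$tg(times), i_lpl)
  set.seed(8)
  df <- data.frame(series = "tg", time = times,
                   mean = flux + rnorm(7, 0, 0.01),
                   sd = 0.02)
  rank <- select_term(lpl_term_variants(), df, f, seed = 22)
  del_row <- which(rank$name == "lpl_linear_delayed")
  und_row <- which(rank$name == "lpl_linear_undelayed")
  expect_lt(rank$aicc[del_row], rank$aicc[und_row])
})

test_that("identical variants tie with a stable name order", {
  f <- test_forcing()
  times <- canonical_times()[canonical_times() > 0]
  df <- data.frame(series = "spill_fraction", time = times,
                   mean = 0.25, sd = 0.05)
  v <- spill_term_variants()[[3]]  # constant spill
  v2 <- v; v2$name <- "spill_constant_copy"
  rank <- select_term(list(v2, v), df, f, seed = 5)
  expect_equal(rank$aicc[1], rank$aicc[2])
  expect_equal(rank$name, c("spill_constant", "spill_constant_copy"))
})

test_that("profile likelihood distinguishes informative from inert parameters", {
  coh <- zero_noise_cohort()
  ds <- unit_sigma(coh$dataset)
  ds <- ds[ds$series == "tg", ]
  ds$sd <- 0.01  # tight weights make the TG parameters sharply profiled
  f <- coh$forcing
  free <- c("k_ad", "tau_lpl", "k_reester")
  fit <- fit_local(default_parameters(), ds, f, free = free,
                   compute_ci = FALSE)
  pk <- profile_likelihood(fit, "k_ad", ds, f, n_per_side = 4, span = 10,
                           maxiter = 30)
  expect_equal(pk$classification, "identifiable")
  # profile minimum matches the fit cost and the grid contains the optimum
  expect_lte(pk$min_cost, fit$cost + 1e-6)
  expect_true(any(pk$grid == fit$par[["k_ad"]]))
  # k_reester does not enter the TG flux at all: flat profile
  pr <- profile_likelihood(fit, "k_reester", ds, f, n_per_side = 3,
                           span = 10, maxiter = 20)
  expect_equal(pr$classification, "non_identifiable")
  cls <- classify_identifiability(list(pk, pr))
  expect_equal(sum(cls$counts), 2L)
  expect_equal(unname(cls$counts["identifiable"]), 1L)
  expect_equal(unname(cls$counts["non_identifiable"]), 1L)
})

test_that("log-scale sensitivities obey the linear-in-parameter identity", {
  f <- test_forcing()
  p <- default_parameters()
  times <- canonical_times()
  S <- local_sensitivities(p, f, times = times,
                           free = c("k_ad", "glut1", "k_reester"))
  sim <- simulate_adipose(p, f, times = times)
  mf <- model_fluxes(sim)
  # TG flux is linear in k_ad, so d flux / d log k_ad = flux itself
  tg_rows <- grep("^tg@", rownames(S))
  expect_equal(unname(S[tg_rows, "k_ad"]), mf$tg, tolerance = 1e-4)
  # glucose uptake does not depend on k_reester (structural zero, up to
  # the ODE-solver noise amplified by the finite-difference step)
  glc_rows <- grep("^glucose@", rownames(S))
  expect_lt(max(abs(S[glc_rows, "k_reester"])), 5e-3)
  # a parameter at zero is flagged, its column left zero
  p0 <- p
  p0["glut1"] <- 0
  expect_warning(S0 <- local_sensitivities(p0, f, times = times,
                                           free = c("glut1", "k_ad")),
                 "at zero")
  expect_true(attr(S0, "at_zero")[["glut1"]])
  expect_equal(max(abs(S0[, "glut1"])), 0)
})
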