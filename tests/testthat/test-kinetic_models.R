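protocol_times <- c(0, 0.5, 1, 2, 4)

test_that("zero-order fit recovers exact linear data and matches closed-form OLS", {
  exact <- make_profile(c(0.5, 1, 2, 4), 10 * c(0.5, 1, 2, 4))
  f <- fit_zero_order(exact)
  expect_equal(f$parameters$flux_j, 10, tolerance = 1e-12)
  expect_equal(f$parameters$lag_tl, 0, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  # on non-linear (square-root) data the fit is still the plain OLS line
  t <- c(0.25, 1, 4)
  q <- 20 * sqrt(t)
  f2 <- fit_zero_order(make_profile(t, q))
  line <- ols_line(t, q)
  expect_equal(f2$parameters$slope, unname(line["slope"]), tolerance = 1e-12)
  expect_equal(f2$parameters$intercept, unname(line["intercept"]),
               tolerance = 1e-12)

  z <- fit_zero_order(make_profile(c(0, 1, 2), c(0, 0, 0)))
  expect_true(z$degenerate)
  expect_equal(z$parameters$flux_j, 0)
})

test_that("first-order fit recovers its generator and loses to the line on linear data", {
  q <- 100 * (1 - exp(-0.5 * protocol_times))
  f <- fit_first_order(make_profile(protocol_times, q))
  expect_equal(f$parameters$q_inf, 100, tolerance = 1e-6)
  expect_equal(f$parameters$k, 0.5, tolerance = 1e-6)

  lin <- make_profile(protocol_times, 10 * protocol_times)
  expect_lt(fit_first_order(lin)$r2_adj, fit_zero_order(lin)$r2_adj)

  z <- fit_first_order(make_profile(c(0, 1, 2), c(0, 0, 0)))
  expect_true(z$degenerate)
})

test_that("Higuchi fit equals the through-origin closed form", {
  f <- fit_higuchi(make_profile(c(1, 4), c(5, 10)))
  expect_equal(f$parameters$kh, 5, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)

  expect_equal(fit_higuchi(make_profile(c(1, 2, 3), c(0, 0, 0)))$parameters$kh, 0)

  # KH = sum(Q sqrt(t)) / sum(t) = (1 + 6 + 15) / 14
  mixed <- fit_higuchi(make_profile(c(1, 4, 9), c(1, 3, 5)))
  expect_equal(mixed$parameters$kh, 22 / 14, tolerance = 1e-12)
})

test_that("model selection attributes noise-free data to its generator", {
  fits_for <- function(q) {
    p <- make_profile(protocol_times, q)
    list(fit_zero_order(p), fit_first_order(p), fit_higuchi(p))
  }
  expect_equal(select_model(fits_for(10 * protocol_times))$model, "zero_order")
  expect_equal(select_model(fits_for(20 * sqrt(protocol_times)))$model,
               "higuchi")
  expect_equal(select_model(fits_for(100 * (1 - exp(-0.5 * protocol_times))))$model,
               "first_order")
})

test_that("model-selection ties break toward fewer parameters, and all-degenerate errors", {
  stub <- function(model, r2_adj, n_par) {
    structure(list(model = model, r2_adj = r2_adj, n_par = n_par,
                   degenerate = FALSE), class = "kinetic_fit")
  }
  win <- select_model(list(stub("first_order", 0.9, 2),
                           stub("higuchi", 0.9, 1)))
  expect_equal(win$model, "higuchi")
  # equal r2_adj and equal p: fixed order zero < higuchi < first
  win2 <- select_model(list(stub("first_order", 0.9, 2),
                            stub("zero_order", 0.9, 2)))
  expect_equal(win2$model, "zero_order")

  degen <- structure(list(model = "zero_order", r2_adj = NA_real_,
                          n_par = 2, degenerate = TRUE),
                     class = "kinetic_fit")
  expect_error(select_model(list(degen, degen)), "degenerate")
})

test_that("steady-state flux reads the linear portion: slope, lag and window", {
  # a perfect line Q = 10 (t - 0.5)
  lin <- make_profile(c(1, 2, 4), 10 * (c(1, 2, 4) - 0.5))
  ss <- steady_state_flux(lin)
  expect_equal(ss$flux_j, 10, tolerance = 1e-12)
  expect_equal(ss$lag_tl, 0.5, tolerance = 1e-12)
  expect_length(ss$window, 3)

  # lag-diffusion profile, dense late sampling: the analytic asymptote
  m <- membrane_preset("mucosa")
  times <- seq(1, 6, by = 0.5)
  prof <- diffusion_profile(m, 10000, times)
  cl <- franz_cell(times_h = times)
  sim <- simulate_franz_sampling(prof, cl,
                                 sim_config(noise_cv = 0, times_h = times))
  ss2 <- steady_state_flux(cumulative_amount(sim, cl))
  expect_lt(abs(ss2$flux_j - prof$flux_inf) / prof$flux_inf, 0.05)
  expect_lt(abs(ss2$lag_tl - m$lag_h) / m$lag_h, 0.10)

  # strongly saturating first-order data: no long window is linear enough
  t <- c(0, 0.5, 1, 2, 4)
  sat <- make_profile(t, 100 * (1 - exp(-3 * t)))
  ss3 <- steady_state_flux(sat)
  expect_length(ss3$window, 3)
  expect_false(ss3$qualified)
  expect_gte(ss3$flux_j, 0)

  expect_error(steady_state_flux(make_profile(c(1, 2), c(1, 2))),
               "at least 3")
})

test_that("permeability coefficient is flux over donor concentration", {
  d <- dose_spec()   # C0 = 10,000 ug/mL
  expect_equal(permeability_coefficient(51, d), 5.1e-3)
  expect_equal(permeability_coefficient(547, d), 54.7e-3)
  expect_equal(permeability_coefficient(0, d), 0)
  # invariance: scaling C0 and flux jointly leaves Kp unchanged
  expect_equal(permeability_coefficient(51 * 7, dose_spec(0.3, 10000 * 7)),
               permeability_coefficient(51, d))
})

test_that("peak quantities take the earliest maximum and the ledger Qmax", {
  s <- conc_series("c", c(0, 1, 2, 4), c(0, 10, 30, 25))
  pk <- cmax_tmax(s, cumulative_amount(s))
  expect_equal(pk$cmax_ug_ml, 30)
  expect_equal(pk$tmax_h, 2)

  const <- conc_series("c", c(1, 2, 4), c(5, 5, 5))
  expect_equal(cmax_tmax(const)$tmax_h, 1)

  cell <- franz_cell()
  q <- cumulative_amount(s, cell)
  expect_equal(cmax_tmax(s, q)$qmax_ug_cm2,
               max(ledger_cumulative_q(s$conc_ug_ml, 3, 0.2, 1.86)))
})

test_that("trapezoidal AUC is exact on piecewise-linear profiles", {
  expect_equal(auc_trapezoid(make_profile(c(0, 1), c(0, 10))), 5)
  expect_equal(auc_trapezoid(make_profile(c(0, 3), c(7, 7))), 21)
  t <- c(0, 0.5, 1, 2, 4)
  expect_equal(auc_trapezoid(make_profile(t, 10 * t)), 80)  # int 10 t dt
  expect_error(auc_trapezoid(make_profile(1, 5)), "at least 2")
})

test_that("zero-order flux recovery under proportional noise stays within 10%", {
  t <- c(0, 0.5, 1, 2, 4)
  for (j_true in c(1, 10, 100)) {
    noise_free <- fit_zero_order(make_profile(t, j_true * t))
    expect_lt(abs(noise_free$parameters$flux_j - j_true) / j_true, 1e-3)
    errs <- vapply(1:20, function(seed) {
      set.seed(seed)
      q <- j_true * t * (1 + pmax(rnorm(length(t), 0, 0.05), -0.15))
      abs(fit_zero_order(make_profile(t, q))$parameters$flux_j - j_true) /
        j_true
    }, numeric(1))
    expect_lte(median(errs), 0.10)
  }
})

test_that("the full per-cell pipeline is internally consistent", {
  cell <- franz_cell()
  dose <- dose_spec()
  m <- membrane_preset("nuclepore")
  prof <- diffusion_profile(m, dose$c0_ug_ml, cell$times_h)
  sim <- simulate_franz_sampling(prof, cell,
                                 sim_config(noise_cv = 0.05, seed = 3))
  sim$analyte <- analyte_spec("caffeine", lod = 0.82, loq = 2.49)
  p <- fit_permeation(sim, cell, dose)
  expect_equal(p$kp * dose$c0_ug_ml, p$flux_j, tolerance = 1e-9)
  expect_gte(p$lag_tl, 0)
  expect_true(p$tmax %in% cell$times_h)
  expect_true(p$selected_model %in% c("zero_order", "first_order",
                                      "higuchi"))
  expect_equal(p$cmax, max(sim$conc_ug_ml))
})
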