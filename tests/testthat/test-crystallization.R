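test_that("permittivity normalization matches the defining substitution", {
  tr <- crystallization_trace(c(0, 10, 20), c(10, 7, 4), axis = "time",
                              eps0 = 10, eps_inf_limit = 4)
  trn <- normalize_permittivity(tr)
  expect_equal(trn$eps_norm, c(0, 0.5, 1))
  expect_error(normalize_permittivity(
    crystallization_trace(c(0, 10), c(4, 4), axis = "time"), eps0 = 4, eps_inf = 4),
    "must exceed")
})

test_that("normalization is invariant under affine rescaling of eps'", {
  set.seed(21)
  tgrid <- seq(0, 3600 * 10, by = 600)
  tr <- generate_isothermal_trace(10, 4, kernel = list(t_onset = 3600, k = 1e-7, n = 2),
                                  time_grid = tgrid)
  base <- normalize_permittivity(tr)$eps_norm
  for (i in 1:10) {
    gain <- runif(1, 0.1, 5); offset <- runif(1, -3, 3)
    tr2 <- crystallization_trace(tgrid, gain * tr$eps_real + offset,
                                 axis = "time",
                                 eps0 = gain * 10 + offset,
                                 eps_inf_limit = gain * 4 + offset)
    expect_equal(normalize_permittivity(tr2)$eps_norm, base, tolerance = 1e-10)
  }
})

test_that("onset detection hits the programmed collapse within one grid step", {
  f <- freq_grid_std()
  vft <- list(tau_inf = 1e-14, B = 2200, T0 = 270)
  step <- 2
  grid <- seq(300, 420, by = step)
  scan <- generate_single_frequency_scan(vft, A = 1500, eps_inf = 3,
                                         tc_true = 376, temp_grid = grid)
  res <- detect_onset(scan)
  expect_true(res$detected)
  expect_lte(abs(res$onset - 376), step)
  ## threshold sweep 5-15%: onset moves by at most one grid step
  onsets <- vapply(c(0.05, 0.08, 0.1, 0.12, 0.15),
                   function(th) detect_onset(scan, threshold = th)$onset,
                   numeric(1))
  expect_lte(diff(range(onsets)), step)
  ## no programmed collapse: clean A/T trend gives a no-onset result
  scan2 <- generate_single_frequency_scan(vft, A = 1500, eps_inf = 3,
                                          temp_grid = grid)
  res2 <- detect_onset(scan2)
  expect_false(res2$detected)
  expect_true(is.na(res2$onset))
})

test_that("wide-band dielectric-strength collapse is detected against the 1/T baseline", {
  vft <- list(tau_inf = 1e-14, B = 2200, T0 = 270)
  grid <- seq(340, 400, by = 2)
  deps <- 1500 / grid
  X <- 1 - exp(-0.5 * pmax(0, grid - 376)^2)
  df <- data.frame(temperature = grid, delta_eps = deps * (1 - X))
  res <- detect_onset(df)
  expect_true(res$detected)
  expect_lte(abs(res$onset - 376), 2)
  expect_identical(res$method, "delta_eps_drop")
  ## monotone A/T trend alone: no onset
  res2 <- detect_onset(data.frame(temperature = grid, delta_eps = deps))
  expect_false(res2$detected)
})

test_that("kinetics summaries recover induction, cessation and plateau level", {
  tgrid <- seq(0, 40 * 3600, by = 300)
  t_on <- 2 * 3600
  tr <- generate_isothermal_trace(10, 4,
                                  kernel = list(t_onset = t_on, k = 5e-8, n = 2),
                                  time_grid = tgrid)
  ks <- kinetics_summary(normalize_permittivity(tr))
  ## detection threshold 0.05 puts induction just past the true onset
  t_ind_true <- t_on + (-log(1 - 0.05) / 5e-8)^(1 / 2)
  expect_lt(abs(ks$induction_time - t_ind_true) / t_ind_true, 0.05)
  expect_gte(ks$cessation_time, ks$induction_time)
  expect_equal(ks$final_norm, 1, tolerance = 1e-3)
  expect_true(ks$complete)

  ## incomplete crystallization stalls at the crystallizable cap
  tr8 <- generate_isothermal_trace(10, 4,
                                   kernel = list(t_onset = t_on, k = 5e-8, n = 2,
                                                 x_max = 0.8),
                                   time_grid = tgrid)
  ks8 <- kinetics_summary(normalize_permittivity(tr8))
  expect_equal(ks8$final_norm, 0.8, tolerance = 1e-3)
  expect_false(ks8$complete)

  ## flat trace: no induction, plateau near zero
  flat <- generate_isothermal_trace(10, 4,
                                    kernel = list(t_onset = 0, k = 1e-300, n = 1),
                                    time_grid = tgrid, noise_sd = 0.001, seed = 2)
  ksf <- kinetics_summary(normalize_permittivity(flat, eps0 = 10, eps_inf = 4))
  expect_true(is.na(ksf$induction_time))
  expect_true(is.na(ksf$cessation_time))
  expect_lt(abs(ksf$final_norm), 0.02)
})

test_that("the stability factor is a plain antisymmetric difference", {
  expect_equal(stability_factor(350, 350), 0)
  expect_equal(stability_factor(328, 374), 46)   # Tc - Tg of the neat drug
  expect_equal(stability_factor(374, 328), -stability_factor(328, 374))
  expect_error(stability_factor(NA, 370), "finite")
})

test_that("residual composition recovers the saturated drug fraction end-to-end", {
  f <- freq_grid_std()
  gm <- gt_model(tg1 = 328, tg2 = 310, k = 2.2)
  w_drug_true <- 0.17
  tg_sat <- gt_predict(gm, 1 - w_drug_true)
  vft <- vft_for_tg(tg_sat)
  temps <- temps_for_tau(vft, 10^seq(-1, -5, length.out = 12))
  post <- generate_temperature_series(vft, A = 1200, eps_inf = 3,
                                      temp_grid = temps, freq_grid = f,
                                      noise_sd = 0.01, seed = 7)
  rc <- residual_composition(post, gm)
  expect_lt(abs(rc$w_drug - w_drug_true), 0.02)
  expect_true(is.finite(rc$w_drug_sd))

  ## residual process at the neat-polymer Tg: composition ~ 0 with a warning
  vft0 <- vft_for_tg(gm$tg2)
  temps0 <- temps_for_tau(vft0, 10^seq(-1, -5, length.out = 12))
  post0 <- generate_temperature_series(vft0, A = 1200, eps_inf = 3,
                                       temp_grid = temps0, freq_grid = f,
                                       noise_sd = 0.005, seed = 8)
  w <- testthat::capture_warnings(rc0 <- residual_composition(post0, gm))
  expect_true(any(grepl("crystallized completely|immiscible", w)))
  expect_lt(abs(rc0$w_drug), 0.02)
})
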