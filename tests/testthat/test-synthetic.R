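test_that("noiseless spectra equal the analytic forward model exactly", {
  f <- freq_grid_std()
  sp <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 1e-9, f, 353)
  ref <- eval_hn(list(delta_eps = 5, tau_hn = 1e-3, a = 0.8, b = 0.6,
                      eps_inf = 3, sigma_dc = 1e-9), f)
  expect_equal(sp$eps_real, ref$eps_real, tolerance = 1e-12)
  expect_equal(sp$eps_imag, ref$eps_imag, tolerance = 1e-12)
})

test_that("Debye spectrum peaks at f = 1/(2 pi tau) to grid resolution", {
  f <- freq_grid_std()
  tau <- 1e-3
  sp <- generate_spectrum(5, tau, 1, 1, 3, 0, f, 353)
  fpk <- f[which.max(sp$eps_imag)]
  ## nearest grid point to the true peak frequency (grid is 30 pts/decade)
  expect_lt(abs(log10(fpk) - log10(1 / (2 * pi * tau))), 1 / 30)
})

test_that("dc conduction gives a log-log loss slope of -1 at low frequency", {
  f <- freq_grid_std()
  sp <- generate_spectrum(5, 1e-5, 0.8, 0.6, 3, 1e-8, f, 353)
  low <- f < 1          # conduction-dominated limb
  fit <- stats::lm.fit(cbind(1, log(f[low])), log(sp$eps_imag[low]))
  expect_equal(unname(fit$coefficients[2]), -1, tolerance = 1e-3)
})

test_that("generators are deterministic in the seed", {
  f <- freq_grid_std()
  s1 <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 0, f, 353, noise_sd = 0.01, seed = 11)
  s2 <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 0, f, 353, noise_sd = 0.01, seed = 11)
  s3 <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 0, f, 353, noise_sd = 0.01, seed = 12)
  expect_identical(s1$eps_imag, s2$eps_imag)
  expect_false(identical(s1$eps_imag, s3$eps_imag))

  vft <- list(tau_inf = 1e-14, B = 2000, T0 = 250)
  g <- seq(300, 330, by = 3)
  a1 <- generate_temperature_series(vft, A = 1500, eps_inf = 3, temp_grid = g,
                                    freq_grid = f, noise_sd = 0.01, seed = 5)
  a2 <- generate_temperature_series(vft, A = 1500, eps_inf = 3, temp_grid = g,
                                    freq_grid = f, noise_sd = 0.01, seed = 5)
  expect_identical(lapply(a1$spectra, `[[`, "eps_imag"),
                   lapply(a2$spectra, `[[`, "eps_imag"))
  ## byte-identical CSV from equal seeds
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_spectrum_series(a1, p1); write_spectrum_series(a2, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("temperature-series manifest records the exact VFT relaxation times", {
  f <- freq_grid_std()
  vft <- list(tau_inf = 1e-14, B = 2000, T0 = 250)
  g <- seq(300, 330, by = 3)
  ser <- generate_temperature_series(vft, A = 1500, eps_inf = 3,
                                     temp_grid = g, freq_grid = f)
  man <- ground_truth(ser)
  taus <- vapply(man$hn_by_condition, `[[`, numeric(1), "tau_hn")
  expect_equal(taus, eval_vft(vft, g), tolerance = 1e-15)
  ## no crystallization branch: delta_eps strictly decreasing as A/T
  deps <- vapply(man$hn_by_condition, `[[`, numeric(1), "delta_eps")
  expect_true(all(diff(deps) < 0))
  expect_equal(deps, 1500 / g, tolerance = 1e-15)
  ## temperature at or below T0 is a domain error
  expect_error(generate_temperature_series(vft, A = 1500, eps_inf = 3,
                                           temp_grid = c(250, 300),
                                           freq_grid = f),
               "VFT divergence")
})

test_that("isothermal traces follow the stretched-exponential kernel", {
  tg <- seq(0, 30 * 3600, by = 600)
  k <- 2e-8; n <- 2; t_on <- 2 * 3600
  tr <- generate_isothermal_trace(10, 4, kernel = list(t_onset = t_on, k = k, n = n),
                                  time_grid = tg)
  ## plateau before onset
  expect_true(all(tr$eps_real[tg <= t_on] == 10))
  ## normalized trace crosses 1 - exp(-1) where k (t - t_on)^n = 1
  trn <- normalize_permittivity(tr)
  t63_true <- t_on + (1 / k)^(1 / n)
  grow <- trn$eps_norm > 1e-6 & trn$eps_norm < 1 - 1e-6   # strictly monotone part
  t63_obs <- stats::approx(trn$eps_norm[grow], tg[grow], xout = 1 - exp(-1))$y
  expect_equal(t63_obs, t63_true, tolerance = 1e-3)
  ## near-zero rate: trace stays flat at eps0
  flat <- generate_isothermal_trace(10, 4, kernel = list(t_onset = 0, k = 1e-300, n = 1),
                                    time_grid = tg)
  expect_true(all(flat$eps_real == 10))
  ## incomplete crystallization: observed plateau stays above eps_inf
  part <- generate_isothermal_trace(10, 4,
                                    kernel = list(t_onset = 0, k = 1e-3, n = 1, x_max = 0.8),
                                    time_grid = tg)
  expect_equal(min(part$eps_real), 4 + 6 * 0.2, tolerance = 1e-10)
  expect_error(generate_isothermal_trace(4, 10, time_grid = tg),
               "'eps0' must exceed")
})

test_that("synthetic composition tables follow the Gordon-Taylor forward model", {
  gm <- gt_model(331, 376, 1)
  tab <- generate_tg_composition(gm, seq(0, 1, by = 0.25))
  ## K = 1 reduces to the weighted mean of the component Tgs
  expect_equal(tab$tg, 331 + (376 - 331) * tab$w2, tolerance = 1e-12)
  expect_equal(tab$tg[tab$w2 == 0], 331)
  ## round trip: fitting K on noiseless output recovers it to 1e-10
  gm2 <- gt_model(331, 376, 1.7)
  tab2 <- generate_tg_composition(gm2, seq(0.1, 0.9, by = 0.2))
  expect_equal(fit_gt_k(tab2, 331, 376)$k, 1.7, tolerance = 1e-10)
})
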