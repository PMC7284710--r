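test_that("eval_hn matches closed forms and an independent complex oracle", {
  ## Debye at omega * tau = 1: eps' = eps_inf + deps/2, eps'' = deps/2
  tau <- 1e-3
  m <- eval_hn(list(delta_eps = 5, tau_hn = tau, a = 1, b = 1, eps_inf = 3,
                    sigma_dc = 0), 1 / (2 * pi * tau))
  expect_equal(m$eps_real, 3 + 2.5, tolerance = 1e-12)
  expect_equal(m$eps_imag, 2.5, tolerance = 1e-12)
  ## static limit eps_s = eps_inf + delta_eps
  lo <- eval_hn(list(delta_eps = 5, tau_hn = tau, a = 1, b = 1, eps_inf = 3,
                     sigma_dc = 0), 1e-9)
  expect_equal(lo$eps_real, 8, tolerance = 1e-8)
  ## independent term-by-term polar-form evaluation at a = 0.8, b = 0.6
  a <- 0.8; b <- 0.6; f <- c(0.5, 50, 5e3); w <- 2 * pi * f
  r <- (w * tau)^a; phi <- pi * a / 2          # (i w tau)^a in polar form
  den_re <- 1 + r * cos(phi); den_im <- r * sin(phi)
  mod <- (den_re^2 + den_im^2)^(b / 2); arg <- b * atan2(den_im, den_re)
  expect_ref <- data.frame(eps_real = 3 + 5 * cos(arg) / mod,
                           eps_imag = 5 * sin(arg) / mod)
  got <- eval_hn(list(delta_eps = 5, tau_hn = tau, a = a, b = b, eps_inf = 3,
                      sigma_dc = 0), f)
  expect_equal(got$eps_real, expect_ref$eps_real, tolerance = 1e-12)
  expect_equal(got$eps_imag, expect_ref$eps_imag, tolerance = 1e-12)
})

test_that("dielectric strength is conserved across the relaxation", {
  set.seed(42)
  for (i in 1:20) {
    p <- list(delta_eps = runif(1, 0.5, 20), tau_hn = 10^runif(1, -6, 0),
              a = runif(1, 0.3, 1), b = runif(1, 0.2, 1),
              eps_inf = runif(1, 2, 5), sigma_dc = 0)
    ## the wings decay as (w tau)^a (low side) and (w tau)^(-ab) (high
    ## side), so push each limit far enough for its own exponent
    lo <- eval_hn(p, 10^(-12 / p$a) / p$tau_hn)$eps_real
    hi <- eval_hn(p, 10^(12 / (p$a * p$b)) / p$tau_hn)$eps_real
    expect_equal(lo - hi, p$delta_eps, tolerance = 1e-6)
  }
})

test_that("hn_peak_time matches the Debye identity and Cole-Davidson closed form", {
  expect_equal(hn_peak_time(list(tau_hn = 2e-4, a = 1, b = 1)), 2e-4,
               tolerance = 1e-14)
  ## Cole-Davidson (a = 1): omega_max * tau = tan(pi / (2b + 2))
  expect_equal(hn_peak_time(list(tau_hn = 1, a = 1, b = 0.5)),
               1 / tan(pi / 3), tolerance = 1e-12)
  for (b in c(0.2, 0.4, 0.7, 0.9))
    expect_equal(hn_peak_time(list(tau_hn = 1, a = 1, b = b)),
                 1 / tan(pi / (2 * b + 2)), tolerance = 1e-12)
  expect_error(hn_peak_time(list(tau_hn = 1, a = 1.2, b = 0.5)), "\\(0, 1\\]")
  expect_error(hn_peak_time(list(tau_hn = 1, a = 0.5, b = 0)), "\\(0, 1\\]")
})

test_that("hn_peak_time agrees with numeric loss-peak search away from limits", {
  ## spot checks here; the full (a, b) grid runs in the acceptance suite
  for (ab in list(c(0.5, 0.3), c(0.8, 0.6), c(0.9, 1), c(0.3, 0.9))) {
    tn <- numeric_peak_time(ab[1], ab[2])
    ta <- hn_peak_time(list(tau_hn = 1, a = ab[1], b = ab[2]))
    expect_equal(ta, tn, tolerance = 1e-6)
  }
})

test_that("fit_hn recovers noiseless synthetic parameters to 1e-6 relative", {
  f <- freq_grid_std()
  sp <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 0, f, 353)
  fit <- fit_hn(sp)
  expect_true(fit$converged)
  expect_equal(fit$par$delta_eps, 5, tolerance = 1e-6)
  expect_equal(fit$par$tau_hn, 1e-3, tolerance = 1e-6)
  expect_equal(fit$par$a, 0.8, tolerance = 1e-6)
  expect_equal(fit$par$b, 0.6, tolerance = 1e-6)
})

test_that("complex-mode fitting also recovers eps_inf and sigma_dc", {
  f <- freq_grid_std()
  sp <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3.4, 5e-10, f, 353)
  fit <- fit_hn(sp, mode = "complex")
  expect_true(fit$converged)
  expect_equal(fit$par$eps_inf, 3.4, tolerance = 1e-4)
  expect_equal(fit$par$sigma_dc, 5e-10, tolerance = 1e-3)
  expect_equal(fit$par$tau_hn, 1e-3, tolerance = 1e-4)
})

test_that("degenerate inputs are flagged or rejected, not mis-fit", {
  f <- freq_grid_std()
  w <- 2 * pi * f
  ## conduction-only loss: flagged non-identifiable, no exception
  sp <- dielectric_spectrum(f, eps_imag = 1e-9 / (8.8541878128e-12 * w),
                            temperature = 353)
  fit <- fit_hn(sp)
  expect_false(fit$identifiable)
  expect_false(fit$converged)
  expect_equal(fit$par$sigma_dc, 1e-9, tolerance = 1e-6)
  ## peak beyond the grid and no conduction signature: initialization error
  sp2 <- generate_spectrum(5, 1e-9, 0.8, 0.6, 3, 0, 10^seq(-1, 4, by = 0.1), 353)
  expect_error(fit_hn(sp2), "no interior loss maximum")
  ## but an explicit init rescues it only when physically sensible
  expect_error(fit_hn(sp2, init = list(a = 0.8)), "must supply")
})

test_that("fitting is invariant under joint frequency/time rescaling", {
  f <- freq_grid_std()
  sp <- generate_spectrum(5, 1e-3, 0.8, 0.6, 3, 0, f, 353, noise_sd = 0.01,
                          seed = 3)
  c_scale <- 100
  sp_scaled <- dielectric_spectrum(f * c_scale, eps_real = sp$eps_real,
                                   eps_imag = sp$eps_imag, temperature = 353)
  f1 <- fit_hn(sp); f2 <- fit_hn(sp_scaled)
  expect_equal(f2$par$tau_hn * c_scale, f1$par$tau_hn, tolerance = 1e-6)
  expect_equal(f2$par$a, f1$par$a, tolerance = 1e-6)
  expect_equal(f2$par$b, f1$par$b, tolerance = 1e-6)
  expect_equal(f2$residual, f1$residual, tolerance = 1e-6)
})

test_that("relaxation maps are monotone, accurate, and truncated at collapse", {
  f <- freq_grid_std()
  vft <- list(tau_inf = 1e-14, B = 2000, T0 = 260)
  g <- seq(305, 345, by = 2.5)
  ser <- generate_temperature_series(vft, A = 1500, eps_inf = 3, temp_grid = g,
                                     freq_grid = f, noise_sd = 0.01, seed = 9)
  map <- extract_relaxation_map(ser)
  expect_s3_class(map, "relaxation_map")
  expect_true(all(diff(map$tau_alpha) < 0))          # faster when hotter
  ## cold spectra whose peak sits below the window are skipped, not mis-fit
  reasons0 <- vapply(attr(map, "skipped"), `[[`, character(1), "reason")
  expect_true(any(grepl("frequency window", reasons0)))
  man <- ground_truth(ser)
  true_ta <- vapply(man$hn_by_condition, `[[`, numeric(1), "tau_alpha")
  true_kept <- true_ta[match(round(map$temperature, 6), round(g, 6))]
  expect_true(all(abs(map$tau_alpha / true_kept - 1) < 0.05))  # 5% at 1% noise

  ## crystallized high-T spectra are flagged and the map truncated
  ser2 <- generate_temperature_series(vft, A = 1500, eps_inf = 3, tc_true = 330,
                                      temp_grid = g, freq_grid = f)
  map2 <- extract_relaxation_map(ser2)
  expect_true(max(map2$temperature) <= 330)
  reasons <- vapply(attr(map2, "skipped"), `[[`, character(1), "reason")
  expect_true(any(grepl("crystallized", reasons)))

  ## a series in which nothing fits raises an empty-result error
  w <- 2 * pi * f
  cond_only <- spectrum_series(list(
    dielectric_spectrum(f, eps_imag = 1e-9 / (8.8541878128e-12 * w), temperature = 300),
    dielectric_spectrum(f, eps_imag = 2e-9 / (8.8541878128e-12 * w), temperature = 310)))
  expect_error(extract_relaxation_map(cond_only), "could be fitted")
})
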