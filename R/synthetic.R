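## Seeded synthetic dielectric data with ground-truth manifests.  Forward
## models: HN + conductivity for spectra, VFT for tau(T), Langevin A/T for
## the dielectric strength, and a stretched-exponential (Avrami-like)
## crystallized-fraction kernel X(t) = x_max * (1 - exp(-k * (t - onset)^n)).
## Noise is multiplicative Gaussian (relative), applied last; the noiseless
## branch equals the analytic forward model exactly.

#' Ground truth attached to a synthetic dataset
#'
#' Every generator in the package attaches a manifest (parameters, grids,
#' seed) sufficient to regenerate the dataset bit-exactly.
#'
#' @param x An object produced by one of the `generate_*` functions.
#' @return The manifest list, or `NULL`.
#' @export
ground_truth <- function(x) attr(x, "ground_truth", exact = TRUE)

#' Write a ground-truth manifest as JSON
#'
#' @param x An object carrying a manifest (see [ground_truth()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_manifest <- function(x, path) {
  gt <- ground_truth(x)
  if (is.null(gt)) stop("object carries no ground-truth manifest", call. = FALSE)
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

.mult_noise <- function(x, noise_sd) {
  if (noise_sd == 0) return(x)
  x * (1 + stats::rnorm(length(x), sd = noise_sd))
}

#' Generate one synthetic dielectric spectrum
#'
#' Evaluates the HN + conductivity forward model on a frequency grid and
#' applies multiplicative Gaussian noise of relative standard deviation
#' `noise_sd` to \eqn{\varepsilon'} and \eqn{\varepsilon''} independently.
#' `noise_sd = 0` returns the exact model.
#'
#' @param delta_eps,tau_hn,a,b,eps_inf,sigma_dc HN parameters (see
#'   [eval_hn()]); `0 < a, b <= 1`, `delta_eps > 0`, `tau_hn > 0`,
#'   `sigma_dc >= 0`.
#' @param frequencies Frequency grid in Hz.
#' @param temperature Temperature label in kelvin.
#' @param time Optional time label in seconds.
#' @param noise_sd Relative noise level (default 0).
#' @param seed Integer seed (default 1); same seed, same arrays.
#' @return A [dielectric_spectrum] with a [ground_truth()] manifest.
#' @export
generate_spectrum <- function(delta_eps, tau_hn, a, b, eps_inf, sigma_dc = 0,
                              frequencies, temperature, time = NA_real_,
                              noise_sd = 0, seed = 1L) {
  .check_hn_params(delta_eps, tau_hn, a, b, eps_inf, sigma_dc)
  m <- .hn_complex(frequencies, delta_eps, tau_hn, a, b, eps_inf, sigma_dc)
  set.seed(seed)
  sp <- dielectric_spectrum(frequency = frequencies,
                            eps_real = .mult_noise(m$eps_real, noise_sd),
                            eps_imag = .mult_noise(m$eps_imag, noise_sd),
                            temperature = temperature, time = time)
  attr(sp, "ground_truth") <- list(
    model = "havriliak_negami",
    hn = list(delta_eps = delta_eps, tau_hn = tau_hn, a = a, b = b,
              eps_inf = eps_inf, sigma_dc = sigma_dc),
    tau_alpha = hn_peak_time(list(tau_hn = tau_hn, a = a, b = b)),
    noise_sd = noise_sd, seed = seed, frequencies = frequencies)
  sp
}

## Crystallized-fraction kernel on either axis (time in s or kelvin above
## onset).  Returns 0 below the onset.
.cryst_fraction <- function(x, onset, k, n, x_max = 1) {
  dx <- pmax(0, x - onset)
  x_max * (1 - exp(-k * dx^n))
}

## 1 - X(t) computed without cancellation (X -> 1 underflows 1 - X to 0).
.amorphous_fraction <- function(x, onset, k, n, x_max = 1) {
  dx <- pmax(0, x - onset)
  (1 - x_max) + x_max * exp(-k * dx^n)
}

.check_kernel <- function(kernel) {
  k <- utils::modifyList(list(onset = 0, k = 1, n = 1, x_max = 1), kernel)
  if (k$onset < 0) stop("kernel 'onset' must be >= 0", call. = FALSE)
  if (k$k < 0) stop("kernel rate 'k' must be >= 0", call. = FALSE)
  if (k$n <= 0) stop("kernel exponent 'n' must be > 0", call. = FALSE)
  if (k$x_max <= 0 || k$x_max > 1)
    stop("kernel 'x_max' must lie in (0, 1]", call. = FALSE)
  k
}

#' Generate a VFT-governed temperature series of spectra
#'
#' Per-temperature spectra whose true HN time follows the VFT law
#' \eqn{\tau(T) = \tau_\infty\exp(B/(T - T_0))}, with dielectric strength
#' \eqn{\Delta\varepsilon(T) = A/T} (thermal agitation, Langevin) below the
#' programmed crystallization onset and \eqn{A/T\,(1 - X(T))} above it,
#' where \eqn{X} is the crystallized-fraction kernel.
#'
#' @param vft Named list `tau_inf` (s), `B` (K), `T0` (K).
#' @param A Dielectric-strength amplitude in kelvin units
#'   (\eqn{\Delta\varepsilon = A/T}).
#' @param eps_inf High-frequency permittivity.
#' @param sigma_dc dc conductivity in S/m (default 0).
#' @param tc_true Programmed crystallization-onset temperature in kelvin;
#'   `Inf` (default) disables crystallization.
#' @param kernel Crystallized-fraction kernel above `tc_true`: list with
#'   rate `k` (default 0.5, per kelvin^n), exponent `n` (default 2) and cap
#'   `x_max` in (0, 1] (default 1).  The default is a sharp collapse, as
#'   recrystallization appears in scans.
#' @param temp_grid Temperatures in kelvin, strictly increasing, all above
#'   `T0` (a temperature at or below `T0` is a domain error: the VFT law
#'   diverges there).
#' @param freq_grid Frequency grid in Hz.
#' @param shape HN shape exponents, list `a`, `b` (default 0.8, 0.6).
#' @param noise_sd Relative noise (default 0).
#' @param seed Global integer seed; per-spectrum substreams are derived
#'   deterministically from (seed, index).
#' @return A wide-band [spectrum_series] with a [ground_truth()] manifest
#'   recording, per temperature, the true HN parameters and
#'   \eqn{\tau_\alpha}.
#' @export
generate_temperature_series <- function(vft, A, eps_inf, sigma_dc = 0,
                                        tc_true = Inf, kernel = list(),
                                        temp_grid, freq_grid,
                                        shape = list(a = 0.8, b = 0.6),
                                        noise_sd = 0, seed = 1L) {
  .assert_number(A, "A", positive = TRUE)
  if (any(temp_grid <= vft$T0))
    stop(sprintf("temperatures must exceed T0 = %.4g K (VFT divergence)",
                 vft$T0), call. = FALSE)
  kern <- .check_kernel(utils::modifyList(list(k = 0.5, n = 2), kernel))
  a <- shape$a %||% 0.8
  b <- shape$b %||% 0.6
  tau_true <- eval_vft(vft, temp_grid)
  X <- if (is.finite(tc_true))
    .cryst_fraction(temp_grid, tc_true, kern$k, kern$n, kern$x_max)
  else rep(0, length(temp_grid))
  amorph <- if (is.finite(tc_true))
    .amorphous_fraction(temp_grid, tc_true, kern$k, kern$n, kern$x_max)
  else rep(1, length(temp_grid))
  deps_true <- (A / temp_grid) * amorph
  spectra <- vector("list", length(temp_grid))
  hn_by_condition <- vector("list", length(temp_grid))
  for (i in seq_along(temp_grid)) {
    sub <- .substream(seed, i)
    spectra[[i]] <- generate_spectrum(deps_true[i], tau_true[i], a, b,
                                      eps_inf, sigma_dc, freq_grid,
                                      temperature = temp_grid[i],
                                      noise_sd = noise_sd, seed = sub)
    hn_by_condition[[i]] <- list(temperature = temp_grid[i],
                                 delta_eps = deps_true[i],
                                 tau_hn = tau_true[i], a = a, b = b,
                                 eps_inf = eps_inf, sigma_dc = sigma_dc,
                                 tau_alpha = hn_peak_time(
                                   list(tau_hn = tau_true[i], a = a, b = b)),
                                 crystallized_fraction = X[i],
                                 seed = sub)
  }
  series <- spectrum_series(spectra, axis = "temperature")
  attr(series, "ground_truth") <- list(
    model = "vft_temperature_series", vft = vft, A = A, eps_inf = eps_inf,
    sigma_dc = sigma_dc, tc_true = tc_true, kernel = kern,
    shape = list(a = a, b = b), temp_grid = temp_grid,
    freq_grid = freq_grid, noise_sd = noise_sd, seed = seed,
    hn_by_condition = hn_by_condition)
  series
}

#' Generate a single-frequency temperature scan
#'
#' \eqn{\varepsilon'} at one fixed frequency (1 kHz by default) along a
#' heating ramp, evaluated from the same forward model as
#' [generate_temperature_series()]: below the glass transition the scan
#' sits at \eqn{\varepsilon_\infty}, steps up to the static permittivity
#' where the relaxation crosses the measurement frequency, decays as
#' \eqn{A/T}, and collapses above the programmed crystallization onset.
#'
#' @inheritParams generate_temperature_series
#' @param frequency Fixed measurement frequency in Hz (default 1000).
#' @return A single-frequency [spectrum_series] with a manifest.
#' @export
generate_single_frequency_scan <- function(vft, A, eps_inf, tc_true = Inf,
                                           kernel = list(), temp_grid,
                                           frequency = 1e3,
                                           shape = list(a = 0.8, b = 0.6),
                                           noise_sd = 0, seed = 1L) {
  .assert_number(A, "A", positive = TRUE)
  if (any(temp_grid <= vft$T0))
    stop(sprintf("temperatures must exceed T0 = %.4g K (VFT divergence)",
                 vft$T0), call. = FALSE)
  kern <- .check_kernel(utils::modifyList(list(k = 0.5, n = 2), kernel))
  a <- shape$a %||% 0.8
  b <- shape$b %||% 0.6
  tau_true <- eval_vft(vft, temp_grid)
  amorph <- if (is.finite(tc_true))
    .amorphous_fraction(temp_grid, tc_true, kern$k, kern$n, kern$x_max)
  else rep(1, length(temp_grid))
  deps_true <- (A / temp_grid) * amorph
  eps_real <- vapply(seq_along(temp_grid), function(i)
    .hn_complex(frequency, deps_true[i], tau_true[i], a, b, eps_inf,
                0)$eps_real, numeric(1))
  set.seed(seed)
  eps_real <- .mult_noise(eps_real, noise_sd)
  series <- spectrum_series(axis = "temperature", fixed_frequency = frequency,
                            scan = data.frame(temperature = temp_grid,
                                              eps_real = eps_real))
  attr(series, "ground_truth") <- list(
    model = "single_frequency_scan", vft = vft, A = A, eps_inf = eps_inf,
    tc_true = tc_true, kernel = kern, shape = list(a = a, b = b),
    temp_grid = temp_grid, frequency = frequency, noise_sd = noise_sd,
    seed = seed)
  series
}

#' Generate an isothermal crystallization trace
#'
#' \deqn{\varepsilon'(t) = \varepsilon'(\infty) +
#'   [\varepsilon'(0) - \varepsilon'(\infty)]\,[1 - X(t)],}
#' with the stretched-exponential kernel
#' \eqn{X(t) = x_{max}[1 - \exp(-k\,\max(0, t - t_{onset})^n)]}; the trace
#' is flat at \eqn{\varepsilon'(0)} before the onset.  With the default
#' cap \eqn{x_{max} = 1} this is exactly
#' \eqn{\varepsilon'(\infty) + [\varepsilon'(0) - \varepsilon'(\infty)]
#' \exp(-k (t - t_{onset})^n)} after the onset; a cap below 1 models
#' incomplete crystallization, leaving the observed plateau above
#' \eqn{\varepsilon'(\infty)} (a saturated residual amorphous phase).
#'
#' @param eps0 Initial static permittivity \eqn{\varepsilon'(0)}; must
#'   exceed `eps_inf`.
#' @param eps_inf High-frequency limit \eqn{\varepsilon'(\infty)}.
#' @param kernel List `t_onset` (s, >= 0), `k` (> 0), `n` (> 0), `x_max`
#'   in (0, 1] (default 1).
#' @param time_grid Times in seconds, strictly increasing.
#' @param frequency Fixed measurement frequency label in Hz.
#' @param noise_sd Relative noise (default 0).
#' @param seed Integer seed.
#' @return A [crystallization_trace] (time axis) with stored references
#'   and a [ground_truth()] manifest.
#' @export
generate_isothermal_trace <- function(eps0, eps_inf,
                                      kernel = list(t_onset = 0, k = 1e-4, n = 1.5),
                                      time_grid, frequency = 1e3,
                                      noise_sd = 0, seed = 1L) {
  .assert_number(eps0, "eps0"); .assert_number(eps_inf, "eps_inf")
  if (eps0 <= eps_inf) stop("'eps0' must exceed 'eps_inf'", call. = FALSE)
  kern <- .check_kernel(utils::modifyList(list(onset = kernel$t_onset %||% 0),
                                          kernel[setdiff(names(kernel), "t_onset")]))
  if (kern$k <= 0) stop("kernel rate 'k' must be > 0", call. = FALSE)
  eps_real <- eps_inf + (eps0 - eps_inf) *
    .amorphous_fraction(time_grid, kern$onset, kern$k, kern$n, kern$x_max)
  set.seed(seed)
  eps_real <- .mult_noise(eps_real, noise_sd)
  tr <- crystallization_trace(time_grid, eps_real, axis = "time",
                              frequency = frequency, eps0 = eps0,
                              eps_inf_limit = eps_inf)
  attr(tr, "ground_truth") <- list(
    model = "isothermal_avrami_trace", eps0 = eps0, eps_inf = eps_inf,
    kernel = list(t_onset = kern$onset, k = kern$k, n = kern$n,
                  x_max = kern$x_max),
    time_grid = time_grid, frequency = frequency, noise_sd = noise_sd,
    seed = seed)
  tr
}

#' Generate a synthetic glass-transition versus composition table
#'
#' Evaluates the Gordon-Taylor forward model on a grid of polymer weight
#' fractions and adds Gaussian noise in kelvin.
#'
#' @param gt_model A [gt_model].
#' @param w2_grid Polymer weight fractions in \[0, 1\].
#' @param noise_sd_K Noise standard deviation in kelvin (default 0).
#' @param seed Integer seed.
#' @return A `composition_table` data frame (`w2`, `tg`, `method`) with a
#'   [ground_truth()] manifest.
#' @export
generate_tg_composition <- function(gt_model, w2_grid, noise_sd_K = 0,
                                    seed = 1L) {
  tg <- gt_predict(gt_model, w2_grid)
  set.seed(seed)
  if (noise_sd_K > 0) tg <- tg + stats::rnorm(length(tg), sd = noise_sd_K)
  out <- data.frame(w2 = w2_grid, tg = tg, method = "synthetic")
  class(out) <- c("composition_table", "data.frame")
  attr(out, "ground_truth") <- list(
    model = "gordon_taylor", tg1 = gt_model$tg1, tg2 = gt_model$tg2,
    K = gt_model$k, w2_grid = w2_grid, noise_sd_K = noise_sd_K, seed = seed)
  out
}
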