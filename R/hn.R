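## Havriliak-Negami spectral fitting and alpha-relaxation peak times.

## Complex HN + conductivity forward model.  Physics sign convention
## eps* = eps' - i eps'': the HN term Delta_eps / (1 + (i w tau)^a)^b has a
## negative imaginary part, so eps'' = -Im(term) + sigma_dc/(eps0 w) >= 0.
.hn_complex <- function(frequency, delta_eps, tau_hn, a, b, eps_inf, sigma_dc) {
  w <- 2 * pi * frequency
  hn <- delta_eps / (1 + (1i * w * tau_hn)^a)^b
  list(eps_real = eps_inf + Re(hn),
       eps_imag = -Im(hn) + if (sigma_dc > 0) sigma_dc / (.eps0 * w) else 0)
}

.check_hn_params <- function(delta_eps, tau_hn, a, b, eps_inf, sigma_dc) {
  .assert_number(delta_eps, "delta_eps", positive = TRUE)
  .assert_number(tau_hn, "tau_hn", positive = TRUE)
  .assert_number(a, "a"); .assert_number(b, "b")
  if (a <= 0 || a > 1) stop("'a' must lie in (0, 1]", call. = FALSE)
  if (b <= 0 || b > 1) stop("'b' must lie in (0, 1]", call. = FALSE)
  .assert_number(eps_inf, "eps_inf")
  .assert_number(sigma_dc, "sigma_dc")
  if (sigma_dc < 0) stop("'sigma_dc' must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the Havriliak-Negami function with dc conductivity
#'
#' Evaluates
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon}{[1 + (i\omega\tau_{HN})^a]^b} +
#'   \frac{\sigma_{dc}}{\varepsilon_0 i \omega}, \quad \omega = 2\pi f,}
#' returning \eqn{\varepsilon'} and \eqn{\varepsilon''} under the physics
#' convention \eqn{\varepsilon^* = \varepsilon' - i\varepsilon''} (so the
#' loss is non-negative for admissible parameters).
#'
#' @param fit An [hn_fit] object, or a named list with elements
#'   `delta_eps`, `tau_hn`, `a`, `b`, `eps_inf`, `sigma_dc`.
#' @param frequencies Frequencies in Hz (strictly positive).
#' @return A data frame with columns `frequency`, `eps_real`, `eps_imag`.
#' @examples
#' eval_hn(list(delta_eps = 5, tau_hn = 1e-3, a = 1, b = 1,
#'              eps_inf = 3, sigma_dc = 0),
#'         frequencies = 1 / (2 * pi * 1e-3))  # Debye at omega*tau = 1
#' @export
eval_hn <- function(fit, frequencies) {
  p <- if (inherits(fit, "hn_fit")) fit$par else fit
  .check_hn_params(p$delta_eps, p$tau_hn, p$a, p$b, p$eps_inf, p$sigma_dc)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0))
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  m <- .hn_complex(frequencies, p$delta_eps, p$tau_hn, p$a, p$b, p$eps_inf,
                   p$sigma_dc)
  data.frame(frequency = frequencies, eps_real = m$eps_real,
             eps_imag = m$eps_imag)
}

#' Alpha-relaxation peak time from Havriliak-Negami parameters
#'
#' Converts the fitted HN time \eqn{\tau_{HN}} to the reciprocal of the
#' loss-peak angular frequency,
#' \deqn{\tau_\alpha = \tau_{HN}
#'   \left[\sin\frac{\pi a}{2 + 2b}\right]^{-1/a}
#'   \left[\sin\frac{\pi a b}{2 + 2b}\right]^{1/a}.}
#' This is the standard peak-time expression: it reduces to
#' \eqn{\tau_\alpha = \tau_{HN}} in the Debye limit (a = b = 1) and to the
#' Cole-Davidson closed form \eqn{\omega_{max}\tau = \tan(\pi/(2b + 2))}
#' at a = 1, and it agrees with dense numeric maximization of the HN loss
#' (the reciprocal exponent convention sometimes seen in print fails both
#' checks).
#'
#' @param fit An [hn_fit] object, or a named list with `tau_hn`, `a`, `b`.
#' @return Peak relaxation time \eqn{\tau_\alpha} in seconds.
#' @export
hn_peak_time <- function(fit) {
  p <- if (inherits(fit, "hn_fit")) fit$par else fit
  if (!is.finite(p$a) || p$a <= 0 || p$a > 1) stop("'a' must lie in (0, 1]", call. = FALSE)
  if (!is.finite(p$b) || p$b <= 0 || p$b > 1) stop("'b' must lie in (0, 1]", call. = FALSE)
  .assert_number(p$tau_hn, "tau_hn", positive = TRUE)
  p$tau_hn * sin(pi * p$a / (2 + 2 * p$b))^(-1 / p$a) *
    sin(pi * p$a * p$b / (2 + 2 * p$b))^(1 / p$a)
}

## Index of an interior maximum of y, or NA if the maximum sits on either
## boundary of the grid.
.interior_peak <- function(y) {
  i <- which.max(y)
  if (i == 1L || i == length(y)) NA_integer_ else i
}

## Does log(loss) vs log(omega) look like a pure -1 power law (dc
## conduction with no resolvable relaxation)?
.conductivity_dominated <- function(frequency, loss) {
  ok <- loss > 0
  if (sum(ok) < 4L) return(FALSE)
  x <- log(2 * pi * frequency[ok]); y <- log(loss[ok])
  f <- stats::lm.fit(cbind(1, x), y)
  slope <- f$coefficients[2L]
  r2 <- 1 - sum(f$residuals^2) / max(sum((y - mean(y))^2), 1e-300)
  abs(slope + 1) < 0.1 && r2 > 0.995
}

.hn_fit_obj <- function(par, residual, converged, identifiable, mode,
                        spectrum, message = NULL, eps_inf_source = "fitted") {
  structure(list(par = par, residual = residual, converged = converged,
                 identifiable = identifiable, mode = mode,
                 eps_inf_source = eps_inf_source, spectrum = spectrum,
                 message = message),
            class = "hn_fit")
}

#' Fit the Havriliak-Negami function to a dielectric spectrum
#'
#' Least-squares fit of the HN function with a dc-conductivity term.  The
#' default objective (`mode = "loss_only"`) minimizes residuals on
#' \eqn{\log\varepsilon''}, appropriate because the loss spans decades; the
#' `"complex"` mode jointly fits relative residuals on \eqn{\varepsilon'}
#' and log residuals on \eqn{\varepsilon''}, and additionally estimates
#' \eqn{\varepsilon_\infty} (which the loss alone does not constrain).
#' Optimization uses Levenberg-Marquardt with box bounds
#' (\code{minpack.lm::nls.lm}) on the transformed parameters
#' \eqn{(\log_{10}\Delta\varepsilon, \log_{10}\tau_{HN}, a, b,
#' \log_{10}\sigma_{dc}[, \varepsilon_\infty])}.
#'
#' Initialization, when `init` is absent, reads \eqn{\tau_{HN}} off the
#' observed interior loss peak (Debye assumption), takes
#' \eqn{\Delta\varepsilon} as twice the peak height and a = b = 0.8.  If no
#' interior peak is visible even after subtracting an estimated conduction
#' limb, the fit either errors (no initialization possible) or - when the
#' loss is a clean \eqn{\omega^{-1}} power law, i.e. conduction with no
#' resolvable relaxation - returns a result flagged non-identifiable
#' rather than an exception.
#'
#' @param spectrum A [dielectric_spectrum] with at least 6 frequency
#'   points; `mode = "loss_only"` requires `eps_imag`.
#' @param mode `"loss_only"` (default) or `"complex"`.
#' @param bounds Optional named list overriding box bounds: elements among
#'   `a`, `b` (length-2 ranges within (0, 1]), `eps_inf_min` (default 1),
#'   `sigma_max` (S/m).
#' @param init Optional named list of starting values (`delta_eps`,
#'   `tau_hn`, `a`, `b`, `sigma_dc`, `eps_inf`).
#' @param control Passed to [minpack.lm::nls.lm()].
#' @return An object of class `hn_fit` with components `par` (named list:
#'   `delta_eps`, `tau_hn`, `a`, `b`, `eps_inf`, `sigma_dc`), `residual`
#'   (sum of squared objective residuals), `converged`, `identifiable`.
#' @seealso [eval_hn()], [hn_peak_time()], [extract_relaxation_map()]
#' @export
fit_hn <- function(spectrum, mode = c("loss_only", "complex"),
                   bounds = list(), init = NULL,
                   control = minpack.lm::nls.lm.control(maxiter = 500,
                                                        ftol = 1e-15,
                                                        ptol = 1e-15)) {
  mode <- match.arg(mode)
  if (!inherits(spectrum, "dielectric_spectrum"))
    stop("'spectrum' must be a dielectric_spectrum", call. = FALSE)
  if (length(spectrum$frequency) < 6L)
    stop("need at least 6 frequency points", call. = FALSE)
  if (is.null(spectrum$eps_imag))
    stop("fitting requires the dielectric loss 'eps_imag'", call. = FALSE)
  if (mode == "complex" && is.null(spectrum$eps_real))
    stop("mode = 'complex' requires 'eps_real'", call. = FALSE)

  freq <- spectrum$frequency
  w <- 2 * pi * freq
  loss <- spectrum$eps_imag
  a_rng <- bounds$a %||% c(1e-3, 1)
  b_rng <- bounds$b %||% c(1e-3, 1)
  eps_inf_min <- bounds$eps_inf_min %||% 1
  sigma_max <- bounds$sigma_max %||% 1e5

  ## ---- initialization -------------------------------------------------
  sigma0 <- 0
  ipk <- .interior_peak(loss)
  if (is.null(init) && is.na(ipk)) {
    nlow <- min(5L, length(freq))
    sigma_cand <- stats::median(loss[seq_len(nlow)] * .eps0 * w[seq_len(nlow)])
    cond <- sigma_cand / (.eps0 * w)
    resid_loss <- loss - cond
    ## search for the relaxation peak only where conduction is subdominant
    cand <- which(cond < 0.5 * loss)
    j <- NA_integer_
    if (length(cand)) {
      jj <- cand[which.max(resid_loss[cand])]
      if (jj > 1L && jj < length(loss)) j <- jj
    }
    if (!.conductivity_dominated(freq, loss) && !is.na(j) && resid_loss[j] > 0) {
      ipk <- j
      sigma0 <- sigma_cand
      loss_for_init <- resid_loss
    } else if (.conductivity_dominated(freq, loss)) {
      par <- list(delta_eps = NA_real_, tau_hn = NA_real_, a = NA_real_,
                  b = NA_real_, eps_inf = NA_real_, sigma_dc = sigma_cand)
      return(.hn_fit_obj(par, NA_real_, FALSE, FALSE, mode, spectrum,
                         message = paste("loss is a pure dc-conduction power law;",
                                         "relaxation strength not identifiable"),
                         eps_inf_source = "none"))
    } else {
      stop("no interior loss maximum found; supply 'init'", call. = FALSE)
    }
  } else {
    loss_for_init <- loss
  }
  if (is.null(init)) {
    ## dc conduction shows up as a decaying low-frequency limb steeper than
    ## the HN loss wing; seed sigma from the lowest point when present.
    if (sigma0 == 0 && length(freq) >= 4L && ipk >= 4L) {
      lf <- seq_len(min(4L, ipk - 1L))
      if (length(lf) >= 3L) {
        sl <- stats::lm.fit(cbind(1, log(w[lf])), log(pmax(loss[lf], 1e-300)))$coefficients[2L]
        if (is.finite(sl) && sl < -0.8) sigma0 <- loss[1L] * .eps0 * w[1L]
      }
    }
    tau0 <- 1 / w[ipk]
    deps0 <- 2 * loss_for_init[ipk]
    init <- list(delta_eps = deps0, tau_hn = tau0, a = 0.8, b = 0.8,
                 sigma_dc = sigma0)
  } else {
    if (is.null(init$delta_eps) || is.null(init$tau_hn))
      stop("'init' must supply at least 'delta_eps' and 'tau_hn'", call. = FALSE)
    init <- utils::modifyList(list(a = 0.8, b = 0.8, sigma_dc = 0), init)
  }
  eps_inf0 <- init$eps_inf %||%
    (if (!is.null(spectrum$eps_real)) max(eps_inf_min, min(spectrum$eps_real))
     else max(eps_inf_min, 3))
  l10sig0 <- log10(max(init$sigma_dc %||% 0, 1e-30))

  ## ---- objective ------------------------------------------------------
  use <- loss > 0
  if (sum(use) < 6L) stop("need at least 6 positive loss values", call. = FALSE)
  fobs <- freq[use]; lobs <- log(loss[use])
  robs <- if (mode == "complex") spectrum$eps_real[use]
  resid_fun <- function(p) {
    eps_inf <- if (mode == "complex") p[6L] else eps_inf0
    m <- .hn_complex(fobs, 10^p[1L], 10^p[2L], p[3L], p[4L], eps_inf, 10^p[5L])
    r <- log(pmax(m$eps_imag, 1e-300)) - lobs
    if (mode == "complex") r <- c(r, (m$eps_real - robs) / robs)
    r
  }
  p0 <- c(log10(init$delta_eps), log10(init$tau_hn),
          min(max(init$a %||% 0.8, a_rng[1L]), a_rng[2L]),
          min(max(init$b %||% 0.8, b_rng[1L]), b_rng[2L]), l10sig0)
  lower <- c(-8, -15, a_rng[1L], b_rng[1L], -30)
  upper <- c(8, 8, a_rng[2L], b_rng[2L], log10(sigma_max))
  if (mode == "complex") {
    p0 <- c(p0, eps_inf0)
    lower <- c(lower, eps_inf_min)
    upper <- c(upper, Inf)
  }
  fit <- minpack.lm::nls.lm(par = p0, lower = lower, upper = upper,
                            fn = resid_fun, control = control)
  p <- fit$par
  par <- list(delta_eps = 10^p[1L], tau_hn = 10^p[2L], a = p[3L], b = p[4L],
              eps_inf = if (mode == "complex") p[6L] else eps_inf0,
              sigma_dc = 10^p[5L])
  if (par$sigma_dc < 1e-25) par$sigma_dc <- 0
  converged <- fit$info %in% 1:4 && is.finite(fit$deviance)
  .hn_fit_obj(par, fit$deviance, converged, TRUE, mode, spectrum,
              message = fit$message,
              eps_inf_source = if (mode == "complex") "fitted"
                               else if (!is.null(spectrum$eps_real)) "eps_real minimum"
                               else "default")
}

#' @export
print.hn_fit <- function(x, ...) {
  cat("<hn_fit>", if (!x$identifiable) "NON-IDENTIFIABLE"
      else if (!x$converged) "NOT CONVERGED" else "converged", "\n")
  if (x$identifiable) {
    with(x$par, cat(sprintf(
      "  delta_eps = %.4g, tau_hn = %.4g s, a = %.3f, b = %.3f\n  eps_inf = %.4g (%s), sigma_dc = %.3g S/m\n",
      delta_eps, tau_hn, a, b, eps_inf, x$eps_inf_source, sigma_dc)))
    cat(sprintf("  tau_alpha (peak time) = %.4g s, objective = %.3g (%s)\n",
                hn_peak_time(x), x$residual, x$mode))
  } else if (!is.null(x$message)) cat(" ", x$message, "\n")
  invisible(x)
}

#' @export
coef.hn_fit <- function(object, ...) {
  unlist(object$par)
}

#' @export
predict.hn_fit <- function(object, frequencies = NULL, ...) {
  if (!object$identifiable)
    stop("cannot predict from a non-identifiable fit", call. = FALSE)
  frequencies <- frequencies %||% object$spectrum$frequency
  eval_hn(object, frequencies)
}

#' @export
residuals.hn_fit <- function(object, ...) {
  if (!object$identifiable)
    stop("no residuals for a non-identifiable fit", call. = FALSE)
  m <- eval_hn(object, object$spectrum$frequency)
  obs <- object$spectrum$eps_imag
  ok <- obs > 0
  r <- rep(NA_real_, length(obs))
  r[ok] <- log(m$eps_imag[ok]) - log(obs[ok])
  r
}

#' @export
plot.hn_fit <- function(x, ...) {
  sp <- x$spectrum
  graphics::plot(sp$frequency, sp$eps_imag, log = "xy",
                 xlab = "frequency (Hz)",
                 ylab = expression(epsilon * minute * minute),
                 main = sprintf("HN fit, T = %.1f K", sp$temperature), ...)
  if (x$identifiable) {
    fgrid <- 10^seq(log10(min(sp$frequency)), log10(max(sp$frequency)),
                    length.out = 300)
    graphics::lines(fgrid, eval_hn(x, fgrid)$eps_imag, col = 2)
  }
  invisible(x)
}

#' Extract the alpha-relaxation map from a wide-band series
#'
#' Fits every spectrum of a wide-band [spectrum_series] with [fit_hn()] and
#' converts each fitted \eqn{\tau_{HN}} to the peak time \eqn{\tau_\alpha}
#' via [hn_peak_time()].  Spectra that fail to fit (no interior peak,
#' non-convergence, non-identifiable conduction-only loss) are skipped and
#' recorded, never silently interpolated.  When `drop_crystallized` is
#' `TRUE` the dielectric strengths are screened with [detect_onset()]
#' (baseline \eqn{\Delta\varepsilon \propto 1/T}) and fits at or above a
#' detected crystallization onset are excluded from the returned map.
#'
#' @param series Wide-band [spectrum_series] (temperature axis).
#' @param mode,bounds Passed to [fit_hn()].
#' @param drop_crystallized Screen out spectra whose dielectric strength
#'   has collapsed by crystallization (default `TRUE`).
#' @param onset_threshold Relative dielectric-strength shortfall treated
#'   as collapse (default 0.1).
#' @return A data frame of class `relaxation_map` with columns
#'   `temperature`, `tau_alpha`, `delta_eps`, `tau_hn`, `a`, `b`;
#'   attributes `fits` (the underlying `hn_fit` objects), `skipped`
#'   (reasons per skipped spectrum) and `onset` (the [detect_onset()]
#'   result, when screening ran).
#' @export
extract_relaxation_map <- function(series, mode = c("loss_only", "complex"),
                                   bounds = list(), drop_crystallized = TRUE,
                                   onset_threshold = 0.1) {
  mode <- match.arg(mode)
  if (!inherits(series, "spectrum_series") || is_single_frequency(series))
    stop("'series' must be a wide-band spectrum_series", call. = FALSE)
  n <- length(series$spectra)
  fits <- vector("list", n)
  skipped <- list()
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- series$spectra[[i]]
    f <- tryCatch(fit_hn(sp, mode = mode, bounds = bounds),
                  error = function(e) e)
    if (inherits(f, "error")) {
      skipped[[length(skipped) + 1L]] <- list(index = i,
                                              temperature = sp$temperature,
                                              reason = conditionMessage(f))
      next
    }
    fits[[i]] <- f
    if (!f$identifiable || !f$converged) {
      skipped[[length(skipped) + 1L]] <- list(
        index = i, temperature = sp$temperature,
        reason = if (!f$identifiable) "non-identifiable" else "not converged")
      next
    }
    ## a trustworthy tau requires the loss peak inside the measured window
    fpk <- 1 / (2 * pi * hn_peak_time(f))
    if (fpk < min(sp$frequency) || fpk > max(sp$frequency)) {
      skipped[[length(skipped) + 1L]] <- list(
        index = i, temperature = sp$temperature,
        reason = "loss peak outside the measured frequency window")
      next
    }
    rows[[i]] <- data.frame(temperature = sp$temperature,
                            tau_alpha = hn_peak_time(f),
                            delta_eps = f$par$delta_eps,
                            tau_hn = f$par$tau_hn, a = f$par$a, b = f$par$b)
  }
  map <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(map) || nrow(map) == 0L)
    stop("no spectrum in the series could be fitted", call. = FALSE)
  map <- map[order(map$temperature), , drop = FALSE]
  onset <- NULL
  if (drop_crystallized && nrow(map) >= 6L) {
    onset <- tryCatch(
      detect_onset(data.frame(temperature = map$temperature,
                              delta_eps = map$delta_eps),
                   threshold = onset_threshold),
      error = function(e) NULL)
    if (!is.null(onset) && isTRUE(onset$detected)) {
      cryst <- map$temperature >= onset$onset
      for (tcr in map$temperature[cryst])
        skipped[[length(skipped) + 1L]] <- list(index = NA_integer_,
                                                temperature = tcr,
                                                reason = "crystallized (dielectric strength collapsed)")
      map <- map[!cryst, , drop = FALSE]
    }
  }
  rownames(map) <- NULL
  structure(map, class = c("relaxation_map", "data.frame"),
            fits = fits, skipped = skipped, onset = onset)
}

#' @export
plot.relaxation_map <- function(x, ...) {
  graphics::plot(1000 / x$temperature, log10(x$tau_alpha),
                 xlab = "1000 / T (1/K)",
                 ylab = expression(log[10] * tau[alpha] ~ "(s)"),
                 main = "relaxation map", ...)
  invisible(x)
}
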