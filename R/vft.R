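## Vogel-Fulcher-Tammann analysis of the alpha-relaxation map.

#' Fit the Vogel-Fulcher-Tammann law to a relaxation map
#'
#' Fits \eqn{\tau_\alpha(T) = \tau_\infty \exp(B / (T - T_0))} by least
#' squares on \eqn{\log_{10}\tau} with unit weights (the relaxation time
#' spans many decades, so linear-time residuals would be dominated by the
#' slowest points).  The Vogel temperature is first located by profiling:
#' for fixed \eqn{T_0} the model is linear in \eqn{1/(T - T_0)}, so a 1-D
#' search over \eqn{T_0} with an embedded linear fit provides the start,
#' which a bounded Levenberg-Marquardt step then polishes.  The parameter
#' covariance (on \eqn{\log_{10}\tau_\infty, B, T_0}) comes from the final
#' Jacobian.
#'
#' @param points A `relaxation_map` (see [extract_relaxation_map()]) or any
#'   data frame with columns `temperature` (K) and `tau_alpha` (s; a column
#'   named `tau` is also accepted).  At least 4 points spanning at least
#'   two decades in \eqn{\tau} are required.
#' @param control Passed to [minpack.lm::nls.lm()].
#' @return An object of class `vft_fit` with components `tau_inf` (s),
#'   `B` (K), `T0` (K), `covariance` (3x3, on \eqn{\log_{10}\tau_\infty,
#'   B, T_0}), `residual` (sum of squared log10 residuals), `converged`,
#'   `t0_bounded` (flag: \eqn{T_0} pushed to its lower bound, i.e. the data
#'   are Arrhenius-like), and `data`.
#' @examples
#' tr <- list(tau_inf = 1e-14, B = 2000, T0 = 250)
#' temps <- seq(290, 330, length.out = 10)
#' map <- data.frame(temperature = temps, tau_alpha = eval_vft(tr, temps))
#' fit <- fit_vft(map)
#' tg_from_vft(fit)
#' @export
fit_vft <- function(points,
                    control = minpack.lm::nls.lm.control(maxiter = 500,
                                                         ftol = 1e-15,
                                                         ptol = 1e-15)) {
  df <- as.data.frame(points)
  if (!"tau_alpha" %in% names(df) && "tau" %in% names(df))
    df$tau_alpha <- df$tau
  if (!all(c("temperature", "tau_alpha") %in% names(df)))
    stop("'points' needs columns temperature and tau_alpha", call. = FALSE)
  df <- df[is.finite(df$temperature) & is.finite(df$tau_alpha) &
             df$tau_alpha > 0, , drop = FALSE]
  if (nrow(df) < 4L)
    stop("under-determined: need at least 4 relaxation points", call. = FALSE)
  lt <- log10(df$tau_alpha)
  if (diff(range(lt)) < 2)
    stop("under-determined: relaxation times must span at least 2 decades",
         call. = FALSE)
  temp <- df$temperature
  t0_lo <- 1e-3
  t0_hi <- min(temp) - 1e-3

  prof_rss <- function(T0) {
    x <- 1 / (temp - T0)
    sum(stats::lm.fit(cbind(1, x), lt)$residuals^2)
  }
  opt <- stats::optimize(prof_rss, c(t0_lo, t0_hi), tol = 1e-8)
  T00 <- opt$minimum
  cf <- stats::lm.fit(cbind(1, 1 / (temp - T00)), lt)$coefficients
  p0 <- c(cf[1L], max(cf[2L] * log(10), 1e-6), T00)

  resid_fun <- function(p) p[1L] + p[2L] / (log(10) * (temp - p[3L])) - lt
  fit <- minpack.lm::nls.lm(par = unname(p0), fn = resid_fun,
                            lower = c(-60, 1e-6, t0_lo),
                            upper = c(20, 1e7, t0_hi), control = control)
  p <- unname(fit$par)
  ## covariance from the final Jacobian, sigma^2 = RSS / (n - 3)
  jac <- matrix(0, nrow(df), 3L)
  h <- pmax(abs(p), 1) * 1e-7
  for (k in 1:3) {
    pp <- p; pp[k] <- pp[k] + h[k]
    pm <- p; pm[k] <- pm[k] - h[k]
    jac[, k] <- (resid_fun(pp) - resid_fun(pm)) / (2 * h[k])
  }
  covmat <- tryCatch({
    s2 <- fit$deviance / max(nrow(df) - 3L, 1L)
    s2 * solve(crossprod(jac))
  }, error = function(e) matrix(NA_real_, 3L, 3L))
  dimnames(covmat) <- rep(list(c("log10_tau_inf", "B", "T0")), 2L)

  structure(list(tau_inf = 10^p[1L], B = p[2L], T0 = p[3L],
                 log10_tau_inf = p[1L], covariance = covmat,
                 residual = fit$deviance,
                 converged = fit$info %in% 1:4 && is.finite(fit$deviance),
                 t0_bounded = (p[3L] - t0_lo) < 1e-2,
                 data = df[, c("temperature", "tau_alpha")]),
            class = "vft_fit")
}

#' Evaluate the VFT law
#'
#' @param fit A [fit_vft()] result, or a named list with `tau_inf` (s),
#'   `B` (K), `T0` (K).
#' @param temperature Temperatures in kelvin, each strictly above `T0`.
#' @return Relaxation times \eqn{\tau_\infty \exp(B/(T - T_0))} in seconds.
#' @export
eval_vft <- function(fit, temperature) {
  .assert_number(fit$tau_inf, "tau_inf", positive = TRUE)
  .assert_number(fit$B, "B", positive = TRUE)
  .assert_number(fit$T0, "T0")
  if (any(!is.finite(temperature)))
    stop("'temperature' must be finite", call. = FALSE)
  if (any(temperature <= fit$T0))
    stop(sprintf("temperature must exceed the Vogel temperature T0 = %.4g K",
                 fit$T0), call. = FALSE)
  fit$tau_inf * exp(fit$B / (temperature - fit$T0))
}

#' Glass-transition temperature from a VFT fit
#'
#' Uses the dielectric convention \eqn{T_g = T(\tau_\alpha = \tau_{ref})}
#' with \eqn{\tau_{ref} = 100} s by default; the closed-form inverse of the
#' VFT law is \eqn{T_g = T_0 + B / \ln(\tau_{ref}/\tau_\infty)}.
#'
#' @param fit A [fit_vft()] result (or compatible list).
#' @param tau_ref Reference relaxation time in seconds (default 100).
#' @return \eqn{T_g} in kelvin.  When `fit` carries a covariance, the
#'   result has attributes `sd` (first-order standard error in K) and
#'   `extrapolation_K` (distance below the coldest fitted temperature;
#'   `NA` when the fit carries no data).
#' @export
tg_from_vft <- function(fit, tau_ref = 100) {
  isochronal_temperature(fit, tau = tau_ref)
}

#' Isochronal temperature from a VFT fit
#'
#' Inverts the VFT law to find the temperature at which the relaxation
#' time equals `tau`, e.g. the \eqn{\tau_\alpha = 1.5} ms condition used to
#' compare samples at matched molecular mobility.
#'
#' @param fit A [fit_vft()] result (or compatible list).
#' @param tau Target relaxation time in seconds; must exceed `tau_inf`.
#' @return Temperature in kelvin (see [tg_from_vft()] for attributes).
#' @export
isochronal_temperature <- function(fit, tau) {
  .assert_number(tau, "tau", positive = TRUE)
  .assert_number(fit$tau_inf, "tau_inf", positive = TRUE)
  if (tau <= fit$tau_inf)
    stop("'tau' must exceed tau_inf: no finite solution", call. = FALSE)
  L <- log(tau / fit$tau_inf)
  out <- fit$T0 + fit$B / L
  if (!is.null(fit$covariance) && all(is.finite(fit$covariance))) {
    ## gradient wrt (log10 tau_inf, B, T0): L = ln(tau) - ln(10) l10tinf
    g <- c(fit$B * log(10) / L^2, 1 / L, 1)
    attr(out, "sd") <- sqrt(drop(t(g) %*% fit$covariance %*% g))
  }
  if (!is.null(fit$data))
    attr(out, "extrapolation_K") <- min(fit$data$temperature) - out
  out
}

#' @export
print.vft_fit <- function(x, ...) {
  cat("<vft_fit>", if (!x$converged) "NOT CONVERGED" else "converged",
      if (x$t0_bounded) "(T0 at lower bound: Arrhenius-like)" else "", "\n")
  cat(sprintf("  tau_inf = %.4g s, B = %.6g K, T0 = %.4f K  (n = %d, RSS = %.3g dex^2)\n",
              x$tau_inf, x$B, x$T0, nrow(x$data), x$residual))
  tg <- tg_from_vft(x)
  cat(sprintf("  Tg (tau = 100 s) = %.2f K (se %.2g K, extrapolated %.1f K below data)\n",
              as.numeric(tg), attr(tg, "sd") %||% NA_real_,
              attr(tg, "extrapolation_K") %||% NA_real_))
  invisible(x)
}

#' @export
coef.vft_fit <- function(object, ...) {
  c(tau_inf = object$tau_inf, B = object$B, T0 = object$T0)
}

#' @export
vcov.vft_fit <- function(object, ...) object$covariance

#' @export
predict.vft_fit <- function(object, newdata = NULL, ...) {
  temperature <- if (is.null(newdata)) object$data$temperature
                 else if (is.data.frame(newdata)) newdata$temperature
                 else newdata
  eval_vft(object, temperature)
}

#' @export
residuals.vft_fit <- function(object, ...) {
  log10(object$data$tau_alpha) - log10(predict(object))
}

#' @export
plot.vft_fit <- function(x, ...) {
  graphics::plot(1000 / x$data$temperature, log10(x$data$tau_alpha),
                 xlab = "1000 / T (1/K)",
                 ylab = expression(log[10] * tau[alpha] ~ "(s)"),
                 main = "VFT fit", ...)
  tt <- seq(min(x$data$temperature), max(x$data$temperature), length.out = 200)
  graphics::lines(1000 / tt, log10(eval_vft(x, tt)), col = 2)
  invisible(x)
}
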