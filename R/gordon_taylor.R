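## Gordon-Taylor mixing rule: prediction, K fitting, and inversion of the
## glass-transition versus composition relation.  Component 1 is the drug,
## component 2 the polymer; w2 is the polymer weight fraction throughout.

#' Construct a Gordon-Taylor model
#'
#' The Gordon-Taylor rule predicts a miscible blend's glass transition as
#' \deqn{T_g(w_2) = \frac{(1 - w_2) T_{g1} + K w_2 T_{g2}}
#'                       {(1 - w_2) + K w_2},}
#' where \eqn{T_{g1}}, \eqn{T_{g2}} are the pure-component glass
#' transitions (drug and polymer), \eqn{w_2} the polymer weight fraction,
#' and \eqn{K > 0} a mixing parameter approximable by the ratio of
#' heat-capacity steps, \eqn{K \approx \Delta C_{p2} / \Delta C_{p1}}.
#'
#' @param tg1 Glass transition of the drug (component 1), kelvin.
#' @param tg2 Glass transition of the polymer (component 2), kelvin.
#' @param k Gordon-Taylor parameter, dimensionless, > 0.
#' @return An object of class `gt_model`.
#' @export
gt_model <- function(tg1, tg2, k) {
  .assert_number(tg1, "tg1", positive = TRUE)
  .assert_number(tg2, "tg2", positive = TRUE)
  .assert_number(k, "k", positive = TRUE)
  structure(list(tg1 = as.double(tg1), tg2 = as.double(tg2), k = as.double(k)),
            class = "gt_model")
}

#' @export
print.gt_model <- function(x, ...) {
  cat(sprintf("<gt_model> Tg1 (drug) = %.2f K, Tg2 (polymer) = %.2f K, K = %.4f\n",
              x$tg1, x$tg2, x$k))
  invisible(x)
}

#' Predict the mixture glass transition from composition
#'
#' @param model A [gt_model] (or [fit_gt_k()] result).
#' @param w2 Polymer weight fraction(s) in \[0, 1\].
#' @return Predicted \eqn{T_g} in kelvin, always between the component
#'   glass transitions.
#' @examples
#' gt_predict(gt_model(331, 376, 1), 0.5)  # K = 1: the weighted mean, 353.5
#' @export
gt_predict <- function(model, w2) {
  if (any(!is.finite(w2)) || any(w2 < 0) || any(w2 > 1))
    stop("'w2' must lie in [0, 1]", call. = FALSE)
  w1 <- 1 - w2
  (w1 * model$tg1 + model$k * w2 * model$tg2) / (w1 + model$k * w2)
}

#' Gordon-Taylor K from heat-capacity steps
#'
#' \eqn{K \approx \Delta C_{p2} / \Delta C_{p1}}, the ratio of the polymer
#' and drug heat-capacity increments at their glass transitions.
#'
#' @param dcp1 Heat-capacity step of the drug at its \eqn{T_g}, J/(g K).
#' @param dcp2 Heat-capacity step of the polymer, J/(g K).
#' @return Dimensionless K.
#' @export
gt_k_from_dcp <- function(dcp1, dcp2) {
  .assert_number(dcp1, "dcp1", positive = TRUE)
  .assert_number(dcp2, "dcp2", positive = TRUE)
  dcp2 / dcp1
}

#' Fit the Gordon-Taylor parameter K to measured mixture Tgs
#'
#' Least-squares fit of K (kelvin residuals, unweighted) with the
#' pure-component glass transitions held fixed at their measured values.
#' A single interior point gives the exact one-equation solve.
#'
#' @param points Data frame with columns `w2` and `tg` (K), e.g. from
#'   [read_composition_table()].  Endpoint rows (`w2` of 0 or 1) are
#'   ignored for fitting; at least one interior point is required.
#' @param tg1,tg2 Fixed pure-component glass transitions (drug, polymer).
#' @return An object of classes `gt_fit` and `gt_model`, additionally
#'   carrying `points`, `fitted`, `residuals` (K) and `converged`.
#' @examples
#' pts <- data.frame(w2 = c(0.25, 0.5, 0.75), tg = c(342, 353, 366))
#' fit <- fit_gt_k(pts, tg1 = 331, tg2 = 376)
#' predict(fit, w2 = 0.5)
#' @export
fit_gt_k <- function(points, tg1, tg2) {
  .assert_number(tg1, "tg1", positive = TRUE)
  .assert_number(tg2, "tg2", positive = TRUE)
  if (tg1 == tg2)
    stop("'tg1' and 'tg2' must differ (composition has no effect otherwise)",
         call. = FALSE)
  df <- as.data.frame(points)
  if (!"tg" %in% names(df) && "tg_K" %in% names(df)) df$tg <- df$tg_K
  if (!all(c("w2", "tg") %in% names(df)))
    stop("'points' needs columns w2 and tg", call. = FALSE)
  interior <- df[df$w2 > 0 & df$w2 < 1, , drop = FALSE]
  if (nrow(interior) == 0L)
    stop("under-determined: need at least one interior composition (0 < w2 < 1)",
         call. = FALSE)
  ## per-point exact K as a robust start: from Tg = GT(w2; K),
  ## K = (1 - w2)(tg - tg1) / (w2 (tg2 - tg))
  kpt <- (1 - interior$w2) * (interior$tg - tg1) /
    (interior$w2 * (tg2 - interior$tg))
  k0 <- stats::median(kpt[is.finite(kpt) & kpt > 0])
  if (!is.finite(k0)) k0 <- 1
  gt_at <- function(k, w2) ((1 - w2) * tg1 + k * w2 * tg2) / ((1 - w2) + k * w2)
  fn <- function(lk) interior$tg - gt_at(exp(lk), interior$w2)
  fit <- minpack.lm::nls.lm(par = log(k0), fn = fn,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  k <- exp(fit$par)
  out <- gt_model(tg1, tg2, k)
  out$points <- df
  out$fitted <- gt_at(k, df$w2)
  out$residuals <- df$tg - out$fitted
  out$converged <- fit$info %in% 1:4
  class(out) <- c("gt_fit", class(out))
  out
}

#' @export
print.gt_fit <- function(x, ...) {
  NextMethod()
  cat(sprintf("  fitted on %d interior point(s); residuals (K): %s\n",
              sum(x$points$w2 > 0 & x$points$w2 < 1),
              paste(sprintf("%.2f", x$residuals), collapse = ", ")))
  invisible(x)
}

#' @export
coef.gt_model <- function(object, ...) {
  c(tg1 = object$tg1, tg2 = object$tg2, K = object$k)
}

#' @export
predict.gt_model <- function(object, w2, ...) gt_predict(object, w2)

#' @export
residuals.gt_fit <- function(object, ...) object$residuals

#' @export
plot.gt_fit <- function(x, ...) {
  grid <- seq(0, 1, length.out = 200)
  graphics::plot(x$points$w2, x$points$tg, xlab = "polymer weight fraction w2",
                 ylab = "Tg (K)", main = "Gordon-Taylor fit",
                 xlim = c(0, 1), ylim = range(c(x$points$tg, x$tg1, x$tg2)), ...)
  graphics::lines(grid, gt_predict(x, grid), col = "orange", lwd = 2)
  invisible(x)
}

#' Invert the Gordon-Taylor relation: composition from a glass transition
#'
#' Solves \eqn{T_g(w_2) = tg} in closed form,
#' \deqn{w_2 = \frac{tg - T_{g1}}{(tg - T_{g1}) + K (T_{g2} - tg)},}
#' e.g. to convert the glass transition of the residual amorphous phase
#' left after crystallization into the saturation (solubility-limit)
#' composition of the drug in the polymer.  Because the relation flattens
#' when the component glass transitions are close, a first-order
#' uncertainty \eqn{dw_2/dT_g = K (T_{g2} - T_{g1}) / [(tg - T_{g1}) +
#' K(T_{g2} - tg)]^2} is reported alongside.
#'
#' @param model A [gt_model] (or [fit_gt_k()] result).
#' @param tg Observed glass transition, kelvin.  Must lie between the
#'   component glass transitions unless `extrapolate = TRUE`.
#' @param tg_sd Optional standard error of `tg` in kelvin, propagated to
#'   `w2_sd`.
#' @param extrapolate Allow `tg` outside the closed interval spanned by
#'   the endpoints (the closed form still applies; default `FALSE` errors
#'   with the out-of-range distance).
#' @return An object of class `gt_inversion`: list with `w2` (polymer
#'   fraction), `w1` (drug fraction), `dw2_dtg` (1/K), and `w2_sd`
#'   (when `tg_sd` was given).
#' @export
gt_invert <- function(model, tg, tg_sd = NULL, extrapolate = FALSE) {
  .assert_number(tg, "tg", positive = TRUE)
  lo <- min(model$tg1, model$tg2)
  hi <- max(model$tg1, model$tg2)
  if (!extrapolate && (tg < lo || tg > hi)) {
    dist <- if (tg < lo) lo - tg else tg - hi
    stop(sprintf("tg = %.2f K lies %.2f K outside the endpoint range [%.2f, %.2f] K",
                 tg, dist, lo, hi), call. = FALSE)
  }
  u <- tg - model$tg1
  v <- model$k * (model$tg2 - tg)
  w2 <- u / (u + v)
  dw2 <- model$k * (model$tg2 - model$tg1) / (u + v)^2
  out <- list(w2 = w2, w1 = 1 - w2, dw2_dtg = dw2, tg = tg)
  if (!is.null(tg_sd)) out$w2_sd <- abs(dw2) * tg_sd
  structure(out, class = "gt_inversion")
}

#' @export
print.gt_inversion <- function(x, ...) {
  cat(sprintf("<gt_inversion> Tg = %.2f K -> w2 (polymer) = %.4f, w1 (drug) = %.4f\n",
              x$tg, x$w2, x$w1))
  cat(sprintf("  sensitivity dw2/dTg = %.4g /K%s\n", x$dw2_dtg,
              if (!is.null(x$w2_sd)) sprintf(", w2 se = %.4f", x$w2_sd) else ""))
  invisible(x)
}
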