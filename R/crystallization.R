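## Crystallization detection and kinetics from the collapse of the
## dielectric strength.  Crystallization immobilizes reorienting dipoles
## (Delta_eps ~ N mu^2), so it appears as a drop of Delta_eps in wide-band
## fits, or of eps' in single-frequency temperature scans, below the trend
## expected for a non-crystallizing supercooled liquid.

#' Construct a crystallization trace
#'
#' Holds \eqn{\varepsilon'} at a fixed frequency versus time (isothermal
#' kinetics) or temperature (scans), plus the reference levels needed for
#' normalization.
#'
#' @param axis_values Strictly increasing times (s) or temperatures (K).
#' @param eps_real \eqn{\varepsilon'} values, one per axis point.
#' @param axis `"time"` or `"temperature"`.
#' @param frequency Measurement frequency in Hz (optional bookkeeping).
#' @param eps0 Initial static permittivity reference \eqn{\varepsilon'(0)}
#'   (optional; [normalize_permittivity()] can derive it).
#' @param eps_inf_limit High-frequency limit \eqn{\varepsilon'(\infty)}
#'   (optional).
#' @return An object of class `crystallization_trace`.
#' @export
crystallization_trace <- function(axis_values, eps_real,
                                  axis = c("time", "temperature"),
                                  frequency = NA_real_, eps0 = NULL,
                                  eps_inf_limit = NULL) {
  axis <- match.arg(axis)
  axis_values <- as.double(axis_values)
  eps_real <- as.double(eps_real)
  if (length(axis_values) != length(eps_real))
    stop("'axis_values' and 'eps_real' must have equal length", call. = FALSE)
  if (any(!is.finite(axis_values)) || any(!is.finite(eps_real)))
    stop("trace values must be finite", call. = FALSE)
  if (length(axis_values) > 1L && any(diff(axis_values) <= 0))
    stop("'axis_values' must be strictly increasing", call. = FALSE)
  if (!is.null(eps0) && !is.null(eps_inf_limit) && eps0 <= eps_inf_limit)
    stop("'eps0' must exceed 'eps_inf_limit'", call. = FALSE)
  structure(list(axis = axis, axis_values = axis_values, eps_real = eps_real,
                 frequency = frequency, eps0 = eps0,
                 eps_inf_limit = eps_inf_limit, eps_norm = NULL),
            class = "crystallization_trace")
}

#' @export
print.crystallization_trace <- function(x, ...) {
  cat(sprintf("<crystallization_trace> %d points on %s axis [%.4g, %.4g]%s\n",
              length(x$axis_values), x$axis, min(x$axis_values),
              max(x$axis_values),
              if (!is.null(x$eps_norm)) " (normalized)" else ""))
  invisible(x)
}

#' @export
plot.crystallization_trace <- function(x, ...) {
  y <- x$eps_norm %||% x$eps_real
  graphics::plot(x$axis_values, y,
                 xlab = if (x$axis == "time") "time (s)" else "temperature (K)",
                 ylab = if (!is.null(x$eps_norm))
                   expression(epsilon * minute[N]) else expression(epsilon * minute),
                 ...)
  invisible(x)
}

#' Normalize the real permittivity of a crystallization trace
#'
#' Computes the normalized permittivity
#' \deqn{\varepsilon'_N(t) = \frac{\varepsilon'(0) - \varepsilon'(t)}
#'                                {\varepsilon'(0) - \varepsilon'(\infty)},}
#' which runs from 0 (fully amorphous) to 1 (complete crystallization) and
#' is invariant under affine rescaling (gain/offset) of \eqn{\varepsilon'}.
#'
#' @param trace A [crystallization_trace].
#' @param eps0 \eqn{\varepsilon'(0)}; default: the trace's stored value,
#'   else the mean of the first `baseline_points` points.
#' @param eps_inf \eqn{\varepsilon'(\infty)}; default: the trace's stored
#'   value.  Required (there is no safe way to guess it for incomplete
#'   crystallization).
#' @param baseline_points Number of initial points averaged for the
#'   default \eqn{\varepsilon'(0)} (default 3).
#' @return The trace with `eps_norm`, `eps0` and `eps_inf_limit` filled in.
#' @export
normalize_permittivity <- function(trace, eps0 = NULL, eps_inf = NULL,
                                   baseline_points = 3L) {
  if (!inherits(trace, "crystallization_trace"))
    stop("'trace' must be a crystallization_trace", call. = FALSE)
  eps0 <- eps0 %||% trace$eps0 %||%
    mean(trace$eps_real[seq_len(min(baseline_points, length(trace$eps_real)))])
  eps_inf <- eps_inf %||% trace$eps_inf_limit
  if (is.null(eps_inf))
    stop("'eps_inf' is required (supply it or store it on the trace)",
         call. = FALSE)
  if (eps0 <= eps_inf)
    stop("'eps0' must exceed 'eps_inf'", call. = FALSE)
  trace$eps0 <- eps0
  trace$eps_inf_limit <- eps_inf
  trace$eps_norm <- (eps0 - trace$eps_real) / (eps0 - eps_inf)
  trace
}

#' Detect a crystallization onset from a dielectric-strength collapse
#'
#' Scans along the axis with an expanding (wide-band) or sliding
#' (single-frequency) pre-onset baseline and reports the first point whose
#' observed value falls below \eqn{(1 - threshold)} times the
#' extrapolated baseline:
#' \itemize{
#'   \item wide-band input (columns `temperature`, `delta_eps`): the
#'     baseline is a least-squares \eqn{A/T} fit (the Langevin
#'     \eqn{\Delta\varepsilon \propto 1/T} decay of a non-crystallizing
#'     liquid) over all points before the candidate;
#'   \item single-frequency input (columns `temperature`/`time` and
#'     `eps_real`, a single-frequency [spectrum_series], or a
#'     [crystallization_trace]): the baseline is a local linear trend over
#'     the last `window` pre-onset points.
#' }
#' Finding no collapse is a first-class result (`detected = FALSE`), not
#' an error - some formulations never crystallize within the experiment.
#'
#' @param x Input (see above).
#' @param threshold Relative shortfall treated as a "noticeable drop"
#'   (default 0.1).
#' @param min_baseline Points used to seed the baseline (default 4).
#' @param window Sliding-window length for the linear baseline (default 5).
#' @return An object of class `onset_result`: list with `onset` (K or s;
#'   `NA` when none), `detected`, `method` (`"delta_eps_drop"` or
#'   `"single_freq_drop"`), `threshold_used`, `baseline_model`, `axis`.
#' @export
detect_onset <- function(x, threshold = 0.1, min_baseline = 4L, window = 5L) {
  if (inherits(x, "spectrum_series")) {
    if (!is_single_frequency(x))
      stop("wide-band series: fit spectra first and pass temperature/delta_eps",
           call. = FALSE)
    x <- data.frame(temperature = x$scan$temperature, eps_real = x$scan$eps_real)
  } else if (inherits(x, "crystallization_trace")) {
    x <- if (x$axis == "time")
      data.frame(time = x$axis_values, eps_real = x$eps_real)
    else data.frame(temperature = x$axis_values, eps_real = x$eps_real)
  }
  x <- as.data.frame(x)
  axis <- if ("temperature" %in% names(x)) "temperature" else "time"
  if (!axis %in% names(x)) stop("no 'temperature' or 'time' column", call. = FALSE)
  tvals <- x[[axis]]
  if (any(diff(order(tvals)) < 0)) {
    ord <- order(tvals)
    x <- x[ord, , drop = FALSE]
    tvals <- tvals[ord]
  }
  if (.assert_number(threshold, "threshold") <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)

  if ("delta_eps" %in% names(x)) {
    method <- "delta_eps_drop"
    baseline_model <- "least-squares A/T over the pre-onset window"
    y <- x$delta_eps
    n <- length(y)
    if (n < min_baseline + 1L)
      stop(sprintf("need more than %d points", min_baseline), call. = FALSE)
    onset <- NA_real_
    for (i in (min_baseline + 1L):n) {
      idx <- seq_len(i - 1L)
      invT <- 1 / tvals[idx]
      A <- sum(y[idx] * invT) / sum(invT^2)       # LS fit of y = A/T
      pred <- A / tvals[i]
      if (is.finite(pred) && y[i] < (1 - threshold) * pred) {
        onset <- tvals[i]
        break
      }
    }
  } else if ("eps_real" %in% names(x)) {
    method <- "single_freq_drop"
    baseline_model <- sprintf("local linear trend over the last %d pre-onset points",
                              window)
    y <- x$eps_real
    n <- length(y)
    if (n < window + 1L)
      stop(sprintf("need more than %d points", window), call. = FALSE)
    onset <- NA_real_
    for (i in (window + 1L):n) {
      idx <- (i - window):(i - 1L)
      cf <- stats::lm.fit(cbind(1, tvals[idx]), y[idx])$coefficients
      pred <- cf[1L] + cf[2L] * tvals[i]
      if (is.finite(pred) && pred > 0 && y[i] < (1 - threshold) * pred) {
        onset <- tvals[i]
        break
      }
    }
  } else {
    stop("input needs a 'delta_eps' or 'eps_real' column", call. = FALSE)
  }
  structure(list(onset = onset, detected = is.finite(onset), method = method,
                 threshold_used = threshold, baseline_model = baseline_model,
                 axis = axis),
            class = "onset_result")
}

#' @export
print.onset_result <- function(x, ...) {
  if (x$detected)
    cat(sprintf("<onset_result> crystallization onset at %.4g %s (%s, threshold %.0f%%)\n",
                x$onset, if (x$axis == "temperature") "K" else "s",
                x$method, 100 * x$threshold_used))
  else
    cat(sprintf("<onset_result> no onset detected (%s, threshold %.0f%%)\n",
                x$method, 100 * x$threshold_used))
  cat("  baseline:", x$baseline_model, "\n")
  invisible(x)
}

#' Summarize isothermal crystallization kinetics
#'
#' From a normalized time trace, reports the induction time (first time
#' \eqn{\varepsilon'_N} exceeds `induction_threshold`), the cessation time
#' (start of the final window over which the slope of \eqn{\varepsilon'_N}
#' stays below `slope_tol`), and the final plateau level (mean
#' \eqn{\varepsilon'_N} over that window; below 1 for incomplete
#' crystallization).
#'
#' @param trace A [crystallization_trace] on the time axis, already
#'   normalized (see [normalize_permittivity()]).
#' @param induction_threshold Normalized level defining induction
#'   (default 0.05).
#' @param slope_tol Flatness tolerance for the terminal plateau, in
#'   normalized units per second (default `1e-3/3600`, i.e. 1e-3 per hour).
#' @param window Number of points per local slope estimate (default 5).
#' @return An object of class `kinetics_summary`: `induction_time` (s,
#'   `NA` when the trace never crystallizes), `cessation_time` (s),
#'   `final_norm`, and `complete` (`final_norm >= 0.95`).
#' @export
kinetics_summary <- function(trace, induction_threshold = 0.05,
                             slope_tol = 1e-3 / 3600, window = 5L) {
  if (!inherits(trace, "crystallization_trace"))
    stop("'trace' must be a crystallization_trace", call. = FALSE)
  if (trace$axis != "time")
    stop("kinetics need a time-axis trace", call. = FALSE)
  if (is.null(trace$eps_norm))
    stop("normalize the trace first (normalize_permittivity)", call. = FALSE)
  t <- trace$axis_values
  y <- trace$eps_norm
  n <- length(y)
  if (n < window + 2L) stop("trace too short", call. = FALSE)

  idx <- which(y > induction_threshold)
  induction <- if (length(idx)) t[idx[1L]] else NA_real_

  ## local slopes over trailing windows; the terminal plateau is the
  ## longest suffix of windows whose slope magnitude stays below tolerance
  nw <- n - window + 1L
  slope <- vapply(seq_len(nw), function(i) {
    j <- i:(i + window - 1L)
    stats::lm.fit(cbind(1, t[j]), y[j])$coefficients[2L]
  }, numeric(1))
  flat <- abs(slope) < slope_tol
  cessation <- NA_real_
  plateau_idx <- NULL
  if (flat[nw]) {
    i0 <- nw
    while (i0 > 1L && flat[i0 - 1L]) i0 <- i0 - 1L
    ## plateau must come after crystallization started, if it did
    if (!is.na(induction)) {
      while (i0 <= nw && t[i0] < induction) i0 <- i0 + 1L
      if (i0 <= nw) cessation <- t[i0]
    }
    plateau_idx <- if (i0 <= nw) i0:n else (n - window + 1L):n
  }
  if (is.null(plateau_idx)) plateau_idx <- (n - window + 1L):n
  final_norm <- mean(y[plateau_idx])
  if (is.na(induction)) cessation <- NA_real_
  structure(list(induction_time = induction, cessation_time = cessation,
                 final_norm = final_norm,
                 complete = is.finite(final_norm) && final_norm >= 0.95,
                 induction_threshold = induction_threshold,
                 slope_tol = slope_tol),
            class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("<kinetics_summary>\n")
  if (is.na(x$induction_time)) {
    cat(sprintf("  no crystallization detected (final eps'_N = %.3f)\n",
                x$final_norm))
  } else {
    cat(sprintf("  induction %.4g s, cessation %s, final eps'_N = %.3f (%s)\n",
                x$induction_time,
                if (is.na(x$cessation_time)) "not reached"
                else sprintf("%.4g s", x$cessation_time),
                x$final_norm,
                if (x$complete) "complete" else "incomplete"))
  }
  invisible(x)
}

#' Thermal stability factor
#'
#' The difference between the crystallization-onset and glass-transition
#' temperatures, \eqn{T_C - T_g}: the width of the temperature window over
#' which the supercooled liquid resists crystallization.  Antisymmetric
#' under argument swap, which guards against order mistakes.
#'
#' @param tg Glass-transition temperature, kelvin.
#' @param tc Crystallization-onset temperature, kelvin.
#' @return `tc - tg` in kelvin (vectorized).
#' @export
stability_factor <- function(tg, tc) {
  if (any(!is.finite(tg)) || any(!is.finite(tc)))
    stop("'tg' and 'tc' must be finite", call. = FALSE)
  tc - tg
}

#' Residual composition (solubility limit) after crystallization
#'
#' Runs the post-crystallization pipeline: fit the residual
#' (\eqn{\alpha'}) relaxation of a cooling series recorded after
#' crystallization ceased, extrapolate its VFT fit to the \eqn{T_g}
#' reference time, and invert the Gordon-Taylor model to read off the
#' composition of the saturated drug-polymer solution that remains.  The
#' drug weight fraction it returns is the solubility limit of the drug in
#' the polymer at the crystallization temperature.
#'
#' @param post_series Wide-band [spectrum_series] of the sample after
#'   crystallization ceased (the \eqn{\alpha'} process).
#' @param gt_model A [gt_model] for the drug-polymer system.
#' @param tau_ref \eqn{T_g} reference time in seconds (default 100).
#' @param mode,bounds Passed to [extract_relaxation_map()].
#' @return An object of class `residual_composition`: `w_drug`,
#'   `w_polymer`, `w_drug_sd` (first-order), `tg` (K), `tg_sd`, plus the
#'   intermediate `vft` fit and `map`.  A `tg` outside the endpoint range
#'   is reported (with a warning), never clamped; a composition
#'   indistinguishable from the neat polymer (drug fraction < 0.02) warns
#'   that the drug may have crystallized completely.
#' @export
residual_composition <- function(post_series, gt_model, tau_ref = 100,
                                 mode = "loss_only", bounds = list()) {
  map <- extract_relaxation_map(post_series, mode = mode, bounds = bounds,
                                drop_crystallized = FALSE)
  vft <- fit_vft(map)
  tg <- tg_from_vft(vft, tau_ref = tau_ref)
  tg_sd <- attr(tg, "sd") %||% NA_real_
  tgv <- as.numeric(tg)
  lo <- min(gt_model$tg1, gt_model$tg2)
  hi <- max(gt_model$tg1, gt_model$tg2)
  if (tgv < lo || tgv > hi)
    warning(sprintf("alpha' Tg = %.2f K lies outside the endpoint range [%.2f, %.2f] K; composition extrapolated",
                    tgv, lo, hi), call. = FALSE)
  inv <- gt_invert(gt_model, tgv,
                   tg_sd = if (is.finite(tg_sd)) tg_sd else NULL,
                   extrapolate = TRUE)
  if (inv$w1 < 0.02)
    warning("residual relaxation is indistinguishable from the neat polymer; the drug may have crystallized completely (or be immiscible)",
            call. = FALSE)
  structure(list(w_drug = inv$w1, w_polymer = inv$w2,
                 w_drug_sd = inv$w2_sd %||% NA_real_, tg = tgv, tg_sd = tg_sd,
                 vft = vft, map = map, inversion = inv),
            class = "residual_composition")
}

#' @export
print.residual_composition <- function(x, ...) {
  cat(sprintf("<residual_composition> alpha' Tg = %.2f K (se %.2g K)\n",
              x$tg, x$tg_sd))
  cat(sprintf("  saturated drug fraction = %.4f (se %.2g); polymer fraction = %.4f\n",
              x$w_drug, x$w_drug_sd, x$w_polymer))
  invisible(x)
}
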