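## End-to-end workflows: non-isothermal characterization (relaxation map ->
## VFT -> Tg / isochronal temperature / onset / stability factor) and the
## isothermal-versus-isochronal stability comparison.

#' Characterize samples from non-isothermal wide-band series
#'
#' For each sample: fit every spectrum with [fit_hn()], detect the
#' crystallization onset from the collapse of the dielectric strength,
#' fit the VFT law to the pre-onset relaxation map, and report the
#' glass-transition temperature (\eqn{\tau_\alpha = } `tau_ref`), the
#' isochronal temperature (\eqn{\tau_\alpha = } `tau_iso`), and the
#' thermal stability factor \eqn{T_C - T_g}.  Samples with no detected
#' onset get `tc = NA` and no stability factor (a first-class outcome).
#'
#' @param samples Named list of wide-band [spectrum_series] objects.
#' @param tau_ref \eqn{T_g} reference time in seconds (default 100).
#' @param tau_iso Isochronal reference time in seconds (default 1.5e-3).
#' @param onset_threshold Relative dielectric-strength shortfall treated
#'   as crystallization (default 0.1).
#' @param mode,bounds Passed to [fit_hn()].
#' @param config Optional [run_config()]; when supplied its fields
#'   override `tau_ref`, `tau_iso`, `onset_threshold` and `mode`.
#' @return An object of class `stability_report_set`: a list of per-sample
#'   reports (class `stability_report`, fields `sample`, `tg`, `tg_sd`,
#'   `tc`, `stability_factor`, `isochronal_temperature`, `vft`, `map`,
#'   `n_spectra`, `n_fitted`, `skipped`).  `as.data.frame()` gives the
#'   summary table.
#' @export
run_characterize <- function(samples, tau_ref = 100, tau_iso = 1.5e-3,
                             onset_threshold = 0.1, mode = "loss_only",
                             bounds = list(), config = NULL) {
  if (!is.null(config)) {
    tau_ref <- config$tau_ref
    tau_iso <- config$tau_iso
    onset_threshold <- config$onset_threshold
    mode <- config$mode
  }
  if (!is.list(samples) || length(samples) == 0L)
    stop("'samples' must be a non-empty list of spectrum_series", call. = FALSE)
  nm <- names(samples) %||% paste0("sample", seq_along(samples))
  nm[nm == ""] <- paste0("sample", which(nm == ""))
  reports <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    series <- samples[[i]]
    map <- extract_relaxation_map(series, mode = mode, bounds = bounds,
                                  drop_crystallized = TRUE,
                                  onset_threshold = onset_threshold)
    onset <- attr(map, "onset")
    tc <- if (!is.null(onset) && isTRUE(onset$detected)) onset$onset else NA_real_
    vft <- fit_vft(map)
    tg <- tg_from_vft(vft, tau_ref = tau_ref)
    tiso <- isochronal_temperature(vft, tau = tau_iso)
    reports[[i]] <- structure(
      list(sample = nm[i], tg = as.numeric(tg),
           tg_sd = attr(tg, "sd") %||% NA_real_, tc = tc,
           stability_factor = if (is.finite(tc))
             stability_factor(as.numeric(tg), tc) else NA_real_,
           isochronal_temperature = as.numeric(tiso), tau_ref = tau_ref,
           tau_iso = tau_iso, vft = vft, map = map,
           n_spectra = length(series$spectra), n_fitted = nrow(map),
           skipped = attr(map, "skipped")),
      class = "stability_report")
  }
  names(reports) <- nm
  structure(reports, class = "stability_report_set")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report> %s\n", x$sample))
  cat(sprintf("  Tg(tau = %g s) = %.2f K (se %.2g K)\n", x$tau_ref, x$tg, x$tg_sd))
  cat(sprintf("  T(tau = %g s) = %.2f K (isochronal reference)\n",
              x$tau_iso, x$isochronal_temperature))
  if (is.finite(x$tc))
    cat(sprintf("  Tc = %.2f K, stability factor Tc - Tg = %.2f K\n",
                x$tc, x$stability_factor))
  else cat("  no crystallization onset detected\n")
  cat(sprintf("  %d/%d spectra fitted (%d skipped)\n", x$n_fitted,
              x$n_spectra, length(x$skipped)))
  invisible(x)
}

#' @export
print.stability_report_set <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}

#' @export
as.data.frame.stability_report_set <- function(x, ...) {
  do.call(rbind, lapply(x, function(r)
    data.frame(sample = r$sample, tg = r$tg, tc = r$tc,
               stability_factor = r$stability_factor,
               isochronal_temperature = r$isochronal_temperature,
               n_fitted = r$n_fitted, row.names = NULL)))
}

#' Compare isothermal and isochronal crystallization stability
#'
#' Summarizes crystallization kinetics for each sample under both storage
#' conditions - one common temperature for all samples (isothermal) and
#' per-sample temperatures of equal relaxation time (isochronal) - and,
#' when a Gordon-Taylor model and post-crystallization series are
#' supplied, appends the residual-composition (solubility-limit) estimate.
#'
#' @param isothermal Named list of normalized time-axis
#'   [crystallization_trace] objects (missing entries allowed).
#' @param isochronal Named list of normalized traces under isochronal
#'   conditions (same names; missing entries allowed).
#' @param gt_model Optional [gt_model] for residual-composition estimates.
#' @param post_cryst Optional named list of post-crystallization wide-band
#'   [spectrum_series] (see [residual_composition()]).
#' @param ... Passed to [kinetics_summary()].
#' @return An object of class `stability_comparison`: list with `table`
#'   (one row per sample and condition: induction, cessation, final
#'   normalized level, completeness) and `compositions` (named list of
#'   [residual_composition()] results, possibly empty).  Samples missing
#'   one condition produce a partial table with a warning.
#' @export
run_stability_compare <- function(isothermal = list(), isochronal = list(),
                                  gt_model = NULL, post_cryst = NULL, ...) {
  nm <- union(names(isothermal), names(isochronal))
  if (length(nm) == 0L) stop("no traces supplied", call. = FALSE)
  rows <- list()
  for (s in nm) {
    for (cond in c("isothermal", "isochronal")) {
      tr <- (if (cond == "isothermal") isothermal else isochronal)[[s]]
      if (is.null(tr)) {
        warning(sprintf("sample '%s' has no %s trace", s, cond), call. = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, condition = cond, induction_time = NA_real_,
          cessation_time = NA_real_, final_norm = NA_real_, complete = NA)
        next
      }
      ks <- kinetics_summary(tr, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, condition = cond, induction_time = ks$induction_time,
        cessation_time = ks$cessation_time, final_norm = ks$final_norm,
        complete = ks$complete)
    }
  }
  comps <- list()
  if (!is.null(gt_model) && !is.null(post_cryst)) {
    for (s in names(post_cryst))
      comps[[s]] <- residual_composition(post_cryst[[s]], gt_model)
  }
  structure(list(table = do.call(rbind, rows), compositions = comps),
            class = "stability_comparison")
}

#' @export
print.stability_comparison <- function(x, ...) {
  cat("<stability_comparison>\n")
  print(x$table, row.names = FALSE)
  if (length(x$compositions)) {
    cat("residual compositions:\n")
    for (s in names(x$compositions))
      cat(sprintf("  %s: drug fraction %.4f (Tg' = %.2f K)\n", s,
                  x$compositions[[s]]$w_drug, x$compositions[[s]]$tg))
  }
  invisible(x)
}

#' Assemble a run configuration
#'
#' Bundles the tunable analysis parameters (reference times, detection
#' thresholds, fit mode, seed) so a whole run is reproducible from one
#' object; [read_run_config()] loads the same structure from YAML.
#' Unknown fields are rejected rather than silently ignored.
#'
#' @param tau_ref Glass-transition reference time, s (default 100).
#' @param tau_iso Isochronal reference time, s (default 1.5e-3).
#' @param onset_threshold Relative dielectric-strength shortfall treated
#'   as crystallization (default 0.1).
#' @param induction_threshold Normalized level defining induction
#'   (default 0.05).
#' @param mode HN fit objective, `"loss_only"` or `"complex"`.
#' @param seed Integer seed for synthetic-data generation (default 1).
#' @return An object of class `run_config`.
#' @export
run_config <- function(tau_ref = 100, tau_iso = 1.5e-3, onset_threshold = 0.1,
                       induction_threshold = 0.05, mode = "loss_only",
                       seed = 1L) {
  .assert_number(tau_ref, "tau_ref", positive = TRUE)
  .assert_number(tau_iso, "tau_iso", positive = TRUE)
  .assert_number(onset_threshold, "onset_threshold", positive = TRUE)
  .assert_number(induction_threshold, "induction_threshold", positive = TRUE)
  mode <- match.arg(mode, c("loss_only", "complex"))
  structure(list(tau_ref = tau_ref, tau_iso = tau_iso,
                 onset_threshold = onset_threshold,
                 induction_threshold = induction_threshold, mode = mode,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config()]; missing keys take the defaults.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop(sprintf("unknown config field(s): %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  do.call(run_config, vals)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  tau_ref = %g s, tau_iso = %g s, mode = %s, seed = %d\n",
              x$tau_ref, x$tau_iso, x$mode, x$seed))
  cat(sprintf("  onset_threshold = %g, induction_threshold = %g\n",
              x$onset_threshold, x$induction_threshold))
  invisible(x)
}
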