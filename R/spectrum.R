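#' Construct a dielectric spectrum
#'
#' A `dielectric_spectrum` holds one frequency sweep of the complex
#' permittivity \eqn{\varepsilon^*(\omega) = \varepsilon' - i\varepsilon''}
#' recorded at a fixed temperature (and, for isothermal series, a fixed
#' elapsed time).  Frequencies are in Hz on a strictly increasing grid;
#' angular frequency \eqn{\omega = 2\pi f} is used internally wherever the
#' physics requires it.
#'
#' @param frequency Numeric vector of measurement frequencies in Hz,
#'   strictly positive and strictly increasing.
#' @param eps_real Real part \eqn{\varepsilon'} of the permittivity, one
#'   value per frequency.  May be `NULL` when only the loss was recorded.
#' @param eps_imag Dielectric loss \eqn{\varepsilon''}, one value per
#'   frequency.  May be `NULL` when only \eqn{\varepsilon'} was recorded.
#' @param temperature Sample temperature in kelvin (> 0).
#' @param time Optional elapsed time in seconds for isothermal series.
#' @return An object of class `dielectric_spectrum`.
#' @examples
#' f <- 10^seq(-1, 6, length.out = 50)
#' sp <- generate_spectrum(delta_eps = 5, tau_hn = 1e-3, a = 0.8, b = 0.6,
#'                         eps_inf = 3, sigma_dc = 0, frequencies = f,
#'                         temperature = 353)
#' sp
#' @export
dielectric_spectrum <- function(frequency, eps_real = NULL, eps_imag = NULL,
                                temperature, time = NA_real_) {
  frequency <- as.double(frequency)
  n <- length(frequency)
  if (n < 1L) stop("spectrum needs at least one frequency point", call. = FALSE)
  if (any(!is.finite(frequency)) || any(frequency <= 0))
    stop("frequencies must be finite and strictly positive", call. = FALSE)
  if (n > 1L && any(diff(frequency) <= 0))
    stop("frequencies must be strictly increasing", call. = FALSE)
  for (nm in c("eps_real", "eps_imag")) {
    v <- get(nm)
    if (!is.null(v)) {
      v <- as.double(v)
      if (length(v) != n)
        stop(sprintf("'%s' must have one value per frequency", nm), call. = FALSE)
      if (any(!is.finite(v)))
        stop(sprintf("'%s' must be finite", nm), call. = FALSE)
      assign(nm, v)
    }
  }
  if (is.null(eps_real) && is.null(eps_imag))
    stop("at least one of 'eps_real', 'eps_imag' is required", call. = FALSE)
  .assert_number(temperature, "temperature", positive = TRUE)
  structure(
    list(frequency = frequency, eps_real = eps_real, eps_imag = eps_imag,
         temperature = as.double(temperature), time = as.double(time)),
    class = "dielectric_spectrum"
  )
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf("<dielectric_spectrum> T = %.2f K%s, %d frequencies [%.3g, %.3g] Hz\n",
              x$temperature,
              if (is.finite(x$time)) sprintf(", t = %.4g s", x$time) else "",
              length(x$frequency), min(x$frequency), max(x$frequency)))
  cat(sprintf("  components: %s\n",
              paste(c("eps_real", "eps_imag")[!c(is.null(x$eps_real), is.null(x$eps_imag))],
                    collapse = ", ")))
  invisible(x)
}

#' Construct an ordered series of dielectric spectra
#'
#' A `spectrum_series` collects spectra recorded along a temperature ramp or
#' an isothermal time series (wide-band mode), or a single-frequency scan of
#' \eqn{\varepsilon'} versus temperature (single-frequency mode, e.g. the
#' 1 kHz scans used to track crystallization).
#'
#' @param spectra List of [dielectric_spectrum] objects sharing one
#'   frequency grid, ordered strictly monotonically along `axis`.
#' @param axis Ordering axis, `"temperature"` or `"time"`.
#' @param fixed_frequency Frequency in Hz for single-frequency mode.
#' @param scan Data frame with columns `temperature` (K) and `eps_real` for
#'   single-frequency mode; mutually exclusive with non-empty `spectra`.
#' @return An object of class `spectrum_series`.
#' @export
spectrum_series <- function(spectra = list(), axis = c("temperature", "time"),
                            fixed_frequency = NULL, scan = NULL) {
  axis <- match.arg(axis)
  if (!is.null(scan)) {
    if (length(spectra) > 0L)
      stop("supply either 'spectra' or 'scan', not both", call. = FALSE)
    if (!all(c("temperature", "eps_real") %in% names(scan)))
      stop("'scan' needs columns temperature, eps_real", call. = FALSE)
    if (nrow(scan) > 1L && any(diff(scan$temperature) <= 0))
      stop("scan temperatures must be strictly increasing", call. = FALSE)
    if (any(!is.finite(scan$eps_real)))
      stop("scan eps_real must be finite", call. = FALSE)
    return(structure(list(spectra = list(), axis = axis,
                          fixed_frequency = fixed_frequency %||% NA_real_,
                          scan = as.data.frame(scan)),
                     class = "spectrum_series"))
  }
  if (length(spectra) > 0L) {
    ok <- vapply(spectra, inherits, logical(1), "dielectric_spectrum")
    if (!all(ok)) stop("'spectra' must contain dielectric_spectrum objects", call. = FALSE)
    key <- vapply(spectra, function(s)
      if (axis == "temperature") s$temperature else s$time, numeric(1))
    if (any(!is.finite(key)))
      stop(sprintf("every spectrum needs a finite %s", axis), call. = FALSE)
    d <- diff(key)
    if (length(d) && !(all(d > 0) || all(d < 0)))
      stop(sprintf("spectra must be strictly monotone in %s", axis), call. = FALSE)
    grid <- spectra[[1L]]$frequency
    same <- vapply(spectra, function(s) {
      length(s$frequency) == length(grid) &&
        all(abs(s$frequency - grid) <= 1e-9 * pmax(grid, 1e-300))
    }, logical(1))
    if (!all(same))
      stop("all spectra in a wide-band series must share one frequency grid",
           call. = FALSE)
  }
  structure(list(spectra = spectra, axis = axis,
                 fixed_frequency = fixed_frequency %||% NA_real_, scan = NULL),
            class = "spectrum_series")
}

#' @export
print.spectrum_series <- function(x, ...) {
  if (is_single_frequency(x)) {
    cat(sprintf("<spectrum_series> single-frequency scan (%s Hz), %d points, %s axis\n",
                format(x$fixed_frequency), nrow(x$scan), x$axis))
  } else {
    cat(sprintf("<spectrum_series> %d wide-band spectra along %s\n",
                length(x$spectra), x$axis))
    if (length(x$spectra)) {
      key <- series_axis_values(x)
      cat(sprintf("  %s range: [%.4g, %.4g]\n", x$axis, min(key), max(key)))
    }
  }
  invisible(x)
}

#' Is a series a single-frequency scan?
#' @param series A [spectrum_series].
#' @return Logical.
#' @export
is_single_frequency <- function(series) {
  inherits(series, "spectrum_series") && !is.null(series$scan)
}

#' Ordering-axis values of a spectrum series
#' @param series A [spectrum_series].
#' @return Numeric vector of temperatures (K) or times (s).
#' @export
series_axis_values <- function(series) {
  if (is_single_frequency(series)) return(series$scan$temperature)
  vapply(series$spectra, function(s)
    if (series$axis == "temperature") s$temperature else s$time, numeric(1))
}

## Cluster sorted values whose consecutive gaps are <= tol into groups.
.group_by_tolerance <- function(x, tol) {
  ord <- order(x)
  xs <- x[ord]
  grp <- integer(length(x))
  g <- 1L
  grp[ord[1L]] <- 1L
  if (length(x) > 1L) {
    for (i in 2:length(xs)) {
      if (xs[i] - xs[i - 1L] > tol) g <- g + 1L
      grp[ord[i]] <- g
    }
  }
  grp
}

#' Read a spectrum series from a long-format CSV file
#'
#' The expected dialect uses unit-suffixed headers: `temperature_K`
#' (required), `time_s` (optional), `frequency_Hz`, `eps_real`, `eps_imag`
#' (at least one of the last two).  Rows are grouped into spectra by
#' temperature (or time, when `time_s` varies), with groups never merging
#' values differing by more than `group_tol`.  A file without a
#' `frequency_Hz` column is read as a single-frequency scan
#' (`temperature_K`, `eps_real`).
#'
#' @param path Path to a CSV file.
#' @param fixed_frequency Frequency in Hz to record for single-frequency
#'   scans (the dialect does not carry it).
#' @param group_tol Grouping tolerance in kelvin (or seconds) within which
#'   rows are considered to belong to one spectrum.  Default 0.01.
#' @return A [spectrum_series].
#' @seealso [write_spectrum_series()]
#' @export
read_spectrum_series <- function(path, fixed_frequency = NULL, group_tol = 0.01) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L)
    stop(sprintf("empty input: %s contains no data rows", path), call. = FALSE)
  if (!"temperature_K" %in% names(df))
    stop("missing column 'temperature_K'", call. = FALSE)
  single <- !"frequency_Hz" %in% names(df)
  if (single) {
    if (!"eps_real" %in% names(df))
      stop("missing column 'eps_real' (single-frequency dialect)", call. = FALSE)
    ord <- order(df$temperature_K)
    return(spectrum_series(axis = "temperature",
                           fixed_frequency = fixed_frequency,
                           scan = data.frame(temperature = df$temperature_K[ord],
                                             eps_real = df$eps_real[ord])))
  }
  has_real <- "eps_real" %in% names(df)
  has_imag <- "eps_imag" %in% names(df)
  if (!has_real && !has_imag)
    stop("missing column 'eps_real' (or 'eps_imag')", call. = FALSE)
  has_time <- "time_s" %in% names(df) && length(unique(df$time_s)) > 1L
  axis <- if (has_time) "time" else "temperature"
  key <- if (has_time) df$time_s else df$temperature_K
  grp <- .group_by_tolerance(key, group_tol)
  spectra <- lapply(sort(unique(grp)), function(g) {
    rows <- df[grp == g, , drop = FALSE]
    ord <- order(rows$frequency_Hz)
    rows <- rows[ord, , drop = FALSE]
    if (nrow(rows) > 1L && any(diff(rows$frequency_Hz) <= 0))
      stop(sprintf("non-monotone frequency grid within the group at %s = %.6g",
                   axis, mean(if (has_time) rows$time_s else rows$temperature_K)),
           call. = FALSE)
    dielectric_spectrum(
      frequency = rows$frequency_Hz,
      eps_real = if (has_real) rows$eps_real else NULL,
      eps_imag = if (has_imag) rows$eps_imag else NULL,
      temperature = mean(rows$temperature_K),
      time = if ("time_s" %in% names(rows)) mean(rows$time_s) else NA_real_
    )
  })
  key_per_spec <- vapply(spectra, function(s)
    if (axis == "time") s$time else s$temperature, numeric(1))
  spectrum_series(spectra[order(key_per_spec)], axis = axis)
}

.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

#' Write a spectrum series to CSV
#'
#' Writes the long-format dialect read by [read_spectrum_series()], with
#' enough digits that a write/read round trip preserves values to better
#' than 1e-12 relative.
#'
#' @param series A [spectrum_series].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spectrum_series <- function(series, path) {
  if (!inherits(series, "spectrum_series"))
    stop("'series' must be a spectrum_series", call. = FALSE)
  if (is_single_frequency(series)) {
    lines <- c("temperature_K,eps_real",
               paste(.fmt_num(series$scan$temperature),
                     .fmt_num(series$scan$eps_real), sep = ","))
  } else {
    has_real <- length(series$spectra) > 0L && !is.null(series$spectra[[1L]]$eps_real)
    has_imag <- length(series$spectra) == 0L || !is.null(series$spectra[[1L]]$eps_imag)
    has_time <- length(series$spectra) > 0L &&
      any(vapply(series$spectra, function(s) is.finite(s$time), logical(1)))
    header <- c("temperature_K", if (has_time) "time_s", "frequency_Hz",
                if (has_real) "eps_real", if (has_imag) "eps_imag")
    body <- unlist(lapply(series$spectra, function(s) {
      cols <- list(.fmt_num(rep(s$temperature, length(s$frequency))))
      if (has_time) cols <- c(cols, list(.fmt_num(rep(s$time, length(s$frequency)))))
      cols <- c(cols, list(.fmt_num(s$frequency)))
      if (has_real) cols <- c(cols, list(.fmt_num(s$eps_real)))
      if (has_imag) cols <- c(cols, list(.fmt_num(s$eps_imag)))
      do.call(paste, c(cols, sep = ","))
    }))
    lines <- c(paste(header, collapse = ","), body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a glass-transition versus composition table
#'
#' Expects columns `w2` (polymer weight fraction in \[0, 1\]) and `tg_K`
#' (glass-transition temperature in kelvin); an optional `method` column
#' records whether each point came from calorimetry (DSC) or dielectric
#' (BDS) measurement.  Duplicate `w2` rows (replicates) are preserved.
#'
#' @param path Path to a CSV file.
#' @return A data frame of class `composition_table` with columns `w2`,
#'   `tg` (K) and `method`, sorted by `w2`.
#' @export
read_composition_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c("w2", "tg_K"))
    if (!col %in% names(df))
      stop(sprintf("missing column '%s'", col), call. = FALSE)
  bad <- which(!is.finite(df$w2) | df$w2 < 0 | df$w2 > 1)
  if (length(bad))
    stop(sprintf("row %d: w2 = %s outside [0, 1]", bad[1L], format(df$w2[bad[1L]])),
         call. = FALSE)
  bad_tg <- which(!is.finite(df$tg_K) | df$tg_K <= 0)
  if (length(bad_tg))
    stop(sprintf("row %d: tg_K = %s is not a positive temperature",
                 bad_tg[1L], format(df$tg_K[bad_tg[1L]])), call. = FALSE)
  out <- data.frame(w2 = df$w2, tg = df$tg_K,
                    method = if ("method" %in% names(df)) as.character(df$method)
                             else NA_character_)
  out <- out[order(out$w2), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("composition_table", "data.frame")
  out
}
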