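# Shared fixtures: frequency grids, VFT constructors tied to a target Tg,
# and an independent numeric loss-peak oracle.

# 0.1 Hz .. 1 MHz at 30 points/decade
freq_grid_std <- function() 10^seq(-1, 6, by = 1 / 30)

# ratio tau_alpha / tau_hn for given shape exponents
peak_ratio <- function(a, b) hn_peak_time(list(tau_hn = 1, a = a, b = b))

# VFT parameters (governing tau_HN in the generators) chosen so that the
# alpha-relaxation peak time reaches tau_ref (100 s) exactly at tg_target,
# given the HN shape used by the generator.
vft_for_tg <- function(tg_target, a = 0.8, b = 0.6, B = 2000,
                       tau_inf = 1e-14, tau_ref = 100) {
  r <- peak_ratio(a, b)
  list(tau_inf = tau_inf, B = B,
       T0 = tg_target - B / log(tau_ref / (r * tau_inf)))
}

# temperatures at which tau_HN takes the requested values
temps_for_tau <- function(vft, tau) {
  sort(vft$T0 + vft$B / log(tau / vft$tau_inf))
}

# Independent numeric maximization of the HN loss (golden-section on
# log-omega), used as the brute-force oracle for hn_peak_time().
numeric_peak_time <- function(a, b, tau_hn = 1) {
  negloss <- function(lw) {
    z <- (1i * exp(lw) * tau_hn)^a
    Im(1 / (1 + z)^b)   # Im of HN term is -loss/delta_eps
  }
  opt <- stats::optimize(negloss, c(log(1e-8 / tau_hn), log(1e8 / tau_hn)),
                         tol = 1e-12)
  exp(-opt$minimum)
}

# printed glass-transition tables shipped with the package
tg_table <- function(name) {
  read_composition_table(system.file("extdata", paste0(name, ".csv"),
                                     package = "dielstab"))
}
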