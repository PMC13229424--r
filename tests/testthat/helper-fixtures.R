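# Shared fixtures: small geometries and fast presets so unit tests stay
# well under a second each. Heavier cohort-scale objects are built once and
# memoised here.

small_tube <- function(n_axial = 12L, n_circ = 12L, length_mm = 30)
  make_tube(radius_mm = 3.5, length_mm = length_mm,
            n_axial = n_axial, n_circ = n_circ)

# A light preset: one 50 Hz band, modest sampling works at dt = 1e-3.
fast_preset <- function(...) {
  args <- list(group_label = "test",
               target_timeavg_amp_um = 10, target_strain_e3 = 0.8,
               vib_bands = list(c(50, 10, 1)))
  args[names(list(...))] <- list(...)
  do.call(synthetic_preset, args)
}

# FFT brick-wall high-pass: the independent oracle for the Butterworth
# filter (zero out all bins strictly below the cutoff).
fft_highpass_oracle <- function(x, dt, cutoff_hz) {
  n <- length(x)
  X <- stats::fft(x)
  f <- (seq_len(n) - 1L) / (n * dt)
  f <- pmin(f, 1 / dt - f)
  X[f < cutoff_hz] <- 0
  Re(stats::fft(X, inverse = TRUE)) / n
}

# Displacement series holder for a plain (n_steps x n_nodes x 3) array.
disp_series <- function(values, dt = 5e-4, cycle_length = 1)
  field_series(values, dt = dt, field_name = "displacement",
               cycle_length = cycle_length)

# Null-cohort presets: every group uses the patency spectrum/targets.
null_cohort_presets <- function() {
  pr <- default_presets()
  out <- list(patency = pr$patency, stenosis = pr$patency,
              dilatation = pr$patency)
  out$stenosis$group_label <- "stenosis"
  out$dilatation$group_label <- "dilatation"
  out
}
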