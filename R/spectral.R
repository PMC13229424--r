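## Short-time spectral analysis of wall-motion traces: Hann-windowed STFT
## spectrograms in dB, detection of narrow supra-threshold frequency bands
## (the stenosis / dilatation signatures), and the spectral power index
## (SPI): the fraction of a mean-removed signal's power above the cutoff.

DB_FLOOR <- -120

#' Spectrogram of a scalar trace
#'
#' Hann-windowed short-time Fourier transform, one-sided power spectral
#' density. `power_db` is 10*log10 of the PSD in (signal unit)^2 per Hz,
#' referenced to 1 unit, floored at -120 dB; Parseval holds per window:
#' the PSD integrated over frequency matches the windowed time-domain power.
#'
#' @param trace numeric vector, a per-timestep scalar signal.
#' @param dt timestep (s).
#' @param window_s window length (s), default 0.2 (5 Hz resolution,
#'   needed to separate band pairs ~25 Hz apart with a Hann main lobe).
#' @param overlap_frac fractional overlap between windows in [0, 1).
#' @return An object of class `spectrogram` with `time_bins` (s, window
#'   centers), `freq_bins` (Hz), `power` (linear PSD, freq x time) and
#'   `power_db`.
#' @export
spectrogram <- function(trace, dt, window_s = 0.2, overlap_frac = 0.9) {
  stopifnot(overlap_frac >= 0, overlap_frac < 1, window_s > 0)
  fs <- 1 / dt
  nw <- as.integer(round(window_s * fs))
  if (nw < 8L) stop("window too short for the sampling rate")
  if (nw > length(trace)) stop("window longer than the signal")
  hop <- max(1L, as.integer(round(nw * (1 - overlap_frac))))
  w <- 0.5 * (1 - cos(2 * pi * seq_len(nw) / (nw + 1)))  # Hann (periodic-ish)
  w2 <- sum(w^2)
  starts <- seq(1L, length(trace) - nw + 1L, by = hop)
  nfreq <- nw %/% 2L + 1L
  pow <- matrix(0, nfreq, length(starts))
  for (j in seq_along(starts)) {
    seg <- trace[starts[j]:(starts[j] + nw - 1L)] * w
    X <- stats::fft(seg)[seq_len(nfreq)]
    p <- Mod(X)^2 / (fs * w2)
    p[-c(1L, if (nw %% 2L == 0L) nfreq)] <- 2 * p[-c(1L, if (nw %% 2L == 0L) nfreq)]
    pow[, j] <- p
  }
  structure(list(time_bins = (starts - 1L + nw / 2) * dt,
                 freq_bins = (seq_len(nfreq) - 1L) * fs / nw,
                 power = pow,
                 power_db = pmax(10 * log10(pow + 10^(DB_FLOOR / 10)), DB_FLOOR),
                 fs = fs, window_s = window_s, df = fs / nw),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freq bins (df %.2f Hz) x %d windows of %.3g s\n",
              length(x$freq_bins), x$df, length(x$time_bins), x$window_s))
  invisible(x)
}

#' Time-averaged power spectral density of a spectrogram
#' @param spec a [spectrogram()].
#' @return A data.frame with `freq_hz` and `psd` (linear) and `psd_db`.
#' @export
psd_timeavg <- function(spec) {
  p <- rowMeans(spec$power)
  data.frame(freq_hz = spec$freq_bins, psd = p,
             psd_db = pmax(10 * log10(p + 10^(DB_FLOOR / 10)), DB_FLOOR))
}

#' Detect narrow frequency bands in a spectrum
#'
#' Contiguous supra-threshold frequency intervals above the high-pass
#' cutoff are found in the time-averaged PSD; intervals separated by gaps
#' narrower than `min_gap_hz` are merged, intervals narrower than
#' `min_width_hz` are discarded. Band centers are power-weighted centroids.
#' In the default `"relative"` mode the threshold is the larger of
#' (median supra-cutoff PSD + `threshold_db`) and (peak PSD -
#' `prominence_drop_db`): a band must both rise above the broadband floor
#' and be within the prominence drop of the strongest peak. This is robust
#' to the unknown absolute normalization of reported dB levels and does not
#' flag a flat broadband plateau (whose median is its own level) as a band;
#' `"absolute"` compares `psd_db` against `threshold_db` directly.
#'
#' @param spec a [spectrogram()] or a data.frame as from [psd_timeavg()].
#' @param threshold_db threshold (dB), above the median floor in
#'   `"relative"` mode, absolute in `"absolute"` mode.
#' @param mode `"relative"` (default) or `"absolute"`.
#' @param cutoff_hz lower bound of the search (the high-pass cutoff).
#' @param fmax_hz upper bound of the search.
#' @param min_width_hz minimum band width kept.
#' @param min_gap_hz bands separated by less than this are merged.
#' @param prominence_drop_db in `"relative"` mode, bins more than this far
#'   below the supra-cutoff peak never count as band content.
#' @return An object of class `band_set`: data.frame with `f_low_hz`,
#'   `f_high_hz`, `f_center_hz`, `peak_db`; possibly zero rows.
#' @export
detect_bands <- function(spec, threshold_db = 10,
                         mode = c("relative", "absolute"),
                         cutoff_hz = 25, fmax_hz = 200,
                         min_width_hz = 8, min_gap_hz = 10,
                         prominence_drop_db = 15) {
  mode <- match.arg(mode)
  psd <- if (inherits(spec, "spectrogram")) psd_timeavg(spec) else spec
  stopifnot(all(c("freq_hz", "psd") %in% names(psd)))
  df <- if (length(psd$freq_hz) > 1L) stats::median(diff(psd$freq_hz)) else 1
  sel <- psd$freq_hz > cutoff_hz & psd$freq_hz <= fmax_hz
  empty <- structure(data.frame(f_low_hz = numeric(), f_high_hz = numeric(),
                                f_center_hz = numeric(), peak_db = numeric()),
                     class = c("band_set", "data.frame"))
  if (!any(sel)) return(empty)
  f <- psd$freq_hz[sel]
  p <- psd$psd[sel]
  p_db <- 10 * log10(p + 10^(DB_FLOOR / 10))
  thr_db <- if (mode == "relative")
    max(stats::median(p_db) + threshold_db, max(p_db) - prominence_drop_db)
  else threshold_db
  above <- p_db > thr_db
  if (!any(above)) return(empty)
  # runs of supra-threshold bins
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge runs separated by gaps < min_gap_hz
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (k in 2:nrow(runs)) {
    gap <- (runs$i0[k] - merged$i1[nrow(merged)] - 1L) * df
    if (gap < min_gap_hz) merged$i1[nrow(merged)] <- runs$i1[k]
    else merged <- rbind(merged, runs[k, ])
  }
  out <- do.call(rbind, lapply(seq_len(nrow(merged)), function(k) {
    idx <- merged$i0[k]:merged$i1[k]
    # half-bin flanks so a single-bin band still has finite width
    data.frame(f_low_hz = f[idx[1L]] - df / 2,
               f_high_hz = f[idx[length(idx)]] + df / 2,
               f_center_hz = sum(f[idx] * p[idx]) / sum(p[idx]),
               peak_db = max(p_db[idx]))
  }))
  out <- out[out$f_high_hz - out$f_low_hz >= min_width_hz, , drop = FALSE]
  out <- out[order(out$f_center_hz), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("band_set", "data.frame"))
}

#' Spectral power index (SPI)
#'
#' Fraction of the mean-removed signal's spectral power at frequencies
#' strictly above the cutoff, from the periodogram; a proxy for
#' cycle-invariant turbulent-like fluctuation. Bounded in [0, 1]; a
#' constant signal has SPI 0 by definition.
#'
#' @param x numeric vector (per-timestep scalar signal) spanning at least
#'   one cardiac cycle.
#' @param dt timestep (s).
#' @param cutoff_hz cutoff frequency (default 25 Hz, matching the
#'   vibration high-pass).
#' @return SPI in [0, 1].
#' @export
spi <- function(x, dt, cutoff_hz = 25) {
  x <- x - mean(x)
  tot <- sum(x^2)
  if (tot <= 0) return(0)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1L) / (n * dt)
  freqs <- pmin(freqs, 1 / dt - freqs)  # alias to [0, Nyquist]
  min(1, max(0, sum(P[freqs > cutoff_hz]) / sum(P[-1L])))
}

#' Spatial-mean normal-displacement trace over the JAV
#'
#' The scalar trace used for displacement spectrograms: the spatial mean,
#' over nodes within the analyzed JAV extent, of the outward-normal
#' component of the (typically high-pass) displacement. The signed normal
#' projection preserves the oscillation frequencies, which magnitude-based
#' averages rectify to their second harmonic.
#'
#' @param series a displacement [field_series()] (mm).
#' @param mesh a [surface_mesh()] with node normals.
#' @param cl a [centerline()].
#' @param extent_mm JAV extent considered (default 25 mm).
#' @return Numeric vector, one value per timestep (mm).
#' @export
jav_mean_trace <- function(series, mesh, cl, extent_mm = 25) {
  if (is.null(mesh$node_normals)) stop("mesh has no node normals")
  proj <- project_to_centerline(mesh$node_coords, cl)
  keep <- proj$arclength >= 0 & proj$arclength < extent_mm
  if (!any(keep)) stop("no nodes within the JAV extent")
  nrm <- mesh$node_normals[keep, , drop = FALSE]
  v <- series$values
  (v[, keep, 1L] %*% nrm[, 1L] + v[, keep, 2L] %*% nrm[, 2L] +
     v[, keep, 3L] %*% nrm[, 3L])[, 1L] / sum(keep)
}
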