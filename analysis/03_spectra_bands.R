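#!/usr/bin/env Rscript
# Step 3 -- spectral signatures of the three outcome groups: JAV-mean
# displacement spectrograms of the high-pass wall motion, time-averaged
# PSDs, and narrowband detection (expected: none for patency, a single
# ~50 Hz band for dilatation, two bands within 45-100 Hz for stenosis).
#
# Writes results/spectra/psd_<group>.csv and results/spectra/bands.csv.

library(vesselvib)

dir.create("results/spectra", recursive = TRUE, showWarnings = FALSE)
cfg <- pipeline_config()
tube <- make_tube()
presets <- default_presets()

band_rows <- list()
for (g in names(presets)) {
  set.seed(10L + match(g, names(presets)))
  d <- generate_wall_motion(tube$mesh, tube$centerline, presets[[g]])
  hp <- highpass_filter(d, cfg$highpass_cutoff_hz)
  tr <- jav_mean_trace(hp, tube$mesh, tube$centerline)
  sp <- spectrogram(tr, d$dt, cfg$spectrogram_window_s, cfg$spectrogram_overlap_frac)
  ps <- psd_timeavg(sp)
  utils::write.csv(ps, sprintf("results/spectra/psd_%s.csv", g), row.names = FALSE)
  bs <- detect_bands(sp, threshold_db = cfg$band_threshold_db,
                     cutoff_hz = cfg$highpass_cutoff_hz,
                     fmax_hz = cfg$band_fmax_hz,
                     min_width_hz = cfg$band_min_width_hz,
                     min_gap_hz = cfg$band_min_gap_hz,
                     prominence_drop_db = cfg$band_prominence_db)
  cat(sprintf("%-11s %d band(s)%s\n", g, nrow(bs),
              if (nrow(bs)) paste0(": ", paste(sprintf("%.1f Hz", bs$f_center_hz),
                                               collapse = ", ")) else ""))
  if (nrow(bs)) band_rows[[g]] <- cbind(group = g, as.data.frame(bs))
}
bands <- if (length(band_rows)) do.call(rbind, band_rows) else
  data.frame(group = character(), f_low_hz = numeric(), f_high_hz = numeric(),
             f_center_hz = numeric(), peak_db = numeric())
utils::write.csv(bands, "results/spectra/bands.csv", row.names = FALSE)
cat("wrote results/spectra\n")
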