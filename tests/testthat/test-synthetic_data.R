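test_that("tube geometry satisfies its construction contract", {
  tube <- make_tube(radius_mm = 3, length_mm = 30, n_axial = 31L, n_circ = 32L)
  expect_equal(max(tube$centerline$arclength), 30)
  d <- sqrt(tube$mesh$node_coords[, 1L]^2 + tube$mesh$node_coords[, 2L]^2)
  expect_equal(d, rep(3, length(d)), tolerance = 1e-12)
  expect_true(all(abs(rowSums(tube$mesh$node_normals *
                                tube$mesh$node_coords[, 1:3] /
                                cbind(d, d, pmax(d, 1)))[1:5] - 1) < 1))
  expect_error(make_tube(radius_mm = -1), "positive")
  expect_error(make_tube(n_axial = 1L), "n_axial")
  expect_error(make_tube(n_circ = 2L), "n_circ")
})

test_that("presets validate band definitions and cutoff consistency", {
  expect_error(synthetic_preset("x", 5, 0.3, vib_bands = list(c(50, -2, 1))),
               "width")
  tube <- small_tube()
  low <- fast_preset(vib_bands = list(c(10, 4, 1)))
  expect_error(generate_wall_motion(tube$mesh, tube$centerline, low, dt = 1e-3,
                                    n_cycles = 1),
               "configuration error")
  hi <- fast_preset(vib_bands = list(c(400, 10, 1)))
  expect_error(generate_wall_motion(tube$mesh, tube$centerline, hi, dt = 1e-2,
                                    n_cycles = 1), "too coarse")
})

test_that("a silent preset produces no high-pass content", {
  tube <- small_tube()
  silent <- synthetic_preset("quiet", target_timeavg_amp_um = 0,
                             target_strain_e3 = 0, vib_bands = list(),
                             base_pulsation_amp_mm = 0, noise_floor_um = 0)
  d <- generate_wall_motion(tube$mesh, tube$centerline, silent, dt = 1e-3,
                            n_cycles = 2)
  hp <- highpass_filter(d, 25)
  expect_lt(max(vibration_amplitude(hp)$amp_map), 1e-9)  # um
})

test_that("the generator self-calibrates the slice-mean amplitude within 5%", {
  tube <- small_tube(n_axial = 31L, n_circ = 12L)
  pre <- fast_preset(target_timeavg_amp_um = 12, target_strain_e3 = 0.9)
  set.seed(41)
  d <- generate_wall_motion(tube$mesh, tube$centerline, pre, dt = 1e-3,
                            n_cycles = 2)
  hp <- highpass_filter(d, 25)
  sa <- assign_nodes_to_slices(tube$mesh, tube$centerline)
  amp <- slice_means(vibration_amplitude(hp)$amp_map, sa, "amp")$mean_value
  expect_equal(mean(amp), 12, tolerance = 0.05)
  strain <- slice_means(highpass_strain(tube$mesh, hp)$strain_map, sa, "s")$mean_value
  expect_equal(mean(strain), 0.9e-3, tolerance = 0.10)
})

test_that("generated series are reproducible from the seed", {
  tube <- small_tube(n_axial = 10L, n_circ = 8L)
  pre <- fast_preset(target_strain_e3 = 0)
  d1 <- generate_wall_motion(tube$mesh, tube$centerline, pre, dt = 1e-3,
                             n_cycles = 1, seed = 7L, calibrate = FALSE)
  d2 <- generate_wall_motion(tube$mesh, tube$centerline, pre, dt = 1e-3,
                             n_cycles = 1, seed = 7L, calibrate = FALSE)
  expect_identical(d1$values, d2$values)
})

test_that("at least 90% of supra-cutoff vibration power lies in the declared bands", {
  tube <- small_tube(n_axial = 10L, n_circ = 8L)
  pre <- fast_preset(target_strain_e3 = 0, noise_floor_um = 0,
                     base_pulsation_amp_mm = 0)
  set.seed(42)
  d <- generate_wall_motion(tube$mesh, tube$centerline, pre, dt = 1e-3,
                            n_cycles = 2, calibrate = FALSE)
  # FFT oracle on a few node traces
  for (node in c(1L, 20L, 45L)) {
    x <- d$values[, node, 1L] + d$values[, node, 2L]
    P <- Mod(stats::fft(x - mean(x)))^2
    f <- (seq_along(x) - 1L) / (length(x) * d$dt)
    f <- pmin(f, 1 / d$dt - f)
    hi <- sum(P[f > 25])
    in_band <- sum(P[f >= 45 & f <= 55])
    if (hi > 0) expect_gte(in_band / hi, 0.9)
  }
})

test_that("traction regimes hit their closed-form index values", {
  tube <- small_tube(n_axial = 8L, n_circ = 8L)
  st <- generate_traction_series(tube$mesh, "steady", dt = 1e-3, n_cycles = 1,
                                 magnitude_pa = 1.5)
  expect_equal(unique(round(tawss(st), 12)), 1.5)
  expect_equal(max(osi(st)), 0)

  osc <- generate_traction_series(tube$mesh, "oscillatory", dt = 1e-3,
                                  n_cycles = 2, magnitude_pa = 2)
  expect_equal(unique(round(osi(osc), 6)), 0.5)
  expect_equal(unique(round(tawss(osc), 4)), round(2 * 2 / pi, 4))

  set.seed(43)
  tb <- generate_traction_series(tube$mesh, "turbulent_like", dt = 1e-3,
                                 n_cycles = 2, hf_power_frac = 0.3)
  sp_vals <- apply(field_magnitude(tb), 2L, spi, dt = 1e-3)
  expect_equal(mean(sp_vals), 0.3, tolerance = 0.02)
  expect_error(generate_traction_series(tube$mesh, "warp"), "arg")
})

test_that("cohorts are seed-reproducible and follow the 2+2+2 study design", {
  c1 <- make_cohort(seed = 5L, dt = 2e-3, n_cycles = 1,
                    presets = lapply(default_presets(), function(p) {
                      p$vib_bands <- list(c(50, 10, 1)); p
                    }),
                    mesh_args = list(n_axial = 10L, n_circ = 8L),
                    traction = FALSE, calibrate = FALSE)
  expect_length(c1, 6L)
  expect_equal(unname(vapply(c1, `[[`, character(1L), "group_label")),
               rep(c("patency", "stenosis", "dilatation"), each = 2L))
  expect_equal(names(c1), c("P1", "P2", "S1", "S2", "D1", "D2"))
  c2 <- make_cohort(seed = 5L, dt = 2e-3, n_cycles = 1,
                    presets = lapply(default_presets(), function(p) {
                      p$vib_bands <- list(c(50, 10, 1)); p
                    }),
                    mesh_args = list(n_axial = 10L, n_circ = 8L),
                    traction = FALSE, calibrate = FALSE)
  expect_identical(c1$S1$displacement$values, c2$S1$displacement$values)
  expect_error(make_cohort(n_per_group = c(patency = 0L)), "at least one")
})

test_that("zero between-patient SD pins every patient to the group mean", {
  pre <- fast_preset(amp_sd_um = 0, strain_sd_e3 = 0, target_strain_e3 = 0)
  set.seed(44)
  co <- make_cohort(n_per_group = c(test = 2L), presets = list(test = pre),
                    dt = 1e-3, n_cycles = 2,
                    mesh_args = list(n_axial = 31L, n_circ = 12L),
                    traction = FALSE, calibrate = FALSE)
  for (p in co) {
    expect_equal(unname(p$targets["amp_um"]), 10)
    expect_equal(unname(attr(p$displacement, "realized_amp_um")), 10,
                 tolerance = 0.05)
  }
})

test_that("slice-level simulation is seed-stable with positive values", {
  s1 <- simulate_slice_table(seed = 45L)
  s2 <- simulate_slice_table(seed = 45L)
  expect_identical(s1, s2)
  expect_true(all(s1$mean_value > 0))
})
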