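test_that("high-pass filter rejects DC and passes the band with unit gain", {
  fs <- 2000
  nt <- 4000L
  const <- disp_series(array(2.5, dim = c(nt, 3L, 3L)), dt = 1 / fs)
  hp <- highpass_filter(const, 25)
  expect_lt(max(abs(hp$values)) / 2.5, 1e-12)

  t <- (seq_len(nt) - 1L) / fs
  a <- 0.8
  u <- array(0, dim = c(nt, 1L, 3L))
  u[, 1L, 1L] <- a * sin(2 * pi * 50 * t)
  hp2 <- highpass_filter(disp_series(u, dt = 1 / fs), 25)
  int <- 501:3500
  expect_equal(max(abs(hp2$values[int, 1L, 1L])), a, tolerance = 0.01)
})

test_that("filter matches the FFT brick-wall oracle on a 5 + 50 Hz mixture", {
  fs <- 2000
  t <- (0:5999) / fs
  x <- 3 * sin(2 * pi * 5 * t) + 1.5 * sin(2 * pi * 50 * t + 0.3)
  u <- array(0, dim = c(6000L, 1L, 3L)); u[, 1L, 1L] <- x
  y <- highpass_filter(disp_series(u, dt = 1 / fs), 25)$values[, 1L, 1L]
  yo <- fft_highpass_oracle(x, 1 / fs, 25)
  int <- 1001:5000
  rel_rms <- sqrt(mean((y - yo)[int]^2)) / sqrt(mean(yo[int]^2))
  expect_lt(rel_rms, 0.02)
})

test_that("filter is linear and does not amplify energy", {
  fs <- 1000
  set.seed(5)
  mk <- function(x) {
    u <- array(0, dim = c(length(x), 1L, 3L)); u[, 1L, 1L] <- x
    disp_series(u, dt = 1 / fs)
  }
  x1 <- rnorm(2000); x2 <- cumsum(rnorm(2000)) / 10
  h <- function(x) highpass_filter(mk(x), 25)$values[, 1L, 1L]
  lhs <- h(2 * x1 - 3 * x2)
  rhs <- 2 * h(x1) - 3 * h(x2)
  expect_equal(lhs, rhs, tolerance = 1e-10)
  expect_lte(sqrt(mean(h(x1)^2)), sqrt(mean(x1^2)) * (1 + 1e-6))
})

test_that("filter refuses series too short for the cutoff", {
  u <- array(rnorm(50 * 3), dim = c(50L, 1L, 3L))
  s <- field_series(u, dt = 1e-3, field_name = "displacement", cycle_length = 0.05)
  expect_error(highpass_filter(s, 25), "too short")
})

test_that("vibration amplitude is the time-averaged magnitude in micrometres", {
  zero <- disp_series(array(0, dim = c(2000L, 4L, 3L)), dt = 1e-3)
  expect_true(all(vibration_amplitude(zero)$amp_map == 0))

  # single node oscillating along one axis: mean |A sin| = 2A/pi
  fs <- 1000; nt <- 3000L
  A <- 0.012  # mm
  u <- array(0, dim = c(nt, 1L, 3L))
  u[, 1L, 1L] <- A * sin(2 * pi * 50 * (seq_len(nt) - 1L) / fs)
  va <- vibration_amplitude(disp_series(u, dt = 1 / fs))
  # 20 samples per period: discrete mean of |sin| is within 1% of 2/pi
  expect_equal(va$amp_map[1L], 1000 * A * 2 / pi, tolerance = 0.01)
})

test_that("percentile trace follows the order-statistic interpolation oracle", {
  # brute-force oracle: position (n+1)*q/100 between sorted values
  brute <- function(x, q) {
    x <- sort(x); n <- length(x)
    h <- (n + 1) * q / 100
    lo <- floor(h); hi <- ceiling(h)
    if (lo < 1) return(x[1L]); if (hi > n) return(x[n])
    x[lo] + (h - lo) * (x[hi] - x[lo])
  }
  mags <- rbind(1:100, sample(1:100), rep(7, 100))
  pt99 <- percentile_trace(mags, 99)
  expect_equal(pt99$trace[1L], brute(1:100, 99))
  expect_equal(pt99$trace[1L], 99.99)
  expect_equal(pt99$trace[2L], brute(mags[2L, ], 99))
  expect_equal(pt99$trace[3L], 7)
  expect_equal(percentile_trace(mags, 100)$trace, apply(mags, 1L, max))
  expect_gte(pt99$peak_amp_um, pt99$cycleavg_amp_um)
  expect_error(percentile_trace(matrix(nrow = 3L, ncol = 0L), 99), "empty")
})

test_that("membrane strain vanishes for rigid motion and matches hoop strain for inflation", {
  tube <- small_tube(n_axial = 10L, n_circ = 16L)
  mesh <- tube$mesh
  nn <- nrow(mesh$node_coords)
  nt <- 4L

  # rigid translation
  u <- array(0, dim = c(nt, nn, 3L))
  u[, , 1L] <- 0.4; u[, , 3L] <- -0.2
  st <- vesselvib:::strain_scalar_timeavg(mesh, u)
  expect_lt(max(st$node), 1e-12)

  # uniform radial inflation by stretch lambda: hoop Green-Lagrange strain
  lam <- 1.02
  u2 <- array(0, dim = c(nt, nn, 3L))
  u2[, , 1L] <- rep((lam - 1) * mesh$node_coords[, 1L], each = nt)
  u2[, , 2L] <- rep((lam - 1) * mesh$node_coords[, 2L], each = nt)
  st2 <- vesselvib:::strain_scalar_timeavg(mesh, u2)
  expect_equal(unname(st2$node), rep((lam^2 - 1) / 2, nn), tolerance = 1e-10)
})

test_that("strain is objective: superposed rigid rotation leaves it unchanged", {
  tube <- small_tube(n_axial = 8L, n_circ = 12L)
  mesh <- tube$mesh
  nn <- nrow(mesh$node_coords)
  set.seed(9)
  u <- array(rnorm(3L * nn * 3L, sd = 0.01), dim = c(3L, nn, 3L))
  base <- vesselvib:::strain_scalar_timeavg(mesh, u)
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  X <- mesh$node_coords
  u_rot <- u
  for (s in 1:3) {
    def <- X + u[s, , ]
    def_rot <- def %*% t(R)
    u_rot[s, , ] <- def_rot - X
  }
  rot <- vesselvib:::strain_scalar_timeavg(mesh, u_rot)
  expect_equal(rot$node, base$node, tolerance = 1e-9)
})

test_that("strain on a modulated radial field converges to the local hoop value", {
  # w(z) = w0 sin(pi z / L): membrane hoop strain ~ w/R at leading order
  run <- function(n_axial) {
    tube <- make_tube(radius_mm = 3, length_mm = 30, n_axial = n_axial, n_circ = 48L)
    mesh <- tube$mesh
    z <- mesh$node_coords[, 3L]
    w <- 2e-3 * sin(pi * z / 30)
    nn <- nrow(mesh$node_coords)
    u <- array(0, dim = c(2L, nn, 3L))
    u[, , 1L] <- rep(w * mesh$node_coords[, 1L] / 3, each = 2L)
    u[, , 2L] <- rep(w * mesh$node_coords[, 2L] / 3, each = 2L)
    st <- vesselvib:::strain_scalar_timeavg(mesh, u)
    interior <- z > 5 & z < 25
    max(abs(st$node[interior] - abs(w[interior]) / 3) / (2e-3 / 3))
  }
  err_coarse <- run(16L)
  err_fine <- run(32L)
  expect_lt(err_fine, 0.05)
  expect_lt(err_fine, err_coarse)
})

test_that("vibration summary combines filter, amplitude, percentile and strain", {
  tube <- small_tube()
  set.seed(21)
  pre <- fast_preset(target_strain_e3 = 0, noise_floor_um = 0.02)
  d <- generate_wall_motion(tube$mesh, tube$centerline, pre, dt = 1e-3,
                            n_cycles = 2, calibrate = FALSE)
  vs <- vibration_summary(tube$mesh, d)
  expect_length(vs$p99_trace, 2000L)
  expect_gte(vs$peak_amp_um, vs$cycleavg_amp_um)
  expect_true(all(vs$amp_map >= 0))
  expect_true(all(vs$strain_map >= 0))
})
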