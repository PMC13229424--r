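make_traction <- function(scal, dirs = NULL, dt = 1e-3, cycle_length = 1) {
  nt <- nrow(scal); nn <- ncol(scal)
  if (is.null(dirs)) dirs <- matrix(rep(c(1, 0, 0), each = nn), ncol = 3L)
  vals <- array(0, dim = c(nt, nn, 3L))
  for (cc in 1:3) vals[, , cc] <- scal * rep(dirs[, cc], each = nt)
  field_series(vals, dt = dt, field_name = "wall_traction",
               cycle_length = cycle_length)
}

test_that("TAWSS matches closed forms for constant, sinusoidal and zero traction", {
  nt <- 1000L
  expect_equal(tawss(make_traction(matrix(1.5, nt, 2L))), c(1.5, 1.5))
  t <- (seq_len(nt) - 1L) / nt
  s <- make_traction(matrix(2.4 * sin(2 * pi * t), nt, 1L))
  expect_equal(tawss(s), 2.4 * 2 / pi, tolerance = 1e-4)
  expect_equal(tawss(make_traction(matrix(0, nt, 3L))), c(0, 0, 0))
})

test_that("OSI hits its limits and the hand-integrated asymmetric case", {
  nt <- 1000L
  expect_equal(osi(make_traction(matrix(3, nt, 2L))), c(0, 0))
  t <- (seq_len(nt) - 1L) / nt
  expect_equal(osi(make_traction(matrix(sin(2 * pi * t), nt, 1L))), 0.5,
               tolerance = 1e-3)
  # half cycle forward at 2, half reverse at 1: 0.5 * (1 - 1/3) = 1/3
  x <- c(rep(2, nt / 2), rep(-1, nt / 2))
  expect_equal(osi(make_traction(matrix(x, nt, 1L))), 1 / 3, tolerance = 1e-9)
  expect_equal(osi(make_traction(matrix(0, nt, 1L))), 0)
})

test_that("OSI stays within [0, 0.5] for arbitrary finite tractions", {
  set.seed(13)
  for (k in 1:20) {
    nt <- 400L; nn <- 5L
    vals <- array(rnorm(nt * nn * 3L, sd = runif(1, 0.1, 10)),
                  dim = c(nt, nn, 3L))
    s <- field_series(vals, dt = 1e-3, field_name = "wall_traction",
                      cycle_length = 0.4)
    o <- osi(s)
    expect_true(all(o >= 0 & o <= 0.5))
  }
})

test_that("TAWSS and OSI are invariant under a rigid rotation of the traction frame", {
  set.seed(14)
  nt <- 600L; nn <- 4L
  vals <- array(rnorm(nt * nn * 3L), dim = c(nt, nn, 3L))
  s <- field_series(vals, dt = 1e-3, field_name = "wall_traction",
                    cycle_length = 0.6)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- vals
  for (i in seq_len(nt)) rot[i, , ] <- vals[i, , ] %*% t(R)
  s2 <- field_series(rot, dt = 1e-3, field_name = "wall_traction",
                     cycle_length = 0.6)
  expect_equal(tawss(s2), tawss(s), tolerance = 1e-12)
  expect_equal(osi(s2), osi(s), tolerance = 1e-12)
})

test_that("Q-criterion gives the analytic values for canonical flows", {
  w <- 3.2
  expect_equal(unique(as.vector(q_criterion(generate_velocity_gradients("solid_rotation", w)))),
               w^2)
  expect_equal(max(abs(q_criterion(generate_velocity_gradients("simple_shear", 5)))), 0)
  a <- 1.7
  expect_equal(unique(as.vector(q_criterion(generate_velocity_gradients("pure_extension", a)))),
               -a^2)
})

test_that("Q-criterion is frame-indifferent under orthogonal change of basis", {
  set.seed(15)
  g <- array(rnorm(2L * 3L * 9L), dim = c(2L, 3L, 3L, 3L))
  gs <- velocity_gradient_series(g)
  th <- 0.4
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  g2 <- g
  for (s in 1:2) for (p in 1:3) g2[s, p, , ] <- R %*% g[s, p, , ] %*% t(R)
  expect_equal(q_criterion(velocity_gradient_series(g2)), q_criterion(gs),
               tolerance = 1e-12)
})

test_that("wall shear summary reports SPI of the traction magnitude with JAV means", {
  tube <- small_tube()
  set.seed(16)
  s <- generate_traction_series(tube$mesh, "turbulent_like", dt = 1e-3,
                                n_cycles = 2, hf_power_frac = 0.3)
  ws <- wall_shear_summary(s, tube$mesh, tube$centerline)
  expect_true(all(ws$spi >= 0 & ws$spi <= 1))
  expect_equal(unname(ws$jav_means["spi"]), 0.3, tolerance = 0.03)
  expect_true(all(ws$tawss > 0))
})

test_that("conditional R is 1 for an exact affine per-patient relationship", {
  set.seed(17)
  rows <- list()
  for (i in 1:4) {
    x <- runif(25, 0, 0.5)
    y <- 2 + 30 * x + i  # patient-specific intercept, no noise
    base <- data.frame(patient_id = paste0("P", i), group_label = "g",
                       slice_index = 0:24, arclength_mm = 0:24 + 0.5)
    rows[[paste0(i, "x")]] <- transform(base, metric_name = "spi", mean_value = x,
                                        n_nodes = NA, flagged = FALSE)
    rows[[paste0(i, "y")]] <- transform(base, metric_name = "amp_um", mean_value = y,
                                        n_nodes = NA, flagged = FALSE)
  }
  st <- do.call(rbind, rows)
  # noise-free data: the optimizer rightly grumbles about a boundary fit
  res <- suppressWarnings(correlate_indices(st, wss_metrics = "spi",
                                            vib_metrics = "amp_um"))
  expect_equal(res$R, 1, tolerance = 1e-6)
  expect_lt(res$p_value, 1e-10)
})

test_that("slope inference is calibrated under independence", {
  set.seed(18)
  pvals <- replicate(200, {
    st <- simulate_coupled_indices(n_patients = 6L, n_slices = 25L,
                                   slope = 0, sd_patient = 2, sd_resid = 3)
    res <- correlate_indices(st, wss_metrics = "spi", vib_metrics = "amp_um")
    res$p_value
  })
  expect_gte(mean(pvals > 0.05), 0.9)
})

test_that("conditional R recovers the generating coupling strength", {
  set.seed(19)
  diffs <- replicate(50, {
    st <- simulate_coupled_indices()
    res <- correlate_indices(st, wss_metrics = "spi", vib_metrics = "amp_um")
    res$R - attr(st, "true_R")
  })
  expect_lt(abs(mean(diffs)), 0.1)
  expect_lt(max(abs(diffs)), 0.25)
})

test_that("correlation refuses a single-patient table", {
  st <- simulate_coupled_indices(n_patients = 1L)
  expect_error(correlate_indices(st, wss_metrics = "spi", vib_metrics = "amp_um"),
               "2 patients")
})
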