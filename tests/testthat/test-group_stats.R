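test_that("Bonferroni adjustment follows alpha/n and is monotone", {
  expect_equal(bonferroni(0.05, 3), 0.0167)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.10, 4), 0.025)
  alphas <- sapply(1:8, function(n) bonferroni(0.05, n))
  expect_true(all(diff(alphas) < 0))
  expect_error(bonferroni(1.2, 3))
})

test_that("Shapiro-Wilk wrapper matches an independent reference implementation", {
  x <- c(-2, -1, -1, 0, 0, 0, 0, 1, 1, 2)
  sw <- shapiro_wilk(x)
  # reference value from an independent implementation (scipy.stats.shapiro)
  expect_equal(sw$W, 0.9528768050401295, tolerance = 1e-6)

  # perfect normal quantiles are near-ideal
  q <- qnorm(((1:50) - 0.5) / 50)
  expect_gt(shapiro_wilk(q)$W, 0.99)

  # power against strong skew at n = 100
  set.seed(31)
  rej <- mean(replicate(200, shapiro_wilk(rexp(100))$p < 0.05))
  expect_gte(rej, 0.99)

  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("group summaries are slice-pooled means and sample SDs", {
  one <- data.frame(patient_id = "P1", group_label = "patency",
                    slice_index = 0:9, arclength_mm = 0:9 + 0.5,
                    metric_name = "amp_um", mean_value = 5,
                    n_nodes = NA, flagged = FALSE)
  gs <- summarize_groups(one)
  expect_equal(gs$sd, 0)
  two <- one[1:2, ]; two$mean_value <- c(1, 3)
  gs2 <- summarize_groups(two)
  expect_equal(gs2$mean, 2)
  expect_equal(gs2$sd, sqrt(2))
})

test_that("cohort simulation reproduces the group statistics in expectation", {
  set.seed(32)
  reps <- lapply(1:40, function(i) summarize_groups(simulate_slice_table()))
  all_gs <- do.call(rbind, reps)
  amp <- all_gs[all_gs$metric_name == "amp_um", ]
  means <- tapply(amp$mean, amp$group_label, mean)
  expect_equal(unname(means["patency"]), 6.6, tolerance = 0.08)
  expect_equal(unname(means["stenosis"]), 31.7, tolerance = 0.08)
  expect_equal(unname(means["dilatation"]), 15.9, tolerance = 0.08)
  sds <- tapply(amp$sd, amp$group_label, mean)
  expect_equal(unname(sds["patency"]), 2.0, tolerance = 0.25)
  expect_equal(unname(sds["stenosis"]), 9.7, tolerance = 0.25)
})

test_that("degenerate noise-free data give the exact contrast with p = 0", {
  pr <- default_presets()
  for (g in names(pr)) { pr[[g]]$amp_sd_um <- 0; pr[[g]]$strain_sd_e3 <- 0 }
  st <- simulate_slice_table(presets = pr, seed = 33L)
  m <- fit_lmm(st, "amp_um", "two_group")
  expect_equal(m$model_family, "degenerate")
  expect_equal(m$fixed_effects$estimate, (31.7 + 15.9) / 2 - 6.6, tolerance = 1e-9)
  expect_equal(m$fixed_effects$p_value, 0)
})

test_that("balanced Gaussian fits recover the closed-form GLS (group means)", {
  # balanced random-intercept design: ML fixed effects equal the group means
  set.seed(34)
  rows <- list()
  for (g in c("patency", "stenosis")) {
    mu <- if (g == "patency") 5 else 12
    for (k in 1:3) {
      b <- rnorm(1, sd = 1.5)
      rows[[paste(g, k)]] <- data.frame(
        patient_id = paste0(g, k), group_label = g, slice_index = 0:24,
        arclength_mm = 0:24 + 0.5, metric_name = "amp_um",
        mean_value = mu + b + rnorm(25, sd = 40),  # noisy enough to stay Gaussian
        n_nodes = NA, flagged = FALSE)
    }
  }
  st <- do.call(rbind, rows)
  m <- fit_lmm(st, "amp_um", "two_group")
  expect_equal(m$model_family, "gaussian")
  gm <- tapply(st$mean_value, st$group_label == "patency", mean)
  # balanced design: GLS estimate of the difference = difference of group means
  expect_equal(m$fixed_effects$estimate, unname(gm["FALSE"] - gm["TRUE"]),
               tolerance = 1e-6)
})

test_that("Gaussian and Gamma-log fits agree in contrast sign on separated data", {
  st <- simulate_slice_table(seed = 35L)
  d <- st[st$metric_name == "amp_um", ]
  g <- fit_lmm(st, "amp_um", "two_group")
  lmm <- lme4::lmer(mean_value ~ I(group_label != "patency") + (1 | patient_id),
                    data = d, REML = FALSE)
  expect_gt(g$fixed_effects$estimate * lme4::fixef(lmm)[2L], 0)
})

test_that("three-group contrasts report the Bonferroni-adjusted level", {
  st <- simulate_slice_table(seed = 36L)
  m <- fit_lmm(st, "strain", "three_group")
  expect_equal(m$alpha_adjusted, 0.0167)
  expect_equal(nrow(m$fixed_effects), 2L)
  expect_true(all(c("dilatation - patency", "stenosis - patency") %in%
                    m$fixed_effects$contrast))
  expect_true(m$var_patient >= 0 && m$var_resid >= 0)
  expect_true(all(m$fixed_effects$p_value >= 0 & m$fixed_effects$p_value <= 1))
})

test_that("the patient-level permutation test orders separated vs null cohorts", {
  st <- simulate_slice_table(seed = 37L)
  sep <- permutation_test_groups(st, "amp_um")
  expect_equal(sep$n_assignments, choose(6, 4))
  expect_lte(sep$p_value, 2 / 15 + 1e-9)  # best attainable two-sided with 6 patients
  null <- permutation_test_groups(simulate_slice_table(presets = null_cohort_presets(),
                                                       seed = 38L), "amp_um")
  expect_gt(null$p_value, sep$p_value - 1e-9)
})

test_that("fit_lmm validates its inputs", {
  st <- simulate_slice_table(seed = 39L)
  expect_error(fit_lmm(st, "nope"), "no rows")
  one <- st[st$patient_id == "P1", ]
  expect_error(fit_lmm(one, "amp_um"), "2 patients")
})
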