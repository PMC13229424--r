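## Group comparison of slice-level metrics. A random-intercept linear
## mixed model (ML) is fitted first; when the Shapiro-Wilk test rejects
## normality of its residuals (p < 0.05) the model is refitted as a Gamma
## GLMM with log link (Laplace approximation), the family used in practice
## for positive right-skewed vibration metrics. Group contrasts are
## between-patient comparisons, so their Wald statistics are referred to a
## t distribution with (patients - groups) degrees of freedom -- with six
## patients a normal reference would be badly anticonservative. Two-group design
## contrasts Patency vs Adverse remodeling at alpha = 0.05; three-group
## contrasts each complication group against Patency at the
## Bonferroni-adjusted level alpha / 3.

#' Bonferroni-adjusted significance level
#'
#' @param alpha nominal level in (0, 1).
#' @param n_comparisons number of comparisons (>= 1).
#' @return `alpha / n_comparisons`, rounded to 4 decimals (e.g. 0.05 over
#'   three comparisons gives 0.0167).
#' @export
bonferroni <- function(alpha, n_comparisons) {
  stopifnot(alpha > 0, alpha < 1, n_comparisons >= 1)
  round(alpha / n_comparisons, 4L)
}

#' Shapiro-Wilk normality test
#'
#' @param residuals numeric vector, 3 <= n <= 5000.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(residuals) {
  n <- length(residuals)
  if (n < 3L || n > 5000L) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  t <- stats::shapiro.test(residuals)
  list(W = unname(t$statistic), p = unname(t$p.value))
}

#' Per-group mean and SD of slice-level metrics
#'
#' Summaries are pooled over slices within group (the scale on which the
#' group values are reported); sample SD.
#'
#' @param slice_table long-format slice table (see [slice_means()]).
#' @return data.frame with `group_label`, `metric_name`, `mean`, `sd`, `n`.
#' @export
summarize_groups <- function(slice_table) {
  if (is.null(slice_table) || nrow(slice_table) == 0L) stop("empty slice table")
  dt <- data.table::as.data.table(slice_table)
  out <- dt[, list(mean = mean(mean_value), sd = stats::sd(mean_value), n = .N),
            by = list(group_label, metric_name)]
  data.table::setorderv(out, c("metric_name", "group_label"))
  as.data.frame(out)
}

#' Fit the mixed-effects group comparison for one metric
#'
#' Random-intercept model `value ~ group + (1 | patient)` fitted by maximum
#' likelihood. `two_group` collapses stenosis/dilatation into "Adverse" and
#' contrasts it against Patency; `three_group` contrasts stenosis and
#' dilatation each against Patency, with the Bonferroni-adjusted level
#' reported. When the Shapiro-Wilk test on the Gaussian residuals rejects
#' (p < 0.05), the model is refitted as a Gamma GLMM with log link and
#' that family is reported. Wald statistics for the group contrasts are
#' referred to a t distribution with (patients - groups) degrees of
#' freedom, since the contrasts compare patients, of which there are few.
#' Degenerate data with (near) zero residual variance are handled
#' directly: the contrast is the exact group difference with p = 0.
#'
#' @param slice_table long-format slice table.
#' @param response metric name to analyze (e.g. `"amp_um"`).
#' @param grouping `"two_group"` or `"three_group"`.
#' @param reference reference group label (default `"patency"`).
#' @param alpha nominal significance level.
#' @return A list of class `mixed_model_result`: `fixed_effects` (data.frame
#'   with estimate, SE, z, p per contrast), `var_patient`, `var_resid`,
#'   `shapiro_p`, `model_family`, `conditional_R`, `alpha_adjusted`, `fit`.
#' @export
fit_lmm <- function(slice_table, response,
                    grouping = c("two_group", "three_group"),
                    reference = "patency", alpha = 0.05) {
  grouping <- match.arg(grouping)
  st <- slice_table[slice_table$metric_name == response, , drop = FALSE]
  if (nrow(st) == 0L) stop("no rows for response metric: ", response)
  if (length(unique(st$patient_id)) < 2L)
    stop("need >= 2 patients to identify the patient random effect")
  d <- data.frame(y = st$mean_value,
                  patient = factor(st$patient_id),
                  group = st$group_label, stringsAsFactors = FALSE)
  if (!reference %in% d$group) stop("reference group absent: ", reference)
  if (grouping == "two_group") {
    d$group <- factor(ifelse(d$group == reference, "Patency", "Adverse"),
                      levels = c("Patency", "Adverse"))
    n_comp <- 1L
  } else {
    lev <- c(reference, sort(setdiff(unique(d$group), reference)))
    d$group <- factor(d$group, levels = lev)
    n_comp <- length(lev) - 1L
  }
  if (nlevels(d$group) < 2L) stop("only one group present after grouping")
  alpha_adj <- bonferroni(alpha, max(1L, if (grouping == "three_group") 3L else 1L))

  gm <- tapply(d$y, d$group, mean)
  resid_scale <- sqrt(mean(unlist(tapply(d$y, interaction(d$patient, d$group, drop = TRUE),
                                         function(v) stats::var(v))), na.rm = TRUE))
  if (!is.finite(resid_scale) || resid_scale < 1e-12 * max(abs(gm))) {
    # degenerate: no within-patient variability; report exact differences
    fe <- data.frame(contrast = paste0(levels(d$group)[-1L], " - ", levels(d$group)[1L]),
                     estimate = as.numeric(gm[-1L] - gm[1L]),
                     se = 0, z = Inf, df = NA_integer_, p_value = 0)
    return(structure(list(fixed_effects = fe, var_patient = 0, var_resid = 0,
                          shapiro_p = NA_real_, model_family = "degenerate",
                          conditional_R = 1, alpha_adjusted = alpha_adj,
                          grouping = grouping, response = response, fit = NULL),
                     class = "mixed_model_result"))
  }

  fit <- lme4::lmer(y ~ group + (1 | patient), data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  sw <- shapiro_wilk(stats::residuals(fit))
  family_used <- "gaussian"
  if (sw$p < 0.05 && all(d$y > 0)) {
    fit <- glmmTMB::glmmTMB(y ~ group + (1 | patient), data = d,
                            family = stats::Gamma(link = "log"))
    family_used <- "gamma_log"
  }
  if (family_used == "gaussian") {
    co <- summary(fit)$coefficients
    vc <- lme4::VarCorr(fit)
    var_patient <- as.numeric(vc$patient[1L, 1L])
    var_resid <- attr(vc, "sc")^2
  } else {
    co <- summary(fit)$coefficients$cond
    var_patient <- glmmTMB::VarCorr(fit)$cond$patient[1L, 1L]
    var_resid <- stats::sigma(fit)^2  # Gamma dispersion
  }
  rows <- grep("^group", rownames(co))
  est <- co[rows, 1L]; se <- co[rows, 2L]
  z <- est / se
  # group contrasts compare patients; use the between-patient df
  df_bp <- max(1L, nlevels(d$patient) - nlevels(d$group))
  fe <- data.frame(contrast = paste0(sub("^group", "", rownames(co)[rows]),
                                     " - ", levels(d$group)[1L]),
                   estimate = unname(est), se = unname(se), z = unname(z),
                   df = df_bp,
                   p_value = unname(2 * stats::pt(-abs(z), df = df_bp)))
  structure(list(fixed_effects = fe,
                 var_patient = var_patient, var_resid = var_resid,
                 shapiro_p = sw$p, model_family = family_used,
                 conditional_R = stats::cor(d$y, stats::fitted(fit)),
                 alpha_adjusted = alpha_adj,
                 grouping = grouping, response = response, fit = fit),
            class = "mixed_model_result")
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("<mixed_model_result> %s, %s, family %s (Shapiro p = %s)\n",
              x$response, x$grouping, x$model_family,
              format(x$shapiro_p, digits = 3)))
  cat(sprintf("  var(patient) = %.4g, var(resid/dispersion) = %.4g, conditional R = %.3f\n",
              x$var_patient, x$var_resid, x$conditional_R))
  print(x$fixed_effects, row.names = FALSE, digits = 4)
  cat(sprintf("  adjusted alpha = %.4f\n", x$alpha_adjusted))
  invisible(x)
}

#' Patient-level permutation test for the two-group contrast
#'
#' Distribution-free cross-check of the mixed model: permutes group labels
#' at the patient level and compares the observed difference of group means
#' of patient means against the permutation distribution.
#'
#' @param slice_table long-format slice table.
#' @param response metric name.
#' @param reference reference group label.
#' @param n_perm number of permutations (all distinct assignments are
#'   enumerated when fewer).
#' @return List with `observed` difference and `p_value`.
#' @export
permutation_test_groups <- function(slice_table, response,
                                    reference = "patency", n_perm = 1000L) {
  st <- slice_table[slice_table$metric_name == response, , drop = FALSE]
  pm <- tapply(st$mean_value, st$patient_id, mean)
  grp <- tapply(st$group_label, st$patient_id, function(g) g[1L]) != reference
  obs <- mean(pm[grp]) - mean(pm[!grp])
  n <- length(pm); k <- sum(grp)
  all_assign <- utils::combn(n, k)
  stat <- apply(all_assign, 2L, function(idx) {
    sel <- rep(FALSE, n); sel[idx] <- TRUE
    mean(pm[sel]) - mean(pm[!sel])
  })
  list(observed = obs,
       p_value = mean(abs(stat) >= abs(obs) - 1e-12),
       n_assignments = ncol(all_assign))
}
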