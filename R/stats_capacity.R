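# Outcome statistics and the treatment-capacity calculation.
#
# Group comparisons follow the study's analysis plan: a two-sided t test for
# the two-group infusion-method comparison (Welch form by default, since the
# reported group SDs differ by about 2x), type-II ANOVA with post-hoc Tukey
# HSD for the sonication-parameter effects (the design is unbalanced),
# ANCOVA with relative Gd contrast enhancement as the covariate, and
# ordinary linear regression for the imaging-histology correlations.

#' Two-sample t test from group summaries
#'
#' Welch's unequal-variance t test (or the pooled-variance Student form)
#' computed directly from per-group mean, SD and n.
#'
#' @param mean1,sd1,n1 Summary of group 1.
#' @param mean2,sd2,n2 Summary of group 2.
#' @param pooled Use the pooled-variance (classical Student) form?
#' @return List: `t`, `df`, `p` (two-sided).
#' @examples
#' # infusion-method comparison from group summaries
#' welch_from_summary(1.43, 0.16, 8, 1.14, 0.09, 18)$p  # < 0.01
#' @export
welch_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               pooled = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (sd1 == 0 && sd2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = n1 + n2 - 2, p = 1))
    return(list(t = sign(mean1 - mean2) * Inf, df = n1 + n2 - 2, p = 0))
  }
  if (pooled) {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- sd1^2 / n1
    v2 <- sd2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  tval <- (mean1 - mean2) / se
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df))
}

#' ANOVA with post-hoc Tukey HSD
#'
#' Fits a fixed-effects linear model of `response` on the given factors
#' (additive by default), reports type-II F tests (suited to the unbalanced
#' target counts of the design), and Tukey-adjusted pairwise comparisons of
#' the estimated marginal means of each factor.
#'
#' @param data Outcome table (one row per target).
#' @param response Response column name.
#' @param factors Character vector of factor column names.
#' @param covariate Optional numeric covariate column name (ANCOVA).
#' @param interactions Include pairwise factor interactions?
#' @return List: `anova` (data frame with factor, F, df, p), `tukey` (named
#'   list of pairwise-comparison data frames), `model` (the `lm` fit).
#' @export
anova_tukey <- function(data, response, factors, covariate = NULL,
                        interactions = FALSE) {
  stopifnot(all(c(response, factors, covariate) %in% names(data)))
  df <- data
  for (f in factors) {
    df[[f]] <- factor(df[[f]])
    if (nlevels(df[[f]]) < 2) stop(sprintf("factor %s has fewer than 2 levels", f))
  }
  if (stats::var(df[[response]]) == 0) {
    an <- data.frame(factor = factors, F = 0, df = NA_real_, p = 1)
    return(list(anova = an, tukey = NULL, model = NULL))
  }
  rhs <- paste(c(covariate, factors), collapse = " + ")
  if (interactions && length(factors) > 1) {
    rhs <- paste(rhs, "+", paste(utils::combn(factors, 2, paste, collapse = ":"),
                                 collapse = " + "))
  }
  fml <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(fml, data = df)
  if (any(is.na(stats::coef(fit)))) stop("singular design: aliased coefficients")
  a2 <- car::Anova(fit, type = "II")
  rows <- rownames(a2)
  keep <- rows %in% c(factors, covariate,
                      if (interactions) utils::combn(factors, 2, paste, collapse = ":"))
  an <- data.frame(factor = rows[keep],
                   F = a2$`F value`[keep],
                   df = a2$Df[keep],
                   p = a2$`Pr(>F)`[keep])
  tk <- lapply(factors, function(f) {
    emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", f)))
    as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  })
  names(tk) <- factors
  list(anova = an, tukey = tk, model = fit)
}

#' ANCOVA: factor effects adjusted for relative Gd contrast enhancement
#'
#' @inheritParams anova_tukey
#' @param covariate Covariate column (defaults to `"rel_gd"`).
#' @return As [anova_tukey()].
#' @export
ancova <- function(data, response, factors, covariate = "rel_gd",
                   interactions = FALSE) {
  anova_tukey(data, response, factors, covariate = covariate,
              interactions = interactions)
}

#' Simple linear regression with explained variance
#'
#' @param x,y Numeric vectors.
#' @return List: `slope`, `intercept`, `r2`, `p` (slope t test).
#' @export
linregress_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = sm$r.squared,
       p = unname(sm$coefficients[2, 4]))
}

#' Treatment-capacity plan under the microbubble dose limit
#'
#' Given the regulatory total dose limit and the infusion rate, computes the
#' available delivery window, the ultrasound on-time budget implied by the
#' duty cycle, and the number of targets (and tissue volume at the stated
#' grid spacing) that can be treated with the per-target burst budget.
#'
#' @param dose_limit Total microbubble dose limit, uL/kg.
#' @param dose_rate Infusion rate, uL/kg/min.
#' @param pre_infusion Infusion time before the first sonication, min.
#' @param calib_bursts Expected calibration-phase bursts per target.
#' @param tx_bursts Treatment-phase bursts per target.
#' @param burst_length Burst length, s.
#' @param duty_cycle Fraction of the sonication window spent transmitting.
#' @param cell_dims Treatment-cell dimensions `c(x, y, z)`, m.
#' @return Object of class `capacity_plan`: `delivery_window_min`,
#'   `sonication_window_min`, `on_time_budget_s`, `per_target_on_time_s`,
#'   `n_targets`, `volume_cm3`.
#' @examples
#' capacity_plan()  # ~94 min window, 3500+ targets, 70+ cm^3
#' @export
capacity_plan <- function(dose_limit = 150, dose_rate = 1.6,
                          pre_infusion = 15, calib_bursts = 20,
                          tx_bursts = 60, burst_length = 5e-3,
                          duty_cycle = 0.30,
                          cell_dims = c(2.2e-3, 2.2e-3, 4.4e-3)) {
  stopifnot(dose_limit > 0, dose_rate > 0, pre_infusion >= 0,
            calib_bursts > 0, tx_bursts >= 0, burst_length > 0,
            duty_cycle > 0, duty_cycle <= 1, all(cell_dims > 0))
  delivery <- dose_limit / dose_rate
  sonication <- delivery - pre_infusion
  if (sonication <= 0) stop("pre-infusion time consumes the entire delivery window")
  budget <- sonication * 60 * duty_cycle
  per_target <- (calib_bursts + tx_bursts) * burst_length
  n <- floor(budget / per_target)
  vol <- n * prod(cell_dims) * 1e6  # m^3 -> cm^3
  structure(list(delivery_window_min = delivery,
                 sonication_window_min = sonication,
                 on_time_budget_s = budget,
                 per_target_on_time_s = per_target,
                 n_targets = n,
                 volume_cm3 = vol),
            class = "capacity_plan")
}

#' @export
print.capacity_plan <- function(x, ...) {
  cat(sprintf("capacity_plan: %.2f min delivery window -> %d targets, %.1f cm^3\n",
              x$delivery_window_min, x$n_targets, x$volume_cm3))
  invisible(x)
}
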