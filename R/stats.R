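#' Pooled two-sample t test from group summaries
#'
#' Student's pooled-variance two-sample t statistic computed from group
#' means, standard errors and sizes (as printed in descriptive tables).
#' Standard errors are converted to standard deviations via
#' `sd = se * sqrt(n)`.  The statistic is signed as `mean1 - mean2`.
#'
#' @param mean1,se1,n1 Summary of group 1.
#' @param mean2,se2,n2 Summary of group 2.
#' @return An object of class `htest` with `statistic` (t), `parameter`
#'   (df = n1 + n2 - 2) and two-sided `p.value`.
#' @examples
#' pooled_two_sample_t(68.9, 3.0, 22, 47.9, 1.7, 29)  # |t| about 6.45
#' @export
pooled_two_sample_t <- function(mean1, se1, n1, mean2, se2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, se1 > 0, se2 > 0)
  v1 <- (se1 * sqrt(n1))^2
  v2 <- (se2 * sqrt(n2))^2
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  tstat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(list(statistic = c(t = tstat), parameter = c(df = df),
                 p.value = 2 * pt(-abs(tstat), df),
                 estimate = c(mean1 = mean1, mean2 = mean2),
                 method = "Pooled two-sample t-test (from summaries)",
                 alternative = "two.sided",
                 data.name = "group summaries"),
            class = "htest")
}

#' Pearson chi-square test for a 2x2 table
#'
#' Pearson's chi-square statistic without continuity correction, as used
#' for group sex comparisons.
#'
#' @param counts 2x2 matrix (or length-4 vector, filled by column) of
#'   nonnegative counts.
#' @return An object of class `htest`.
#' @examples
#' chi_square_2x2(matrix(c(16, 14, 13, 8), 2))  # 0.37
#' @export
chi_square_2x2 <- function(counts) {
  if (!is.matrix(counts)) counts <- matrix(counts, 2, 2)
  stopifnot(all(dim(counts) == 2), all(counts >= 0))
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chi-square undefined: zero marginal total")
  out <- stats::chisq.test(counts, correct = FALSE)
  out$data.name <- "2x2 counts"
  out
}

#' Bonferroni significance gate
#'
#' Flags p-values significant at the Bonferroni-adjusted level
#' `0.05 / n_comparisons`, using a strict inequality.  With the default 5
#' region families the threshold is 0.01; subgroup analyses over 2
#' comparisons use 0.025.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @param n_comparisons Number of comparisons corrected for.
#' @return Logical vector.
#' @export
bonferroni_gate <- function(p_values, n_comparisons = 5) {
  stopifnot(all(p_values >= 0 & p_values <= 1, na.rm = TRUE),
            n_comparisons >= 1)
  p_values < 0.05 / n_comparisons
}

# Prepare a region slice of a PAF table for modelling: reference levels
# TD, DR, female; drops rows with missing PAF.
region_model_frame <- function(table, region) {
  req <- c("subject", "diagnosis", "condition", "region", "paf_hz",
           "age_months", "sex")
  stopifnot(all(req %in% names(table)))
  if (!region %in% table$region)
    stop(sprintf("region '%s' not present in table", region))
  df <- table[table$region == region & !is.na(table$paf_hz), ]
  df$diagnosis <- factor(df$diagnosis, levels = c("TD", "ASD"))
  df$condition <- factor(df$condition, levels = c("DR", "EO"))
  df$sex <- factor(df$sex, levels = c("female", "male"))
  df$age <- df$age_months
  df
}

new_paf_model <- function(terms, stat_type, vcov_type, fit, meta) {
  structure(list(coefficients = terms, stat_type = stat_type,
                 vcov_type = vcov_type, fit = fit, meta = meta),
            class = "paf_model")
}

wald_table <- function(est, se, stat_type = c("z", "t"), df = Inf,
                       level = 0.95) {
  stat_type <- match.arg(stat_type)
  stat <- est / se
  if (stat_type == "z") {
    p <- 2 * pnorm(-abs(stat))
    q <- qnorm(1 - (1 - level) / 2)
  } else {
    p <- 2 * pt(-abs(stat), df)
    q <- qt(1 - (1 - level) / 2, df)
  }
  data.frame(term = names(est), estimate = unname(est), se = unname(se),
             statistic = unname(stat), p = unname(p),
             ci_lo = unname(est - q * se), ci_hi = unname(est + q * se),
             stringsAsFactors = FALSE)
}

#' Condition-by-diagnosis mixed model for one macro-region
#'
#' Fits, by maximum likelihood, the linear mixed-effects model
#' `paf_hz ~ diagnosis * condition + age + sex + (1 | subject)` on the
#' non-missing rows of one macro-region, with TD / DR / female as reference
#' levels.  Inference is by Wald z statistics on the fixed effects,
#' matching the asymptotic z columns conventionally reported for such
#' models.
#'
#' @param table A PAF table (see [generate_cohort()] for the layout).
#' @param region Macro-region name, e.g. `"temporal_right"`.
#' @param reml Use REML instead of ML (default `FALSE`).
#' @return A `paf_model` with the fixed-effect Wald table; the underlying
#'   `lme4` fit is in `$fit`, singular-fit and convergence flags in
#'   `$meta`.
#' @export
fit_reactivity_lmm <- function(table, region, reml = FALSE) {
  df <- region_model_frame(table, region)
  for (g in c("TD", "ASD"))
    if (length(unique(df$subject[df$diagnosis == g])) < 2)
      stop(sprintf("fewer than 2 %s subjects with data in %s", g, region))
  fit <- lme4::lmer(paf_hz ~ diagnosis * condition + age + sex +
                      (1 | subject),
                    data = df, REML = reml)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  terms <- wald_table(est, se, "z")
  msgs <- fit@optinfo$conv$lme4$messages
  new_paf_model(terms, "z", "model-based", fit,
                list(region = region, subgroup = NULL,
                     estimator = if (reml) "REML" else "ML",
                     n_obs = nrow(df),
                     n_subjects = length(unique(df$subject)),
                     singular = lme4::isSingular(fit),
                     convergence_messages =
                       if (is.null(msgs)) character(0) else msgs))
}

#' Within-group condition effect for one macro-region
#'
#' The subgroup follow-up to [fit_reactivity_lmm()]: restricted to one
#' diagnostic group, the model drops the diagnosis terms and fits
#' `paf_hz ~ condition + age + sex + (1 | subject)` by maximum likelihood.
#'
#' @inheritParams fit_reactivity_lmm
#' @param diagnosis `"TD"` or `"ASD"`.
#' @return A `paf_model`.
#' @export
fit_subgroup_lmm <- function(table, region, diagnosis = c("TD", "ASD"),
                             reml = FALSE) {
  diagnosis <- match.arg(diagnosis)
  df <- region_model_frame(table, region)
  df <- df[df$diagnosis == diagnosis, ]
  if (length(unique(df$subject)) < 2)
    stop(sprintf("fewer than 2 %s subjects with data in %s",
                 diagnosis, region))
  fit <- lme4::lmer(paf_hz ~ condition + age + sex + (1 | subject),
                    data = df, REML = reml)
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  msgs <- fit@optinfo$conv$lme4$messages
  new_paf_model(wald_table(est, se, "z"), "z", "model-based", fit,
                list(region = region, subgroup = diagnosis,
                     estimator = if (reml) "REML" else "ML",
                     n_obs = nrow(df),
                     n_subjects = length(unique(df$subject)),
                     singular = lme4::isSingular(fit),
                     convergence_messages =
                       if (is.null(msgs)) character(0) else msgs))
}

#' Change scores (EO minus DR) for one macro-region
#'
#' One row per subject with both conditions observed in the region:
#' `delta_paf = EO - DR` and `baseline_paf = DR`, with covariates.
#'
#' @inheritParams fit_reactivity_lmm
#' @return Data frame with columns `subject`, `diagnosis`, `baseline_paf`,
#'   `delta_paf`, `age_months`, `sex`, `srs_total`.
#' @export
change_scores <- function(table, region) {
  df <- region_model_frame(table, region)
  wide <- merge(df[df$condition == "DR",
                   c("subject", "diagnosis", "paf_hz", "age_months", "sex",
                     if ("srs_total" %in% names(df)) "srs_total")],
                df[df$condition == "EO", c("subject", "paf_hz")],
                by = "subject", suffixes = c("_dr", "_eo"))
  out <- data.frame(subject = wide$subject, diagnosis = wide$diagnosis,
                    baseline_paf = wide$paf_hz_dr,
                    delta_paf = wide$paf_hz_eo - wide$paf_hz_dr,
                    age_months = wide$age_months, sex = wide$sex,
                    stringsAsFactors = FALSE)
  if ("srs_total" %in% names(wide)) out$srs_total <- wide$srs_total
  out
}

# OLS with optional HC1 heteroscedasticity-robust standard errors.
ols_model <- function(formula, data, robust = TRUE, meta = list()) {
  fit <- lm(formula, data = data)
  if (fit$df.residual < 1)
    stop("fewer observations than parameters")
  est <- coef(fit)
  if (anyNA(est)) {
    warning("dropping aliased coefficient(s): ",
            paste(names(est)[is.na(est)], collapse = ", "))
    est <- est[!is.na(est)]
  }
  V <- if (robust) sandwich::vcovHC(fit, type = "HC1") else vcov(fit)
  se <- sqrt(diag(V))
  terms <- wald_table(est, se, "t", df = fit$df.residual)
  meta$df <- fit$df.residual
  meta$n_obs <- nrow(data)
  new_paf_model(terms, "t", if (robust) "HC1" else "classical", fit, meta)
}

#' Baseline-dependent change regression for one macro-region
#'
#' Ordinary least squares of the PAF change score (EO minus DR) on the
#' baseline (DR) PAF, diagnosis, age and sex, with HC1
#' heteroscedasticity-robust standard errors.  Optionally adds a
#' diagnosis-by-baseline interaction to test whether the baseline
#' dependence differs by group.
#'
#' @inheritParams fit_reactivity_lmm
#' @param include_interaction Add `diagnosis:baseline_paf`.
#' @param robust Use HC1 robust standard errors (default) or classical.
#' @return A `paf_model` with t statistics on `n - p` residual df.
#' @export
change_score_regression <- function(table, region,
                                    include_interaction = FALSE,
                                    robust = TRUE) {
  cs <- change_scores(table, region)
  f <- if (include_interaction)
    delta_paf ~ baseline_paf * diagnosis + age_months + sex
  else
    delta_paf ~ baseline_paf + diagnosis + age_months + sex
  ols_model(f, cs, robust,
            list(region = region, model = "change-score"))
}

#' Association between PAF reactivity and social responsiveness
#'
#' Regresses log-transformed raw SRS totals on the PAF change score
#' (EO minus DR) for one macro-region, with age and sex as covariates and
#' HC1 robust standard errors.  Raw SRS scores must be strictly positive;
#' the natural log is used (the base rescales coefficients by a constant
#' only).
#'
#' @inheritParams fit_reactivity_lmm
#' @param robust Use HC1 robust standard errors (default).
#' @return A `paf_model`.
#' @export
srs_association <- function(table, region, robust = TRUE) {
  cs <- change_scores(table, region)
  if (!"srs_total" %in% names(cs))
    stop("table has no srs_total column")
  cs <- cs[!is.na(cs$srs_total), ]
  if (any(cs$srs_total <= 0))
    stop("nonpositive SRS raw score; log transform undefined")
  cs$log_srs <- log(cs$srs_total)
  ols_model(log_srs ~ delta_paf + age_months + sex, cs, robust,
            list(region = region, model = "srs-association",
                 srs_log_base = "natural"))
}

#' @export
print.paf_model <- function(x, digits = 3, ...) {
  m <- x$meta
  hdr <- sprintf("%s model", if (!is.null(m$model)) m$model
                 else if (is.null(m$subgroup)) "reactivity mixed"
                 else paste0(m$subgroup, " subgroup mixed"))
  cat(sprintf("%s — region %s (%s SEs, %s statistics)\n", hdr,
              m$region, x$vcov_type, x$stat_type))
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  if (isTRUE(m$singular)) cat("note: random-effects fit is singular\n")
  if (length(m$convergence_messages))
    cat("convergence:", paste(m$convergence_messages, collapse = "; "), "\n")
  invisible(x)
}

#' @export
coef.paf_model <- function(object, ...) {
  setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
summary.paf_model <- function(object, ...) object

#' @export
confint.paf_model <- function(object, parm, level = 0.95, ...) {
  tab <- object$coefficients
  q <- if (object$stat_type == "z") qnorm(1 - (1 - level) / 2)
       else qt(1 - (1 - level) / 2, object$meta$df)
  out <- cbind(tab$estimate - q * tab$se, tab$estimate + q * tab$se)
  rownames(out) <- tab$term
  colnames(out) <- sprintf("%.1f %%", c((1 - level) / 2,
                                        1 - (1 - level) / 2) * 100)
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}
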