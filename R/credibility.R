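#' Power of the two-proportion z-test
#'
#' Normal-approximation power of the two-sided, uncorrected two-proportion
#' z-test for a case-control comparison where the control exposure
#' (present-genotype) prevalence is `p0` and the case prevalence is implied
#' by the alternative odds ratio: `p1 = or_alt * p0 / (1 - p0 + or_alt *
#' p0)`.
#'
#' @param n_cases,n_controls arm sizes (at least 2 each).
#' @param p0 control exposure prevalence, in (0, 1).
#' @param or_alt alternative odds ratio (> 0).
#' @param alpha two-sided significance level, default 0.05.
#' @return power in \[0, 1\].
#' @export
two_proportion_power <- function(n_cases, n_controls, p0, or_alt,
                                 alpha = 0.05) {
  if (!(p0 > 0 && p0 < 1)) stop("`p0` must lie in (0, 1)", call. = FALSE)
  if (or_alt <= 0) stop("`or_alt` must be positive", call. = FALSE)
  if (n_cases < 2 || n_controls < 2) {
    stop("arm sizes must be at least 2", call. = FALSE)
  }
  p1 <- or_alt * p0 / (1 - p0 + or_alt * p0)
  se <- sqrt(p1 * (1 - p1) / n_cases + p0 * (1 - p0) / n_controls)
  zc <- stats::qnorm(1 - alpha / 2)
  delta <- (p1 - p0) / se
  stats::pnorm(delta - zc) + stats::pnorm(-delta - zc)
}

#' False-positive report probability
#'
#' Wacholder's posterior probability that a statistically significant
#' association is in fact a false positive, given the observed significance
#' level, the power of the study to detect the stated alternative odds
#' ratio, and a prior probability that the association is real:
#' `FPRP = p (1 - prior) / (p (1 - prior) + power * prior)`. Vectorized over
#' `prior`; findings with FPRP below 0.2 are conventionally considered
#' noteworthy.
#'
#' @param p_obs observed p-value (used as the significance level), in (0, 1\].
#' @param power_at_alt power to detect the alternative OR, in (0, 1\].
#' @param prior prior probability (or vector of priors) in (0, 1\].
#' @return FPRP value(s) in \[0, 1\], named by prior when `prior` has
#'   length > 1.
#' @export
fprp <- function(p_obs, power_at_alt, prior) {
  if (any(c(p_obs, power_at_alt, prior) <= 0) ||
      any(c(p_obs, power_at_alt, prior) > 1)) {
    stop("all arguments must lie in (0, 1]", call. = FALSE)
  }
  out <- p_obs * (1 - prior) / (p_obs * (1 - prior) + power_at_alt * prior)
  if (length(prior) > 1L) names(out) <- format(prior) else out <- unname(out)
  out
}

#' Venice interim criteria grading
#'
#' Grades the cumulative epidemiological evidence for a pooled association
#' on three axes. Amount of evidence: A when `n_minor` (total cases plus
#' controls with the least frequent genotype) exceeds 1,000, B for 100 to
#' 1,000 inclusive, C below 100. Replication: A when I-squared is below 25%,
#' B for 25 to 50 inclusive, C above 50. Protection from bias: A when any of
#' the supplied checks passes, C otherwise; the recognised checks are
#' `or_in_null_band` (pooled OR within 0.87-1.15, where modest bias could
#' not explain an association away), `genotyping_ok` (high genotyping
#' quality / low error rate), `robust_to_first_study` (significance retained
#' after excluding the first published study) and `no_small_study_effects`
#' (Harbord regression p >= 0.05). Overall: "strong" when all grades are A,
#' "weak" when any grade is C, "moderate" otherwise.
#'
#' @param n_minor nonnegative count.
#' @param i2 I-squared in \[0, 100\].
#' @param bias_checks named logical list/vector; unnamed or missing checks
#'   default to FALSE.
#' @return object of class `credibility_grade`: list with `grade_amount`,
#'   `grade_replication`, `grade_bias`, `overall`, `bias_checks`,
#'   `n_minor`, `i2`.
#' @export
venice_grade <- function(n_minor, i2,
                         bias_checks = list(or_in_null_band = FALSE,
                                            genotyping_ok = FALSE,
                                            robust_to_first_study = FALSE,
                                            no_small_study_effects = FALSE)) {
  if (n_minor < 0) stop("`n_minor` must be nonnegative", call. = FALSE)
  if (i2 < 0 || i2 > 100) stop("`i2` must lie in [0, 100]", call. = FALSE)
  checks <- c(or_in_null_band = FALSE, genotyping_ok = FALSE,
              robust_to_first_study = FALSE, no_small_study_effects = FALSE)
  supplied <- unlist(bias_checks)
  checks[names(supplied)] <- as.logical(supplied)

  grade_amount <- if (n_minor > 1000) "A" else if (n_minor >= 100) "B" else "C"
  grade_replication <- if (i2 < 25) "A" else if (i2 <= 50) "B" else "C"
  grade_bias <- if (any(checks)) "A" else "C"
  grades <- c(grade_amount, grade_replication, grade_bias)
  overall <- if (all(grades == "A")) "strong"
             else if (any(grades == "C")) "weak"
             else "moderate"
  structure(
    list(grade_amount = grade_amount, grade_replication = grade_replication,
         grade_bias = grade_bias, overall = overall,
         bias_checks = as.list(checks), n_minor = n_minor, i2 = i2),
    class = "credibility_grade")
}

#' @export
print.credibility_grade <- function(x, ...) {
  cat(sprintf(
    "Venice grading: amount %s (n_minor = %s), replication %s (I2 = %.1f%%), bias %s -> %s evidence\n",
    x$grade_amount, format(x$n_minor, big.mark = ","),
    x$grade_replication, x$i2, x$grade_bias, x$overall))
  invisible(x)
}

#' Credibility assessment of a pooled genotype association
#'
#' Convenience composition of the credibility stage for one study table:
#' pools the studies, computes power at the stated alternative OR from the
#' aggregated arm sizes and the control present-genotype prevalence, FPRP at
#' each prior, and the Venice grades. The bias-protection checks that can be
#' derived from the data (pooled OR in the null band; Harbord regression
#' p >= 0.05; significance retained after dropping the first study, taken as
#' the first row of the table) are filled in automatically; `genotyping_ok`
#' is a study-quality judgement the caller must supply.
#'
#' @param studies a `genotype_studies` table (first row = earliest study).
#' @param alt_or alternative odds ratio for the power/FPRP calculations.
#' @param priors vector of prior probabilities, default
#'   `c(0.05, 0.01, 0.001, 1e-4, 1e-5, 1e-6)`.
#' @param model pooling model passed to [pool_studies()].
#' @param genotyping_ok logical study-quality flag (default FALSE).
#' @param fprp_alpha `"observed"` (default) evaluates the FPRP power term at
#'   a significance level equal to the observed pooled p; `"nominal"` uses
#'   0.05.
#' @return list: `pooled` (a `pooled_result`), `power`, `fprp_by_prior`,
#'   `grades` (a `credibility_grade`), `n_minor`.
#' @export
assess_credibility <- function(studies, alt_or,
                               priors = c(0.05, 0.01, 0.001, 1e-4, 1e-5,
                                          1e-6),
                               model = "auto", genotyping_ok = FALSE,
                               fprp_alpha = c("observed", "nominal")) {
  fprp_alpha <- match.arg(fprp_alpha)
  d <- as_genotype_studies(studies)
  pooled <- pool_studies(d, model = model)
  gs <- genotype_summary(d)
  n_cases <- gs$totals[["case_null"]] + gs$totals[["case_present"]]
  n_controls <- gs$totals[["control_null"]] + gs$totals[["control_present"]]
  p0 <- gs$totals[["control_present"]] / n_controls
  power <- two_proportion_power(n_cases, n_controls, p0, pooled$pooled_or)
  alpha <- if (fprp_alpha == "observed") pooled$p else 0.05
  power_alt <- two_proportion_power(n_cases, n_controls, p0, alt_or,
                                    alpha = alpha)
  fp <- fprp(pooled$p, power_alt, priors)
  harbord <- if (nrow(d) >= 3L) harbord_test(d) else NULL
  drop_first <- if (nrow(d) >= 3L) {
    pool_studies(d[-1L, , drop = FALSE], model = model)$p < 0.05
  } else FALSE
  grades <- venice_grade(
    gs$n_minor, pooled$i2,
    bias_checks = list(
      or_in_null_band = pooled$pooled_or >= 0.87 & pooled$pooled_or <= 1.15,
      genotyping_ok = genotyping_ok,
      robust_to_first_study = drop_first,
      no_small_study_effects = !is.null(harbord) && harbord$p >= 0.05))
  list(pooled = pooled, power = power, fprp_by_prior = fp, grades = grades,
       n_minor = gs$n_minor)
}
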