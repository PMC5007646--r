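#' Read genotype case-control study tables
#'
#' Reads a CSV with one row per study and columns `study_id`, `ethnicity`,
#' `case_null`, `case_present`, `control_null`, `control_present`. The null
#' genotype is homozygous loss of the gene; the present genotype is any
#' retained copy (heterozygous loss or homozygous presence). All pooled odds
#' ratios produced downstream are for the *present* genotype (exposure =
#' present, so an OR below 1 means the present genotype is protective).
#'
#' @param path CSV file path.
#' @return data.frame of class `genotype_studies`.
#' @export
read_studies <- function(path) {
  if (!file.exists(path)) stop("study file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_genotype_studies(d)
}

#' Coerce a data.frame to a validated study table
#'
#' @param d data.frame with the columns described in [read_studies()].
#' @return the same data.frame, validated, with class `genotype_studies`.
#' @export
as_genotype_studies <- function(d) {
  need <- c("study_id", "ethnicity", "case_null", "case_present",
            "control_null", "control_present")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("study table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  cnt <- c("case_null", "case_present", "control_null", "control_present")
  for (cl in cnt) {
    v <- d[[cl]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0) || any(v != round(v))) {
      stop("column ", cl, " must hold nonnegative integer counts",
           call. = FALSE)
    }
    d[[cl]] <- as.numeric(v)  # doubles: avoids integer overflow downstream
  }
  if (any(d$case_null + d$case_present < 1) ||
      any(d$control_null + d$control_present < 1)) {
    stop("every study needs at least one case and one control", call. = FALSE)
  }
  class(d) <- c("genotype_studies", "data.frame")
  d
}

#' Per-study odds ratios for the present genotype
#'
#' Computes each study's odds ratio for carrying the gene (present vs null
#' genotype): `OR = (case_present * control_null) / (case_null *
#' control_present)`, with the Woolf standard error of the log OR,
#' `sqrt(sum of 1/cell)`. When any cell is zero the Haldane-Anscombe
#' correction adds 0.5 to all four cells of that study before computing
#' (flagged in `corrected`). A study with an entirely empty margin carries
#' no information about the association and is an error.
#'
#' @param studies a `genotype_studies` table (or coercible data.frame).
#' @return data.frame of class `study_effects`: `study_id`, `or`, `log_or`,
#'   `se`, `corrected`.
#' @export
study_effects <- function(studies) {
  d <- as_genotype_studies(studies)
  a <- d$case_present; b <- d$control_present
  cc <- d$case_null;   dd <- d$control_null
  n_tot <- a + b + cc + dd
  if (any(a + b == 0 | cc + dd == 0 | a + cc == 0 | b + dd == 0)) {
    stop("degenerate study: an entire margin of the 2x2 table is zero",
         call. = FALSE)
  }
  corrected <- a == 0 | b == 0 | cc == 0 | dd == 0
  a <- a + 0.5 * corrected; b <- b + 0.5 * corrected
  cc <- cc + 0.5 * corrected; dd <- dd + 0.5 * corrected
  log_or <- log((a * dd) / (cc * b))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  structure(
    data.frame(study_id = d$study_id, or = exp(log_or), log_or = log_or,
               se = se, corrected = corrected, stringsAsFactors = FALSE),
    class = c("study_effects", "data.frame"))
}

#' Per-study Pearson chi-square test of genotype distribution
#'
#' Uncorrected (no Yates continuity correction) Pearson chi-square on each
#' study's 2x2 genotype table, 1 degree of freedom.
#'
#' @param studies a `genotype_studies` table.
#' @return data.frame: `study_id`, `statistic`, `p`.
#' @export
genotype_chisq <- function(studies) {
  d <- as_genotype_studies(studies)
  a <- d$case_present; b <- d$control_present
  cc <- d$case_null;   dd <- d$control_null
  n <- a + b + cc + dd
  r1 <- a + cc; r2 <- b + dd; c1 <- a + b; c2 <- cc + dd
  if (any(r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0)) {
    stop("zero margin: chi-square test undefined", call. = FALSE)
  }
  stat <- n * (a * dd - b * cc)^2 / (r1 * r2 * c1 * c2)
  data.frame(study_id = d$study_id, statistic = stat,
             p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Cochran's Q heterogeneity statistic
#'
#' Inverse-variance weighted heterogeneity test of the per-study log odds
#' ratios: `Q = sum w_i (y_i - ybar)^2` with `w_i = 1/se_i^2`, referred to a
#' chi-square with k - 1 degrees of freedom. By meta-analytic convention a
#' p-value below 0.1 flags significant heterogeneity.
#'
#' @param effects a `study_effects` table (from [study_effects()]).
#' @return list: `Q`, `df`, `p`.
#' @export
cochran_q <- function(effects) {
  y <- effects$log_or; se <- effects$se
  k <- length(y)
  if (k < 2L) stop("Cochran's Q needs at least 2 studies", call. = FALSE)
  w <- 1 / se^2
  ybar <- sum(w * y) / sum(w)
  Q <- sum(w * (y - ybar)^2)
  df <- k - 1L
  list(Q = Q, df = df, p = stats::pchisq(Q, df, lower.tail = FALSE))
}

#' I-squared with Higgins-Thompson confidence interval
#'
#' `I2 = max(0, (Q - df)/Q) * 100` is the percentage of variability in the
#' effect estimates attributable to between-study heterogeneity rather than
#' sampling error. The confidence interval is the Higgins-Thompson
#' test-based interval on `ln H` (`H = sqrt(Q/df)`), using
#' `se(ln H) = (ln Q - ln df) / (2 (sqrt(2Q) - sqrt(2 df - 1)))` when
#' `Q > df` and the small-Q closed form
#' `sqrt(1/(2(df-1)) * (1 - 1/(3(df-1)^2)))` otherwise, back-transformed via
#' `I2 = (H^2 - 1)/H^2` and truncated to \[0, 100\].
#'
#' @param Q Cochran's Q.
#' @param df degrees of freedom (k - 1), at least 1.
#' @param level confidence level, default 0.95.
#' @return list: `i2`, `ci_low`, `ci_high` (percent).
#' @export
i_squared <- function(Q, df, level = 0.95) {
  if (df < 1L) stop("`df` must be at least 1", call. = FALSE)
  i2 <- if (Q > 0) max(0, (Q - df) / Q) * 100 else 0
  zc <- stats::qnorm(1 - (1 - level) / 2)
  if (df == 1L && Q <= df) {
    # se(lnH) undefined for a single df at small Q; the interval is vacuous
    return(list(i2 = i2, ci_low = 0, ci_high = 100))
  }
  se_lnH <- if (Q > df) {
    0.5 * (log(Q) - log(df)) / (sqrt(2 * Q) - sqrt(2 * df - 1))
  } else {
    sqrt(1 / (2 * (df - 1)) * (1 - 1 / (3 * (df - 1)^2)))
  }
  lnH <- log(sqrt(max(Q, .Machine$double.xmin) / df))
  h2i2 <- function(h) max(0, min(100, (h^2 - 1) / h^2 * 100))
  list(i2 = i2,
       ci_low = h2i2(exp(lnH - zc * se_lnH)),
       ci_high = h2i2(exp(lnH + zc * se_lnH)))
}

new_pooled_result <- function(model, k, log_or, se, het) {
  z <- log_or / se
  structure(
    list(model = model, k = k,
         pooled_or = exp(log_or),
         ci_low = exp(log_or - 1.96 * se),
         ci_high = exp(log_or + 1.96 * se),
         log_or = log_or, se = se, z = z,
         p = 2 * stats::pnorm(-abs(z)),
         Q = het$Q, df = het$df, q_p = het$q_p, tau2 = het$tau2,
         i2 = het$i2, i2_ci_low = het$i2_ci_low, i2_ci_high = het$i2_ci_high),
    class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, digits = 3, ...) {
  cat(sprintf("%s pooling of %d studies (present vs null genotype)\n",
              x$model, x$k))
  cat(sprintf("  OR %.*f (95%% CI %.*f-%.*f), z = %.*f, p = %.3g\n",
              digits, x$pooled_or, digits, x$ci_low, digits, x$ci_high,
              digits, x$z, x$p))
  cat(sprintf(
    "  Q = %.*f (df %d, p = %.3g), tau2 = %.*f, I2 = %.1f%% (%.1f-%.1f)\n",
    digits, x$Q, x$df, x$q_p, digits, x$tau2, x$i2, x$i2_ci_low,
    x$i2_ci_high))
  invisible(x)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Moment-based random-effects meta-analysis of the per-study log odds
#' ratios: the between-study variance is
#' `tau2 = max(0, (Q - df) / (sum w - sum w^2 / sum w))` with
#' inverse-variance weights `w = 1/se^2`; studies are then re-weighted by
#' `1/(se^2 + tau2)` and the pooled log OR, its normal-approximation 95%
#' confidence interval (1.96 critical value, the RevMan convention) and a
#' two-sided z-test are reported along with Q, tau2 and I-squared.
#'
#' @param effects a `study_effects` table with at least 2 rows.
#' @return object of class `pooled_result`.
#' @export
pool_dl <- function(effects) {
  if (inherits(effects, "genotype_studies")) effects <- study_effects(effects)
  k <- nrow(effects)
  if (is.null(k) || k < 2L) stop("pooling needs at least 2 studies",
                                 call. = FALSE)
  y <- effects$log_or; v <- effects$se^2
  het <- cochran_q(effects)
  w <- 1 / v
  tau2 <- max(0, (het$Q - het$df) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (v + tau2)
  mu <- sum(ws * y) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  i2 <- i_squared(het$Q, het$df)
  new_pooled_result("DL_random", k, mu, se,
                    list(Q = het$Q, df = het$df, q_p = het$p, tau2 = tau2,
                         i2 = i2$i2, i2_ci_low = i2$ci_low,
                         i2_ci_high = i2$ci_high))
}

#' Mantel-Haenszel fixed-effect pooling
#'
#' Stratified fixed-effect odds ratio
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)` (a = case present,
#' b = control present, c = case null, d = control null), with the
#' Robins-Breslow-Greenland variance for the confidence interval.
#' Heterogeneity statistics (Q, I-squared) are computed from the
#' inverse-variance log odds ratios as usual; `tau2` is 0 by construction
#' under the fixed-effect model.
#'
#' @param studies a `genotype_studies` table with at least 2 rows.
#' @return object of class `pooled_result`.
#' @export
pool_mh <- function(studies) {
  d <- as_genotype_studies(studies)
  k <- nrow(d)
  if (k < 2L) stop("pooling needs at least 2 studies", call. = FALSE)
  a <- d$case_present; b <- d$control_present
  cc <- d$case_null;  dd <- d$control_null
  n <- a + b + cc + dd
  R <- sum(a * dd / n); S <- sum(b * cc / n)
  if (R == 0 || S == 0) {
    stop("Mantel-Haenszel denominator sum is zero", call. = FALSE)
  }
  P <- (a + dd) / n; Qi <- (b + cc) / n
  Ri <- a * dd / n; Si <- b * cc / n
  var_log <- sum(P * Ri) / (2 * R^2) +
    sum(P * Si + Qi * Ri) / (2 * R * S) +
    sum(Qi * Si) / (2 * S^2)
  het <- cochran_q(study_effects(d))
  i2 <- i_squared(het$Q, het$df)
  new_pooled_result("MH_fixed", k, log(R / S), sqrt(var_log),
                    list(Q = het$Q, df = het$df, q_p = het$p, tau2 = 0,
                         i2 = i2$i2, i2_ci_low = i2$ci_low,
                         i2_ci_high = i2$ci_high))
}

#' Model selection by study count
#'
#' Fewer than 20 studies: DerSimonian-Laird random effects; 20 or more:
#' Mantel-Haenszel fixed effect.
#'
#' @param k number of studies (at least 2).
#' @return `"DL_random"` or `"MH_fixed"`.
#' @export
select_model <- function(k) {
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (k < 20L) "DL_random" else "MH_fixed"
}

#' Pool a study table under the count-selected (or a forced) model
#'
#' @param studies a `genotype_studies` table.
#' @param model `"auto"` (default, see [select_model()]), `"DL_random"` or
#'   `"MH_fixed"`.
#' @return a `pooled_result`.
#' @export
pool_studies <- function(studies, model = c("auto", "DL_random", "MH_fixed")) {
  model <- match.arg(model)
  d <- as_genotype_studies(studies)
  if (model == "auto") model <- select_model(nrow(d))
  if (model == "DL_random") pool_dl(study_effects(d)) else pool_mh(d)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-pools the studies k times, omitting one study each time, and reports
#' the pooled OR, CI and overall-effect p for every omission. Following the
#' field-synopsis convention the default re-pools under the model *not*
#' selected for the primary analysis (`model = "alternate"`), so the
#' sensitivity scan also probes model dependence; a specific model can be
#' forced instead.
#'
#' @param studies a `genotype_studies` table with at least 3 rows.
#' @param model `"alternate"` (default), `"DL_random"` or `"MH_fixed"`.
#' @return data.frame: `omitted_id`, `pooled_or`, `ci_low`, `ci_high`, `p`;
#'   attributes `p_range` (min/max of p) and `model`.
#' @export
leave_one_out <- function(studies,
                          model = c("alternate", "DL_random", "MH_fixed")) {
  model <- match.arg(model)
  d <- as_genotype_studies(studies)
  k <- nrow(d)
  if (k < 3L) stop("leave-one-out needs at least 3 studies", call. = FALSE)
  if (model == "alternate") {
    model <- setdiff(c("DL_random", "MH_fixed"), select_model(k))
  }
  rows <- lapply(seq_len(k), function(i) {
    p <- pool_studies(d[-i, , drop = FALSE], model = model)
    data.frame(omitted_id = d$study_id[i], pooled_or = p$pooled_or,
               ci_low = p$ci_low, ci_high = p$ci_high, p = p$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "p_range") <- range(out$p)
  attr(out, "model") <- model
  out
}

#' Harbord's test for small-study effects
#'
#' Score-based regression test for funnel-plot asymmetry in meta-analyses of
#' binary outcomes. For each study, with a = case present, b = control
#' present, c = case null, d = control null and n the study total, the
#' efficient score of the log odds ratio is `Z = a - (a + b)(a + c)/n` and
#' its variance `V = (a + b)(c + d)(a + c)(b + d) / (n^2 (n - 1))`. The test
#' fits `Z/sqrt(V)` on `sqrt(V)` by ordinary least squares and refers the
#' intercept to a t distribution with k - 2 degrees of freedom; by
#' field-synopsis convention p < 0.1 flags significant small-study effects.
#'
#' @param studies a `genotype_studies` table with at least 3 rows.
#' @return list: `intercept`, `se`, `t`, `p`, `k`.
#' @export
harbord_test <- function(studies) {
  d <- as_genotype_studies(studies)
  k <- nrow(d)
  if (k < 3L) stop("Harbord's test needs at least 3 studies", call. = FALSE)
  a <- d$case_present; b <- d$control_present
  cc <- d$case_null;  dd <- d$control_null
  n <- a + b + cc + dd
  Z <- a - (a + b) * (a + cc) / n
  V <- (a + b) * (cc + dd) * (a + cc) * (b + dd) / (n^2 * (n - 1))
  if (any(V <= 0)) {
    stop("zero score variance in at least one study; test undefined",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = data.frame(y = Z / sqrt(V), x = sqrt(V)))
  est <- summary(fit)$coefficients
  list(intercept = est[1L, 1L], se = est[1L, 2L],
       t = est[1L, 3L], p = est[1L, 4L], k = k)
}

#' Genotype totals and null-genotype frequencies
#'
#' Column totals over all studies plus the null-genotype frequency (percent)
#' among cases and controls, and `n_minor`: the total number of cases and
#' controls carrying the less frequent genotype (the "amount of evidence"
#' input to the Venice grading).
#'
#' @param studies a `genotype_studies` table.
#' @return list: `totals` (named vector of the four cell totals),
#'   `null_freq_cases`, `null_freq_controls` (percent), `n_minor`,
#'   `minor_genotype` (`"null"` or `"present"`).
#' @export
genotype_summary <- function(studies) {
  d <- as_genotype_studies(studies)
  tot <- c(case_null = sum(d$case_null), case_present = sum(d$case_present),
           control_null = sum(d$control_null),
           control_present = sum(d$control_present))
  n_null <- tot[["case_null"]] + tot[["control_null"]]
  n_present <- tot[["case_present"]] + tot[["control_present"]]
  minor <- if (n_null <= n_present) "null" else "present"
  list(totals = tot,
       null_freq_cases = 100 * tot[["case_null"]] /
         (tot[["case_null"]] + tot[["case_present"]]),
       null_freq_controls = 100 * tot[["control_null"]] /
         (tot[["control_null"]] + tot[["control_present"]]),
       n_minor = min(n_null, n_present),
       minor_genotype = minor)
}
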