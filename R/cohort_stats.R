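#' Questionnaire response rate
#'
#' Returned questionnaires (partially or totally completed) divided by the
#' number of arthroplasties minus those of deceased patients:
#' `n_returned / (n_thas - n_deceased)`.
#'
#' @param n_returned number of returned questionnaires at the timepoint.
#' @param n_thas number of arthroplasties in the cohort.
#' @param n_deceased number of THAs of patients deceased by the timepoint.
#' @return list: `n_returned`, `n_thas`, `n_deceased`, `rate` (exact
#'   fraction), `pct` (percentage rounded half-away-from-zero to one
#'   decimal).
#' @export
#' @examples
#' response_rate(703, 746, 0)$pct  # 94.2
response_rate <- function(n_returned, n_thas, n_deceased = 0) {
  if (n_deceased >= n_thas) pt_stop("n_deceased must be < n_thas")
  if (n_returned < 0 || n_returned > n_thas - n_deceased)
    pt_stop("n_returned must lie in [0, n_thas - n_deceased]")
  rate <- n_returned / (n_thas - n_deceased)
  list(n_returned = as.integer(n_returned), n_thas = as.integer(n_thas),
       n_deceased = as.integer(n_deceased), rate = rate,
       pct = round_half_up(100 * rate, 1))
}

#' Compare a continuous variable between two cohorts
#'
#' Normality of each sample is checked with Shapiro-Wilk at
#' `normality_alpha`; when both samples pass, a two-sample t test is used
#' (Welch by default), otherwise the Mann-Whitney U test (normal
#' approximation with tie correction). Degenerate samples (zero variance)
#' count as non-normal; two identical constant samples give `p = 1`.
#'
#' @param a,b numeric vectors (NAs dropped; each needs n >= 3).
#' @param normality_alpha Shapiro-Wilk level (default 0.05).
#' @param welch use Welch's unequal-variance t test (default) rather than
#'   the pooled-variance test.
#' @return list: `method` (`"T_TEST"` or `"MANN_WHITNEY"`), `statistic`,
#'   `p_value`, `n_a`, `n_b`, `normal_a`, `normal_b`,
#'   `summary_a`, `summary_b` (mean (SD) under t, median (IQR) otherwise).
#' @export
compare_continuous <- function(a, b, normality_alpha = 0.05, welch = TRUE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) pt_stop("each sample needs at least 3 values")
  is_normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    n <- length(x)
    if (n > 5000) x <- x[round(seq(1, n, length.out = 5000))]
    stats::shapiro.test(x)$p.value > normality_alpha
  }
  na <- is_normal(a); nb <- is_normal(b)
  fmt_med <- function(x) {
    q <- stats::quantile(x, c(.25, .5, .75), type = 7)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  if (na && nb) {
    tt <- stats::t.test(a, b, var.equal = !welch)
    out <- list(method = "T_TEST", statistic = unname(tt$statistic),
                p_value = tt$p.value,
                summary_a = sprintf("%.1f (%.1f)", mean(a), stats::sd(a)),
                summary_b = sprintf("%.1f (%.1f)", mean(b), stats::sd(b)))
  } else if (stats::sd(c(a, b)) == 0) {
    out <- list(method = "MANN_WHITNEY", statistic = length(a) * length(b) / 2,
                p_value = 1, summary_a = fmt_med(a), summary_b = fmt_med(b))
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
    out <- list(method = "MANN_WHITNEY", statistic = unname(wt$statistic),
                p_value = wt$p.value, summary_a = fmt_med(a), summary_b = fmt_med(b))
  }
  c(out, list(n_a = length(a), n_b = length(b), normal_a = na, normal_b = nb))
}

#' Compare a categorical variable between two cohorts
#'
#' Pearson chi-square on the contingency table unless any expected cell
#' count is below 5: then Fisher's exact test for 2x2 tables, and
#' chi-square with a low-expected-count warning for larger tables. A zero
#' margin on a 2x2 table also falls through to Fisher.
#'
#' @param tab contingency table (matrix of nonnegative counts, at least
#'   2x2); rows typically cohorts, columns categories.
#' @param correct Yates continuity correction for 2x2 chi-square
#'   (default `FALSE`; see [compare_rates()] for the both-variants view).
#' @return list: `method` (`"CHI_SQUARE"` or `"FISHER"`), `statistic`,
#'   `p_value`, `expected`, `warning` (`NULL` or text).
#' @export
compare_categorical <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != floor(tab))) pt_stop("counts must be nonnegative integers")
  if (nrow(tab) < 2 || ncol(tab) < 2) pt_stop("table must be at least 2x2")
  if (sum(tab) == 0) pt_stop("empty table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  low <- any(expected < 5) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  if (low && nrow(tab) == 2 && ncol(tab) == 2) {
    ft <- stats::fisher.test(tab)
    return(list(method = "FISHER", statistic = NA_real_, p_value = ft$p.value,
                expected = expected, warning = NULL))
  }
  if (low && (any(rowSums(tab) == 0) || any(colSums(tab) == 0)))
    pt_stop("zero margin in a table larger than 2x2")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(method = "CHI_SQUARE", statistic = unname(ct$statistic), p_value = ct$p.value,
       expected = expected,
       warning = if (low) "expected cell count < 5; chi-square approximation doubtful" else NULL)
}

#' Baseline comparison table between two cohorts
#'
#' One row per patient characteristic and preoperative PRO, each dispatched
#' to the appropriate comparison: age, BMI and the preoperative PRO scores
#' (NRS rest/activity, HOOS-PS, EQ VAS, OHS total) via
#' [compare_continuous()]; gender, ASA (I vs higher) and the four-level
#' Charnley classification via [compare_categorical()]. Per-timepoint
#' response rates are compared as returned-vs-not 2x2 tables.
#'
#' @param training,test two [pro_cohort()]s.
#' @param deceased per-timepoint deceased THA counts, named `PRE`, `M3`,
#'   `M12`, recycled for both cohorts (default all zero).
#' @param normality_alpha passed to [compare_continuous()].
#' @return data frame with columns `variable`, `method`,
#'   `summary_training`, `summary_test`, `p_value`.
#' @export
baseline_table <- function(training, test, deceased = c(PRE = 0, M3 = 0, M12 = 0),
                           normality_alpha = 0.05) {
  stopifnot(inherits(training, "pro_cohort"), inherits(test, "pro_cohort"))
  rows <- list()
  add <- function(variable, res) {
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, method = res$method %||% NA_character_,
      summary_training = res$summary_a %||% NA_character_,
      summary_test = res$summary_b %||% NA_character_,
      p_value = res$p_value %||% NA_real_)
  }
  # response rates
  for (tp in c("PRE", "M3", "M12")) {
    cn <- c(PRE = "returned_pre", M3 = "returned_m3", M12 = "returned_m12")[[tp]]
    ra <- response_rate(sum(training$patients[[cn]]), training$n_thas, deceased[[tp]])
    rb <- response_rate(sum(test$patients[[cn]]), test$n_thas, deceased[[tp]])
    tab <- rbind(c(ra$n_returned, ra$n_thas - ra$n_deceased - ra$n_returned),
                 c(rb$n_returned, rb$n_thas - rb$n_deceased - rb$n_returned))
    res <- tryCatch(compare_categorical(tab), promtriage_error = function(e) list())
    res$summary_a <- fmt_pct(ra$n_returned, ra$n_thas - ra$n_deceased)
    res$summary_b <- fmt_pct(rb$n_returned, rb$n_thas - rb$n_deceased)
    add(paste0("response_rate_", tolower(tp)), res)
  }
  cont <- function(variable, va, vb) {
    res <- tryCatch(compare_continuous(va, vb, normality_alpha),
                    promtriage_error = function(e)
                      list(method = "NOT_COMPUTABLE", p_value = NA_real_))
    add(variable, res)
  }
  cat2 <- function(variable, fa, fb, levels) {
    tab <- rbind(table(factor(fa, levels = levels)), table(factor(fb, levels = levels)))
    res <- tryCatch(compare_categorical(tab),
                    promtriage_error = function(e)
                      list(method = "NOT_COMPUTABLE", p_value = NA_real_))
    res$summary_a <- paste(fmt_pct(sum(fa == levels[1], na.rm = TRUE), length(fa)))
    res$summary_b <- paste(fmt_pct(sum(fb == levels[1], na.rm = TRUE), length(fb)))
    add(variable, res)
  }
  pa <- training$patients; pb <- test$patients
  cont("age_years", pa$age, pb$age)
  cat2("gender_male", pa$gender, pb$gender, c("M", "F"))
  cont("bmi", pa$bmi, pb$bmi)
  cat2("asa_I", pa$asa, pb$asa, c("I", "II", "III", "IV")[c(1, 2)])
  cat2("charnley", pa$charnley, pb$charnley,
       c("ONE_HIP", "BOTH_HIPS", "CONTRALATERAL_THA", "MULTI_JOINT"))
  # preoperative PROs
  pre_score <- function(cohort, keys, f = NULL) {
    m <- response_matrix(cohort, keys, "PRE")
    if (is.null(f)) m[, 1] else f(m)
  }
  cont("pre_nrs_rest", pre_score(training, "NRS_REST"), pre_score(test, "NRS_REST"))
  cont("pre_nrs_activity", pre_score(training, "NRS_ACTIVITY"), pre_score(test, "NRS_ACTIVITY"))
  cont("pre_hoos_ps",
       pre_score(training, item_key("HOOSPS", 1:5), score_hoos_ps),
       pre_score(test, item_key("HOOSPS", 1:5), score_hoos_ps))
  cont("pre_eq_vas", pre_score(training, "EQVAS"), pre_score(test, "EQVAS"))
  cont("pre_ohs_total",
       pre_score(training, item_key("OHS", 1:12), score_ohs_total),
       pre_score(test, item_key("OHS", 1:12), score_ohs_total))
  do.call(rbind, rows)
}
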