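#' Distribution summary of one item
#'
#' Median and quartiles of an item's scores. An item whose first quartile,
#' median and third quartile coincide "shows no distribution": it cannot
#' discriminate between patients and is unusable as a triage question.
#'
#' @param values integer scores (NAs dropped).
#' @param quartile_type quantile algorithm, passed to [stats::quantile()]'s
#'   `type`. Default 7 (linear interpolation between order statistics);
#'   type 6 reproduces the weighted-average convention of several
#'   commercial statistics packages.
#' @return list: `n`, `median`, `q1`, `q3`, `degenerate`, `quartile_type`.
#' @export
#' @examples
#' distribution_summary(rep(4, 20))$degenerate  # TRUE
distribution_summary <- function(values, quartile_type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0) pt_stop("distribution_summary: no observed values")
  q <- unname(stats::quantile(values, c(.25, .5, .75), type = quartile_type))
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       degenerate = q[1] == q[2] && q[2] == q[3], quartile_type = quartile_type)
}

#' Floor effect of one item
#'
#' Proportion of respondents at the item's worst possible score (the
#' maximum for higher-is-worse items, the minimum for higher-is-better
#' items). An item is flagged when strictly more than `floor_cutoff`
#' (default 15%) of respondents sit at the floor: it then cannot register
#' deterioration.
#'
#' @param values integer scores (NAs dropped).
#' @param def single-row item definition (see [pro_items()]).
#' @param floor_cutoff flagging cutoff as a proportion (default 0.15).
#' @return list: `n`, `n_worst`, `proportion`, `pct` (1-decimal),
#'   `flagged`, `worst_score`.
#' @export
floor_effect <- function(values, def, floor_cutoff = 0.15) {
  values <- values[!is.na(values)]
  if (length(values) == 0) pt_stop("floor_effect: no observed values")
  worst <- if (def$direction == "HIGHER_WORSE") def$max_score else def$min_score
  n_worst <- sum(values == worst)
  p <- n_worst / length(values)
  list(n = length(values), n_worst = n_worst, proportion = p,
       pct = round_half_up(100 * p, 1), flagged = p > floor_cutoff,
       worst_score = worst)
}

#' Pairwise Spearman correlations between items
#'
#' Spearman rank correlation (average ranks for ties) for every item pair,
#' with pairwise-complete deletion and a p-value from the t-distribution
#' approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`. Pairs at or above
#' `cutoff` in absolute value are flagged as redundant.
#'
#' @param m numeric matrix, patients x items (columns named by item key).
#' @param cutoff absolute-correlation flagging cutoff (default 0.7).
#' @return data frame with one row per unordered pair: `item_a`, `item_b`,
#'   `n`, `rho`, `p_value`, `flagged`. A pair with a constant column has
#'   `rho = NA` and is never flagged.
#' @export
spearman_matrix <- function(m, cutoff = 0.7) {
  if (ncol(m) < 2) pt_stop("spearman_matrix needs at least two items")
  ks <- colnames(m)
  out <- list()
  for (i in seq_len(ncol(m) - 1)) for (j in (i + 1):ncol(m)) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    n <- sum(ok)
    x <- m[ok, i]; y <- m[ok, j]
    if (n < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      rho <- NA_real_; p <- NA_real_
    } else {
      rho <- stats::cor(x, y, method = "spearman")
      p <- if (abs(rho) >= 1) 0 else {
        tt <- rho * sqrt((n - 2) / (1 - rho^2))
        2 * stats::pt(-abs(tt), df = n - 2)
      }
    }
    out[[length(out) + 1]] <- data.frame(
      item_a = ks[i], item_b = ks[j], n = n, rho = rho, p_value = p,
      flagged = !is.na(rho) && abs(rho) >= cutoff)
  }
  do.call(rbind, out)
}

# exact null distribution of the positive-rank sum W+ given the (average)
# ranks of the |differences|; handles ties by doubling ranks to integers.
# returns two-sided p for observed w (2 * min tail, capped at 1).
exact_signed_rank_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)
  f[1] <- 1
  for (r in r2) {
    idx <- (total + 1):(r + 1)
    f[idx] <- f[idx] + f[idx - r]
  }
  denom <- 2^length(r2)
  w2 <- round(2 * w)
  p_le <- sum(f[seq_len(w2 + 1)]) / denom
  p_ge <- sum(f[(w2 + 1):(total + 1)]) / denom
  min(1, 2 * min(p_le, p_ge))
}

#' Responsiveness of one item (preoperative vs 3 months)
#'
#' Wilcoxon signed-rank test on paired preoperative and 3-month scores. An
#' item that does not register the pre-to-post change (`p > alpha`) cannot
#' separate clinically relevant from irrelevant states and is unusable for
#' triage. Zero differences are discarded; the exact tie-aware null
#' distribution is enumerated when 25 or fewer nonzero pairs remain,
#' otherwise the normal approximation with continuity and tie correction is
#' used. All-zero differences give `p = 1` (no signal).
#'
#' Also reports the matched-pairs rank-biserial correlation
#' `(W+ - W-) / (W+ + W-)` as an effect size (negative = scores decreased).
#'
#' @param pre,m3 paired score vectors, aligned by patient (`NA` allowed;
#'   incomplete pairs are dropped).
#' @param alpha significance level for the responsiveness verdict
#'   (default 0.05).
#' @return list: `n_pairs`, `n_nonzero`, `statistic` (W+), `p_value`,
#'   `responsive`, `effect` (rank-biserial), `method`.
#' @export
responsiveness <- function(pre, m3, alpha = 0.05) {
  if (length(pre) != length(m3)) pt_stop("pre and m3 must be aligned by patient")
  ok <- !is.na(pre) & !is.na(m3)
  if (sum(ok) == 0) pt_stop("responsiveness: no complete pairs")
  d <- m3[ok] - pre[ok]
  nz <- d[d != 0]
  n_nonzero <- length(nz)
  if (n_nonzero == 0)
    return(list(n_pairs = sum(ok), n_nonzero = 0L, statistic = NA_real_,
                p_value = 1, responsive = FALSE, effect = 0, method = "none"))
  rk <- rank(abs(nz))
  w_pos <- sum(rk[nz > 0])
  w_neg <- sum(rk[nz < 0])
  effect <- (w_pos - w_neg) / (w_pos + w_neg)
  if (n_nonzero <= 25) {
    p <- exact_signed_rank_p(rk, w_pos)
    method <- "exact"
  } else {
    p <- suppressWarnings(
      stats::wilcox.test(m3[ok], pre[ok], paired = TRUE, exact = FALSE,
                         correct = TRUE)$p.value)
    method <- "normal_approx"
  }
  list(n_pairs = sum(ok), n_nonzero = n_nonzero, statistic = w_pos,
       p_value = p, responsive = p <= alpha, effect = effect, method = method)
}

#' PRO patient journey of one item
#'
#' Splits patients observed at both 3 and 12 months by whether their
#' 3-month score crossed the item's triage threshold (the "worse" group)
#' and summarizes each group's 12-month scores. If the worse group "scores
#' well" at 12 months the item's bad 3-month score carries no prognostic
#' information and the item is flagged.
#'
#' Two operationalizations of "scored well":
#' * `"relative"` (default): flagged iff the worse group's 12-month median
#'   is strictly better (lower severity) than the better group's — the
#'   groups' trajectories actually swapped.
#' * `"threshold"`: flagged iff the worse group's 12-month median no longer
#'   crosses the threshold. Stricter; on typical recovery data it flags
#'   almost every item, so it serves as a sensitivity analysis.
#'
#' No flag is computed when either group has fewer than 5 patients
#' (`small_group_warning`): medians of tiny groups are uninformative.
#'
#' @param m3,m12 paired score vectors aligned by patient.
#' @param criterion one criterion row of a [triage_rule()] (`key`,
#'   `comparator`, `cutoff`).
#' @param policy `"relative"` or `"threshold"`.
#' @param quartile_type see [distribution_summary()].
#' @param defs item definitions.
#' @return list: `n_worse`, `n_better`, `worse` / `better` (each `NULL`
#'   when empty, else `n`, `median`, `q1`, `q3`), `flagged` (`NA` when not
#'   computable), `small_group_warning`, `policy`.
#' @export
journey <- function(m3, m12, criterion, policy = c("relative", "threshold"),
                    quartile_type = 7, defs = pro_items()) {
  policy <- match.arg(policy)
  if (length(m3) != length(m12)) pt_stop("m3 and m12 must be aligned by patient")
  ok <- !is.na(m3) & !is.na(m12)
  m3 <- m3[ok]; m12 <- m12[ok]
  worse <- if (criterion$comparator == ">=") m3 >= criterion$cutoff else m3 <= criterion$cutoff
  summ <- function(v) if (length(v) == 0) NULL else
    distribution_summary(v, quartile_type)[c("n", "median", "q1", "q3")]
  res <- list(n_worse = sum(worse), n_better = sum(!worse),
              worse = summ(m12[worse]), better = summ(m12[!worse]),
              flagged = NA, small_group_warning = min(sum(worse), sum(!worse)) < 5,
              policy = policy)
  if (is.null(res$worse) || is.null(res$better) || res$small_group_warning)
    return(res)
  d <- item_def(criterion$key, defs)
  severity <- function(med) if (d$direction == "HIGHER_WORSE") med else d$max_score - med
  res$flagged <- switch(policy,
    relative = severity(res$worse$median) < severity(res$better$median),
    threshold = {
      med_crossed <- if (criterion$comparator == ">=") res$worse$median >= criterion$cutoff
                     else res$worse$median <= criterion$cutoff
      !med_crossed
    })
  res
}

#' Cronbach's alpha of an item group
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(row totals))`
#' with sample variances (denominator `n - 1`) over listwise-complete rows.
#' Scores must share a direction — recode first (see
#' [recode_common_direction()] or `response_matrix(..., recode = TRUE)`).
#'
#' @param m numeric matrix, patients x items (>= 2 columns).
#' @return list: `alpha` (`NA` when the total variance is zero),
#'   `n_complete`, `k`.
#' @export
#' @examples
#' cronbach_alpha(cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))$alpha  # 1
cronbach_alpha <- function(m) {
  if (ncol(m) < 2) pt_stop("cronbach_alpha needs at least two items")
  cc <- stats::complete.cases(m)
  m <- m[cc, , drop = FALSE]
  if (nrow(m) < 2) pt_stop("cronbach_alpha needs at least two complete rows")
  k <- ncol(m)
  tot_var <- stats::var(rowSums(m))
  if (tot_var == 0)
    return(list(alpha = NA_real_, n_complete = nrow(m), k = k))
  item_var <- apply(m, 2, stats::var)
  list(alpha = k / (k - 1) * (1 - sum(item_var) / tot_var),
       n_complete = nrow(m), k = k)
}

#' Alpha-if-item-deleted analysis of one triage-criteria group
#'
#' Recomputes Cronbach's alpha with each item removed in turn. An item is a
#' removal candidate when deleting it both increases alpha above the full
#' group's value and leaves the reduced group above `alpha_floor`
#' (default 0.7): the item then does not fit its clinical criteria group.
#' For a 2-item group the item-deleted map is empty and no candidate is
#' ever produced (a single remaining item has no internal consistency).
#'
#' @param m numeric matrix of common-direction (recoded) scores,
#'   patients x items, listwise-complete rows used.
#' @param alpha_floor minimum deleted-alpha for a removal candidate.
#' @return list: `alpha`, `n_complete`, `k`, `alpha_if_deleted` (named
#'   numeric, empty for 2-item groups), `removal_candidates` (character).
#' @export
alpha_if_deleted <- function(m, alpha_floor = 0.7) {
  full <- cronbach_alpha(m)
  if (ncol(m) == 2)
    return(c(full, list(alpha_if_deleted = stats::setNames(numeric(0), character(0)),
                        removal_candidates = character(0))))
  aid <- vapply(seq_len(ncol(m)), function(j)
    cronbach_alpha(m[, -j, drop = FALSE])$alpha, numeric(1))
  names(aid) <- colnames(m)
  cand <- names(aid)[!is.na(aid) & !is.na(full$alpha) &
                       aid > full$alpha & aid > alpha_floor]
  c(full, list(alpha_if_deleted = aid, removal_candidates = cand))
}
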