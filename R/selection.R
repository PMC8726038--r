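#' Configuration of the item-selection procedure
#'
#' Houses the clinimetric decision constants and the policies left open by
#' the selection procedure. Unknown arguments are errors (R's matching
#' rejects them), so profiles cannot drift silently.
#'
#' @param floor_cutoff proportion of respondents at the worst score above
#'   which an item is removed (strictly; default 0.15).
#' @param correlation_cutoff absolute Spearman correlation at or above
#'   which two items are considered redundant (default 0.7, the stated
#'   criterion; see [paper_profile()] for the 0.6 variant).
#' @param responsiveness_alpha significance level below which an item
#'   counts as responsive (default 0.05).
#' @param alpha_floor minimum alpha-if-deleted for a homogeneity removal
#'   candidate (default 0.7).
#' @param correlation_keep optional character vector of item keys: inside a
#'   redundant set, a listed item (first match in list order) is kept.
#'   Encodes an expert-panel choice deterministically.
#' @param correlation_keep_policy fallback when no keep-list item is in the
#'   set: `"effect"` keeps the item with the largest absolute
#'   responsiveness effect (rank-biserial), ties broken lexicographically
#'   by key; `"first"` keeps the lexicographically first key.
#' @param journey_policy `"relative"` (default) or `"threshold"`, see
#'   [journey()].
#' @param quartile_type quantile algorithm for medians/IQRs (default 7).
#' @return list of class `selection_config`.
#' @export
selection_config <- function(floor_cutoff = 0.15, correlation_cutoff = 0.7,
                             responsiveness_alpha = 0.05, alpha_floor = 0.7,
                             correlation_keep = NULL,
                             correlation_keep_policy = c("effect", "first"),
                             journey_policy = c("relative", "threshold"),
                             quartile_type = 7) {
  stopifnot(floor_cutoff > 0, floor_cutoff < 1,
            correlation_cutoff > 0, correlation_cutoff <= 1,
            responsiveness_alpha > 0, responsiveness_alpha < 1,
            alpha_floor > 0, alpha_floor < 1)
  structure(list(
    floor_cutoff = floor_cutoff,
    correlation_cutoff = correlation_cutoff,
    responsiveness_alpha = responsiveness_alpha,
    alpha_floor = alpha_floor,
    correlation_keep = correlation_keep,
    correlation_keep_policy = match.arg(correlation_keep_policy),
    journey_policy = match.arg(journey_policy),
    quartile_type = quartile_type,
    stage_order = c("distribution", "floor", "responsiveness", "journey",
                    "correlation", "homogeneity")),
    class = "selection_config")
}

#' Shipped selection profiles
#'
#' `stated_profile()` applies the criteria exactly as stated: correlation
#' cutoff 0.7, effect-size keep policy. `paper_profile()` is the
#' replication profile: correlation cutoff 0.6 — the study presented and
#' acted on correlations above 0.6 (its removed pairs sat at 0.659 and
#' -0.676, both below the stated 0.7) — and a keep-list preferring NRS
#' pain during activity inside a redundant set, encoding the expert
#' panels' choice. The discrepancy between the stated 0.7 criterion and
#' the applied 0.6 presentation cutoff is documented, not silently
#' resolved: both profiles ship.
#'
#' @return a [selection_config()].
#' @export
stated_profile <- function() selection_config()

#' @rdname stated_profile
#' @export
paper_profile <- function() {
  selection_config(correlation_cutoff = 0.6, correlation_keep = "NRS_ACTIVITY")
}

#' Run the six-stage clinimetric item-selection procedure
#'
#' Reduces a candidate triage rule to its final form on a training cohort
#' by applying, in order:
#' 1. **distribution** — remove items whose 3-month median and quartiles
#'    coincide (no discrimination);
#' 2. **floor effect** — remove items with more than `floor_cutoff` of
#'    respondents at the worst 3-month score;
#' 3. **responsiveness** — remove items whose preoperative-to-3-month
#'    change is not significant by Wilcoxon signed rank;
#' 4. **patient journey** — remove items whose worse-than-threshold group
#'    at 3 months "scores well" at 12 months (see [journey()]);
#' 5. **correlation pruning** — among surviving items, flag pairs with
#'    `|rho| >=` the cutoff, form connected redundant sets, and keep
#'    exactly one item per set (keep-list, else largest responsiveness
#'    effect);
#' 6. **homogeneity** — within each clinical criteria group, remove items
#'    whose deletion raises Cronbach's alpha above both the group's alpha
#'    and `alpha_floor` (common-direction recoded scores; groups of 2 are
#'    never reduced).
#'
#' Each removal records the earliest stage that fired. Re-running the
#' procedure on the retained set is idempotent by construction of the
#' stage conditions.
#'
#' @param cohort training [pro_cohort()] with PRE, M3 and M12 data.
#' @param rule candidate [triage_rule()] (default [candidate_rule()]).
#' @param cfg a [selection_config()].
#' @param defs item definitions.
#' @return object of class `promtriage_selection`: list with
#'   `decisions` (data frame: `key`, `group`, `status`, `reason`, `stage`),
#'   `final_rule` (a [triage_rule()] of the retained criteria),
#'   `report` (per-stage metric tables: `distribution`, `floor`,
#'   `responsiveness`, `journey`, `correlation`, `redundant_sets`,
#'   `homogeneity`), and `config`.
#' @export
run_selection <- function(cohort, rule = candidate_rule(), cfg = selection_config(),
                          defs = pro_items()) {
  stopifnot(inherits(cohort, "pro_cohort"), inherits(rule, "triage_rule"),
            inherits(cfg, "selection_config"))
  keys <- rule$criteria$key
  m_pre <- response_matrix(cohort, keys, "PRE", defs = defs)
  m3 <- response_matrix(cohort, keys, "M3", defs = defs)
  m12 <- response_matrix(cohort, keys, "M12", defs = defs)
  alive <- keys
  removed <- data.frame(key = character(), reason = character(), stage = character())
  drop_items <- function(ks, reason, stage) {
    if (length(ks) == 0) return()
    removed <<- rbind(removed, data.frame(key = ks, reason = reason, stage = stage))
    alive <<- setdiff(alive, ks)
  }
  report <- list()

  # stage 1: degenerate 3-month distribution
  dist <- do.call(rbind, lapply(alive, function(k) {
    s <- distribution_summary(m3[, k], cfg$quartile_type)
    data.frame(key = k, n = s$n, median = s$median, q1 = s$q1, q3 = s$q3,
               degenerate = s$degenerate)
  }))
  report$distribution <- dist
  drop_items(dist$key[dist$degenerate], "DEGENERATE_DISTRIBUTION", "distribution")

  # stage 2: floor effect at 3 months
  fl <- do.call(rbind, lapply(alive, function(k) {
    f <- floor_effect(m3[, k], item_def(k, defs), cfg$floor_cutoff)
    data.frame(key = k, n = f$n, n_worst = f$n_worst, proportion = f$proportion,
               pct = f$pct, flagged = f$flagged)
  }))
  report$floor <- fl
  drop_items(fl$key[fl$flagged], "FLOOR_EFFECT", "floor")

  # stage 3: responsiveness PRE -> M3 (effect sizes kept for stage 5)
  shared <- intersect(rownames(m_pre), rownames(m3))
  resp <- do.call(rbind, lapply(alive, function(k) {
    r <- responsiveness(m_pre[shared, k], m3[shared, k], cfg$responsiveness_alpha)
    data.frame(key = k, n_pairs = r$n_pairs, n_nonzero = r$n_nonzero,
               statistic = r$statistic, p_value = r$p_value,
               responsive = r$responsive, effect = r$effect, method = r$method)
  }))
  report$responsiveness <- resp
  drop_items(resp$key[!resp$responsive], "NOT_RESPONSIVE", "responsiveness")

  # stage 4: patient journey M3 -> M12
  shared2 <- intersect(rownames(m3), rownames(m12))
  jn <- do.call(rbind, lapply(alive, function(k) {
    cr <- rule$criteria[rule$criteria$key == k, ]
    j <- journey(m3[shared2, k], m12[shared2, k], cr, policy = cfg$journey_policy,
                 quartile_type = cfg$quartile_type, defs = defs)
    data.frame(key = k, n_worse = j$n_worse, n_better = j$n_better,
               worse_median_12m = j$worse$median %||% NA_real_,
               worse_q1 = j$worse$q1 %||% NA_real_, worse_q3 = j$worse$q3 %||% NA_real_,
               better_median_12m = j$better$median %||% NA_real_,
               better_q1 = j$better$q1 %||% NA_real_, better_q3 = j$better$q3 %||% NA_real_,
               flagged = isTRUE(j$flagged), small_group_warning = j$small_group_warning)
  }))
  report$journey <- jn
  drop_items(jn$key[jn$flagged], "JOURNEY_FLAG", "journey")

  # stage 5: correlation pruning among survivors
  report$correlation <- NULL
  report$redundant_sets <- list()
  if (length(alive) >= 2) {
    cors <- spearman_matrix(m3[, alive, drop = FALSE], cfg$correlation_cutoff)
    report$correlation <- cors
    flg <- cors[cors$flagged, , drop = FALSE]
    if (nrow(flg) > 0) {
      comp <- stats::setNames(seq_along(alive), alive)
      for (i in seq_len(nrow(flg))) {
        a <- comp[[flg$item_a[i]]]; b <- comp[[flg$item_b[i]]]
        comp[comp == b] <- a
      }
      for (cid in unique(comp[duplicated(comp) | duplicated(comp, fromLast = TRUE)])) {
        set <- sort(names(comp)[comp == cid])
        keep <- NULL
        if (!is.null(cfg$correlation_keep))
          keep <- cfg$correlation_keep[cfg$correlation_keep %in% set][1]
        if (is.null(keep) || is.na(keep)) {
          keep <- if (cfg$correlation_keep_policy == "effect") {
            eff <- abs(resp$effect[match(set, resp$key)])
            set[order(-eff, set)][1]
          } else set[1]
        }
        report$redundant_sets[[length(report$redundant_sets) + 1]] <-
          list(items = set, kept = keep)
        drop_items(setdiff(set, keep), "CORRELATION_PRUNED", "correlation")
      }
    }
  }

  # stage 6: homogeneity per clinical criteria group (recoded direction)
  report$homogeneity <- list()
  groups <- split(alive, rule$criteria$group[match(alive, rule$criteria$key)])
  for (g in names(groups)) {
    if (length(groups[[g]]) < 2) next
    mg <- response_matrix(cohort, groups[[g]], "M3", recode = TRUE, defs = defs)
    h <- alpha_if_deleted(mg, cfg$alpha_floor)
    report$homogeneity[[g]] <- h
    drop_items(h$removal_candidates, "HOMOGENEITY", "homogeneity")
  }

  decisions <- data.frame(
    key = keys,
    group = rule$criteria$group,
    status = ifelse(keys %in% alive, "RETAINED", "REMOVED"),
    reason = removed$reason[match(keys, removed$key)],
    stage = removed$stage[match(keys, removed$key)])
  final <- triage_rule(rule$criteria[rule$criteria$key %in% alive, ],
                       name = paste0(rule$name, "_selected"),
                       policy = rule$policy,
                       unallocatable_default = rule$unallocatable_default,
                       defs = defs)
  structure(list(decisions = decisions, final_rule = final, report = report,
                 config = cfg),
            class = "promtriage_selection")
}

#' @export
print.promtriage_selection <- function(x, ...) {
  d <- x$decisions
  cat(sprintf("<promtriage_selection> %d retained, %d removed\n",
              sum(d$status == "RETAINED"), sum(d$status == "REMOVED")))
  for (i in which(d$status == "REMOVED"))
    cat(sprintf("  removed %-14s (%s)\n", d$key[i], d$reason[i]))
  cat("  retained:", paste(d$key[d$status == "RETAINED"], collapse = ", "), "\n")
  invisible(x)
}
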