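#' Define a triage rule
#'
#' A triage rule is an ordered set of per-item threshold criteria grouped
#' under clinical criteria ("having moderate or severe pain" = `PAIN`,
#' "using 2 crutches" = `CRUTCHES`). A patient crossing any criterion's
#' threshold on the worse side is allocated to a hospital consultation;
#' a patient with at least one observed rule item and no crossing gets a
#' video consultation. Thresholds follow the worse-side convention:
#' `>=` for higher-is-worse items, `<=` for higher-is-better items.
#'
#' @param criteria data frame with columns `instrument`, `item`,
#'   `comparator` (`">="` or `"<="`), `cutoff`, `group` (`PAIN`/`CRUTCHES`).
#' @param name rule name.
#' @param policy combination policy. `"any"` (default): hospital if any
#'   criterion is crossed; `"group_all"`: hospital if, within at least one
#'   group, every observed criterion is crossed (sensitivity analysis).
#' @param unallocatable_default operational allocation for patients whose
#'   rule items are all missing: `"HOSPITAL"` (conservative default) or
#'   `"VIDEO"`. Such patients are always excluded from the allocation
#'   proportion.
#' @param defs item definitions.
#' @return object of class `triage_rule`.
#' @export
#' @examples
#' final_rule()
triage_rule <- function(criteria, name = "custom", policy = c("any", "group_all"),
                        unallocatable_default = c("HOSPITAL", "VIDEO"),
                        defs = pro_items()) {
  policy <- match.arg(policy)
  unallocatable_default <- match.arg(unallocatable_default)
  req <- c("instrument", "item", "comparator", "cutoff", "group")
  miss <- setdiff(req, names(criteria))
  if (length(miss)) pt_stop(paste("criteria missing columns:", paste(miss, collapse = ", ")))
  if (nrow(criteria) < 1) pt_stop("a triage rule needs at least one criterion")
  criteria$key <- item_key(criteria$instrument, criteria$item)
  if (anyDuplicated(criteria$key))
    pt_stop("duplicate items in triage rule", class = "promtriage_validation_error")
  d <- item_def(criteria$key, defs)
  if (any(criteria$cutoff < d$min_score | criteria$cutoff > d$max_score))
    pt_stop("criterion cutoff outside item score range",
            class = "promtriage_validation_error")
  want <- ifelse(d$direction == "HIGHER_WORSE", ">=", "<=")
  if (any(criteria$comparator != want))
    pt_stop("comparator must point to the worse side of each item (>= for higher-worse, <= for higher-better)",
            class = "promtriage_validation_error")
  if (!all(criteria$group %in% c("PAIN", "CRUTCHES")))
    pt_stop("criterion group must be PAIN or CRUTCHES")
  structure(list(name = name,
                 criteria = criteria[, c("key", "instrument", "item", "comparator",
                                         "cutoff", "group")],
                 policy = policy, unallocatable_default = unallocatable_default),
            class = "triage_rule")
}

#' @export
print.triage_rule <- function(x, ...) {
  cat(sprintf("<triage_rule '%s'> %d criteria, policy=%s\n",
              x$name, nrow(x$criteria), x$policy))
  for (i in seq_len(nrow(x$criteria)))
    cat(sprintf("  [%s] %s %s %d\n", x$criteria$group[i], x$criteria$key[i],
                x$criteria$comparator[i], x$criteria$cutoff[i]))
  invisible(x)
}

#' Read / write a triage rule as JSON
#'
#' The file is a JSON object with `name`, `policy`,
#' `unallocatable_default` and a `criteria` array of
#' `{instrument, item, comparator, cutoff, group}` objects.
#'
#' @param path file path.
#' @param defs item definitions.
#' @return [triage_rule()] (reader) / the rule invisibly (writer).
#' @export
read_triage_rule <- function(path, defs = pro_items()) {
  if (!file.exists(path)) pt_stop(paste("rule file not found:", path))
  j <- jsonlite::fromJSON(path)
  triage_rule(as.data.frame(j$criteria), name = j$name %||% "unnamed",
              policy = j$policy %||% "any",
              unallocatable_default = j$unallocatable_default %||% "HOSPITAL",
              defs = defs)
}

#' @rdname read_triage_rule
#' @param rule a [triage_rule()].
#' @export
write_triage_rule <- function(rule, path) {
  stopifnot(inherits(rule, "triage_rule"))
  jsonlite::write_json(
    list(name = rule$name, policy = rule$policy,
         unallocatable_default = rule$unallocatable_default,
         criteria = rule$criteria[, c("instrument", "item", "comparator", "cutoff", "group")]),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rule)
}

#' Built-in triage rules
#'
#' `candidate_rule()` is the nine-question rule assembled by the expert
#' panels (NRS pain at rest and during activity, EQ-5D-3L questions 1 and
#' 4, OHS questions 1, 6, 8, 10 and 12, each with its defined threshold).
#' `final_rule()` is the six-question tool that survives clinimetric item
#' selection: NRS pain during activity, EQ-5D-3L questions 1 and 4, OHS
#' questions 6, 8 and 12. Both ship as JSON under
#' `system.file("extdata", package = "promtriage")`.
#'
#' @return a [triage_rule()].
#' @export
candidate_rule <- function() {
  read_triage_rule(system.file("extdata", "candidate_9item.json",
                               package = "promtriage", mustWork = TRUE))
}

#' @rdname candidate_rule
#' @export
final_rule <- function() {
  read_triage_rule(system.file("extdata", "final_6item.json",
                               package = "promtriage", mustWork = TRUE))
}

#' Evaluate one threshold criterion
#'
#' @param value observed score (`NA` = missing).
#' @param comparator `">="` or `"<="`.
#' @param cutoff threshold.
#' @return list with `crossed` (logical; `FALSE` when missing) and
#'   `missing` (logical).
#' @export
#' @examples
#' item_crossed(4, ">=", 4)  # crossed
item_crossed <- function(value, comparator, cutoff) {
  if (length(value) != 1) pt_stop("item_crossed takes a single value")
  if (is.na(value)) return(list(crossed = FALSE, missing = TRUE))
  crossed <- switch(comparator,
                    ">=" = value >= cutoff,
                    "<=" = value <= cutoff,
                    pt_stop("comparator must be '>=' or '<='"))
  list(crossed = crossed, missing = FALSE)
}

# vectorized crossing over a patients x items score matrix; NA -> FALSE
crossed_matrix <- function(m, rule) {
  cr <- matrix(FALSE, nrow(m), nrow(rule$criteria),
               dimnames = list(rownames(m), rule$criteria$key))
  for (j in seq_len(nrow(rule$criteria))) {
    v <- m[, rule$criteria$key[j]]
    cj <- if (rule$criteria$comparator[j] == ">=") v >= rule$criteria$cutoff[j]
          else v <= rule$criteria$cutoff[j]
    cr[, j] <- !is.na(cj) & cj
  }
  cr
}

#' Triage a single patient
#'
#' @param scores named numeric vector of the patient's scores at the triage
#'   timepoint, names being item keys (missing or `NA` entries = item not
#'   answered).
#' @param rule a [triage_rule()].
#' @return list with `allocation` (`"HOSPITAL"`, `"VIDEO"` or
#'   `"UNALLOCATABLE"`), `triggered` (keys of crossed criteria) and
#'   `missing_items` (keys of unanswered rule items).
#' @export
#' @examples
#' r <- final_rule()
#' triage_patient(c(NRS_ACTIVITY = 7, `EQ5D3L:1` = 1, `EQ5D3L:4` = 1,
#'                  `OHS:6` = 4, `OHS:8` = 4, `OHS:12` = 4), r)
triage_patient <- function(scores, rule) {
  stopifnot(inherits(rule, "triage_rule"))
  m <- matrix(NA_real_, 1, nrow(rule$criteria), dimnames = list(NULL, rule$criteria$key))
  hit <- intersect(names(scores), rule$criteria$key)
  m[1, hit] <- scores[hit]
  d <- item_def(rule$criteria$key)
  bad <- !is.na(m[1, ]) & (m[1, ] < d$min_score | m[1, ] > d$max_score)
  if (any(bad))
    pt_stop(paste("score out of range for", paste(colnames(m)[bad], collapse = ", ")),
            class = "promtriage_validation_error")
  cr <- crossed_matrix(m, rule)
  missing_items <- colnames(m)[is.na(m[1, ])]
  if (all(is.na(m[1, ])))
    return(list(allocation = "UNALLOCATABLE", triggered = character(0),
                missing_items = missing_items))
  hospital <- if (rule$policy == "any") any(cr[1, ]) else {
    any(vapply(split(seq_len(ncol(cr)), rule$criteria$group), function(j) {
      obs <- j[!is.na(m[1, j])]
      length(obs) > 0 && all(cr[1, obs])
    }, TRUE))
  }
  list(allocation = if (hospital) "HOSPITAL" else "VIDEO",
       triggered = colnames(cr)[cr[1, ]],
       missing_items = missing_items)
}

#' Triage a cohort
#'
#' Applies the rule at a timepoint to every patient whose questionnaire was
#' returned. Patients with at least one observed rule item are allocated to
#' hospital (any criterion crossed) or video; patients whose rule items are
#' all missing are `UNALLOCATABLE`, reported separately, counted under the
#' rule's operational default but excluded from the allocation proportion.
#'
#' @param cohort a [pro_cohort()].
#' @param rule a [triage_rule()].
#' @param t timepoint (default `"M3"`, the study's triage timepoint).
#' @return object of class `triage_result`: list with `summary` (an
#'   allocation summary: `n_allocated`, `n_hospital`, `n_video`,
#'   `n_unallocatable`, `hospital_proportion`, `hospital_pct` rounded
#'   half-up to 1 decimal, `label`) and `outcomes` (one row per triaged
#'   patient: `patient_id`, `allocation`, `n_triggered`, `triggered`,
#'   `n_missing`).
#' @export
triage_cohort <- function(cohort, rule, t = "M3") {
  stopifnot(inherits(cohort, "pro_cohort"), inherits(rule, "triage_rule"))
  if (nrow(cohort$patients) == 0) pt_stop("empty cohort")
  m <- response_matrix(cohort, rule$criteria$key, t)
  if (nrow(m) == 0) pt_stop("no patients returned a questionnaire at this timepoint")
  cr <- crossed_matrix(m, rule)
  n_obs <- rowSums(!is.na(m))
  if (rule$policy == "any") {
    hosp <- rowSums(cr) > 0
  } else {
    by_group <- split(seq_len(ncol(cr)), rule$criteria$group)
    hosp <- Reduce(`|`, lapply(by_group, function(j) {
      obs <- !is.na(m[, j, drop = FALSE])
      rowSums(obs) > 0 & rowSums(cr[, j, drop = FALSE] & obs) == rowSums(obs)
    }))
  }
  alloc <- ifelse(n_obs == 0, "UNALLOCATABLE", ifelse(hosp, "HOSPITAL", "VIDEO"))
  n_allocated <- sum(n_obs > 0)
  if (n_allocated == 0) pt_stop("no allocatable patients (all rule items missing everywhere)")
  n_hospital <- sum(alloc == "HOSPITAL")
  outcomes <- data.frame(
    patient_id = rownames(m),
    allocation = alloc,
    n_triggered = rowSums(cr),
    triggered = apply(cr, 1, function(z) paste(colnames(cr)[z], collapse = ";")),
    n_missing = rowSums(is.na(m)),
    row.names = NULL)
  summary <- list(label = cohort$label, rule = rule$name, timepoint = t,
                  n_returned = nrow(m),
                  n_allocated = n_allocated,
                  n_hospital = n_hospital,
                  n_video = n_allocated - n_hospital,
                  n_unallocatable = sum(n_obs == 0),
                  n_hospital_operational = n_hospital +
                    if (rule$unallocatable_default == "HOSPITAL") sum(n_obs == 0) else 0L,
                  hospital_proportion = n_hospital / n_allocated,
                  hospital_pct = round_half_up(100 * n_hospital / n_allocated, 1))
  structure(list(summary = summary, outcomes = outcomes), class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<triage_result> rule '%s' on cohort '%s' at %s\n", s$rule, s$label, s$timepoint))
  cat(sprintf("  hospital: %s   video: %s   unallocatable: %d\n",
              fmt_pct(s$n_hospital, s$n_allocated),
              fmt_pct(s$n_video, s$n_allocated), s$n_unallocatable))
  invisible(x)
}

#' Compare hospital-consultation rates between two cohorts
#'
#' Builds the 2x2 hospital/video-by-cohort table and tests for an
#' association. Pearson's chi-square is used unless any expected cell count
#' is below 5 (or a margin is zero), in which case Fisher's exact test is
#' used. For 2x2 chi-square the result reports both the uncorrected and the
#' Yates continuity-corrected statistic — statistical packages differ in
#' their default and the two can straddle conventional rounding boundaries.
#'
#' @param a,b allocation summaries (the `summary` element of a
#'   [triage_cohort()] result, or any list with `n_hospital`, `n_video`).
#' @param variant which chi-square p-value the `p_value` field carries:
#'   `"both"` (default; reports both, `p_value` = corrected),
#'   `"uncorrected"` or `"corrected"`. Ignored when Fisher's test applies.
#' @return list with `method`, `table`, `expected`, `statistic`,
#'   `statistic_corrected`, `p_uncorrected`, `p_corrected`, `p_value`.
#' @export
#' @examples
#' a <- list(label = "TRAINING", n_hospital = 201, n_video = 502)
#' b <- list(label = "TEST", n_hospital = 150, n_video = 313)
#' compare_rates(a, b)
compare_rates <- function(a, b, variant = c("both", "uncorrected", "corrected")) {
  variant <- match.arg(variant)
  tab <- matrix(c(a$n_hospital, a$n_video, b$n_hospital, b$n_video), 2, byrow = TRUE,
                dimnames = list(cohort = c(a$label %||% "A", b$label %||% "B"),
                                allocation = c("HOSPITAL", "VIDEO")))
  if (any(rowSums(tab) == 0)) pt_stop("a cohort has zero allocated patients")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) || any(colSums(tab) == 0)) {
    ft <- stats::fisher.test(tab)
    return(list(method = "FISHER", table = tab, expected = expected,
                statistic = NA_real_, statistic_corrected = NA_real_,
                p_uncorrected = NA_real_, p_corrected = NA_real_,
                p_value = ft$p.value))
  }
  un <- stats::chisq.test(tab, correct = FALSE)
  co <- stats::chisq.test(tab, correct = TRUE)
  list(method = "CHI_SQUARE", table = tab, expected = expected,
       statistic = unname(un$statistic), statistic_corrected = unname(co$statistic),
       p_uncorrected = un$p.value, p_corrected = co$p.value,
       p_value = switch(variant, both = co$p.value, corrected = co$p.value,
                        uncorrected = un$p.value))
}
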