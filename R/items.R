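#' PROM item definitions
#'
#' The instrument set collected at every follow-up of the hip-arthroplasty
#' cohort: numeric rating scales for pain at rest and during activity
#' (0 best to 10 worst), the five EQ-5D-3L dimensions (1 best to 3 worst)
#' with the EQ VAS (0 worst to 100 best), the twelve Oxford Hip Score items
#' (0 worst to 4 best, total 0-48 higher better), the five HOOS-PS items
#' (0 best to 4 worst, reported on a 0-100 scale where higher is worse),
#' and a 7-point anchor question on functional improvement.
#'
#' `direction` records whether a higher raw score means a worse outcome
#' (`"HIGHER_WORSE"`) or a better one (`"HIGHER_BETTER"`); it drives
#' direction recoding, floor-effect "worst score" identification and the
#' worse-side convention of triage thresholds.
#'
#' @param hoosps_item_max maximum per-item HOOS-PS score. The standard
#'   instrument uses 0-4; some descriptions state 0-5. Configurable so the
#'   0-100 rescaling can follow either convention.
#' @return A data frame with one row per item: `instrument`, `item`
#'   (1-based index, 0 for single-question instruments), `key` (a unique
#'   identifier such as `"OHS:6"` or `"NRS_ACTIVITY"`), `min_score`,
#'   `max_score`, `direction`, `label`.
#' @export
#' @examples
#' defs <- pro_items()
#' subset(defs, instrument == "OHS")
pro_items <- function(hoosps_item_max = 4) {
  stopifnot(hoosps_item_max >= 1)
  rows <- rbind(
    data.frame(instrument = "NRS_REST", item = 0L, min_score = 0L, max_score = 10L,
               direction = "HIGHER_WORSE", label = "NRS pain at rest"),
    data.frame(instrument = "NRS_ACTIVITY", item = 0L, min_score = 0L, max_score = 10L,
               direction = "HIGHER_WORSE", label = "NRS pain during activity"),
    data.frame(instrument = "EQ5D3L", item = 1:5, min_score = 1L, max_score = 3L,
               direction = "HIGHER_WORSE",
               label = paste("EQ-5D-3L", c("mobility", "self-care", "usual activities",
                                           "pain/discomfort", "anxiety/depression"))),
    data.frame(instrument = "EQVAS", item = 0L, min_score = 0L, max_score = 100L,
               direction = "HIGHER_BETTER", label = "EQ VAS self-rated health"),
    data.frame(instrument = "OHS", item = 1:12, min_score = 0L, max_score = 4L,
               direction = "HIGHER_BETTER", label = paste("OHS question", 1:12)),
    data.frame(instrument = "HOOSPS", item = 1:5, min_score = 0L,
               max_score = as.integer(hoosps_item_max),
               direction = "HIGHER_WORSE", label = paste("HOOS-PS item", 1:5)),
    data.frame(instrument = "ANCHOR", item = 0L, min_score = 1L, max_score = 7L,
               direction = "HIGHER_BETTER", label = "anchor: functional improvement")
  )
  rows$key <- item_key(rows$instrument, rows$item)
  rows[, c("instrument", "item", "key", "min_score", "max_score", "direction", "label")]
}

#' Build the canonical key for an item
#'
#' @param instrument instrument code, e.g. `"OHS"`.
#' @param item 1-based item index; 0 for single-question instruments.
#' @return character vector, e.g. `"OHS:6"`, `"NRS_ACTIVITY"`.
#' @export
item_key <- function(instrument, item) {
  ifelse(item == 0L, instrument, paste0(instrument, ":", item))
}

#' Look up item definitions by key
#'
#' @param key character vector of item keys.
#' @param defs definition table, see [pro_items()].
#' @return the matching definition rows; unknown keys are an error.
#' @export
item_def <- function(key, defs = pro_items()) {
  i <- match(key, defs$key)
  if (anyNA(i)) pt_stop(paste0("unknown item: ", paste(key[is.na(i)], collapse = ", ")),
                        class = "promtriage_validation_error")
  defs[i, , drop = FALSE]
}

#' Recode a score to the common (higher-is-better) direction
#'
#' Before homogeneity analysis, NRS pain and EQ-5D-3L scores are recoded to
#' run in the same direction as the Oxford Hip Score items: a
#' `HIGHER_WORSE` item is reflected within its range
#' (`min + max - value`); `HIGHER_BETTER` items pass through unchanged.
#' Recoding is an involution: applying it twice returns the original value.
#'
#' @param value integer score(s), within the item's range (`NA` passes
#'   through as `NA`).
#' @param def a single-row item definition (one row of [pro_items()]).
#' @return recoded score(s) on the same range, higher = better.
#' @export
#' @examples
#' defs <- pro_items()
#' recode_common_direction(10, defs[defs$key == "NRS_ACTIVITY", ])  # 0
recode_common_direction <- function(value, def) {
  stopifnot(nrow(def) == 1)
  bad <- !is.na(value) & (value < def$min_score | value > def$max_score)
  if (any(bad)) {
    pt_stop(sprintf("score out of range for %s: %s (allowed %d-%d)",
                    def$key, paste(value[bad], collapse = ", "),
                    def$min_score, def$max_score),
            class = "promtriage_validation_error")
  }
  if (def$direction == "HIGHER_WORSE") def$min_score + def$max_score - value else value
}

#' Oxford Hip Score total
#'
#' Sum of the 12 OHS item scores, 0 (most severe symptoms) to 48 (least
#' symptoms). Complete-case by default: the total is `NA` unless all 12
#' items are present. The official mean-imputation rule (impute up to 2
#' missing items with the patient's item mean) is available via
#' `impute = TRUE` but is not the default, to keep per-item denominators
#' explicit.
#'
#' @param scores numeric vector of the 12 item scores in item order
#'   (`NA` for missing), or a matrix with 12 columns (one row per patient).
#' @param impute logical; mean-impute up to 2 missing items.
#' @return total score(s) 0-48, `NA` where the policy leaves the total
#'   undefined.
#' @export
#' @examples
#' score_ohs_total(rep(4, 12))  # 48
score_ohs_total <- function(scores, impute = FALSE) {
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (ncol(m) != 12) pt_stop("OHS requires 12 item scores")
  if (any(m < 0 | m > 4, na.rm = TRUE))
    pt_stop("OHS item scores must lie in 0-4", class = "promtriage_validation_error")
  nmiss <- rowSums(is.na(m))
  out <- rowSums(m)
  if (impute) {
    fixable <- nmiss > 0 & nmiss <= 2
    if (any(fixable))
      out[fixable] <- round(rowMeans(m[fixable, , drop = FALSE], na.rm = TRUE) * 12)
  }
  if (length(out) == 1 && !is.matrix(scores)) out[[1]] else out
}

#' HOOS-PS summary score
#'
#' Linear rescaling of the five item scores to 0 (no difficulty) - 100
#' (extreme difficulty): `100 * sum(items) / (5 * item_max)`. Complete-case:
#' `NA` unless all five items are present. The published nomogram
#' transformation is deliberately not implemented; the linear score is used
#' only for baseline comparisons, never by the triage rule.
#'
#' @param scores numeric vector of the 5 item scores, or a 5-column matrix.
#' @param item_max per-item maximum (default 4).
#' @return score(s) on 0-100, higher = more difficulty.
#' @export
#' @examples
#' score_hoos_ps(c(2, 2, 2, 2, 2))  # 50
score_hoos_ps <- function(scores, item_max = 4) {
  m <- if (is.matrix(scores)) scores else matrix(scores, nrow = 1)
  if (ncol(m) != 5) pt_stop("HOOS-PS requires 5 item scores")
  if (any(m < 0 | m > item_max, na.rm = TRUE))
    pt_stop(sprintf("HOOS-PS item scores must lie in 0-%d", item_max),
            class = "promtriage_validation_error")
  out <- 100 * rowSums(m) / (5 * item_max)
  if (length(out) == 1 && !is.matrix(scores)) out[[1]] else out
}
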