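#' Construct a PROM cohort
#'
#' A cohort bundles a patient table with a long-format response table.
#' Patients carry demographics (age, gender, BMI), ASA and Charnley
#' classifications, a deceased flag and per-timepoint questionnaire-return
#' flags; responses are one row per (patient, timepoint, item) with an
#' integer score. Timepoints are `PRE` (preoperative), `M3` and `M12`
#' (3 and 12 months after surgery).
#'
#' @param patients data frame with columns `patient_id`, `surgery_year`,
#'   `cohort` (`TRAINING`/`TEST`), `age`, `gender`, `bmi`, `asa`,
#'   `charnley`, `deceased` (logical), `returned_pre`, `returned_m3`,
#'   `returned_m12` (logical).
#' @param responses data frame with columns `patient_id`, `timepoint`
#'   (`PRE`/`M3`/`M12`), `instrument`, `item`, `score`.
#' @param label cohort label; defaults to the modal `cohort` value.
#' @param n_thas number of arthroplasties represented (>= number of
#'   patients; a patient can contribute one questionnaire set per staged
#'   bilateral operation). Defaults to `nrow(patients)`.
#' @param defs item definitions, see [pro_items()].
#' @param strict if `TRUE` (default) any validation violation is an error;
#'   otherwise violations are attached as an attribute.
#' @return An object of class `pro_cohort`: a list with elements
#'   `label`, `patients`, `responses`, `n_thas`.
#' @seealso [validate_responses()], [read_cohort()], [generate_cohort()]
#' @export
pro_cohort <- function(patients, responses, label = NULL, n_thas = nrow(patients),
                       defs = pro_items(), strict = TRUE) {
  req_p <- c("patient_id", "surgery_year", "cohort", "age", "gender", "bmi",
             "asa", "charnley", "deceased", "returned_pre", "returned_m3", "returned_m12")
  req_r <- c("patient_id", "timepoint", "instrument", "item", "score")
  miss <- setdiff(req_p, names(patients))
  if (length(miss)) pt_stop(paste("patients table missing columns:", paste(miss, collapse = ", ")),
                            class = "promtriage_validation_error")
  miss <- setdiff(req_r, names(responses))
  if (length(miss)) pt_stop(paste("responses table missing columns:", paste(miss, collapse = ", ")),
                            class = "promtriage_validation_error")
  if (anyDuplicated(patients$patient_id))
    pt_stop("duplicate patient_id in patients table", class = "promtriage_validation_error")
  if (n_thas < nrow(patients))
    pt_stop("n_thas must be >= number of patient records", class = "promtriage_validation_error")
  viol <- validate_responses(patients, responses, defs)
  if (strict && nrow(viol) > 0)
    pt_stop(paste0("cohort validation failed (", nrow(viol), " violation(s)); first: ",
                   viol$message[1]),
            class = "promtriage_validation_error")
  out <- structure(
    list(label = label %||% names(sort(table(patients$cohort), decreasing = TRUE))[1],
         patients = patients, responses = responses, n_thas = as.integer(n_thas)),
    class = "pro_cohort")
  if (!strict) attr(out, "violations") <- viol
  out
}

#' @export
print.pro_cohort <- function(x, ...) {
  cat(sprintf("<pro_cohort '%s'> %d patients (%d THAs), %d responses\n",
              x$label, nrow(x$patients), x$n_thas, nrow(x$responses)))
  ret <- vapply(c("returned_pre", "returned_m3", "returned_m12"),
                function(cn) sum(x$patients[[cn]]), 0L)
  cat(sprintf("  returned: PRE %d, M3 %d, M12 %d\n", ret[1], ret[2], ret[3]))
  invisible(x)
}

#' Validate a response table against the item definitions
#'
#' Checks, without raising, that every response references a known item,
#' lies within its score range, uses a known timepoint, is not duplicated,
#' and does not occur at a timepoint whose questionnaire-return flag is
#' `FALSE`. Validation reports; it never stops.
#'
#' @inheritParams pro_cohort
#' @return data frame of violations (zero rows when clean) with columns
#'   `patient_id`, `key`, `timepoint`, `rule`, `message`.
#' @export
validate_responses <- function(patients, responses, defs = pro_items()) {
  v <- list()
  add <- function(pid, key, tp, rule, msg) {
    v[[length(v) + 1]] <<- data.frame(patient_id = as.character(pid), key = key,
                                      timepoint = tp, rule = rule, message = msg)
  }
  if (nrow(responses) == 0) return(empty_violations())
  key <- item_key(responses$instrument, responses$item)
  di <- match(key, defs$key)
  for (j in which(is.na(di)))
    add(responses$patient_id[j], key[j], responses$timepoint[j], "unknown_item",
        sprintf("patient %s: unknown item %s", responses$patient_id[j], key[j]))
  bad_tp <- !(responses$timepoint %in% c("PRE", "M3", "M12"))
  for (j in which(bad_tp))
    add(responses$patient_id[j], key[j], responses$timepoint[j], "unknown_timepoint",
        sprintf("patient %s: unknown timepoint %s", responses$patient_id[j],
                responses$timepoint[j]))
  ok <- !is.na(di) & !bad_tp
  rng <- which(ok & (responses$score < defs$min_score[di] |
                       responses$score > defs$max_score[di] |
                       responses$score != floor(responses$score)))
  for (j in rng)
    add(responses$patient_id[j], key[j], responses$timepoint[j], "score_out_of_range",
        sprintf("patient %s, %s at %s: score %s outside %d-%d",
                responses$patient_id[j], key[j], responses$timepoint[j],
                responses$score[j], defs$min_score[di[j]], defs$max_score[di[j]]))
  dup <- which(duplicated(responses[, c("patient_id", "timepoint", "instrument", "item")]))
  for (j in dup)
    add(responses$patient_id[j], key[j], responses$timepoint[j], "duplicate_response",
        sprintf("patient %s: duplicate response for %s at %s",
                responses$patient_id[j], key[j], responses$timepoint[j]))
  unknown_pid <- !(responses$patient_id %in% patients$patient_id)
  for (j in which(unknown_pid))
    add(responses$patient_id[j], key[j], responses$timepoint[j], "unknown_patient",
        sprintf("response for unknown patient %s", responses$patient_id[j]))
  pi <- match(responses$patient_id, patients$patient_id)
  ret <- rep(NA, nrow(responses))
  for (tp in c("PRE", "M3", "M12")) {
    cn <- c(PRE = "returned_pre", M3 = "returned_m3", M12 = "returned_m12")[[tp]]
    sel <- !bad_tp & responses$timepoint == tp
    ret[sel] <- patients[[cn]][pi[sel]]
  }
  for (j in which(ok & !unknown_pid & !is.na(ret) & !ret))
    add(responses$patient_id[j], key[j], responses$timepoint[j], "response_without_return",
        sprintf("patient %s has a %s response at %s but returned=FALSE",
                responses$patient_id[j], key[j], responses$timepoint[j]))
  if (length(v) == 0) return(empty_violations())
  do.call(rbind, v)
}

empty_violations <- function() {
  data.frame(patient_id = character(), key = character(), timepoint = character(),
             rule = character(), message = character())
}

#' Extract a patients-by-items score matrix at one timepoint
#'
#' Rows are the cohort's patients whose questionnaire was returned at `t`
#' (in patient-table order, patient ids as rownames); columns are the
#' requested item keys; absent responses are `NA`.
#'
#' @param cohort a [pro_cohort()].
#' @param keys character vector of item keys (e.g. `c("NRS_ACTIVITY", "OHS:6")`).
#' @param t timepoint, one of `"PRE"`, `"M3"`, `"M12"`.
#' @param recode recode all scores to the common higher-is-better direction.
#' @param defs item definitions.
#' @return numeric matrix, `length(returned patients)` x `length(keys)`.
#' @export
response_matrix <- function(cohort, keys, t, recode = FALSE, defs = pro_items()) {
  stopifnot(inherits(cohort, "pro_cohort"), t %in% c("PRE", "M3", "M12"))
  ret_col <- c(PRE = "returned_pre", M3 = "returned_m3", M12 = "returned_m12")[[t]]
  pids <- cohort$patients$patient_id[cohort$patients[[ret_col]]]
  r <- cohort$responses[cohort$responses$timepoint == t, ]
  rkey <- item_key(r$instrument, r$item)
  m <- matrix(NA_real_, length(pids), length(keys),
              dimnames = list(as.character(pids), keys))
  sel <- rkey %in% keys & r$patient_id %in% pids
  m[cbind(match(r$patient_id[sel], pids), match(rkey[sel], keys))] <- r$score[sel]
  if (recode) {
    for (k in keys) {
      d <- item_def(k, defs)
      m[, k] <- recode_common_direction(m[, k], d)
    }
  }
  m
}

#' Read a cohort from the two CSV files
#'
#' Expects the package's interchange layout: a patient table
#' (`patient_id,surgery_year,cohort,age,gender,bmi,asa,charnley,deceased,returned_pre,returned_m3,returned_m12`)
#' and a long response table (`patient_id,timepoint,instrument,item,score`)
#' with timepoint tokens `PRE|M3|M12` and absent responses simply absent
#' (no sentinel values). UTF-8 with or without a BOM; LF or CRLF endings.
#'
#' @param patients_path,responses_path paths to the two CSV files.
#' @param n_thas see [pro_cohort()].
#' @param label cohort label override.
#' @param defs item definitions.
#' @return a validated [pro_cohort()]; any violation is a hard error
#'   naming the patient, item and rule.
#' @export
read_cohort <- function(patients_path, responses_path, n_thas = NULL,
                        label = NULL, defs = pro_items()) {
  for (p in c(patients_path, responses_path))
    if (!file.exists(p)) pt_stop(paste("file not found:", p))
  patients <- utils::read.csv(patients_path, fileEncoding = "UTF-8-BOM",
                              stringsAsFactors = FALSE)
  responses <- utils::read.csv(responses_path, fileEncoding = "UTF-8-BOM",
                               stringsAsFactors = FALSE)
  for (cn in c("deceased", "returned_pre", "returned_m3", "returned_m12"))
    if (cn %in% names(patients)) patients[[cn]] <- as.logical(patients[[cn]])
  patients$patient_id <- as.character(patients$patient_id)
  if (nrow(responses)) responses$patient_id <- as.character(responses$patient_id)
  pro_cohort(patients, responses, label = label,
             n_thas = n_thas %||% nrow(patients), defs = defs, strict = TRUE)
}

#' Write a cohort to the two CSV files
#'
#' Inverse of [read_cohort()]: a written cohort reads back equal.
#'
#' @param cohort a [pro_cohort()].
#' @param patients_path,responses_path output paths.
#' @return the input, invisibly.
#' @export
write_cohort <- function(cohort, patients_path, responses_path) {
  stopifnot(inherits(cohort, "pro_cohort"))
  utils::write.csv(cohort$patients, patients_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$responses, responses_path, row.names = FALSE, quote = FALSE)
  invisible(cohort)
}
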