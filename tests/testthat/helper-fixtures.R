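# in-code fixtures shared across test files

# minimal patients table for n hand-built patients, everything returned
mini_patients <- function(n, label = "TRAINING") {
  data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    surgery_year = 2016L, cohort = label,
    age = 66, gender = "F", bmi = 26, asa = "I", charnley = "ONE_HIP",
    deceased = FALSE, returned_pre = TRUE, returned_m3 = TRUE, returned_m12 = TRUE)
}

# long response rows for one patient at one timepoint from a named score
# vector (names are item keys)
response_rows <- function(pid, t, scores) {
  ks <- names(scores)
  instrument <- sub(":.*$", "", ks)
  item <- rep(0L, length(ks))
  item[grepl(":", ks)] <- as.integer(sub("^.*:", "", ks[grepl(":", ks)]))
  data.frame(patient_id = pid, timepoint = t, instrument = instrument,
             item = item, score = unname(scores))
}

# best (least severe) raw score for each item of a rule
best_scores <- function(rule, defs = pro_items()) {
  d <- defs[match(rule$criteria$key, defs$key), ]
  stats::setNames(ifelse(d$direction == "HIGHER_WORSE", d$min_score, d$max_score),
                  rule$criteria$key)
}

# worst raw score per rule item
worst_scores <- function(rule, defs = pro_items()) {
  d <- defs[match(rule$criteria$key, defs$key), ]
  stats::setNames(ifelse(d$direction == "HIGHER_WORSE", d$max_score, d$min_score),
                  rule$criteria$key)
}

# cohort in which exactly n_cross of n_returned respondents cross one
# final-tool threshold (NRS activity set above its cutoff), the rest at
# the best score on every rule item
allocation_fixture <- function(n_returned, n_cross, label = "TRAINING") {
  rule <- final_rule()
  best <- best_scores(rule)
  crossed <- replace(best, "NRS_ACTIVITY", 7)
  patients <- mini_patients(n_returned, label)
  patients$returned_pre <- FALSE
  patients$returned_m12 <- FALSE
  rows <- lapply(seq_len(n_returned), function(i)
    response_rows(patients$patient_id[i], "M3", if (i <= n_cross) crossed else best))
  pro_cohort(patients, do.call(rbind, rows), label = label)
}

# independent signed-rank oracle: two-sided p by full 2^n enumeration of
# sign assignments over the observed absolute-difference ranks
signed_rank_p_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  w_obs <- sum(rk[d > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    s <- as.integer(intToBits(mask))[1:n]
    sum(rk[s == 1])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# independent Fisher oracle for a 2x2 table: sum of hypergeometric
# probabilities of tables as or more extreme than the observed one
fisher_p_enum <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(m, k)
  pr <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
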