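test_that("threshold crossing follows the worse-side convention", {
  expect_true(item_crossed(4, ">=", 4)$crossed)
  expect_false(item_crossed(3, ">=", 4)$crossed)
  expect_false(item_crossed(3, "<=", 2)$crossed)
  expect_true(item_crossed(2, "<=", 2)$crossed)
  miss <- item_crossed(NA, ">=", 4)
  expect_false(miss$crossed)
  expect_true(miss$missing)
})

test_that("shipped rules match the expert-panel criteria", {
  cand <- candidate_rule()
  fin <- final_rule()
  expect_equal(nrow(cand$criteria), 9)
  expect_equal(nrow(fin$criteria), 6)
  expect_setequal(fin$criteria$key,
                  c("NRS_ACTIVITY", "EQ5D3L:1", "EQ5D3L:4", "OHS:6", "OHS:8", "OHS:12"))
  expect_true(all(fin$criteria$key %in% cand$criteria$key))
  expect_equal(cand$criteria$cutoff[cand$criteria$key == "NRS_ACTIVITY"], 4)
  expect_equal(cand$criteria$comparator[cand$criteria$key == "OHS:8"], "<=")
  expect_equal(cand$criteria$cutoff[cand$criteria$key == "OHS:8"], 2)
  expect_setequal(unique(cand$criteria$group), c("PAIN", "CRUTCHES"))
})

test_that("rule validation rejects malformed criteria", {
  crit <- final_rule()$criteria
  crit$comparator[1] <- "<="  # wrong side for a higher-worse item
  expect_error(triage_rule(crit), "worse side")
  crit <- final_rule()$criteria
  crit$cutoff[1] <- 11
  expect_error(triage_rule(crit), "range")
  expect_error(triage_rule(rbind(final_rule()$criteria, final_rule()$criteria[1, ])),
               "duplicate")
})

test_that("single-patient triage allocates by disjunction with missing flagged", {
  rule <- candidate_rule()
  best <- best_scores(rule)
  expect_equal(triage_patient(best, rule)$allocation, "VIDEO")
  one_bad <- replace(best, "NRS_ACTIVITY", 7)
  out <- triage_patient(one_bad, rule)
  expect_equal(out$allocation, "HOSPITAL")
  expect_equal(out$triggered, "NRS_ACTIVITY")
  expect_equal(triage_patient(stats::setNames(numeric(0), character(0)), rule)$allocation,
               "UNALLOCATABLE")
  partial <- best[1:3]
  out2 <- triage_patient(partial, rule)
  expect_equal(out2$allocation, "VIDEO")
  expect_setequal(out2$missing_items, setdiff(rule$criteria$key, names(partial)))
  expect_error(triage_patient(c(NRS_ACTIVITY = 11), rule), "range")
})

test_that("triage agrees with a brute-force disjunction oracle on a score grid", {
  rule <- final_rule()
  defs <- pro_items()
  d <- defs[match(rule$criteria$key, defs$key), ]
  # per item: best, one step short of the cutoff, cutoff, worst
  grid_vals <- lapply(seq_len(nrow(d)), function(i) {
    cut <- rule$criteria$cutoff[i]
    shy <- if (rule$criteria$comparator[i] == ">=") cut - 1 else cut + 1
    best <- if (d$direction[i] == "HIGHER_WORSE") d$min_score[i] else d$max_score[i]
    worst <- if (d$direction[i] == "HIGHER_WORSE") d$max_score[i] else d$min_score[i]
    unique(c(best, shy, cut, worst))
  })
  combos <- as.matrix(expand.grid(grid_vals))
  colnames(combos) <- rule$criteria$key
  oracle <- vapply(seq_len(nrow(combos)), function(r) {
    any(vapply(seq_len(nrow(d)), function(i)
      item_crossed(combos[r, i], rule$criteria$comparator[i],
                   rule$criteria$cutoff[i])$crossed, TRUE))
  }, TRUE)
  got <- vapply(seq_len(nrow(combos)), function(r)
    triage_patient(combos[r, ], rule)$allocation, "")
  expect_equal(got, ifelse(oracle, "HOSPITAL", "VIDEO"))
})

test_that("worsening a single item never flips hospital to video", {
  rule <- final_rule()
  defs <- pro_items()
  d <- defs[match(rule$criteria$key, defs$key), ]
  set.seed(11)
  for (rep in 1:200) {
    sc <- stats::setNames(
      vapply(seq_len(nrow(d)), function(i) sample(d$min_score[i]:d$max_score[i], 1), 0),
      rule$criteria$key)
    before <- triage_patient(sc, rule)$allocation
    i <- sample(nrow(d), 1)
    worse_dir <- if (d$direction[i] == "HIGHER_WORSE") 1 else -1
    sc2 <- sc
    sc2[i] <- min(max(sc[i] + worse_dir, d$min_score[i]), d$max_score[i])
    after <- triage_patient(sc2, rule)$allocation
    if (before == "HOSPITAL") expect_equal(after, "HOSPITAL")
  }
})

test_that("cohort triage counts are consistent and order-invariant", {
  coh <- allocation_fixture(50, 13)
  res <- triage_cohort(coh, final_rule())
  s <- res$summary
  expect_equal(s$n_hospital + s$n_video, s$n_allocated)
  expect_equal(s$n_hospital, sum(res$outcomes$allocation == "HOSPITAL"))
  expect_equal(s$hospital_proportion, 13 / 50)
  # reorder patients: same summary
  coh2 <- coh
  perm <- rev(seq_len(nrow(coh2$patients)))
  coh2$patients <- coh2$patients[perm, ]
  s2 <- triage_cohort(coh2, final_rule())$summary
  expect_equal(s2$hospital_proportion, s$hospital_proportion)
  expect_equal(s2$n_allocated, s$n_allocated)
})

test_that("removing a criterion never increases the hospital count", {
  set.seed(21)
  coh <- generate_cohort(generator_config(n_patients = 150, seed = 21))
  rule <- candidate_rule()
  full <- triage_cohort(coh, rule)$summary$n_hospital
  for (i in seq_len(nrow(rule$criteria))) {
    sub <- triage_rule(rule$criteria[-i, ], name = "sub")
    expect_lte(triage_cohort(coh, sub)$summary$n_hospital, full)
  }
})

test_that("unallocatable patients are reported separately, not in the proportion", {
  patients <- mini_patients(3)
  patients$returned_pre <- FALSE; patients$returned_m12 <- FALSE
  rule <- final_rule()
  rows <- rbind(response_rows("P001", "M3", best_scores(rule)),
                response_rows("P002", "M3", replace(best_scores(rule), "NRS_ACTIVITY", 9)),
                response_rows("P003", "M3", c(ANCHOR = 7)))  # no rule items
  res <- triage_cohort(pro_cohort(patients, rows), rule)
  expect_equal(res$summary$n_unallocatable, 1)
  expect_equal(res$summary$n_allocated, 2)
  expect_equal(res$summary$hospital_proportion, 0.5)
  expect_equal(res$summary$n_hospital_operational, 2)  # conservative default
  expect_equal(res$outcomes$allocation[res$outcomes$patient_id == "P003"],
               "UNALLOCATABLE")
})

test_that("allocation-rate comparison picks chi-square or Fisher by expected counts", {
  same <- list(label = "A", n_hospital = 10, n_video = 10)
  r <- compare_rates(same, replace(same, "label", "B"))
  expect_equal(r$method, "CHI_SQUARE")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_uncorrected, 1)

  tiny <- compare_rates(list(label = "A", n_hospital = 2, n_video = 8),
                        list(label = "B", n_hospital = 3, n_video = 7))
  expect_equal(tiny$method, "FISHER")

  expect_error(compare_rates(list(n_hospital = 0, n_video = 0), same), "zero")
})
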