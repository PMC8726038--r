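test_that("item definitions cover the instrument set with the stated ranges", {
  defs <- pro_items()
  expect_true(all(defs$min_score < defs$max_score))
  expect_equal(sort(unique(defs$instrument)),
               sort(c("NRS_REST", "NRS_ACTIVITY", "EQ5D3L", "EQVAS", "OHS",
                      "HOOSPS", "ANCHOR")))
  nrs <- defs[defs$instrument %in% c("NRS_REST", "NRS_ACTIVITY"), ]
  expect_true(all(nrs$min_score == 0 & nrs$max_score == 10 &
                    nrs$direction == "HIGHER_WORSE"))
  ohs <- defs[defs$instrument == "OHS", ]
  expect_equal(nrow(ohs), 12)
  expect_true(all(ohs$min_score == 0 & ohs$max_score == 4 &
                    ohs$direction == "HIGHER_BETTER"))
  eq <- defs[defs$instrument == "EQ5D3L", ]
  expect_true(all(eq$min_score == 1 & eq$max_score == 3 &
                    eq$direction == "HIGHER_WORSE"))
  expect_false(anyDuplicated(defs$key) > 0)
})

test_that("direction recoding reflects worse-direction items and is an involution", {
  defs <- pro_items()
  expect_equal(recode_common_direction(10, defs[defs$key == "NRS_ACTIVITY", ]), 0)
  expect_equal(recode_common_direction(2, defs[defs$key == "EQ5D3L:4", ]), 2)
  expect_equal(recode_common_direction(3, defs[defs$key == "OHS:6", ]), 3)
  for (i in seq_len(nrow(defs))) {
    d <- defs[i, ]
    rng <- d$min_score:d$max_score
    rec <- recode_common_direction(rng, d)
    expect_true(all(rec >= d$min_score & rec <= d$max_score), info = d$key)
    expect_equal(recode_common_direction(rec, d), rng, info = d$key)
  }
  expect_error(recode_common_direction(11, defs[defs$key == "NRS_REST", ]),
               "out of range")
})

test_that("OHS total follows the complete-case policy and reflection conservation", {
  expect_equal(score_ohs_total(rep(4, 12)), 48)
  expect_equal(score_ohs_total(rep(0, 12)), 0)
  v <- c(4, 3, 2, 4, 4, 1, 0, 2, 3, 4, 4, 2)
  expect_equal(score_ohs_total(v), sum(v))
  expect_true(is.na(score_ohs_total(replace(v, 5, NA))))
  # mean imputation permitted for <= 2 missing items only when asked
  expect_equal(score_ohs_total(replace(rep(3, 12), 1, NA), impute = TRUE), 36)
  expect_true(is.na(score_ohs_total(replace(rep(3, 12), 1:3, NA), impute = TRUE)))
  # total equals 48 minus the item-wise reflected total
  expect_equal(score_ohs_total(v), 48 - sum(4 - v))
  expect_error(score_ohs_total(rep(5, 12)), "0-4")
})

test_that("HOOS-PS rescales linearly to 0-100 under complete cases", {
  expect_equal(score_hoos_ps(rep(0, 5)), 0)
  expect_equal(score_hoos_ps(rep(4, 5)), 100)
  expect_equal(score_hoos_ps(c(2, 2, 2, 2, 2)), 50)
  expect_equal(score_hoos_ps(c(1, 0, 2, 0, 1)), 100 * 4 / 20)
  expect_true(is.na(score_hoos_ps(c(1, NA, 2, 0, 1))))
  # configurable per-item maximum changes the denominator
  expect_equal(score_hoos_ps(rep(5, 5), item_max = 5), 100)
})

test_that("scoring is invariant to response storage order", {
  patients <- mini_patients(2)
  sc <- stats::setNames(c(4, 3, 2, 4, 4, 1, 0, 2, 3, 4, 4, 2), item_key("OHS", 1:12))
  rows <- rbind(response_rows("P001", "M3", sc),
                response_rows("P002", "M3", rev(sc)))
  shuffled <- rows[sample(nrow(rows)), ]
  m1 <- response_matrix(pro_cohort(patients, rows), item_key("OHS", 1:12), "M3")
  m2 <- response_matrix(pro_cohort(patients, shuffled), item_key("OHS", 1:12), "M3")
  expect_identical(m1, m2)
  expect_equal(unname(score_ohs_total(m1)), c(sum(sc), sum(sc)))
})

test_that("validation reports violations without raising", {
  patients <- mini_patients(2)
  ok_rows <- response_rows("P001", "M3", c(`OHS:1` = 4, NRS_REST = 0))
  expect_equal(nrow(validate_responses(patients, ok_rows)), 0)

  bad <- rbind(ok_rows,
               response_rows("P002", "M3", c(`OHS:2` = 5)),        # out of range
               response_rows("P002", "M3", c(`OHS:3` = 2)),
               response_rows("P002", "M3", c(`OHS:3` = 2)))        # duplicate
  v <- validate_responses(patients, bad)
  expect_setequal(v$rule, c("score_out_of_range", "duplicate_response"))
  expect_true(all(c("patient_id", "key", "timepoint", "message") %in% names(v)))
  expect_match(v$message[v$rule == "score_out_of_range"], "P002")

  # a response at a timepoint whose returned flag is false is a violation
  patients$returned_m12 <- FALSE
  v2 <- validate_responses(patients, response_rows("P001", "M12", c(NRS_REST = 1)))
  expect_equal(v2$rule, "response_without_return")

  # strict cohort construction refuses the same data
  expect_error(pro_cohort(patients, response_rows("P001", "M12", c(NRS_REST = 1))),
               "validation failed")
})
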