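test_that("distribution summary detects degeneracy and matches the quartile oracle", {
  deg <- distribution_summary(rep(4, 20))
  expect_true(deg$degenerate)
  expect_equal(c(deg$q1, deg$median, deg$q3), c(4, 4, 4))
  expect_false(distribution_summary(0:10)$degenerate)
  # type-7 linear interpolation between order statistics, hand-checked:
  # sorted {1,2,3,4,4,5,7,8,9}: h=1+(n-1)p -> q1 at h=3, med at h=5, q3 at h=7
  s <- distribution_summary(c(2, 5, 1, 9, 4, 4, 7, 3, 8))
  expect_equal(c(s$q1, s$median, s$q3), c(3, 4, 7))
  expect_error(distribution_summary(numeric(0)), "no observed")
})

test_that("floor effect counts the direction-aware worst score with a strict cutoff", {
  defs <- pro_items()
  nrs <- defs[defs$key == "NRS_REST", ]
  f <- floor_effect(c(rep(10, 3), rep(0, 700)), nrs)
  expect_equal(f$n_worst, 3)
  expect_equal(f$pct, 0.4)
  expect_false(f$flagged)
  expect_true(floor_effect(c(rep(10, 16), rep(0, 84)), nrs)$flagged)
  expect_false(floor_effect(c(rep(10, 15), rep(0, 85)), nrs)$flagged)  # strict >
  # higher-better item floors at its minimum
  ohs <- defs[defs$key == "OHS:6", ]
  expect_equal(floor_effect(c(0, 0, 4, 4), ohs)$n_worst, 2)
  # counting identity on a random fixture
  set.seed(3)
  v <- sample(0:10, 500, replace = TRUE)
  expect_equal(floor_effect(v, nrs)$proportion, mean(v == 10))
})

test_that("spearman matrix matches a rank-then-Pearson oracle and flags at the cutoff", {
  a <- c(1, 2, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 6, 5)
  m <- cbind(x = a, y = b, yr = -b)
  res <- spearman_matrix(m, cutoff = 0.7)
  rho_xy <- res$rho[res$item_a == "x" & res$item_b == "y"]
  expect_equal(rho_xy, stats::cor(rank(a), rank(b)), tolerance = 1e-12)
  expect_equal(rho_xy, 0.7537023, tolerance = 1e-6)
  expect_equal(res$rho[res$item_a == "y" & res$item_b == "yr"], -1)
  expect_true(res$flagged[res$item_a == "x" & res$item_b == "y"])
  # t-approximation p-value oracle
  n <- 6; tt <- rho_xy * sqrt((n - 2) / (1 - rho_xy^2))
  expect_equal(res$p_value[res$item_a == "x" & res$item_b == "y"],
               2 * stats::pt(-abs(tt), n - 2), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  m2 <- cbind(x = exp(a), y = b^3)
  expect_equal(spearman_matrix(m2)$rho, rho_xy, tolerance = 1e-12)
  # constant column is undefined, never flagged
  res3 <- spearman_matrix(cbind(x = a, k = rep(2, 6)))
  expect_true(is.na(res3$rho))
  expect_false(res3$flagged)
})

test_that("responsiveness uses the exact tie-aware null for small samples", {
  # no change: no signal, p = 1
  flat <- responsiveness(c(2, 3, 4, 2), c(2, 3, 4, 2))
  expect_equal(flat$p_value, 1)
  expect_false(flat$responsive)
  expect_equal(flat$effect, 0)
  # hand-enumerable case: ranks {+1..+5, -6}, 2^6 sign assignments
  r <- responsiveness(rep(0, 6), c(1, 2, 3, 4, 5, -6))
  expect_equal(r$method, "exact")
  expect_equal(r$p_value, 0.4375, tolerance = 1e-12)
  expect_equal(r$statistic, 15)
  # exact path vs brute-force enumeration across random tied integer cases
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(4:10, 1)
    pre <- sample(0:4, n, replace = TRUE)
    m3 <- sample(0:4, n, replace = TRUE)
    if (all(m3 - pre == 0)) next
    got <- responsiveness(pre, m3)
    expect_equal(got$p_value, signed_rank_p_enum(m3 - pre), tolerance = 1e-12,
                 info = paste("rep", rep))
  }
  # large uniform improvement: strongly responsive under the normal path
  set.seed(8)
  pre <- sample(5:9, 30, replace = TRUE)
  m3 <- pre - sample(2:4, 30, replace = TRUE)
  big <- responsiveness(pre, m3)
  expect_equal(big$method, "normal_approx")
  expect_lt(big$p_value, 0.001)
  expect_equal(big$effect, -1)  # every pair moved down
  expect_error(responsiveness(NA, NA), "no complete pairs")
})

test_that("journey splits by the 3-month threshold and flags trajectory swaps", {
  crit <- final_rule()$criteria
  nrs <- crit[crit$key == "NRS_ACTIVITY", ]
  # worse group stays worse at 12 months: retained
  m3 <- c(rep(7, 6), rep(1, 8))
  m12 <- c(rep(5, 6), rep(0, 8))
  j <- journey(m3, m12, nrs)
  expect_equal(j$n_worse, 6)
  expect_equal(j$n_better, 8)
  expect_equal(j$n_worse + j$n_better, 14)
  expect_false(j$flagged)
  expect_false(j$small_group_warning)
  # worse group ends up better than the better group: flagged
  j2 <- journey(m3, c(rep(0, 6), rep(2, 8)), nrs)
  expect_true(j2$flagged)
  # threshold policy: retained while the worse group's median still crosses
  j3 <- journey(m3, m12, nrs, policy = "threshold")
  expect_false(j3$flagged)  # worse-group 12m median 5 still >= 4
  j4 <- journey(m3, c(rep(2, 6), rep(0, 8)), nrs, policy = "threshold")
  expect_true(j4$flagged)   # median 2 no longer crosses
  # tiny group: warning, no verdict
  j5 <- journey(c(7, rep(1, 9)), c(0, rep(0, 9)), nrs)
  expect_true(j5$small_group_warning)
  expect_true(is.na(j5$flagged))
  # empty worse group: its summary is absent
  j6 <- journey(rep(1, 8), rep(0, 8), nrs)
  expect_null(j6$worse)
  expect_true(is.na(j6$flagged))
})

test_that("Cronbach alpha matches the covariance-identity oracle and its invariances", {
  expect_equal(cronbach_alpha(cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4)))$alpha, 1)
  M <- matrix(c(1, 2, 3, 2, 3, 4, 3, 3, 3, 4, 5, 6), 4, 3, byrow = TRUE,
              dimnames = list(NULL, c("a", "b", "c")))
  got <- cronbach_alpha(M)$alpha
  # independent identity: alpha = k/(k-1) * (1 - tr(C)/sum(C)) on the
  # sample covariance matrix
  C <- stats::cov(M)
  expect_equal(got, 3 / 2 * (1 - sum(diag(C)) / sum(C)), tolerance = 1e-12)
  expect_equal(got, 0.9473684, tolerance = 1e-6)
  # invariant under adding a constant to a column and under reordering
  M2 <- M; M2[, 2] <- M2[, 2] + 7
  expect_equal(cronbach_alpha(M2)$alpha, got, tolerance = 1e-12)
  expect_equal(cronbach_alpha(M[, c(3, 1, 2)])$alpha, got, tolerance = 1e-12)
  # independent columns: alpha near zero
  set.seed(5)
  R <- cbind(stats::rnorm(1000), stats::rnorm(1000), stats::rnorm(1000))
  expect_lt(abs(cronbach_alpha(R)$alpha), 0.1)
  # zero total variance is undefined, reported as NA
  expect_true(is.na(cronbach_alpha(cbind(c(1, 2), c(2, 1)))$alpha))
  # listwise deletion
  M3 <- rbind(M, c(NA, 1, 1))
  expect_equal(cronbach_alpha(M3)$n_complete, 4)
  expect_equal(cronbach_alpha(M3)$alpha, got, tolerance = 1e-12)
})

test_that("alpha-if-deleted flags only misfitting items, never in 2-item groups", {
  set.seed(6)
  base <- stats::rnorm(400)
  two <- cbind(a = base + stats::rnorm(400, sd = .4),
               b = base + stats::rnorm(400, sd = .4))
  h2 <- alpha_if_deleted(two)
  expect_length(h2$alpha_if_deleted, 0)
  expect_length(h2$removal_candidates, 0)
  expect_false(is.na(h2$alpha))
  # two coherent columns plus pure noise: the noise column is the unique candidate
  three <- cbind(two, c = stats::rnorm(400))
  h3 <- alpha_if_deleted(three)
  expect_equal(h3$removal_candidates, "c")
  expect_equal(unname(h3$alpha_if_deleted["c"]),
               cronbach_alpha(three[, c("a", "b")])$alpha, tolerance = 1e-12)
  # identical columns: deletion cannot strictly increase alpha
  same <- cbind(a = 1:6, b = 1:6, c = 1:6)
  expect_length(alpha_if_deleted(same)$removal_candidates, 0)
})
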