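# default 3-month severity-level probabilities per item (severity 0 = best
# possible score, K = worst). Chosen to mirror a well-recovered THA cohort
# three months after surgery: most patients near the best score, a thin
# worse tail, and one engineered degenerate item (OHS question 10, whose
# 3-month quartiles collapse onto the best score).
default_m3_probs <- function() {
  nrs_rest <- c(.55, .18, .10, .07, .04, .025, .015, .010, .005, .003, .002)
  nrs_act  <- c(.34, .19, .18, .16, .055, .030, .020, .012, .007, .004, .002)
  ohs_generic <- c(.50, .27, .13, .06, .04)
  p <- list(
    NRS_REST = nrs_rest,
    NRS_ACTIVITY = nrs_act,
    `EQ5D3L:1` = c(.64, .34, .02),
    `EQ5D3L:2` = c(.84, .14, .02),
    `EQ5D3L:3` = c(.70, .27, .03),
    `EQ5D3L:4` = c(.60, .35, .05),
    `EQ5D3L:5` = c(.80, .17, .03),
    EQVAS = stats::dnorm(0:100, mean = 22, sd = 15),
    `OHS:6`  = c(.55, .38, .045, .015, .010),
    `OHS:8`  = c(.52, .40, .05, .02, .01),
    `OHS:10` = c(.87, .06, .04, .02, .01),
    `OHS:12` = c(.54, .36, .06, .025, .015),
    `OHS:1`  = c(.45, .32, .13, .06, .04),
    ANCHOR = c(.35, .30, .18, .09, .04, .025, .015)
  )
  for (k in paste0("OHS:", c(2:5, 7, 9, 11))) p[[k]] <- ohs_generic
  for (k in paste0("HOOSPS:", 1:5)) p[[k]] <- c(.55, .25, .12, .05, .03)
  lapply(p, function(x) x / sum(x))
}

#' Configuration of the synthetic cohort generator
#'
#' The generator draws ordinal PROM responses from a latent-Gaussian
#' (ordinal probit / Gaussian copula) model: each patient has a latent
#' severity `mu[t] + u` at timepoint `t`, where `u ~ N(0, tau^2)` is a
#' per-patient random effect inducing 3-to-12-month tracking; each item's
#' latent value adds a residual (standard deviation `resid_sd`, correlated
#' across items via `residual_cor`); item cutpoints map the latent value to
#' the item's integer range, respecting score direction (higher latent
#' severity = worse score). Cutpoints are placed at the latent quantiles of
#' the per-item 3-month severity distributions (`m3_probs`), so 3-month
#' marginals are controlled directly and the preoperative/12-month
#' marginals follow from the `mu` shifts.
#'
#' Defaults emulate the study population: two surgery-year cohorts
#' (training n=746, 2016-2017; test n=482, 2018), near-complete
#' preoperative response with >90% postoperative response, strong
#' preoperative-to-3-month improvement, further slight improvement by 12
#' months, residually correlated NRS-activity/NRS-rest and
#' NRS-activity/OHS-1 pairs, a degenerate OHS-10 3-month distribution, and
#' a roughly 30% rate of crossing at least one final-tool threshold at 3
#' months (tuned exactly via [calibrate_crossing_rate()]).
#'
#' @param n_patients cohort size.
#' @param label `"TRAINING"` or `"TEST"`.
#' @param surgery_years years to sample surgery dates from.
#' @param items item keys to generate (default: the full instrument set).
#' @param timepoints subset of `c("PRE","M3","M12")` to generate.
#' @param mu named latent severity means (`PRE`, `M3`, `M12`); `M3` is the
#'   reference level 0.
#' @param tau standard deviation of the per-patient random effect.
#' @param resid_sd residual standard deviation.
#' @param loadings named item weights on the common severity (default 1
#'   for every item; 0 detaches an item from recovery and from its peers).
#' @param residual_cor data frame `item_a`, `item_b`, `cor` of residual
#'   correlations (identity otherwise).
#' @param m3_probs named list of per-item 3-month severity-level
#'   probability vectors overriding the defaults.
#' @param m3_shift scalar added to the 3-month cutpoints (a positive shift
#'   makes 3-month scores better and lowers the threshold-crossing rate);
#'   set by [calibrate_crossing_rate()].
#' @param target_crossing_rate desired probability of crossing at least
#'   one final-tool threshold at 3 months (default 0.29).
#' @param nonresponse named per-timepoint probabilities of not returning
#'   the questionnaire.
#' @param item_skip per-item skip probability within a returned
#'   questionnaire.
#' @param deceased_rate probability a patient is deceased before follow-up
#'   (postoperative questionnaires then never return).
#' @param seed integer seed; generation is deterministic given the config.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 746, label = "TRAINING",
                             surgery_years = 2016:2017,
                             items = pro_items()$key,
                             timepoints = c("PRE", "M3", "M12"),
                             mu = c(PRE = 2.2, M3 = 0, M12 = -0.25),
                             tau = 1, resid_sd = 1,
                             loadings = NULL, residual_cor = NULL,
                             m3_probs = list(), m3_shift = 0,
                             target_crossing_rate = 0.29,
                             nonresponse = c(PRE = 0.001, M3 = 0.05, M12 = 0.07),
                             item_skip = 0.003, deceased_rate = 0, seed = 1L) {
  stopifnot(n_patients >= 1, tau >= 0, resid_sd > 0,
            all(timepoints %in% c("PRE", "M3", "M12")),
            all(c("PRE", "M3", "M12") %in% names(mu)),
            item_skip >= 0, item_skip <= 1, deceased_rate >= 0, deceased_rate < 1,
            target_crossing_rate > 0, target_crossing_rate < 1)
  defs <- pro_items()
  item_def(items, defs)  # errors on unknown keys
  lam <- stats::setNames(rep(1, length(items)), items)
  if (!is.null(loadings)) {
    unknown <- setdiff(names(loadings), items)
    if (length(unknown)) pt_stop(paste("loadings for unknown items:",
                                       paste(unknown, collapse = ", ")))
    lam[names(loadings)] <- loadings
  }
  if (is.null(residual_cor))
    residual_cor <- data.frame(item_a = c("NRS_REST", "OHS:1"),
                               item_b = c("NRS_ACTIVITY", "NRS_ACTIVITY"),
                               cor = c(0.50, 0.50))
  probs <- default_m3_probs()
  for (k in names(m3_probs)) probs[[k]] <- m3_probs[[k]] / sum(m3_probs[[k]])
  structure(list(n_patients = as.integer(n_patients), label = label,
                 surgery_years = surgery_years, items = items,
                 timepoints = timepoints, mu = mu, tau = tau,
                 resid_sd = resid_sd, loadings = lam,
                 residual_cor = residual_cor, m3_probs = probs,
                 m3_shift = m3_shift, target_crossing_rate = target_crossing_rate,
                 nonresponse = nonresponse, item_skip = item_skip,
                 deceased_rate = deceased_rate, seed = as.integer(seed)),
            class = "generator_config")
}

# residual correlation matrix for the configured items; validated PSD in rmvn
resid_matrix <- function(cfg) {
  k <- length(cfg$items)
  R <- diag(k)
  dimnames(R) <- list(cfg$items, cfg$items)
  rc <- cfg$residual_cor
  for (i in seq_len(nrow(rc))) {
    if (!(rc$item_a[i] %in% cfg$items) || !(rc$item_b[i] %in% cfg$items)) next
    R[rc$item_a[i], rc$item_b[i]] <- R[rc$item_b[i], rc$item_a[i]] <- rc$cor[i]
  }
  R * cfg$resid_sd^2
}

# per-item latent cutpoints: quantiles of the marginal 3-month latent
# distribution at the cumulative severity probabilities
item_cutpoints <- function(cfg, defs = pro_items()) {
  lapply(stats::setNames(cfg$items, cfg$items), function(k) {
    p <- cfg$m3_probs[[k]]
    d <- item_def(k, defs)
    nlev <- d$max_score - d$min_score + 1
    if (is.null(p)) pt_stop(paste("no 3-month level probabilities for item", k))
    if (length(p) != nlev)
      pt_stop(sprintf("m3_probs for %s has %d levels, item has %d", k, length(p), nlev))
    marg_sd <- sqrt(cfg$loadings[[k]]^2 * cfg$tau^2 + cfg$resid_sd^2)
    marg_sd * stats::qnorm(cumsum(p)[-nlev])
  })
}

# severity level required for a criterion's threshold to be crossed, and
# the latent cutpoint above which that happens
criterion_latent_cut <- function(rule, cuts, defs = pro_items()) {
  vapply(seq_len(nrow(rule$criteria)), function(i) {
    k <- rule$criteria$key[i]
    d <- item_def(k, defs)
    sev_req <- if (d$direction == "HIGHER_WORSE") rule$criteria$cutoff[i] - d$min_score
               else d$max_score - rule$criteria$cutoff[i]
    if (sev_req < 1) pt_stop(paste("criterion on", k, "is always crossed"))
    cuts[[k]][sev_req]
  }, numeric(1))
}

#' Generate a synthetic cohort
#'
#' Draws a full [pro_cohort()] (demographics, return flags, long-format
#' responses) from a [generator_config()]. Deterministic given the config's
#' seed.
#'
#' @param cfg a [generator_config()].
#' @return a validated [pro_cohort()].
#' @export
#' @examples
#' coh <- generate_cohort(generator_config(n_patients = 50, seed = 7))
#' coh
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  defs <- pro_items()
  set.seed(cfg$seed)
  n <- cfg$n_patients
  pid <- sprintf("%s%04d", substr(cfg$label, 1, 2), seq_len(n))
  patients <- data.frame(
    patient_id = pid,
    surgery_year = sample(rep(cfg$surgery_years, length.out = max(n, length(cfg$surgery_years)))[seq_len(n)]),
    cohort = cfg$label,
    age = round(pmin(pmax(stats::rnorm(n, 66.3, 8), 40), 92), 1),
    gender = ifelse(stats::runif(n) < 0.40, "M", "F"),
    bmi = round(pmin(pmax(stats::rnorm(n, 26.3, 3.0), 17), 35), 1),
    asa = ifelse(stats::runif(n) < 0.55, "I", "II"),
    charnley = sample(c("ONE_HIP", "BOTH_HIPS", "CONTRALATERAL_THA", "MULTI_JOINT"),
                      n, replace = TRUE, prob = c(.22, .41, .20, .17)),
    deceased = stats::runif(n) < cfg$deceased_rate,
    returned_pre = TRUE, returned_m3 = TRUE, returned_m12 = TRUE)
  for (tp in c("PRE", "M3", "M12")) {
    cn <- c(PRE = "returned_pre", M3 = "returned_m3", M12 = "returned_m12")[[tp]]
    ret <- stats::runif(n) >= cfg$nonresponse[[tp]]
    if (tp != "PRE") ret <- ret & !patients$deceased
    patients[[cn]] <- ret & (tp %in% cfg$timepoints)
  }
  cuts <- item_cutpoints(cfg, defs)
  sigma <- resid_matrix(cfg)
  u <- stats::rnorm(n, 0, cfg$tau)
  d <- item_def(cfg$items, defs)
  resp <- list()
  for (tp in cfg$timepoints) {
    shift <- if (tp == "M3") cfg$m3_shift else 0
    z <- outer(cfg$mu[[tp]] + u, cfg$loadings) + rmvn(n, sigma)
    for (j in seq_along(cfg$items)) {
      sev <- findInterval(z[, j], cuts[[cfg$items[j]]] + shift)
      score <- if (d$direction[j] == "HIGHER_WORSE") d$min_score[j] + sev
               else d$max_score[j] - sev
      cn <- c(PRE = "returned_pre", M3 = "returned_m3", M12 = "returned_m12")[[tp]]
      keep <- patients[[cn]] & stats::runif(n) >= cfg$item_skip
      if (!any(keep)) next
      resp[[length(resp) + 1]] <- data.frame(
        patient_id = pid[keep], timepoint = tp,
        instrument = d$instrument[j], item = d$item[j], score = score[keep])
    }
  }
  responses <- if (length(resp)) do.call(rbind, resp) else
    data.frame(patient_id = character(), timepoint = character(),
               instrument = character(), item = integer(), score = integer())
  pro_cohort(patients, responses, label = cfg$label, n_thas = n, defs = defs,
             strict = TRUE)
}

#' Calibrate the 3-month threshold-crossing rate
#'
#' Finds, by bisection, the scalar shift of the 3-month cutpoints under
#' which the probability of crossing at least one of the rule's thresholds
#' at 3 months matches `target`. The Monte-Carlo sample of latent scores is
#' drawn once and reused across bisection steps (common random numbers),
#' making the empirical rate a monotone step function of the shift, so
#' bisection converges to within the sample's granularity.
#'
#' @param cfg a [generator_config()] (its `target_crossing_rate` is the
#'   default target).
#' @param rule triage rule whose thresholds define "crossing"
#'   (default [final_rule()]).
#' @param target desired crossing probability, in (0, 1).
#' @param mc_reps Monte-Carlo sample size (default 5000).
#' @param tol convergence tolerance on the achieved rate (default 0.005).
#' @param max_iter bisection iteration cap.
#' @return list: `shift`, `achieved` (Monte-Carlo estimate under the
#'   shift), `se` (binomial standard error), `mc_reps`, `iterations`, and
#'   `config` (the input config with `m3_shift` set).
#' @export
calibrate_crossing_rate <- function(cfg, rule = final_rule(),
                                    target = cfg$target_crossing_rate,
                                    mc_reps = 5000, tol = 0.005, max_iter = 60) {
  stopifnot(inherits(cfg, "generator_config"), target > 0, target < 1)
  defs <- pro_items()
  keys <- rule$criteria$key
  miss <- setdiff(keys, cfg$items)
  if (length(miss)) pt_stop(paste("rule items not generated by config:",
                                  paste(miss, collapse = ", ")))
  cuts <- item_cutpoints(cfg, defs)
  ccut <- criterion_latent_cut(rule, cuts, defs)
  sigma <- resid_matrix(cfg)[keys, keys]
  set.seed(cfg$seed + 1L)
  u <- stats::rnorm(mc_reps, 0, cfg$tau)
  z <- outer(cfg$mu[["M3"]] + u, cfg$loadings[keys]) + rmvn(mc_reps, sigma)
  # patient crosses iff any z exceeds its criterion cutpoint + shift
  margin <- apply(sweep(z, 2, ccut), 1, max)
  rate <- function(s) mean(margin > s)
  lo <- min(margin) - 1; hi <- max(margin) + 1
  if (target > rate(lo) || target < rate(hi))
    pt_stop(sprintf("target %.3f outside attainable range [%.4f, %.4f]",
                    target, rate(hi), rate(lo)))
  it <- 0L
  repeat {
    mid <- (lo + hi) / 2
    r <- rate(mid)
    it <- it + 1L
    if (abs(r - target) <= tol || it >= max_iter) break
    if (r > target) lo <- mid else hi <- mid
  }
  cfg$m3_shift <- mid
  list(shift = mid, achieved = r, se = sqrt(r * (1 - r) / mc_reps),
       mc_reps = mc_reps, iterations = it, config = cfg)
}

#' Paper-like two-cohort fixture
#'
#' Generates a training-like (n=746, surgery 2016-2017) and a test-like
#' (n=482, 2018) cohort engineered so that every stage of the selection
#' procedure has a known outcome: OHS question 10's 3-month distribution is
#' degenerate; NRS rest and OHS question 1 are residually correlated with
#' NRS activity strongly enough to be pruned at a 0.6 correlation cutoff;
#' all items are responsive; no floor effects; the worse-at-3-months groups
#' remain worse at 12 months. The 3-month final-tool crossing rate is
#' calibrated to `target` before generation; the same shift is applied to
#' both cohorts.
#'
#' @param seed master seed (sub-seeds are derived for each cohort).
#' @param target 3-month crossing-rate target (default 0.29).
#' @return list with elements `training` and `test` ([pro_cohort()]s),
#'   `shift`, and `calibration`.
#' @export
make_paperlike_fixture <- function(seed = 1L, target = 0.29) {
  seeds <- derive_seeds(seed, 3)
  cfg_tr <- generator_config(n_patients = 746, label = "TRAINING",
                             surgery_years = 2016:2017,
                             target_crossing_rate = target, seed = seeds[1])
  cal <- calibrate_crossing_rate(cfg_tr)
  cfg_tr <- cal$config
  cfg_te <- generator_config(n_patients = 482, label = "TEST",
                             surgery_years = 2018,
                             target_crossing_rate = target,
                             m3_shift = cal$shift, seed = seeds[2])
  list(training = generate_cohort(cfg_tr),
       test = generate_cohort(cfg_te),
       shift = cal$shift, calibration = cal[c("achieved", "se", "mc_reps")])
}
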