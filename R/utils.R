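# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for all reported percentages (base `round()` rounds
#' half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 1).
#' @return numeric vector rounded half-away-from-zero.
#' @export
#' @examples
#' round_half_up(94.25, 1)  # 94.3, not 94.2
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# percentage string with exact fraction alongside, e.g. "28.6% (201/703)"
fmt_pct <- function(num, den, digits = 1) {
  sprintf("%s%% (%d/%d)", format(round_half_up(100 * num / den, digits)), num, den)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with a promtriage condition class so callers can distinguish
# validation failures from runtime errors
pt_stop <- function(msg, class = "promtriage_error", ...) {
  stop(structure(
    class = c(class, "promtriage_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

# draws n rows from N(0, Sigma) given a correlation/covariance matrix;
# uses the upper-triangular chol factor, errors if Sigma is not PSD
rmvn <- function(n, sigma) {
  k <- ncol(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) {
    pt_stop("residual correlation matrix is not positive definite",
            class = "promtriage_config_error")
  })
  matrix(stats::rnorm(n * k), n, k) %*% ch
}

# derive reproducible sub-seeds (< 2^31) from a master seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
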