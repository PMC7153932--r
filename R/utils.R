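#' Population (divisor-n) variance
#'
#' Variance with divisor `n` rather than `n - 1`. The decomposition identities
#' used throughout the package (variance additivity of the adjustment step and
#' the law of total variance in the carrier grouping) hold exactly under this
#' convention; [stats::var()]'s `n - 1` divisor is used only for descriptive
#' SD reporting.
#'
#' @param x numeric vector, no NAs.
#' @return scalar variance, divisor `n`.
#' @export
var_n <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("var_n: input contains NA", call. = FALSE)
  mean((x - mean(x))^2)
}

#' Derive a stage-specific RNG seed from a master seed
#'
#' Deterministic hash of (seed, label) into [1, 2^31 - 2]. Each simulation
#' stage (and each variant's genotype stream) seeds its own draws from the
#' master seed through this function, so e.g. adding a variant to the config
#' never perturbs the covariate or residual draws.
#'
#' @param seed master integer seed.
#' @param label character stage label (may encode a variant id).
#' @return integer seed suitable for [set.seed()].
#' @export
stage_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed), length(label) == 1L)
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double-integer range
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h %% (m - 1)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' Sample from a normal distribution truncated below at zero
#'
#' Inverse-CDF sampler: one uniform draw per value, so the number of RNG draws
#' is deterministic (reproducibility does not depend on rejection counts).
#' Used for oocyte uptake measurements, which are nonnegative.
#'
#' @param n number of draws.
#' @param mean,sd normal parameters before truncation.
#' @return numeric vector of nonnegative draws.
#' @keywords internal
rnorm_nonneg <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean = mean, sd = sd)
  u <- stats::runif(n, min = lo, max = 1)
  stats::qnorm(u, mean = mean, sd = sd)
}
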