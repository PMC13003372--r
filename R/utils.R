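# Shared numeric helpers.

# Physiologic domains used for band coverage validation and generator clamps.
# Resolution is the grid step at which band tables must be gap-free.
.ews_domains <- list(
  age  = list(lower = 0,  upper = 120, resolution = 1),
  hr   = list(lower = 0,  upper = 300, resolution = 1),
  rr   = list(lower = 0,  upper = 120, resolution = 1),
  sbp  = list(lower = 30, upper = 310, resolution = 1),
  dbp  = list(lower = 10, upper = 200, resolution = 1),
  map  = list(lower = 20, upper = 310, resolution = 1),
  temp = list(lower = 25, upper = 45,  resolution = 0.1),
  spo2 = list(lower = 0,  upper = 100, resolution = 1),
  gcs  = list(lower = 3,  upper = 15,  resolution = 1)
)

.ews_numeric_vitals <- c("hr", "rr", "sbp", "dbp", "temp", "spo2")

# Parameters that count toward the ">2 missing" exclusion rule: everything a
# score fixture can consume except derived MAP.
.ews_score_params <- c("hr", "rr", "sbp", "dbp", "temp", "spo2", "gcs", "avpu")

.ews_cohort_columns <- c(
  "age", "sex", "hr", "rr", "sbp", "dbp", "map", "temp", "spo2", "gcs",
  "avpu", "on_oxygen", "t2rf_risk", "outcome24h"
)

#' Wilson score confidence interval for a binomial proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

# Split-normal (two-piece normal) family parameterised by median and quartiles.
# Matches a stated median/IQR exactly; used by the cohort generator.
split_normal_q <- function(p, med, q1, q3) {
  s_lo <- (med - q1) / qnorm(0.75)
  s_hi <- (q3 - med) / qnorm(0.75)
  z <- qnorm(p)
  med + ifelse(p < 0.5, z * s_lo, z * s_hi)
}

split_normal_p <- function(x, med, q1, q3) {
  s_lo <- (med - q1) / qnorm(0.75)
  s_hi <- (q3 - med) / qnorm(0.75)
  ifelse(x < med, pnorm((x - med) / s_lo), pnorm((x - med) / s_hi))
}

split_normal_d <- function(x, med, q1, q3) {
  # Density of the median/quartile-matched two-piece normal (each half is a
  # rescaled normal half; halves carry probability 1/2 each).
  s_lo <- (med - q1) / qnorm(0.75)
  s_hi <- (q3 - med) / qnorm(0.75)
  ifelse(x < med,
         dnorm((x - med) / s_lo) / s_lo,
         dnorm((x - med) / s_hi) / s_hi)
}

round_to <- function(x, resolution) round(x / resolution) * resolution

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

logit_clamped <- function(p, eps = 1e-12) qlogis(clamp(p, eps, 1 - eps))

`%||%` <- function(a, b) if (is.null(a)) b else a
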