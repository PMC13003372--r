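test_that("auroc matches trivial cases and the pair-counting oracle", {
  expect_equal(auroc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auroc, 1.0)
  expect_equal(auroc(rep(2, 10), rep(c(0, 1), 5))$auroc, 0.5)
  expect_equal(auroc(c(3, 1, 2, 4, 2), c(1, 0, 0, 1, 1))$auroc,
               oracle_auroc(c(3, 1, 2, 4, 2), c(1, 0, 0, 1, 1)))
  set.seed(14)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    s <- sample(0:8, n, replace = TRUE)       # heavy ties, like real scores
    y <- runif(n) < 0.4
    if (all(y) || !any(y)) next
    expect_equal(auroc(s, y)$auroc, oracle_auroc(s, y))
  }
  expect_error(auroc(1:5, rep(1, 5)), "both outcome classes")
})

test_that("auroc is antisymmetric and invariant to monotone transforms", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    s <- rnorm(n) + sample(0:3, n, replace = TRUE)
    y <- runif(n) < 0.3
    if (all(y) || !any(y)) next
    a <- auroc(s, y)$auroc
    expect_equal(a + auroc(-s, y)$auroc, 1)
    expect_equal(auroc(exp(s / 2), y)$auroc, a)
    expect_equal(auroc(rank(s, ties.method = "average"), y)$auroc, a)
  }
})

test_that("ROC curve is monotone in the standard sense", {
  set.seed(4)
  s <- sample(0:10, 300, TRUE)
  y <- runif(300) < plogis(s - 5)
  r <- auroc(s, y)
  expect_true(all(diff(r$sensitivity) >= 0))   # thresholds descend
  expect_true(all(diff(r$specificity) <= 0))
})

test_that("delong_compare: self-comparison, power, and bootstrap-SE agreement", {
  set.seed(31)
  s <- rnorm(200); y <- runif(200) < plogis(2 * s)
  d <- delong_compare(s, s, y)
  expect_equal(d$delta_auroc, 0)
  expect_equal(d$p, 1)
  expect_error(delong_compare(s, s[-1], y), "pairing")

  # perfectly separating score vs pure noise: decisive at moderate n
  y2 <- rep(c(FALSE, TRUE), each = 250)
  a <- as.numeric(y2) + seq(0, 0.001, length.out = 500)
  b <- rnorm(500)
  expect_lt(delong_compare(a, b, y2)$p, 0.001)

  # DeLong SE close to a paired-bootstrap SE on small fixed vectors
  set.seed(99)
  n <- 150
  sa <- rnorm(n); y3 <- runif(n) < plogis(sa)
  sb <- sa + rnorm(n)
  if (any(y3) && !all(y3)) {
    dd <- delong_compare(sa, sb, y3)
    B <- 4000
    boot <- numeric(B)
    for (i in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (all(y3[idx]) || !any(y3[idx])) { boot[i] <- NA; next }
      boot[i] <- auroc(sa[idx], y3[idx])$auroc - auroc(sb[idx], y3[idx])$auroc
    }
    expect_lt(abs(dd$se - sd(boot, na.rm = TRUE)) / dd$se, 0.15)
  }
})

test_that("sliding windows have the right centers and flag sparse windows", {
  set.seed(5)
  n <- 20000
  ages <- sample(80:99, n, TRUE)
  y <- runif(n) < 0.05
  s <- rnorm(n) + 2 * y
  ser <- sliding_window_auroc(ages, s, y, width = 5, step = 1)
  expect_equal(ser$center, seq(82, 97))
  expect_equal(ser$age_lo, 80:95)
  expect_true(all(!is.na(ser$auroc)))

  # a null score keeps every window near 0.5
  ser0 <- sliding_window_auroc(ages, rnorm(n), y)
  expect_true(all(abs(ser0$auroc - 0.5) < 0.08))

  # windows with < min_events are absent (NA), not zero
  few <- sliding_window_auroc(ages, s, y & ages < 83, min_events = 10)
  expect_true(anyNA(few$auroc))
  expect_true(all(few$auroc[!is.na(few$auroc)] > 0))
})

test_that("window AUROC declines when the signal fades with age", {
  set.seed(6)
  n <- 30000
  ages <- sample(80:99, n, TRUE)
  strength <- pmax(0, 1.5 - 0.07 * (ages - 80))
  risk <- rnorm(n)
  y <- runif(n) < plogis(-3 + strength * risk)
  ser <- sliding_window_auroc(ages, risk, y)
  ok <- !is.na(ser$auroc)
  expect_lt(cor(ser$center[ok], ser$auroc[ok], method = "spearman"), 0)
})

test_that("fit_age_spline: degenerate, trending and oracle-checked fits", {
  centers <- 82:97
  flat <- data.frame(center = centers, auroc = rep(0.75, 16))
  sp <- fit_age_spline(flat)
  expect_equal(sp$f_stat, 0)
  expect_equal(sp$p_value, 1)

  set.seed(10)
  trend <- data.frame(center = centers,
                      auroc = 0.8 - 0.01 * (centers - 80) +
                        rnorm(16, sd = 0.004))
  sp2 <- fit_age_spline(trend)
  expect_lt(sp2$p_value, 0.01)
  expect_true(all(diff(sp2$pred$fit) < 0.005))  # essentially decreasing

  expect_error(fit_age_spline(flat[1:4, ]), "too few windows")

  # OLS predictions reproduce an independent basis-expansion +
  # normal-equations oracle (restricted cubic basis re-derived inline)
  y <- trend$auroc
  kn <- unname(quantile(centers, c(0.05, 0.35, 0.65, 0.95), type = 7))
  pp <- function(u) ifelse(u > 0, u^3, 0)
  k <- length(kn)
  rcs_col <- function(x, j) {
    (pp(x - kn[j]) -
       pp(x - kn[k - 1]) * (kn[k] - kn[j]) / (kn[k] - kn[k - 1]) +
       pp(x - kn[k]) * (kn[k - 1] - kn[j]) / (kn[k] - kn[k - 1])) /
      (kn[k] - kn[1])^2
  }
  B <- cbind(1, centers, rcs_col(centers, 1), rcs_col(centers, 2))
  beta <- solve(t(B) %*% B, t(B) %*% y)
  expect_equal(unname(sp2$fitted$fit), drop(B %*% beta), tolerance = 1e-8)
})
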