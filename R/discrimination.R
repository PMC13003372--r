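# Discrimination: ROC/AUROC with DeLong variance, paired DeLong
# comparisons, sliding age-window AUROC and restricted-cubic-spline trends.

# midrank placements of case scores among controls and vice versa
.placements <- function(scores, outcomes) {
  pos <- scores[outcomes]
  neg <- scores[!outcomes]
  sneg <- sort(neg)
  spos <- sort(pos)
  # V10_i: fraction of controls below case i (ties half-credit)
  lt <- findInterval(pos, sneg, left.open = TRUE)
  le <- findInterval(pos, sneg)
  v10 <- (lt + 0.5 * (le - lt)) / length(neg)
  # V01_j: fraction of cases above control j (ties half-credit)
  lt2 <- findInterval(neg, spos, left.open = TRUE)
  le2 <- findInterval(neg, spos)
  v01 <- 1 - (lt2 + 0.5 * (le2 - lt2)) / length(pos)
  list(v10 = v10, v01 = v01)
}

.check_two_class <- function(outcomes) {
  outcomes <- as.logical(outcomes)
  if (anyNA(outcomes)) stop("outcomes contain missing values")
  if (all(outcomes) || !any(outcomes)) {
    stop("AUROC undefined: both outcome classes must be present")
  }
  outcomes
}

#' ROC curve and AUROC with DeLong confidence interval
#'
#' The AUROC is the Mann-Whitney tie-corrected concordance probability; its
#' standard error uses the DeLong placement-value variance.
#'
#' @param scores numeric risk scores (higher = more at risk).
#' @param outcomes logical/0-1 outcome vector.
#' @param conf confidence level.
#' @return object of class `ews_roc`: thresholds, sensitivity, specificity,
#'   `auroc`, `se`, `ci95`, `n_pos`, `n_neg`.
#' @export
auroc <- function(scores, outcomes, conf = 0.95) {
  outcomes <- .check_two_class(outcomes)
  stopifnot(length(scores) == length(outcomes), !anyNA(scores))
  pl <- .placements(scores, outcomes)
  auc <- mean(pl$v10)
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  v <- if (n_pos > 1) var(pl$v10) / n_pos else 0
  v <- v + if (n_neg > 1) var(pl$v01) / n_neg else 0
  se <- sqrt(v)
  z <- qnorm(1 - (1 - conf) / 2)
  # ROC curve: classify positive iff score >= threshold
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores >= t & outcomes), 0)
  fp <- vapply(thr, function(t) sum(scores >= t & !outcomes), 0)
  structure(
    list(thresholds = thr, sensitivity = tp / n_pos,
         specificity = 1 - fp / n_neg, auroc = auc, se = se,
         ci95 = c(max(0, auc - z * se), min(1, auc + z * se)),
         n_pos = n_pos, n_neg = n_neg),
    class = "ews_roc"
  )
}

#' @export
print.ews_roc <- function(x, ...) {
  cat(sprintf("<ews_roc> AUROC %.4f (95%% CI %.4f-%.4f), %d cases / %d controls\n",
              x$auroc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong comparison of two correlated AUROCs
#'
#' Both score vectors must refer to the same patients (paired design).
#'
#' @param scores_a,scores_b paired score vectors.
#' @param outcomes logical/0-1 outcomes.
#' @return list: `auroc_a`, `auroc_b`, `delta_auroc`, `se`, `z`, `p`
#'   (two-sided).
#' @export
delong_compare <- function(scores_a, scores_b, outcomes) {
  if (length(scores_a) != length(scores_b)) {
    stop("pairing error: score vectors differ in length")
  }
  outcomes <- .check_two_class(outcomes)
  stopifnot(length(scores_a) == length(outcomes))
  pa <- .placements(scores_a, outcomes)
  pb <- .placements(scores_b, outcomes)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  n_pos <- sum(outcomes); n_neg <- sum(!outcomes)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n_pos +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n_neg
  delta <- auc_a - auc_b
  if (var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  list(auroc_a = auc_a, auroc_b = auc_b, delta_auroc = delta,
       se = sqrt(max(var_diff, 0)), z = z, p = p)
}

#' Sliding-window AUROC across patient age
#'
#' Computes the AUROC within closed `width`-year windows `[a, a + width - 1]`
#' advancing in `step`-year increments, reported at the window midpoint.
#' Windows with fewer than `min_events` events (or a single class) are
#' reported with `NA` AUROC, not zero.
#'
#' @param ages integer ages.
#' @param scores score vector.
#' @param outcomes logical/0-1 outcomes.
#' @param width window width in years.
#' @param step window advance in years.
#' @param min_events minimum events for a window AUROC to be reported.
#' @return data.frame of class `ews_agewindows`: `age_lo`, `age_hi`,
#'   `center`, `n`, `events`, `auroc`, `se`.
#' @export
sliding_window_auroc <- function(ages, scores, outcomes, width = 5,
                                 step = 1, min_events = 10) {
  stopifnot(length(ages) == length(scores),
            length(ages) == length(outcomes))
  outcomes <- as.logical(outcomes)
  starts <- seq(min(ages), max(ages) - width + 1, by = step)
  rows <- lapply(starts, function(a) {
    inw <- ages >= a & ages <= a + width - 1
    ev <- sum(outcomes[inw])
    out <- data.frame(age_lo = a, age_hi = a + width - 1,
                      center = a + (width - 1) / 2, n = sum(inw),
                      events = ev, auroc = NA_real_, se = NA_real_)
    if (ev >= min_events && ev < sum(inw)) {
      r <- auroc(scores[inw], outcomes[inw])
      out$auroc <- r$auroc
      out$se <- r$se
    }
    out
  })
  out <- do.call(rbind, rows)
  class(out) <- c("ews_agewindows", "data.frame")
  out
}

#' Restricted cubic spline basis (Harrell parameterisation)
#'
#' Returns the linear term plus `length(knots) - 2` nonlinear terms; the
#' function is linear beyond the boundary knots.
#'
#' @param x numeric vector.
#' @param knots increasing knot locations (>= 3).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3, !is.unsorted(knots))
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  norm2 <- (tk - t1)^2
  cub <- function(u) pmax(u, 0)^3
  out <- matrix(0, nrow = length(x), ncol = k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cub(x - tj) -
                       cub(x - tk1) * (tk - tj) / (tk - tk1) +
                       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm2
  }
  colnames(out) <- c("x", paste0("x'", seq_len(k - 2)))
  out
}

#' Fit a restricted-cubic-spline trend to a window-AUROC series
#'
#' Unweighted OLS of window AUROC on a restricted cubic spline of window
#' center age (`df` degrees of freedom, knots at the 5/35/65/95th percentiles
#' of the window centers for df = 3), with an F test against the
#' intercept-only (age-constant) model.
#'
#' @param series an `ews_agewindows` data.frame (NA windows are dropped).
#' @param df spline degrees of freedom (`df + 1` knots).
#' @param conf confidence level of the prediction band.
#' @return list of class `ews_agespline`: `knots`, `coefficients`, `f_stat`,
#'   `df1`, `df2`, `p_value`, `fitted` (per retained window) and `pred`
#'   (grid with `fit`, `lwr`, `upr` inside the observed center range).
#' @export
fit_age_spline <- function(series, df = 3, conf = 0.95) {
  keep <- !is.na(series$auroc)
  x <- series$center[keep]
  y <- series$auroc[keep]
  nw <- length(x)
  if (nw < df + 2) {
    stop("too few windows (", nw, ") to fit a ", df, "-df spline")
  }
  probs <- if (df == 3) c(0.05, 0.35, 0.65, 0.95) else
    seq(0.05, 0.95, length.out = df + 1)
  knots <- unname(quantile(x, probs, type = 7))
  if (anyDuplicated(knots)) stop("degenerate knots: window centers too few")
  B <- rcs_basis(x, knots)
  dat <- data.frame(y = y, B)
  fit <- lm(y ~ ., data = dat)
  ss1 <- sum(residuals(fit)^2)
  ss0 <- sum((y - mean(y))^2)
  df1 <- df
  df2 <- nw - df - 1
  if (ss0 - ss1 < 1e-12 * max(ss0, 1)) {
    f_stat <- 0; p <- 1
  } else {
    f_stat <- ((ss0 - ss1) / df1) / (ss1 / df2)
    p <- pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  grid <- seq(min(x), max(x), by = 0.25)
  Bg <- data.frame(rcs_basis(grid, knots))
  pr <- predict(fit, newdata = Bg, interval = "confidence", level = conf)
  structure(
    list(knots = knots, coefficients = coef(fit), f_stat = f_stat,
         df1 = df1, df2 = df2, p_value = p,
         fitted = data.frame(center = x, auroc = y,
                             fit = unname(fitted(fit))),
         pred = data.frame(center = grid, fit = pr[, "fit"],
                           lwr = pr[, "lwr"], upr = pr[, "upr"])),
    class = "ews_agespline"
  )
}

#' @export
print.ews_agespline <- function(x, ...) {
  cat(sprintf("<ews_agespline> F(%d, %d) = %.3f, p = %.4g\n",
              x$df1, x$df2, x$f_stat, x$p_value))
  invisible(x)
}
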