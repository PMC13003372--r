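# Calibration and classification: single-predictor logistic risk models,
# Brier scores with bootstrap inference, calibration slopes and bins,
# PPV-margin threshold metrics, precision-recall curves.

#' Fit a univariable logistic risk model for one score
#'
#' Logistic regression of the outcome on the score as the sole predictor.
#' Complete separation is detected and handled with a lightly ridge-penalised
#' refit (flagged, never silent).
#'
#' @param scores numeric score.
#' @param outcomes logical/0-1 outcomes.
#' @return list of class `ews_riskmodel`: `coefficients`, `pred` (fitted
#'   probabilities), `separation` flag.
#' @export
fit_risk_model <- function(scores, outcomes) {
  outcomes <- .check_two_class(outcomes)
  y <- as.numeric(outcomes)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ scores, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  if (any(abs(cf) > 15)) separated <- TRUE
  if (separated) {
    cf <- .ridge_logistic(cbind(1, scores), y, lambda = 1e-3)
  }
  eta <- cf[1] + cf[2] * scores
  structure(
    list(coefficients = setNames(as.numeric(cf), c("(Intercept)", "score")),
         pred = plogis(eta), separation = separated),
    class = "ews_riskmodel"
  )
}

# IRLS ridge-penalised logistic regression (intercept unpenalised)
.ridge_logistic <- function(X, y, lambda = 1e-3, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1)), ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(new - beta)) < tol) { beta <- new; break }
    beta <- drop(new)
  }
  drop(beta)
}

#' Brier score with bootstrap confidence interval and null-model comparison
#'
#' The Brier score is the mean squared error between predicted probabilities
#' and the binary outcome. The null model predicts the constant prevalence
#' (Brier `p * (1 - p)`). CI and p values come from seeded patient-level
#' bootstrap resampling.
#'
#' @param pred predicted probabilities in `[0, 1]`.
#' @param outcomes logical/0-1 outcomes.
#' @param B bootstrap resamples (0 skips resampling).
#' @param seed bootstrap seed.
#' @return list of class `ews_brier`: `brier`, `ci95`, `brier_null`,
#'   `p_vs_null`.
#' @export
brier_score <- function(pred, outcomes, B = 2000, seed = 1) {
  stopifnot(all(pred >= 0 & pred <= 1))
  y <- as.numeric(outcomes)
  stopifnot(length(pred) == length(y))
  bs <- mean((pred - y)^2)
  prev <- mean(y)
  out <- list(brier = bs, brier_null = prev * (1 - prev),
              ci95 = c(NA_real_, NA_real_), p_vs_null = NA_real_)
  if (B > 0) {
    set.seed(seed)
    n <- length(y)
    stat <- matrix(NA_real_, nrow = B, ncol = 2)
    for (b in seq_len(B)) {
      i <- sample.int(n, n, replace = TRUE)
      pb <- mean(y[i])
      stat[b, ] <- c(mean((pred[i] - y[i])^2), pb * (1 - pb))
    }
    out$ci95 <- unname(quantile(stat[, 1], c(0.025, 0.975)))
    d <- stat[, 1] - stat[, 2]
    out$p_vs_null <- .boot_two_sided_p(d)
  }
  class(out) <- "ews_brier"
  out
}

# CI-inversion two-sided bootstrap p for a difference distribution
.boot_two_sided_p <- function(d) {
  B <- length(d)
  min(1, 2 * min((sum(d >= 0) + 1) / (B + 1), (sum(d <= 0) + 1) / (B + 1)))
}

#' Paired bootstrap comparison of two Brier scores
#'
#' @param pred_a,pred_b predicted probabilities from two models on the same
#'   patients.
#' @param outcomes logical/0-1 outcomes.
#' @param B bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list: `brier_a`, `brier_b`, `delta`, `ci95_delta`, `p`.
#' @export
brier_compare <- function(pred_a, pred_b, outcomes, B = 2000, seed = 1) {
  y <- as.numeric(outcomes)
  stopifnot(length(pred_a) == length(y), length(pred_b) == length(y))
  set.seed(seed)
  n <- length(y)
  d <- numeric(B)
  for (b in seq_len(B)) {
    i <- sample.int(n, n, replace = TRUE)
    d[b] <- mean((pred_a[i] - y[i])^2) - mean((pred_b[i] - y[i])^2)
  }
  list(brier_a = mean((pred_a - y)^2), brier_b = mean((pred_b - y)^2),
       delta = mean((pred_a - y)^2) - mean((pred_b - y)^2),
       ci95_delta = unname(quantile(d, c(0.025, 0.975))),
       p = .boot_two_sided_p(d))
}

#' Logistic calibration slope and intercept
#'
#' Refits the outcome on the logit of the predicted probability; slope 1
#' indicates ideal calibration, below 1 predictions that are too extreme.
#'
#' @param pred predicted probabilities in `(0, 1)`.
#' @param outcomes logical/0-1 outcomes.
#' @return list: `slope`, `intercept`.
#' @export
calibration_slope <- function(pred, outcomes) {
  if (length(unique(pred)) < 2) {
    stop("calibration slope undefined: all predictions identical")
  }
  lp <- logit_clamped(pred)
  fit <- glm(as.numeric(outcomes) ~ lp, family = binomial())
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
}

#' Equal-count calibration bins
#'
#' @param pred predicted probabilities.
#' @param outcomes logical/0-1 outcomes.
#' @param n_bins target number of equal-count bins; collapses (with a
#'   warning) when distinct prediction quantiles are fewer.
#' @return data.frame: `bin`, `n`, `mean_pred`, `obs_rate`.
#' @export
calibration_bins <- function(pred, outcomes, n_bins = 10) {
  y <- as.numeric(outcomes)
  if (length(pred) < n_bins) {
    warning("fewer observations than bins; bins collapse")
  }
  br <- unique(quantile(pred, seq(0, 1, length.out = n_bins + 1), type = 7))
  if (length(br) < 3) br <- c(min(pred) - 1e-9, max(pred) + 1e-9)
  bin <- cut(pred, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin = sort(unique(bin)),
    n = as.vector(table(bin)),
    mean_pred = as.vector(tapply(pred, bin, mean)),
    obs_rate = as.vector(tapply(y, bin, mean))
  )
  rownames(out) <- NULL
  out
}

.threshold_metrics <- function(scores, outcomes, t) {
  pos <- scores >= t
  y <- as.logical(outcomes)
  tp <- sum(pos & y); fp <- sum(pos & !y)
  fn <- sum(!pos & y); tn <- sum(!pos & !y)
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       sens = tp / (tp + fn), spec = tn / (tn + fp),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Select the score threshold attaining a target positive predictive value
#'
#' Scans the integer score cut-offs (classify positive iff score >= t) from
#' the lowest upward and returns the smallest cut-off whose empirical PPV
#' meets the margin, with the full confusion-matrix metrics and Wilson 95\%
#' CIs. A margin no cut-off attains yields an explicit not-attainable
#' result, not an error.
#'
#' @param scores numeric (typically integer) scores.
#' @param outcomes logical/0-1 outcomes.
#' @param margin target PPV fraction.
#' @return list of class `ews_threshold`: `margin`, `attainable`,
#'   `threshold`, `sens`, `spec`, `ppv`, `npv` (each with `*_ci`), and the
#'   confusion counts.
#' @export
select_threshold_for_ppv <- function(scores, outcomes, margin) {
  stopifnot(margin > 0, margin < 1)
  cand <- sort(unique(scores))
  for (t in cand) {
    m <- .threshold_metrics(scores, outcomes, t)
    if (!is.na(m$ppv) && m$ppv >= margin) {
      return(structure(
        c(list(margin = margin, attainable = TRUE, threshold = t),
          m,
          list(sens_ci = wilson_ci(m$tp, m$tp + m$fn),
               spec_ci = wilson_ci(m$tn, m$tn + m$fp),
               ppv_ci = wilson_ci(m$tp, m$tp + m$fp),
               npv_ci = wilson_ci(m$tn, m$tn + m$fn))),
        class = "ews_threshold"))
    }
  }
  structure(list(margin = margin, attainable = FALSE, threshold = NA_real_),
            class = "ews_threshold")
}

#' Precision-recall curve and area under it
#'
#' Precision and recall at every distinct cut-off (positive iff score >=
#' cut-off), with the area computed by step-wise integration (average
#' precision). The baseline for an uninformative score is the outcome
#' prevalence.
#'
#' @param scores numeric scores.
#' @param outcomes logical/0-1 outcomes.
#' @return list of class `ews_pr`: `curve` (threshold, precision, recall)
#'   and `auprc`.
#' @export
precision_recall <- function(scores, outcomes) {
  outcomes <- .check_two_class(outcomes)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(outcomes)
  tp <- cumsum(vapply(thr, function(t) sum(outcomes[scores == t]), 0))
  npos_cls <- cumsum(vapply(thr, function(t) sum(scores == t), 0))
  precision <- tp / npos_cls
  recall <- tp / n_pos
  # average-precision step integration
  auprc <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = thr, precision = precision,
                          recall = recall),
       auprc = auprc) |> structure(class = "ews_pr")
}
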