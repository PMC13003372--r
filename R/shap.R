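# Shapley-value attribution for the boosted-tree outcome model and the
# age-stratum contribution contrast.

#' Per-patient SHAP values for a boosted-tree model
#'
#' Tree-path-dependent exact Shapley values on the margin (log-odds) scale.
#' Local accuracy holds: per patient, `sum(phi) + expected_value` equals the
#' model margin to numerical tolerance.
#'
#' @param model an `ews_gbm` model.
#' @param x numeric feature matrix with the model's feature columns.
#' @param check_additivity verify local accuracy (tolerance `1e-6`).
#' @return numeric matrix (n x features) with attribute `expected_value`
#'   (model base margin plus the trees' cover-weighted means).
#' @export
shap_values <- function(model, x, check_additivity = TRUE) {
  stopifnot(inherits(model, "ews_gbm"))
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature mismatch: model expects ", model$n_features,
         " features, got ", ncol(x))
  }
  if (!is.null(colnames(x)) &&
      !identical(colnames(x), model$feature_names)) {
    stop("feature mismatch: column names differ from the training features")
  }
  res <- .treeshap_cpp(x, model$trees)
  phi <- res$phi
  colnames(phi) <- model$feature_names
  expval <- model$base + res$expected_value
  if (check_additivity && nrow(x) > 0) {
    margin <- predict(model, x, type = "margin")
    err <- max(abs(rowSums(phi) + expval - margin))
    if (err > 1e-6) {
      stop("SHAP additivity violated (max error ", format(err), ")")
    }
  }
  attr(phi, "expected_value") <- expval
  phi
}

#' Mean absolute SHAP contributions, raw and normalized
#'
#' @param model an `ews_gbm` model.
#' @param data cohort data.frame (encoded with the model's feature map) or a
#'   ready feature matrix.
#' @return list of class `ews_shap_summary`: `mean_abs` (raw mean |SHAP| per
#'   feature), `normalized` (divided by the maximum, so exactly one feature
#'   equals 1), `shap` (the per-patient matrix), `expected_value`.
#' @export
shap_contributions <- function(model, data) {
  x <- if (is.matrix(data)) data else
    .ews_feature_matrix(data, model$feature_names)
  phi <- shap_values(model, x)
  mean_abs <- colMeans(abs(phi))
  normalized <- if (max(mean_abs) > 0) mean_abs / max(mean_abs) else mean_abs
  structure(
    list(mean_abs = mean_abs, normalized = normalized, shap = phi,
         expected_value = attr(phi, "expected_value")),
    class = "ews_shap_summary"
  )
}

#' Contrast feature contributions between age strata
#'
#' Fits the boosted-tree outcome model separately in the two age strata
#' (below the cut vs at/above it) with identical hyperparameters, computes
#' normalized mean absolute SHAP contributions per stratum, and tests the
#' per-feature difference (older minus younger stratum, normalized scale)
#' with a two-sided nonparametric bootstrap that resamples patients'
#' per-feature |SHAP| rows within stratum, renormalising in each resample.
#'
#' @param cohort completed cohort data.frame.
#' @param age_cut stratum boundary (default 87: 80-86 vs >= 87).
#' @param B bootstrap resamples.
#' @param seed RNG seed.
#' @param features model features.
#' @param params booster hyperparameters shared by both strata.
#' @return list of class `ews_contribution`: per-stratum summaries, the
#'   `difference` table (raw and normalized with bootstrap `p_boot`), sizes.
#' @export
stratum_contrast <- function(cohort, age_cut = 87, B = 1000, seed = 1,
                             features = .ews_model_features,
                             params = list()) {
  if (age_cut <= min(cohort$age) || age_cut > max(cohort$age)) {
    stop("age_cut ", age_cut, " outside the observed age range")
  }
  lo <- cohort[cohort$age < age_cut, , drop = FALSE]
  hi <- cohort[cohort$age >= age_cut, , drop = FALSE]
  for (s in list(lo, hi)) {
    if (!any(s$outcome24h) || all(s$outcome24h)) {
      stop("stratum without both outcome classes; cannot fit")
    }
  }
  fit_lo <- fit_outcome_model(lo, features, params, seed = seed)
  fit_hi <- fit_outcome_model(hi, features, params, seed = seed)
  sum_lo <- shap_contributions(fit_lo, lo)
  sum_hi <- shap_contributions(fit_hi, hi)

  abs_lo <- abs(sum_lo$shap)
  abs_hi <- abs(sum_hi$shap)
  norm_of <- function(mat, idx) {
    m <- colMeans(mat[idx, , drop = FALSE])
    if (max(m) > 0) m / max(m) else m
  }
  set.seed(seed)
  p <- length(features)
  diffs <- matrix(NA_real_, nrow = B, ncol = p,
                  dimnames = list(NULL, features))
  for (b in seq_len(B)) {
    i_lo <- sample.int(nrow(abs_lo), nrow(abs_lo), replace = TRUE)
    i_hi <- sample.int(nrow(abs_hi), nrow(abs_hi), replace = TRUE)
    diffs[b, ] <- norm_of(abs_hi, i_hi) - norm_of(abs_lo, i_lo)
  }
  delta <- sum_hi$normalized - sum_lo$normalized
  p_boot <- apply(diffs, 2, .boot_two_sided_p)
  difference <- data.frame(
    feature = features,
    norm_lo = unname(sum_lo$normalized),
    norm_hi = unname(sum_hi$normalized),
    shap_difference = unname(delta),
    p_boot = unname(p_boot),
    stringsAsFactors = FALSE
  )
  structure(
    list(age_cut = age_cut,
         n_lo = nrow(lo), n_hi = nrow(hi),
         stratum_lo = sum_lo[c("mean_abs", "normalized")],
         stratum_hi = sum_hi[c("mean_abs", "normalized")],
         difference = difference, B = B),
    class = "ews_contribution"
  )
}

#' @export
print.ews_contribution <- function(x, ...) {
  cat(sprintf(
    "<ews_contribution> strata at age %d: n=%d (younger) vs n=%d (older)\n",
    x$age_cut, x$n_lo, x$n_hi))
  print(x$difference[order(-abs(x$difference$shap_difference)), ],
        row.names = FALSE)
  invisible(x)
}
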