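# Missing-data handling: exclusion rule plus chained-equations multiple
# imputation reduced to a single completed dataset.

#' Apply the missing-parameter exclusion rule
#'
#' Records with more than `max_missing` missing score parameters (heart rate,
#' respiratory rate, pressures, temperature, SpO2, GCS, AVPU) are excluded,
#' mirroring the emulated study's inclusion process.
#'
#' @param cohort cohort data.frame with `NA` marking missing values.
#' @param max_missing inclusive upper bound on missing score parameters
#'   (fixed at 2 in the emulated design).
#' @return list with `cohort` (retained records) and `log` (counts per
#'   exclusion reason).
#' @export
apply_exclusions <- function(cohort, max_missing = 2L) {
  params <- intersect(.ews_score_params, names(cohort))
  n_missing <- rowSums(is.na(cohort[, params, drop = FALSE]))
  keep <- n_missing <= max_missing
  log <- list(
    n_input = nrow(cohort),
    n_retained = sum(keep),
    n_excluded = sum(!keep),
    reasons = list(`missing>2` = sum(!keep))
  )
  list(cohort = cohort[keep, , drop = FALSE], log = log)
}

#' Impute missing vitals by chained equations
#'
#' Chained-equations imputation with predictive-mean-matching draws: each
#' incomplete variable is regressed on age, sex and the other vitals, missing
#' entries receive the observed value of a donor whose prediction is among
#' the `k` nearest, and the procedure is cycled `maxit` times. The `m`
#' independent draws are then reduced to one completed dataset (mean for
#' continuous vitals, rounded to the variable's resolution; median for GCS),
#' because downstream scoring consumes a single completed cohort. The
#' outcome is never used as a predictor. Observed values are never altered.
#'
#' @param cohort cohort data.frame after [apply_exclusions()].
#' @param m number of imputation draws (>= 2).
#' @param maxit chained-equation cycles per draw.
#' @param k donors for predictive mean matching; the default scales with the
#'   observed sample (1\%, at least 10). A classical small donor pool (k = 5)
#'   is tuned for Rubin-pooled analyses; when the draws are instead averaged
#'   into one completed dataset, a small fixed pool leaves an irreducible
#'   donor-noise floor, so the pool grows with n.
#' @param seed RNG seed (fixed seed reproduces the completed data exactly).
#' @return the completed cohort (same rows, no missing score parameters).
#' @export
impute_cohort <- function(cohort, m = 20L, maxit = 5L, k = NULL, seed = 1) {
  stopifnot(m >= 2L)
  vars <- intersect(c(.ews_numeric_vitals, "gcs"), names(cohort))
  vars <- vars[vapply(vars, function(v) anyNA(cohort[[v]]), TRUE)]
  if (!length(vars)) return(cohort)
  for (v in vars) {
    frac <- mean(is.na(cohort[[v]]))
    if (frac >= 0.05) {
      warning("variable '", v, "' has ", round(100 * frac, 1),
              "% missing, outside the <5% regime the procedure assumes")
    }
  }
  predictors <- intersect(c("age", "sex", "avpu", "on_oxygen",
                            .ews_numeric_vitals, "gcs"), names(cohort))

  if (is.null(k)) k <- max(10L, as.integer(ceiling(0.01 * nrow(cohort))))
  set.seed(seed)
  draws <- lapply(seq_len(m), function(d) {
    .impute_once(cohort, vars, predictors, maxit, k)
  })
  out <- cohort
  for (v in vars) {
    miss <- is.na(cohort[[v]])
    vals <- vapply(draws, function(d) d[[v]][miss], numeric(sum(miss)))
    vals <- matrix(vals, nrow = sum(miss))
    combined <- if (v == "gcs") {
      as.integer(round(apply(vals, 1, median)))
    } else {
      res <- .ews_domains[[v]]$resolution
      round_to(rowMeans(vals), res)
    }
    dom <- .ews_domains[[v]]
    out[[v]][miss] <- clamp(combined, dom$lower, dom$upper)
  }
  # imputed pressures may invert the sbp >= dbp ordering; repair by moving
  # only imputed values (observed values are never altered)
  if (all(c("sbp", "dbp") %in% names(out))) {
    bad <- !is.na(out$sbp) & !is.na(out$dbp) & out$sbp < out$dbp + 5
    fix_sbp <- bad & is.na(cohort$sbp)
    out$sbp[fix_sbp] <- out$dbp[fix_sbp] + 5
    bad <- !is.na(out$sbp) & !is.na(out$dbp) & out$sbp < out$dbp + 5
    fix_dbp <- bad & is.na(cohort$dbp)
    out$dbp[fix_dbp] <- out$sbp[fix_dbp] - 5
  }
  if ("map" %in% names(out)) {
    redo <- is.na(out$map) & !is.na(out$sbp) & !is.na(out$dbp)
    out$map[redo] <- round(derive_map(out$sbp[redo], out$dbp[redo]))
  }
  out
}

# One chained-equations pass producing a single completed draw. Intermediate
# cycles impute with random PMM donor draws (Monte Carlo propagation across
# variables); the final cycle settles each gap at its donor-window mean,
# because the chains are averaged into one completed dataset and a random
# final draw would leave an irreducible donor-noise floor in that average.
.impute_once <- function(cohort, vars, predictors, maxit, k) {
  work <- cohort
  # initialise gaps at the observed median
  for (v in vars) {
    miss <- is.na(work[[v]])
    work[[v]][miss] <- median(cohort[[v]], na.rm = TRUE)
  }
  xcols <- function(exclude) {
    preds <- setdiff(predictors, exclude)
    mm <- matrix(1, nrow = nrow(work), ncol = 1,
                 dimnames = list(NULL, "(Intercept)"))
    for (p in preds) {
      mm <- cbind(mm, switch(
        p,
        sex = as.numeric(work$sex == "male"),
        avpu = as.numeric(factor(work$avpu, levels = c("A", "V", "P", "U"))),
        on_oxygen = as.numeric(work$on_oxygen),
        work[[p]]))
    }
    mm
  }
  for (it in seq_len(maxit)) {
    for (v in vars) {
      miss <- is.na(cohort[[v]])
      if (!any(miss)) next
      X <- xcols(v)
      fit <- stats::lm.fit(X[!miss, , drop = FALSE], cohort[[v]][!miss])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(X %*% beta)
      # predictive mean matching window: the k nearest observed predictions
      obs_sorted <- which(!miss)[order(pred[!miss])]
      pos <- findInterval(pred[miss], pred[obs_sorted])
      lo <- pmax(1L, pos - (k %/% 2L))
      hi <- pmin(length(obs_sorted), lo + k - 1L)
      lo <- pmax(1L, hi - k + 1L)
      if (it < maxit) {
        pick <- lo + floor(runif(sum(miss)) * (hi - lo + 1L))
        work[[v]][miss] <- cohort[[v]][obs_sorted[pick]]
      } else {
        cs <- cumsum(c(0, cohort[[v]][obs_sorted]))
        work[[v]][miss] <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
      }
    }
  }
  work
}
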