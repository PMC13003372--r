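# End-to-end pipeline: simulate -> impute -> score -> evaluate ->
# age-spline -> contribution, with a reproducible manifest.

#' Read a patient cohort CSV
#'
#' One row per encounter; empty cells mark missing values. The header must
#' contain the documented cohort columns; unknown columns are kept with a
#' warning. Out-of-domain vitals raise validation errors.
#'
#' @param path CSV path.
#' @return cohort data.frame.
#' @export
read_cohort_csv <- function(path) {
  if (!file.size(path) > 0) stop("empty cohort file: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (nrow(df) == 0) stop("empty cohort: no records in ", path)
  required <- .ews_cohort_columns
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), c(required, "truth", "patient_id"))
  if (length(extra)) {
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (col in c("on_oxygen", "t2rf_risk", "outcome24h")) {
    df[[col]] <- as.logical(df[[col]])
  }
  .validate_cohort(df)
  df
}

.validate_cohort <- function(df) {
  checks <- list(
    spo2 = function(x) x >= 0 & x <= 100,
    gcs = function(x) x >= 3 & x <= 15,
    age = function(x) x >= 80,
    hr = function(x) x > 0 & x < 300,
    rr = function(x) x > 0 & x < 120,
    sbp = function(x) x > 0 & x < 310,
    dbp = function(x) x > 0 & x < 250,
    temp = function(x) x > 25 & x < 45
  )
  for (f in names(checks)) {
    v <- df[[f]]
    bad <- !is.na(v) & !checks[[f]](v)
    if (any(bad)) {
      stop("domain validation error: field '", f, "' out of range at row ",
           which(bad)[1], " (value ", v[which(bad)[1]], ")")
    }
  }
  if (!all(df$avpu %in% c("A", "V", "P", "U") | is.na(df$avpu))) {
    stop("domain validation error: field 'avpu' must be A/V/P/U")
  }
  pbad <- !is.na(df$sbp) & !is.na(df$dbp) & df$sbp < df$dbp
  if (any(pbad)) {
    stop("domain validation error: sbp < dbp at row ", which(pbad)[1])
  }
  mapbad <- !is.na(df$map) & !is.na(df$sbp) & !is.na(df$dbp) &
    (df$map > df$sbp + 1e-6 | df$map < pmin(df$sbp, df$dbp) - 1e-6)
  if (any(mapbad)) {
    stop("domain validation error: map outside [min(sbp,dbp), sbp] at row ",
         which(mapbad)[1])
  }
  invisible(df)
}

#' Write a cohort CSV (empty cell = missing)
#'
#' @param cohort cohort data.frame.
#' @param path output path.
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' A single global seed fans out deterministically to per-stage seeds
#' (`stage_seed = (seed * 7 + stage_index * 1001) mod (2^31 - 1)`), so every
#' stage is independently reproducible.
#'
#' @param n simulated cohort size (ignored when `input_csv` given).
#' @param input_csv optional path to a real cohort CSV.
#' @param seed global seed.
#' @param missing_rate MCAR missingness injected in simulation.
#' @param prevalence simulated event prevalence.
#' @param severity_shift generator class-separation knob.
#' @param bootstrap_B bootstrap resamples for calibration/contribution.
#' @param margins PPV margins (ascending).
#' @param window_width,window_step,min_events sliding-window settings.
#' @param spline_df spline degrees of freedom.
#' @param age_cut contribution stratum boundary.
#' @param m_imputations imputation draws.
#' @param do_contribution run the (slower) boosted-tree contribution stage.
#' @param gbm_params booster hyperparameters.
#' @return list of class `ews_run_config`.
#' @export
pipeline_config <- function(n = 20000, input_csv = NULL, seed = 1,
                            missing_rate = 0.02, prevalence = 0.024,
                            severity_shift = 1, bootstrap_B = 2000,
                            margins = c(0.05, 0.10), window_width = 5,
                            window_step = 1, min_events = 10, spline_df = 3,
                            age_cut = 87, m_imputations = 20,
                            do_contribution = TRUE, gbm_params = list()) {
  if (is.unsorted(margins)) stop("margins must be sorted ascending")
  stage_seeds <- (seed * 7 + seq_len(6) * 1001) %% 2147483647
  names(stage_seeds) <- c("simulate", "impute", "score", "evaluate",
                          "agespline", "contribution")
  structure(
    list(n = n, input_csv = input_csv, seed = seed,
         stage_seeds = stage_seeds, missing_rate = missing_rate,
         prevalence = prevalence, severity_shift = severity_shift,
         bootstrap_B = bootstrap_B, margins = margins,
         window_width = window_width, window_step = window_step,
         min_events = min_events, spline_df = spline_df, age_cut = age_cut,
         m_imputations = m_imputations, do_contribution = do_contribution,
         gbm_params = gbm_params),
    class = "ews_run_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full validation pipeline
#'
#' @param config an [pipeline_config()] object.
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV plus a JSON metrics file and run manifest. Identical configs
#'   reproduce byte-identical artifacts.
#' @return report bundle (list) with the cohort, scores and all evaluation
#'   tables; invisibly written to `out_dir` when provided.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "ews_run_config"))
  defs <- ews_definitions()

  cohort <- .stage("simulate", {
    if (!is.null(config$input_csv)) {
      read_cohort_csv(config$input_csv)
    } else {
      cc <- cohort_config(config$n, prevalence = config$prevalence,
                          seed = config$stage_seeds[["simulate"]],
                          severity_shift = config$severity_shift,
                          missing_rate = config$missing_rate)
      generate_cohort(cc)
    }
  })

  excl <- .stage("impute", apply_exclusions(cohort))
  completed <- .stage("impute", impute_cohort(
    excl$cohort, m = config$m_imputations,
    seed = config$stage_seeds[["impute"]]))

  scores <- .stage("score", compute_all_scores(completed, defs))
  score_names <- names(scores)
  y <- completed$outcome24h

  evaluate <- .stage("evaluate", {
    rocs <- lapply(scores, auroc, outcomes = y)
    auroc_tab <- data.frame(
      score = score_names,
      auroc = vapply(rocs, `[[`, 0, "auroc"),
      ci_lo = vapply(rocs, function(r) r$ci95[1], 0),
      ci_hi = vapply(rocs, function(r) r$ci95[2], 0),
      row.names = NULL
    )
    best <- score_names[which.max(auroc_tab$auroc)]
    delong_tab <- do.call(rbind, lapply(
      setdiff(score_names, best), function(s) {
        d <- delong_compare(scores[[best]], scores[[s]], y)
        data.frame(reference = best, score = s,
                   delta_auroc = d$delta_auroc, z = d$z, p = d$p)
      }))
    risk <- lapply(scores, fit_risk_model, outcomes = y)
    seed_ev <- config$stage_seeds[["evaluate"]]
    briers <- lapply(risk, function(rm) {
      brier_score(rm$pred, y, B = config$bootstrap_B, seed = seed_ev)
    })
    best_cal <- score_names[which.min(vapply(briers, `[[`, 0, "brier"))]
    calib_tab <- do.call(rbind, lapply(score_names, function(s) {
      sl <- calibration_slope(risk[[s]]$pred, y)
      cmp <- if (s == best_cal) list(p = NA_real_) else
        brier_compare(risk[[s]]$pred, risk[[best_cal]]$pred, y,
                      B = config$bootstrap_B, seed = seed_ev)
      data.frame(score = s, brier = briers[[s]]$brier,
                 brier_ci_lo = briers[[s]]$ci95[1],
                 brier_ci_hi = briers[[s]]$ci95[2],
                 p_vs_null = briers[[s]]$p_vs_null,
                 p_vs_best = cmp$p, slope = sl$slope,
                 intercept = sl$intercept)
    }))
    thr_tab <- do.call(rbind, lapply(score_names, function(s) {
      do.call(rbind, lapply(config$margins, function(mg) {
        tm <- select_threshold_for_ppv(scores[[s]], y, mg)
        if (!tm$attainable) {
          return(data.frame(score = s, margin = mg, attainable = FALSE,
                            threshold = NA, sens = NA, spec = NA, ppv = NA,
                            npv = NA))
        }
        data.frame(score = s, margin = mg, attainable = TRUE,
                   threshold = tm$threshold, sens = tm$sens, spec = tm$spec,
                   ppv = tm$ppv, npv = tm$npv)
      }))
    }))
    pr_tab <- do.call(rbind, lapply(score_names, function(s) {
      pr <- precision_recall(scores[[s]], y)
      cbind(score = s, pr$curve, auprc = pr$auprc)
    }))
    list(auroc = auroc_tab, delong = delong_tab, calibration = calib_tab,
         thresholds = thr_tab, pr = pr_tab,
         brier_null = mean(y) * (1 - mean(y)))
  })

  agespline <- .stage("agespline", {
    lapply(setNames(score_names, score_names), function(s) {
      series <- sliding_window_auroc(
        completed$age, scores[[s]], y, width = config$window_width,
        step = config$window_step, min_events = config$min_events)
      spl <- tryCatch(fit_age_spline(series, df = config$spline_df),
                      error = function(e) NULL)
      list(series = series, spline = spl)
    })
  })

  contribution <- if (config$do_contribution) {
    .stage("contribution", stratum_contrast(
      completed, age_cut = config$age_cut, B = min(config$bootstrap_B, 1000),
      seed = config$stage_seeds[["contribution"]],
      params = config$gbm_params))
  } else NULL

  manifest <- list(
    package = "ewsbench",
    version = as.character(packageVersion("ewsbench")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config[setdiff(names(config), "stage_seeds")],
    stage_seeds = as.list(config$stage_seeds)
  )

  bundle <- list(cohort = cohort, completed = completed,
                 exclusion_log = excl$log, scores = scores,
                 evaluate = evaluate, agespline = agespline,
                 contribution = contribution, manifest = manifest)
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' Write a pipeline report bundle to disk
#'
#' Emits CSV tables, a JSON metrics file and the run manifest. Output is a
#' pure function of the bundle (no timestamps), so identical runs produce
#' byte-identical artifacts.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.csv(df, file.path(dir, name), row.names = FALSE, na = "")
  }
  write_cohort_csv(bundle$completed, file.path(dir, "cohort_completed.csv"))
  w(cbind(bundle$scores), "scores.csv")
  w(bundle$evaluate$auroc, "auroc.csv")
  if (!is.null(bundle$evaluate$delong)) w(bundle$evaluate$delong, "delong.csv")
  w(bundle$evaluate$calibration, "calibration.csv")
  w(bundle$evaluate$thresholds, "thresholds.csv")
  w(bundle$evaluate$pr, "precision_recall.csv")
  spl_tab <- do.call(rbind, lapply(names(bundle$agespline), function(s) {
    ser <- bundle$agespline[[s]]$series
    cbind(score = s, as.data.frame(ser))
  }))
  w(spl_tab, "age_windows.csv")
  spl_f <- do.call(rbind, lapply(names(bundle$agespline), function(s) {
    sp <- bundle$agespline[[s]]$spline
    if (is.null(sp)) return(NULL)
    data.frame(score = s, f_stat = sp$f_stat, df1 = sp$df1, df2 = sp$df2,
               p_value = sp$p_value)
  }))
  if (!is.null(spl_f)) w(spl_f, "age_spline_tests.csv")
  if (!is.null(bundle$contribution)) {
    w(bundle$contribution$difference, "contribution_difference.csv")
  }
  metrics <- list(
    exclusion_log = bundle$exclusion_log,
    brier_null = bundle$evaluate$brier_null,
    auroc = bundle$evaluate$auroc,
    calibration = bundle$evaluate$calibration
  )
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
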