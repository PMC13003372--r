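# Independent oracles used across the suite. These deliberately avoid the
# package's fast paths: linear band scans, exhaustive pair counting,
# subset-enumeration Shapley.

# --- brute-force score oracle: linear scan over the JSON fixtures ---------

oracle_load_defs <- function() {
  dir <- system.file("extdata", "definitions", package = "ewsbench")
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  defs <- lapply(files, jsonlite::fromJSON, simplifyVector = FALSE)
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

oracle_band_points <- function(value, bands) {
  for (b in bands) {
    lo <- if (is.null(b[[1]])) -Inf else b[[1]]
    hi <- if (is.null(b[[2]])) Inf else b[[2]]
    if (value >= lo - 1e-9 && value <= hi + 1e-9) return(b[[3]])
  }
  stop("oracle: no band for value ", value)
}

# scores one record (a named list) against one raw JSON definition
oracle_score_record <- function(rec, defn) {
  total <- 0
  for (comp in defn$components) {
    v <- comp$variable
    val <- rec[[v]]
    if (v == "map" && (is.null(val) || is.na(val))) {
      val <- round(rec$dbp + (rec$sbp - rec$dbp) / 3)
    }
    if (!is.null(comp$categorical_points)) {
      key <- if (is.logical(val)) (if (val) "yes" else "no") else
        as.character(val)
      total <- total + comp$categorical_points[[key]]
    } else if (v == "spo2" && !is.null(defn$special_rules$spo2_scale2) &&
               isTRUE(rec$t2rf_risk)) {
      s2 <- defn$special_rules$spo2_scale2
      bands <- if (isTRUE(rec$on_oxygen)) s2$oxygen else s2$air
      total <- total + oracle_band_points(val, bands)
    } else {
      total <- total + oracle_band_points(val, comp$bands)
    }
  }
  total
}

# --- exhaustive pair-counting AUROC oracle --------------------------------

oracle_auroc <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  conc <- 0
  for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
  conc / (length(pos) * length(neg))
}

# --- step-integration AUPRC oracle ----------------------------------------

oracle_auprc <- function(scores, outcomes) {
  y <- as.logical(outcomes)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_recall <- 0
  area <- 0
  for (t in thr) {
    pos <- scores >= t
    tp <- sum(pos & y)
    prec <- tp / sum(pos)
    rec <- tp / sum(y)
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

# --- subset-enumeration Shapley oracle on small trees ---------------------

oracle_expvalue <- function(tr, x, S, j = 1) {
  f <- tr$feature[j]
  if (f < 0) return(tr$value[j])
  l <- tr$left[j]; r <- tr$right[j]
  if (f %in% S) {
    if (x[f] <= tr$threshold[j]) oracle_expvalue(tr, x, S, l)
    else oracle_expvalue(tr, x, S, r)
  } else {
    (tr$cover[l] * oracle_expvalue(tr, x, S, l) +
       tr$cover[r] * oracle_expvalue(tr, x, S, r)) / tr$cover[j]
  }
}

oracle_subsets <- function(v) {
  out <- list(integer(0))
  for (e in v) out <- c(out, lapply(out, function(s) c(s, e)))
  out
}

oracle_shap_tree <- function(tr, x) {
  used <- unique(tr$feature[tr$feature > 0])
  phi <- numeric(length(x))
  for (j in used) {
    for (S in oracle_subsets(setdiff(used, j))) {
      w <- factorial(length(S)) * factorial(length(used) - length(S) - 1) /
        factorial(length(used))
      phi[j] <- phi[j] + w * (oracle_expvalue(tr, x, c(S, j)) -
                                oracle_expvalue(tr, x, S))
    }
  }
  phi
}

oracle_shap_model <- function(model, x) {
  Reduce(`+`, lapply(model$trees, function(tr) oracle_shap_tree(tr, x)))
}

# --- small fixture builders -----------------------------------------------

# an unremarkable 85-year-old with all vitals in zero-point bands
normal_record <- function(...) {
  rec <- list(age = 85L, sex = "female", hr = 80, rr = 18, sbp = 120,
              dbp = 70, map = round(70 + 50 / 3), temp = 36.8, spo2 = 97,
              gcs = 15L, avpu = "A", on_oxygen = FALSE, t2rf_risk = FALSE,
              outcome24h = FALSE)
  modifyList(rec, list(...))
}

as_cohort <- function(records) {
  do.call(rbind, lapply(records, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
}

# random in-domain records drawn uniformly over each variable's band-edge-rich
# range, for oracle-equivalence sweeps
random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = sample(80:105, n, TRUE),
    sex = sample(c("female", "male"), n, TRUE),
    hr = sample(20:220, n, TRUE),
    rr = sample(4:60, n, TRUE),
    sbp = sample(60:250, n, TRUE),
    dbp = sample(30:120, n, TRUE),
    map = NA_real_,
    temp = round(runif(n, 30, 42), 1),
    spo2 = sample(60:100, n, TRUE),
    gcs = sample(3:15, n, TRUE),
    avpu = sample(c("A", "V", "P", "U"), n, TRUE),
    on_oxygen = sample(c(TRUE, FALSE), n, TRUE),
    t2rf_risk = sample(c(TRUE, FALSE), n, TRUE),
    outcome24h = sample(c(TRUE, FALSE), n, TRUE),
    stringsAsFactors = FALSE
  ) |> within({
    dbp <- pmin(dbp, sbp - 10)
  })
}
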