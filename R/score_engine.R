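# Band-table scoring engine.
#
# The vectorised lookup path uses findInterval over the sorted band lower
# bounds; the test suite cross-checks it against an independent per-record
# linear band scan.

.lookup_bands <- function(values, bands, label) {
  idx <- findInterval(values, bands$lower)
  idx[idx == 0L] <- NA_integer_  # below the lowest lower bound
  bad <- is.na(idx) | values > bands$upper[idx] + 1e-9
  if (any(bad, na.rm = TRUE) || anyNA(values)) {
    if (anyNA(values)) {
      stop("missing value for component '", label,
           "' (records must be completed by imputation before scoring)")
    }
    stop("no matching band for component '", label, "' at value ",
         values[which(bad)[1]])
  }
  bands$points[idx]
}

.lookup_categorical <- function(values, map, label) {
  if (is.logical(values)) values <- ifelse(values, "yes", "no")
  values <- as.character(values)
  if (anyNA(values)) {
    stop("missing value for component '", label,
         "' (records must be completed by imputation before scoring)")
  }
  pts <- unname(map[values])
  if (anyNA(pts)) {
    stop("no category mapping for component '", label, "' at value '",
         values[which(is.na(pts))[1]], "'")
  }
  pts
}

#' Score one component of an early warning score
#'
#' Looks up the points of the unique band (or category) matching `value`.
#'
#' @param value a numeric vital value, or a category label for categorical
#'   components (logical values are mapped to `"yes"`/`"no"`).
#' @param comp one element of an `ews_definition`'s `components` list.
#' @return integer points (vectorised over `value`).
#' @export
score_component <- function(value, comp) {
  if (!is.null(comp$bands)) {
    .lookup_bands(as.numeric(value), comp$bands, comp$variable)
  } else {
    .lookup_categorical(value, comp$categorical_points, comp$variable)
  }
}

#' Derive mean arterial pressure from systolic and diastolic pressure
#'
#' Conventional formula `dbp + (sbp - dbp) / 3`.
#'
#' @param sbp,dbp systolic / diastolic pressure, mm Hg.
#' @return MAP in mm Hg.
#' @export
derive_map <- function(sbp, dbp) {
  bad <- !is.na(sbp) & !is.na(dbp) & sbp < dbp
  if (any(bad)) {
    stop("invalid record: sbp < dbp at position ", which(bad)[1])
  }
  dbp + (sbp - dbp) / 3
}

# points matrix (n x components) for one definition against a cohort.
.component_points <- function(cohort, defn) {
  n <- nrow(cohort)
  pts <- matrix(0L, nrow = n, ncol = length(defn$components),
                dimnames = list(NULL, names(defn$components)))
  for (comp in defn$components) {
    v <- comp$variable
    vals <- if (v == "map" && (!v %in% names(cohort) ||
                               anyNA(cohort[[v]]))) {
      # recorded MAP preferred; derive where absent
      m <- if (v %in% names(cohort)) cohort[[v]] else rep(NA_real_, n)
      # derived MAP is rounded to the band grid resolution
      ifelse(is.na(m), round(derive_map(cohort$sbp, cohort$dbp)), m)
    } else {
      if (!v %in% names(cohort)) {
        stop("cohort lacks column '", v, "' required by ", defn$name)
      }
      cohort[[v]]
    }
    pts[, v] <- score_component(vals, comp)
  }
  s2 <- defn$special_rules$spo2_scale2
  if (!is.null(s2)) {
    trig <- cohort[[s2$trigger %||% "t2rf_risk"]]
    if (is.null(trig)) stop("cohort lacks scale-2 trigger column")
    if (anyNA(trig)) stop("missing values in scale-2 trigger column")
    use2 <- as.logical(trig)
    if (any(use2)) {
      oxy <- as.logical(cohort$on_oxygen[use2])
      if (anyNA(oxy)) stop("missing on_oxygen for scale-2 records")
      sp <- as.numeric(cohort$spo2[use2])
      p2 <- integer(sum(use2))
      if (any(oxy)) {
        p2[oxy] <- .lookup_bands(sp[oxy], s2$oxygen, "spo2 (scale 2, oxygen)")
      }
      if (any(!oxy)) {
        p2[!oxy] <- .lookup_bands(sp[!oxy], s2$air, "spo2 (scale 2, air)")
      }
      pts[use2, "spo2"] <- p2
    }
  }
  pts
}

#' Compute one early warning score for a single record
#'
#' @param rec a one-row data.frame or named list with the cohort columns the
#'   definition consumes (complete, i.e. post-imputation).
#' @param defn an `ews_definition`.
#' @return a list of class `ews_score_result` with `name`, `total` and the
#'   per-component `breakdown`.
#' @export
compute_score <- function(rec, defn) {
  rec <- as.data.frame(rec, stringsAsFactors = FALSE)
  stopifnot(nrow(rec) == 1L)
  pts <- .component_points(rec, defn)
  structure(
    list(name = defn$name, total = as.integer(sum(pts)),
         breakdown = setNames(as.integer(pts[1, ]), colnames(pts))),
    class = "ews_score_result"
  )
}

#' @export
print.ews_score_result <- function(x, ...) {
  cat(x$name, "=", x$total, "\n")
  print(x$breakdown)
  invisible(x)
}

#' Compute all scores for a cohort
#'
#' @param cohort cohort data.frame (see [read_cohort_csv()] for the schema);
#'   must be complete for every variable the definitions consume.
#' @param definitions named list of `ews_definition`s (default: the bundled
#'   five).
#' @param breakdown if `TRUE`, attach per-component point matrices as the
#'   `"breakdown"` attribute.
#' @return data.frame with one row per record and one integer column per
#'   score.
#' @export
compute_all_scores <- function(cohort, definitions = ews_definitions(),
                               breakdown = FALSE) {
  out <- as.data.frame(
    setNames(rep(list(integer(nrow(cohort))), length(definitions)),
             names(definitions))
  )
  if (nrow(cohort) == 0L) return(out)
  bds <- list()
  for (nm in names(definitions)) {
    pts <- tryCatch(
      .component_points(cohort, definitions[[nm]]),
      error = function(e) {
        stop("scoring ", nm, " failed: ", conditionMessage(e), call. = FALSE)
      }
    )
    tot <- as.integer(rowSums(pts))
    rng <- definitions[[nm]]$theoretical_range
    if (any(tot < rng[1] | tot > rng[2])) {
      stop("total ", nm, " outside theoretical range for record ",
           which(tot < rng[1] | tot > rng[2])[1])
    }
    out[[nm]] <- tot
    if (breakdown) bds[[nm]] <- pts
  }
  if (breakdown) attr(out, "breakdown") <- bds
  out
}
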