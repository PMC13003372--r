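# Score definitions: declarative band tables loaded from JSON fixtures.
#
# A definition is a list with fields `name`, `theoretical_range`,
# `components` (each either numeric `bands` -- a data.frame with columns
# lower/upper/points, closed intervals, +/-Inf for open ends -- or a
# `categorical_points` named map) and optional `special_rules`.

.band_df <- function(triplets) {
  m <- do.call(rbind, lapply(triplets, function(b) {
    stopifnot(length(b) == 3)
    c(if (is.null(b[[1]])) -Inf else as.numeric(b[[1]]),
      if (is.null(b[[2]])) Inf else as.numeric(b[[2]]),
      as.numeric(b[[3]]))
  }))
  df <- data.frame(lower = m[, 1], upper = m[, 2], points = m[, 3])
  df[order(df$lower), , drop = FALSE]
}

#' Load one early-warning-score definition from a JSON fixture
#'
#' The fixture schema is validated on load and, unless `validate = FALSE`,
#' the band tables are checked for gaps/overlaps against the physiologic
#' domains (see [validate_definition()]).
#'
#' @param path path to a definition JSON file.
#' @param validate run [validate_definition()] and fail on violations.
#' @return an object of class `ews_definition`.
#' @export
load_score_definition <- function(path, validate = TRUE) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (field in c("name", "theoretical_range", "components")) {
    if (is.null(raw[[field]])) {
      stop("definition file ", path, " lacks required field '", field, "'")
    }
  }
  comps <- lapply(raw$components, function(cm) {
    if (is.null(cm$variable)) stop("component without 'variable' in ", path)
    has_bands <- !is.null(cm$bands)
    has_cat <- !is.null(cm$categorical_points)
    if (has_bands == has_cat) {
      stop("component '", cm$variable, "' must have exactly one of bands/",
           "categorical_points (", path, ")")
    }
    out <- list(variable = cm$variable)
    if (has_bands) {
      out$bands <- .band_df(cm$bands)
    } else {
      out$categorical_points <- unlist(cm$categorical_points)
    }
    out
  })
  names(comps) <- vapply(comps, `[[`, "", "variable")
  defn <- structure(
    list(
      name = raw$name,
      theoretical_range = as.numeric(unlist(raw$theoretical_range)),
      components = comps,
      special_rules = raw$special_rules,
      synthetic = isTRUE(raw$synthetic)
    ),
    class = "ews_definition"
  )
  if (!is.null(defn$special_rules$spo2_scale2)) {
    defn$special_rules$spo2_scale2$air <-
      .band_df(defn$special_rules$spo2_scale2$air)
    defn$special_rules$spo2_scale2$oxygen <-
      .band_df(defn$special_rules$spo2_scale2$oxygen)
  }
  if (validate) {
    v <- validate_definition(defn)
    if (length(v)) {
      stop("invalid score definition '", defn$name, "': ",
           paste(v, collapse = "; "))
    }
  }
  defn
}

#' Load the bundled score definitions
#'
#' Loads NEWS, NEWS2, MEWS, REMS and the clearly labelled *synthetic* IEWS
#' stand-in shipped under `inst/extdata/definitions`.
#'
#' @param dir directory of definition JSON files; defaults to the bundled set.
#' @return named list of `ews_definition` objects (named by score).
#' @export
ews_definitions <- function(dir = NULL) {
  if (is.null(dir)) {
    dir <- system.file("extdata", "definitions", package = "ewsbench")
  }
  files <- list.files(dir, pattern = "\\.json$", full.names = TRUE)
  if (!length(files)) stop("no definition files found in ", dir)
  defs <- lapply(files, load_score_definition)
  names(defs) <- vapply(defs, `[[`, "", "name")
  # canonical ordering when the standard five are present
  canon <- c("NEWS", "NEWS2", "MEWS", "REMS", "IEWS")
  if (all(canon %in% names(defs))) defs <- defs[canon]
  defs
}

#' Validate a score definition
#'
#' Checks, for every numeric component, that its bands are non-overlapping
#' and jointly cover the variable's physiologic domain on the domain's
#' resolution grid (1 unit for most vitals, 0.1 degC for temperature), and
#' that the extreme attainable totals stay inside `theoretical_range`.
#' Violations are returned, not raised.
#'
#' @param defn an `ews_definition`.
#' @return character vector of violations; empty if the definition is valid.
#' @export
validate_definition <- function(defn) {
  violations <- character()
  band_sets <- list()
  for (comp in defn$components) {
    if (!is.null(comp$bands)) {
      band_sets[[length(band_sets) + 1L]] <-
        list(label = comp$variable, variable = comp$variable,
             bands = comp$bands)
    }
  }
  s2 <- defn$special_rules$spo2_scale2
  if (!is.null(s2)) {
    band_sets <- c(band_sets, list(
      list(label = "spo2 (scale 2, air)", variable = "spo2", bands = s2$air),
      list(label = "spo2 (scale 2, oxygen)", variable = "spo2",
           bands = s2$oxygen)
    ))
  }
  for (bs in band_sets) {
    dom <- .ews_domains[[bs$variable]]
    if (is.null(dom)) {
      violations <- c(violations, paste0(
        bs$label, ": no physiologic domain registered"))
      next
    }
    grid <- seq(dom$lower, dom$upper, by = dom$resolution)
    tol <- dom$resolution * 1e-6
    hits <- rep(0L, length(grid))
    for (i in seq_len(nrow(bs$bands))) {
      hits <- hits + as.integer(
        grid >= bs$bands$lower[i] - tol & grid <= bs$bands$upper[i] + tol)
    }
    if (any(hits == 0L)) {
      violations <- c(violations, paste0(
        bs$label, ": coverage gap at ",
        paste(head(grid[hits == 0L], 3), collapse = ", ")))
    }
    if (any(hits > 1L)) {
      violations <- c(violations, paste0(
        bs$label, ": overlap at ",
        paste(head(grid[hits > 1L], 3), collapse = ", ")))
    }
    if (any(bs$bands$lower > bs$bands$upper)) {
      violations <- c(violations, paste0(bs$label, ": band with lower > upper"))
    }
    if (any(bs$bands$points < 0) ||
        any(bs$bands$points != round(bs$bands$points))) {
      violations <- c(violations, paste0(
        bs$label, ": points must be non-negative integers"))
    }
  }
  # extreme totals vs theoretical_range
  comp_max <- vapply(defn$components, function(comp) {
    if (!is.null(comp$bands)) max(comp$bands$points)
    else max(comp$categorical_points)
  }, numeric(1))
  comp_min <- vapply(defn$components, function(comp) {
    if (!is.null(comp$bands)) min(comp$bands$points)
    else min(comp$categorical_points)
  }, numeric(1))
  if (sum(comp_min) < defn$theoretical_range[1] ||
      sum(comp_max) > defn$theoretical_range[2]) {
    violations <- c(violations, paste0(
      "attainable totals [", sum(comp_min), ", ", sum(comp_max),
      "] exceed theoretical_range [", defn$theoretical_range[1], ", ",
      defn$theoretical_range[2], "]"))
  }
  violations
}

#' @export
print.ews_definition <- function(x, ...) {
  cat("<ews_definition> ", x$name,
      if (x$synthetic) "  [SYNTHETIC STAND-IN]" else "", "\n", sep = "")
  cat("  components: ", paste(names(x$components), collapse = ", "), "\n",
      sep = "")
  cat("  theoretical range: [", x$theoretical_range[1], ", ",
      x$theoretical_range[2], "]\n", sep = "")
  if (!is.null(x$special_rules)) {
    cat("  special rules: ", paste(names(x$special_rules), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}
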