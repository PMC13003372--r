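# Gradient-boosted trees with logistic loss.
#
# A compact histogram-based booster in the style of the extreme
# gradient boosting family: second-order split gain
# G_L^2/(H_L+lambda) + G_R^2/(H_R+lambda) - G^2/(H+lambda), shallow trees,
# shrinkage, and class-imbalance weighting. Self-contained because no
# boosted-tree library with exact Shapley support is assumed to be
# available at run time; correctness is pinned by the oracle tests.

.gbm_defaults <- function() {
  list(eta = 0.1, max_depth = 3L, nrounds = 200L, lambda = 1.0, gamma = 0.0,
       min_child_weight = 1.0, max_bin = 64L, scale_pos_weight = NULL,
       subsample = 1.0)
}

.make_bins <- function(x, max_bin) {
  vals <- sort(unique(x))
  cuts <- if (length(vals) <= max_bin) {
    vals[-length(vals)]
  } else {
    unique(quantile(x, seq_len(max_bin - 1) / max_bin, type = 7,
                    names = FALSE))
  }
  bin <- findInterval(x, cuts, left.open = TRUE) + 1L
  list(cuts = cuts, bin = bin, n_bins = length(cuts) + 1L)
}

# grow one depth-limited tree; returns flat arrays (feature = -1 at leaves)
.grow_tree <- function(bins, g, h, idx, params) {
  nodes <- list()
  new_node <- function() {
    nodes[[length(nodes) + 1L]] <<- list(feature = -1L, threshold = NA_real_,
                                         left = 0L, right = 0L, value = 0,
                                         cover = 0L)
    length(nodes)
  }
  build <- function(node_id, idx, depth) {
    G <- sum(g[idx]); H <- sum(h[idx])
    nodes[[node_id]]$cover <<- length(idx)
    if (depth < params$max_depth && length(idx) >= 2) {
      best <- list(gain = 0)
      for (f in seq_along(bins)) {
        b <- bins[[f]]$bin[idx]
        nb <- bins[[f]]$n_bins
        if (nb < 2L) next
        gs <- rowsum(cbind(g[idx], h[idx]), b)
        bid <- as.integer(rownames(gs))
        gv <- hv <- numeric(nb)
        gv[bid] <- gs[, 1]; hv[bid] <- gs[, 2]
        GL <- cumsum(gv)[-nb]; HL <- cumsum(hv)[-nb]
        ok <- HL >= params$min_child_weight &
          (H - HL) >= params$min_child_weight
        if (!any(ok)) next
        gain <- 0.5 * (GL^2 / (HL + params$lambda) +
                         (G - GL)^2 / (H - HL + params$lambda) -
                         G^2 / (H + params$lambda)) - params$gamma
        gain[!ok] <- -Inf
        bmax <- which.max(gain)
        if (gain[bmax] > best$gain) {
          best <- list(gain = gain[bmax], feature = f, bin = bmax,
                       threshold = bins[[f]]$cuts[bmax])
        }
      }
      if (best$gain > 0) {
        lid <- new_node(); rid <- new_node()
        nodes[[node_id]]$feature <<- best$feature
        nodes[[node_id]]$threshold <<- best$threshold
        nodes[[node_id]]$left <<- lid
        nodes[[node_id]]$right <<- rid
        goleft <- bins[[best$feature]]$bin[idx] <= best$bin
        build(lid, idx[goleft], depth + 1L)
        build(rid, idx[!goleft], depth + 1L)
        return(invisible())
      }
    }
    nodes[[node_id]]$value <<- -G / (H + params$lambda) * params$eta
    invisible()
  }
  root <- new_node()
  build(root, idx, 0L)
  list(
    feature = vapply(nodes, `[[`, 0L, "feature"),
    threshold = vapply(nodes, `[[`, 0, "threshold"),
    left = vapply(nodes, `[[`, 0L, "left"),
    right = vapply(nodes, `[[`, 0L, "right"),
    value = vapply(nodes, `[[`, 0, "value"),
    cover = vapply(nodes, `[[`, 0L, "cover")
  )
}

.predict_tree <- function(tree, X) {
  node <- rep(1L, nrow(X))
  repeat {
    f <- tree$feature[node]
    active <- which(f > 0L)
    if (!length(active)) break
    xv <- X[cbind(active, f[active])]
    goleft <- xv <= tree$threshold[node[active]]
    node[active] <- ifelse(goleft, tree$left[node[active]],
                           tree$right[node[active]])
  }
  tree$value[node]
}

#' Fit a gradient-boosted tree classifier on a feature matrix
#'
#' @param x numeric feature matrix (one column per feature).
#' @param y logical/0-1 outcomes.
#' @param params named list overriding the defaults (`eta = 0.1`,
#'   `max_depth = 3`, `nrounds = 200`, `lambda = 1`, `min_child_weight = 1`,
#'   `scale_pos_weight` = negatives/positives, `subsample = 1`).
#' @param seed RNG seed (only consumed when `subsample < 1`; the default fit
#'   is fully deterministic).
#' @return object of class `ews_gbm`.
#' @export
ews_gbm <- function(x, y, params = list(), seed = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("cannot fit on a single-class stratum")
  p <- modifyList(.gbm_defaults(), params)
  if (is.null(p$scale_pos_weight)) {
    p$scale_pos_weight <- sum(y == 0) / sum(y == 1)
  }
  w <- ifelse(y == 1, p$scale_pos_weight, 1)
  bins <- lapply(seq_len(ncol(x)), function(j) .make_bins(x[, j], p$max_bin))
  base <- log(sum(w * y) / sum(w * (1 - y)))
  margin <- rep(base, nrow(x))
  set.seed(seed)
  trees <- vector("list", p$nrounds)
  for (r in seq_len(p$nrounds)) {
    prob <- plogis(margin)
    g <- (prob - y) * w
    h <- pmax(prob * (1 - prob), 1e-16) * w
    idx <- if (p$subsample < 1) {
      sort(sample.int(nrow(x), max(1L, round(p$subsample * nrow(x)))))
    } else {
      seq_len(nrow(x))
    }
    tree <- .grow_tree(bins, g, h, idx, p)
    trees[[r]] <- tree
    margin <- margin + .predict_tree(tree, x)
  }
  structure(
    list(trees = trees, base = base, params = p,
         feature_names = colnames(x) %||% paste0("f", seq_len(ncol(x))),
         n_features = ncol(x)),
    class = "ews_gbm"
  )
}

#' Predict from a fitted booster
#'
#' @param object an `ews_gbm` model.
#' @param newdata numeric matrix with the training feature columns.
#' @param type `"prob"` (default) or `"margin"` (log-odds).
#' @param ... unused.
#' @export
predict.ews_gbm <- function(object, newdata, type = c("prob", "margin"),
                            ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  margin <- rep(object$base, nrow(newdata))
  for (tree in object$trees) {
    margin <- margin + .predict_tree(tree, newdata)
  }
  if (type == "margin") margin else plogis(margin)
}

# default encoding of a cohort into the booster's feature matrix
.ews_model_features <- c("age", "sex", "hr", "rr", "sbp", "map", "temp",
                         "spo2", "gcs", "avpu", "on_oxygen", "t2rf_risk")

.ews_feature_matrix <- function(cohort, features = .ews_model_features) {
  enc <- lapply(features, function(f) {
    v <- cohort[[f]]
    if (is.null(v)) stop("cohort lacks model feature '", f, "'")
    switch(f,
           sex = as.numeric(v == "male"),
           avpu = as.numeric(factor(v, levels = c("A", "V", "P", "U"))) - 1,
           as.numeric(v))
  })
  mat <- do.call(cbind, enc)
  colnames(mat) <- features
  if (anyNA(mat)) stop("model features must be complete (impute first)")
  mat
}

#' Fit the outcome model over the core score variables
#'
#' Gradient-boosted trees over the union of all score inputs (age, sex,
#' heart/respiratory rate, systolic and mean pressure, temperature, SpO2,
#' GCS, ordinal AVPU, oxygen-supplementation and COPD flags), predicting
#' 24-hour deterioration.
#'
#' @param cohort completed cohort data.frame.
#' @param features feature columns to use.
#' @param params booster hyperparameters (see [ews_gbm()]).
#' @param seed RNG seed.
#' @return `ews_gbm` model with the feature encoding recorded.
#' @export
fit_outcome_model <- function(cohort, features = .ews_model_features,
                              params = list(), seed = 1) {
  x <- .ews_feature_matrix(cohort, features)
  ews_gbm(x, cohort$outcome24h, params = params, seed = seed)
}
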