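test_that("a single-signal outcome puts that feature on top (normalized 1)", {
  set.seed(1)
  n <- 2000
  X <- matrix(rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.numeric(X[, 3] > 0.5)    # deterministic step in one feature
  m <- ews_gbm(X, y, params = list(nrounds = 30, max_depth = 2))
  cs <- shap_contributions(m, X)
  expect_equal(unname(which.max(cs$normalized)), 3L)
  expect_equal(max(cs$normalized), 1)
  expect_true(all(cs$normalized >= 0 & cs$normalized <= 1))
})

test_that("pure-noise features give chance-level held-out AUROC", {
  set.seed(2)
  n <- 4000
  X <- matrix(rnorm(n * 5), n, 5)
  y <- rbinom(n, 1, 0.3)
  tr <- 1:2000; te <- 2001:4000
  m <- ews_gbm(X[tr, ], y[tr], params = list(nrounds = 40, max_depth = 2))
  a <- auroc(predict(m, X[te, ]), y[te])$auroc
  expect_lt(abs(a - 0.5), 0.06)
})

test_that("booster fit is deterministic and refuses single-class data", {
  set.seed(3)
  X <- matrix(rnorm(600), 200, 3)
  y <- rbinom(200, 1, 0.4)
  m1 <- ews_gbm(X, y, params = list(nrounds = 10))
  m2 <- ews_gbm(X, y, params = list(nrounds = 10))
  expect_identical(predict(m1, X), predict(m2, X))
  expect_error(ews_gbm(X, rep(1, 200)), "single-class")
})

test_that("SHAP: constant and stump models behave exactly", {
  # single-leaf tree: all attributions zero
  leaf <- list(feature = -1L, threshold = NA_real_, left = 0L, right = 0L,
               value = 0.7, cover = 10)
  m <- structure(list(trees = list(lapply(leaf, function(v) v)), base = 0,
                      params = list(), feature_names = c("a", "b"),
                      n_features = 2L), class = "ews_gbm")
  phi <- shap_values(m, matrix(rnorm(10), 5, 2), check_additivity = FALSE)
  expect_true(all(phi == 0))

  # single-split stump: only the split feature is attributed
  stump <- list(feature = c(2L, -1L, -1L), threshold = c(0, NA, NA),
                left = c(2L, 0L, 0L), right = c(3L, 0L, 0L),
                value = c(0, 1.5, -0.5), cover = c(12, 4, 8))
  ms <- structure(list(trees = list(stump), base = 0, params = list(),
                       feature_names = c("a", "b"), n_features = 2L),
                  class = "ews_gbm")
  x <- matrix(c(3, -1), 1, 2)
  phis <- shap_values(ms, x, check_additivity = FALSE)
  expect_equal(unname(phis[1, 1]), 0)
  # f(x) - E[f] = 1.5 - (4*1.5 - 8*0.5)/12
  expect_equal(unname(phis[1, 2]), 1.5 - (4 * 1.5 - 8 * 0.5) / 12)
})

test_that("TreeSHAP equals the subset-enumeration Shapley oracle", {
  set.seed(4)
  for (rep in 1:8) {
    n <- 250
    X <- matrix(rnorm(n * 4), n, 4)
    y <- as.numeric(plogis(X[, 1] - X[, 2] * X[, 3] + 0.5 * X[, 4]) >
                      runif(n))
    if (length(unique(y)) < 2) next
    m <- ews_gbm(X, y, params = list(nrounds = 6, max_depth = 3, eta = 0.3))
    phi <- shap_values(m, X[1:5, , drop = FALSE])
    for (i in 1:5) {
      expect_equal(unname(phi[i, ]), oracle_shap_model(m, X[i, ]),
                   tolerance = 1e-10)
    }
  }
})

test_that("SHAP additivity holds on the cohort model", {
  coh <- generate_cohort(cohort_config(3000, seed = 5))
  m <- fit_outcome_model(coh, params = list(nrounds = 60, max_depth = 3))
  x <- ewsbench:::.ews_feature_matrix(coh)
  phi <- shap_values(m, x[1:500, ], check_additivity = FALSE)
  margin <- predict(m, x[1:500, ], type = "margin")
  expect_lt(max(abs(rowSums(phi) + attr(phi, "expected_value") - margin)),
            1e-6)
  expect_error(shap_values(m, x[, 1:5]), "feature mismatch")
})

test_that("the ensemble roughly dominates the best single score", {
  coh <- generate_cohort(cohort_config(8000, seed = 6))
  sc <- compute_all_scores(coh)
  tr <- 1:4000; te <- 4001:8000
  m <- fit_outcome_model(coh[tr, ], params = list(nrounds = 120,
                                                  max_depth = 3))
  x <- ewsbench:::.ews_feature_matrix(coh)
  a_model <- auroc(predict(m, x[te, ]), coh$outcome24h[te])$auroc
  a_best <- max(vapply(sc, function(s) {
    auroc(s[te], coh$outcome24h[te])$auroc
  }, 0))
  expect_gte(a_model, a_best - 0.02)
})

test_that("stratum_contrast: structure, determinism and degenerate input", {
  coh <- generate_cohort(cohort_config(6000, seed = 7))
  ct <- stratum_contrast(coh, age_cut = 87, B = 100, seed = 1,
                         params = list(nrounds = 40, max_depth = 2))
  expect_equal(ct$n_lo + ct$n_hi, nrow(coh))
  expect_equal(max(ct$difference$norm_lo), 1)
  expect_equal(max(ct$difference$norm_hi), 1)
  expect_true(all(ct$difference$p_boot >= 0 & ct$difference$p_boot <= 1))
  ct2 <- stratum_contrast(coh, age_cut = 87, B = 100, seed = 1,
                          params = list(nrounds = 40, max_depth = 2))
  expect_identical(ct$difference, ct2$difference)
  expect_error(stratum_contrast(coh, age_cut = 200), "age range")
})

test_that("a constructed age-by-oxygen interaction is recovered", {
  set.seed(8)
  n <- 12000
  age <- sample(80:99, n, TRUE)
  on_oxygen <- runif(n) < 0.15
  x1 <- rnorm(n)
  beta_oxy <- ifelse(age >= 87, 2.4, 0.8)  # effect triples in the old stratum
  y <- runif(n) < plogis(-3.4 + beta_oxy * on_oxygen + 0.5 * x1)
  coh <- data.frame(age = age, sex = "female", hr = 80 + 5 * x1, rr = 18,
                    sbp = 120, dbp = 70, map = 87, temp = 36.8, spo2 = 97,
                    gcs = 15L, avpu = "A", on_oxygen = on_oxygen,
                    t2rf_risk = FALSE, outcome24h = y,
                    stringsAsFactors = FALSE)
  ct <- stratum_contrast(coh, age_cut = 87, B = 300, seed = 2,
                         params = list(nrounds = 80, max_depth = 2))
  row <- ct$difference[ct$difference$feature == "on_oxygen", ]
  expect_gt(row$shap_difference, 0)
  expect_lt(row$p_boot, 0.05)
})
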