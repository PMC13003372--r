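defs <- ews_definitions()

test_that("bundled definitions load and validate", {
  expect_setequal(names(defs), c("NEWS", "NEWS2", "MEWS", "REMS", "IEWS"))
  for (d in defs) expect_length(validate_definition(d), 0)
  expect_true(defs$IEWS$synthetic)  # stand-in fixture is labelled
})

test_that("validate_definition reports constructed defects", {
  broken <- defs$NEWS
  hr <- broken$components$hr
  hr$bands <- hr$bands[!(hr$bands$lower == 51 & hr$bands$upper == 90), ]
  broken$components$hr <- hr
  v <- validate_definition(broken)
  expect_true(any(grepl("coverage gap", v)))

  overlapping <- defs$MEWS
  rr <- overlapping$components$rr
  rr$bands <- rbind(rr$bands, data.frame(lower = 10, upper = 12, points = 1))
  rr$bands <- rr$bands[order(rr$bands$lower), ]
  overlapping$components$rr <- rr
  v <- validate_definition(overlapping)
  expect_true(any(grepl("overlap", v)))
})

test_that("score_component looks up bands and categories", {
  expect_equal(score_component(80, defs$NEWS$components$hr), 0)
  expect_equal(score_component(92, defs$NEWS$components$spo2), 2)
  expect_equal(score_component("U", defs$MEWS$components$avpu), 3)
  # vectorised lookup
  expect_equal(score_component(c(40, 41, 90, 91, 131), defs$NEWS$components$hr),
               c(3, 1, 0, 1, 3))
  expect_error(score_component(38.05, defs$NEWS$components$temp),
               "no matching band")
  expect_error(score_component("X", defs$MEWS$components$avpu),
               "no category mapping")
})

test_that("derive_map follows dbp + (sbp - dbp)/3", {
  expect_equal(derive_map(120, 60), 80)
  expect_equal(derive_map(100, 100), 100)
  expect_equal(derive_map(139, 75), 96.33, tolerance = 1e-3)
  expect_error(derive_map(80, 90), "sbp < dbp")
})

test_that("compute_score matches hand-worked examples", {
  rec <- normal_record()
  expect_equal(compute_score(rec, defs$NEWS)$total, 0)
  rems <- compute_score(rec, defs$REMS)
  expect_equal(rems$total, 6)          # age > 74 floor, all else zero-point
  expect_equal(unname(rems$breakdown["age"]), 6L)
  expect_equal(sum(rems$breakdown), rems$total)

  # SpO2 90 on oxygen with COPD: NEWS scores 3 + 2, NEWS2 Scale 2 scores 0 + 2
  hyp <- normal_record(spo2 = 90, on_oxygen = TRUE, t2rf_risk = TRUE)
  news <- compute_score(hyp, defs$NEWS)
  news2 <- compute_score(hyp, defs$NEWS2)
  expect_equal(unname(news$breakdown["spo2"] + news$breakdown["on_oxygen"]), 5L)
  expect_equal(unname(news2$breakdown["spo2"]), 0L)
  expect_equal(unname(news2$breakdown["on_oxygen"]), 2L)
  expect_equal(news$total - news2$total, 3)
})

test_that("compute_all_scores composes element-wise and handles edge cases", {
  recs <- list(normal_record(),
               normal_record(hr = 115, rr = 25, avpu = "V"),
               normal_record(spo2 = 85, on_oxygen = TRUE, t2rf_risk = TRUE))
  cohort <- as_cohort(recs)
  tab <- compute_all_scores(cohort, defs)
  expect_equal(dim(tab), c(3L, 5L))
  for (i in 1:3) {
    for (s in names(defs)) {
      expect_equal(tab[[s]][i], compute_score(recs[[i]], defs[[s]])$total)
    }
  }
  empty <- cohort[0, ]
  expect_equal(nrow(compute_all_scores(empty, defs)), 0L)

  incomplete <- cohort
  incomplete$hr[2] <- NA
  expect_error(compute_all_scores(incomplete, defs), "missing")
})

test_that("engine equals the linear band-scan oracle on random records", {
  raw <- oracle_load_defs()
  cohort <- random_records(400, seed = 11)
  tab <- compute_all_scores(cohort, defs)
  for (i in seq_len(nrow(cohort))) {
    rec <- as.list(cohort[i, ])
    for (s in names(defs)) {
      expect_equal(tab[[s]][i], oracle_score_record(rec, raw[[s]]),
                   info = paste(s, "record", i))
    }
  }
})

test_that("NEWS2 equals NEWS when there is no type-2 respiratory failure risk", {
  cohort <- random_records(500, seed = 3)
  cohort$t2rf_risk <- FALSE
  tab <- compute_all_scores(cohort, defs)
  expect_equal(tab$NEWS2, tab$NEWS)
})

test_that("worsening one vital never decreases a score (monotone dominance)", {
  set.seed(7)
  for (s in c("NEWS", "MEWS", "REMS")) {
    defn <- defs[[s]]
    for (rep in 1:40) {
      rec <- as.list(random_records(1, seed = 1000 + rep))
      rec$t2rf_risk <- FALSE
      base <- compute_score(rec, defn)
      comp_names <- names(defn$components)
      cn <- sample(comp_names, 1)
      comp <- defn$components[[cn]]
      if (is.null(comp$bands) || cn == "map") next
      cur_pts <- base$breakdown[[cn]]
      worse <- comp$bands[comp$bands$points > cur_pts, , drop = FALSE]
      if (!nrow(worse)) next
      b <- worse[sample(nrow(worse), 1), ]
      dom <- ewsbench:::.ews_domains[[comp$variable]]
      newval <- max(min(b$upper, dom$upper), max(b$lower, dom$lower))
      rec2 <- rec
      rec2[[comp$variable]] <- newval
      if (cn == "sbp") rec2$dbp <- min(rec2$dbp, newval - 10)
      expect_gte(compute_score(rec2, defn)$total, base$total)
    }
  }
})

test_that("score totals respect each theoretical range on a synthetic cohort", {
  coh <- generate_cohort(cohort_config(1000, seed = 5))
  tab <- compute_all_scores(coh, defs)
  for (s in names(defs)) {
    rng <- defs[[s]]$theoretical_range
    expect_true(all(tab[[s]] >= rng[1] & tab[[s]] <= rng[2]))
  }
  expect_true(all(tab$REMS >= 6))  # age >= 80 floor
})
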