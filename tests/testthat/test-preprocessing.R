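test_that("inclusion criteria exclude by age, missing doses and missing aPTT", {
  ev <- rbind(
    std_events(1),                                           # fully eligible
    std_events(2),                                           # age 17.9 -> out
    std_events(3, aptt_times = c(-1), aptt_values = 40),     # no post-dose aPTT
    std_events(4, aptt_times = c(9, 12)),                    # no pre-dose aPTT
    data.frame(patient_id = 5, event_type = "aptt",          # never dosed
               time_h = c(-1, 10), value = c(40, 50))
  )
  pats <- data.frame(patient_id = 1:5, age = c(45, 17.9, 50, 60, 70))
  res <- apply_inclusion(make_mini_cohort(pats, ev))
  expect_equal(res$cohort$patients$patient_id, 1)
  expect_equal(unname(res$tally["age"]), 1L)
  expect_equal(unname(res$tally["no_heparin"]), 1L)
  expect_equal(unname(res$tally["aptt_unavailable"]), 2L)
  expect_equal(unname(res$tally["included"]), 1L)
})

test_that("inclusion on an empty cohort yields empty output and zero tallies", {
  empty <- make_mini_cohort(
    data.frame(patient_id = integer(0), age = numeric(0)),
    data.frame(patient_id = integer(0), event_type = character(0),
               time_h = numeric(0), value = numeric(0)))
  res <- apply_inclusion(empty)
  expect_equal(nrow(res$cohort$patients), 0)
  expect_equal(unname(res$tally), c(0L, 0L, 0L, 0L))
})

test_that("3-sigma filter removes exactly the implanted outliers", {
  fx <- make_uniform_fixture(n = 100, n_outliers = 3, seed = 2)
  res <- filter_outliers(fx$rows, c("weight", "initial_aptt", "creatinine",
                                    "liver_enzyme", "total_dose"))
  expect_equal(res$removed, fx$implanted)
  expect_equal(nrow(res$rows), 97)
  expect_true(all(res$bounds$low >= 0))
  expect_true(all(res$bounds$low <= res$bounds$high))
  # refiltering survivors with the ORIGINAL bounds removes nothing
  b <- res$bounds
  for (j in seq_len(nrow(b))) {
    x <- res$rows[[b$feature[j]]]
    expect_true(all(x >= b$low[j] & x <= b$high[j]))
  }
})

test_that("3-sigma filter handles degenerate spreads and the lower bound", {
  const <- data.frame(x = rep(5, 20))
  res <- filter_outliers(const, "x")
  expect_equal(nrow(res$rows), 20)

  # low extreme below max(0, mu - 3 sigma) with mu - 3 sigma > 0
  df <- data.frame(x = c(rep(100, 50), 100.5, 99.5, 1))
  res2 <- filter_outliers(df, "x")
  expect_gt(res2$bounds$low, 0)
  expect_equal(res2$removed, 53L)

  expect_error(filter_outliers(df[0, , drop = FALSE], "x"), "rows")
  expect_error(filter_outliers(data.frame(x = letters[1:5]), "x"), "non-numeric")
})

test_that("kNN imputation takes the mean of the k nearest complete donors", {
  # unanimous donors
  df <- data.frame(a = c(0, 0.1, 0.2, 9), b = c(1, 1.1, 0.9, 9),
                   s = c(2, 2, 2, NA))
  out <- impute_knn(df, "s", k = 3, distance_features = c("a", "b"))
  expect_equal(out$s[4], 2)

  # exactly k complete rows: their mean fills every missing row
  df2 <- data.frame(a = 1:6, s = c(1, 5, 9, NA, NA, NA))
  out2 <- impute_knn(df2, "s", k = 3, distance_features = "a")
  expect_equal(out2$s[4:6], rep(5, 3))

  expect_error(impute_knn(data.frame(a = 1:3, s = c(1, NA, NA)), "s", k = 3,
                          distance_features = "a"), "fewer")
})

test_that("kNN imputation matches the exhaustive-search oracle on a 50-row fixture", {
  set.seed(7)
  n <- 50
  df <- data.frame(a = runif(n), b = runif(n, 0, 10), c = rnorm(n),
                   s1 = sample(0:4, n, replace = TRUE),
                   s2 = sample(0:4, n, replace = TRUE))
  df$s1[sample(n, 8)] <- NA
  df$s2[sample(n, 6)] <- NA
  keep <- df
  out <- impute_knn(df, c("s1", "s2"), k = 3, distance_features = c("a", "b", "c"))
  expect_false(anyNA(out[, c("s1", "s2")]))

  # oracle: same min-max distance scaling, brute-force all-pairs search
  D <- as.matrix(df[, c("a", "b", "c")])
  rng <- apply(D, 2, range)
  Ds <- sweep(sweep(D, 2, rng[1, ]), 2, rng[2, ] - rng[1, ], "/")
  for (f in c("s1", "s2")) {
    for (i in which(is.na(df[[f]]))) {
      expect_equal(out[[f]][i], oracle_knn_value(Ds, df[[f]], i, 3))
    }
    # non-missing values are never altered
    obs <- !is.na(df[[f]])
    expect_equal(out[[f]][obs], df[[f]][obs])
  }
})

test_that("one-hot encoding expands vocabularies and rejects unseen categories", {
  df <- data.frame(gender = c("male", "female", "male"),
                   ethnicity = c("white", "black", "asian"), x = 1:3)
  enc <- one_hot_encode(df, c("gender", "ethnicity"))
  expect_equal(enc$rows$gender_male, c(1, 0, 1))
  expect_equal(enc$rows$gender_female, c(0, 1, 0))
  expect_equal(enc$groups$gender, c("gender_female", "gender_male"))
  # each one-hot group sums to exactly 1 per row
  for (g in enc$groups) {
    expect_equal(rowSums(enc$rows[, g, drop = FALSE]), rep(1, 3))
  }
  df2 <- data.frame(gender = "other", ethnicity = "white", x = 1)
  expect_error(one_hot_encode(df2, c("gender", "ethnicity"), vocab = enc$vocab),
               "unseen")
})

test_that("min-max normalization maps, clips and degenerates as documented", {
  fitted <- fit_minmax(data.frame(x = c(0, 5, 10), y = c(2, 2, 2)), c("x", "y"))
  out <- apply_minmax(data.frame(x = c(0, 5, 10), y = c(2, 2, 2)), fitted)
  expect_equal(out$x, c(0, 0.5, 1))
  expect_equal(out$y, c(0, 0, 0))
  # held-out values outside the fitted range clip into [0, 1]
  held <- apply_minmax(data.frame(x = c(-3, 12), y = c(1, 3)), fitted)
  expect_equal(held$x, c(0, 1))
  expect_error(apply_minmax(data.frame(x = 1), structure(list(z = c(min = 0, max = 1)),
                                                         class = "minmax_params")),
               "missing")
})

test_that("preprocess_cohort runs the full chain and reports each stage", {
  coh <- generate_cohort(generator_config(300, "mimic", seed = 13,
                                          missing_sofa_rate = 0.1,
                                          outlier_rate = 0.03))
  ds <- preprocess_cohort(coh)
  expect_s3_class(ds, "hepadose_dataset")
  expect_false(anyNA(ds$rows[, ds$schema$features]))
  # implanted recording errors are (essentially all) filtered out; a x10 of a
  # weight drawn from the extreme low tail can occasionally stay inside the
  # sample's inflated 3-sigma bound, hence the 1-row slack
  n_implanted <- sum(!is.na(coh$patients$true_outlier_feature))
  expect_lte(sum(!is.na(ds$rows$true_outlier_feature)), 1)
  expect_gte(ds$report$n_outlier_removed, n_implanted - 1)
  expect_gt(ds$report$n_imputed, 0)
  # one-hot groups each sum to one
  for (g in ds$schema$groups) {
    expect_equal(rowSums(ds$rows[, g, drop = FALSE]), rep(1, nrow(ds$rows)),
                 ignore_attr = TRUE)
  }
  # pumch dialect has no ethnicity/admission columns
  ds2 <- preprocess_cohort(generate_cohort(generator_config(200, "pumch", seed = 14)))
  expect_false(any(grepl("ethnicity|admission", ds2$schema$features)))
})
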