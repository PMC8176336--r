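test_that("forward pass reduces to zero logits for an all-zero network", {
  net <- hepadose:::nn_init(4, c(3, 2), 3, seed = 1)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- 0
    net$layers[[l]]$b[] <- 0
  }
  expect_equal(as.numeric(nn_forward(net, c(1, 2, 3, 4))), c(0, 0, 0))
})

test_that("forward pass matches a hand calculation on a 2-feature toy net", {
  # one hidden unit: z = relu(2*x1 - 1*x2 + 0.5); logits = (z, -z, 3z + 1)
  net <- hepadose:::nn_init(2, 1, 3, seed = 1)
  net$layers[[1]]$W <- matrix(c(2, -1), 2, 1)
  net$layers[[1]]$b <- 0.5
  net$layers[[2]]$W <- matrix(c(1, -1, 3), 1, 3)
  net$layers[[2]]$b <- c(0, 0, 1)
  z <- max(0, 2 * 1 - 1 * 2 + 0.5)                 # x = (1, 2) -> z = 0.5
  expect_equal(as.numeric(nn_forward(net, c(1, 2))), c(z, -z, 3 * z + 1))
  # negative pre-activation is clipped by the rectifier
  expect_equal(as.numeric(nn_forward(net, c(0, 3))), c(0, 0, 1))
  # repeated evaluation is identical
  expect_identical(nn_forward(net, c(1, 2)), nn_forward(net, c(1, 2)))
  expect_error(nn_forward(net, c(1, 2, 3)), "expects")
})

test_that("forward pass agrees with the scalar-loop oracle on random tiny networks", {
  set.seed(21)
  for (rep in 1:25) {
    sizes <- c(sample(2:4, 1), sample(2:4, 2, replace = TRUE), 3)
    net <- hepadose:::nn_init(sizes[1], sizes[2:3], 3, seed = rep)
    x <- rnorm(sizes[1])
    expect_equal(as.numeric(nn_forward(net, x)),
                 oracle_forward(net$layers, x), tolerance = 1e-10)
  }
})

test_that("softmax is a shift-invariant simplex map with the printed values", {
  expect_equal(as.numeric(nn_softmax(c(0, 0, 0))), rep(1 / 3, 3))
  p <- as.numeric(nn_softmax(c(1, 2, 3)))
  expect_equal(p[2], exp(2) / (exp(1) + exp(2) + exp(3)), tolerance = 1e-12)
  expect_equal(p[2], 0.2447, tolerance = 1e-3)
  set.seed(4)
  for (i in 1:50) {
    l <- rnorm(3, sd = 10)
    expect_equal(nn_softmax(l), nn_softmax(l + rnorm(1)), tolerance = 1e-12)
    expect_equal(sum(nn_softmax(l)), 1, tolerance = 1e-12)
  }
  # overflow-safe shifting
  expect_equal(sum(nn_softmax(c(1000, 1001, 999))), 1)
  expect_error(nn_softmax(c(1, Inf, 0)), "finite")
})

test_that("stratified split keeps class proportions and is seed-deterministic", {
  labels <- rep(therapeutic_classes(), times = c(100, 100, 100))
  sp <- stratified_split(labels, 0.8, seed = 5)
  expect_equal(length(sp$train), 240)
  tab <- table(labels[sp$train])
  expect_true(all(tab == 80))
  expect_setequal(c(sp$train, sp$test), seq_along(labels))
  expect_equal(length(intersect(sp$train, sp$test)), 0)
  expect_identical(stratified_split(labels, 0.8, seed = 5), sp)

  # uneven classes: test proportions within one rounding unit of the cohort's
  labels2 <- rep(therapeutic_classes(), times = c(53, 31, 16))
  sp2 <- stratified_split(labels2, 0.8, seed = 1)
  tab2 <- table(labels2[sp2$test])   # table() is alphabetical: normal, sub, supra
  expect_true(all(abs(tab2 - 0.2 * c(31, 53, 16)) <= 1))
})

test_that("stratified folds are disjoint, exhaustive and reproducible", {
  labels <- rep(therapeutic_classes(), times = c(40, 30, 20))
  f <- make_folds(labels, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(length(f), 90)
  for (k in 1:5) {
    tab <- table(labels[f == k])     # alphabetical: normal, sub, supra
    expect_true(all(abs(tab - c(30, 40, 20) / 5) <= 1))
  }
  expect_identical(make_folds(labels, 5, seed = 3), f)
  expect_error(make_folds(rep(therapeutic_classes(), times = c(3, 30, 30)), 5), "at least")
})

test_that("training separates a linearly separable 3-class toy problem", {
  for (seed in 1:5) {
    ds <- make_toy_dataset(100, seed = 100 + seed)
    cfg <- train_config(epochs = 2000, learning_rate = 0.015, seed = seed)
    m <- train_network(ds, cfg)
    acc <- mean(predict_classes(m, ds$rows) == ds$rows$label)
    expect_gte(acc, 0.99)
  }
})

test_that("training loss is non-increasing over 100-epoch windows on the toy set", {
  ds <- make_toy_dataset(60, seed = 3)
  dm <- hepadose:::dataset_matrix(ds)
  losses <- sapply(seq(100, 600, by = 100), function(ep) {
    m <- train_network(ds, train_config(epochs = ep, seed = 7))
    P <- predict_proba(m, ds$rows)
    -mean(log(pmax(P[cbind(seq_along(dm$y), as.integer(dm$y))], 1e-300)))
  })
  expect_true(all(diff(losses) <= 1e-8))
})

test_that("training is deterministic and collapses to chance on shuffled labels", {
  ds <- make_toy_dataset(40, seed = 9)
  cfg <- train_config(epochs = 300, seed = 11)
  m1 <- train_network(ds, cfg)
  m2 <- train_network(ds, cfg)
  expect_identical(m1$net, m2$net)

  # destroy the signal: shuffle the labels of a larger cohort so the held-out
  # accuracy collapses to chance (the test set must be large enough that
  # binomial noise stays inside the band)
  ds_null <- make_toy_dataset(250, seed = 9)
  set.seed(31)
  ds_null$rows$label <- sample(ds_null$rows$label)
  sp <- stratified_split(ds_null$rows$label, 0.8, seed = 1)
  mnull <- train_network(ds_null, train_config(epochs = 500, seed = 2, momentum = 0.9, clip_norm = 0.5),
                         rows_idx = sp$train)
  acc <- mean(predict_classes(mnull, ds_null$rows[sp$test, ]) ==
                ds_null$rows$label[sp$test])
  expect_lt(abs(acc - 1 / 3), 0.08)
  expect_error(train_network(ds, cfg, rows_idx = which(ds$rows$label == "normal")),
               "single class")
})

test_that("cross-validation folds partition the cohort and detect leaked labels", {
  ds <- make_toy_dataset(50, seed = 13)
  cfg <- train_config(epochs = 300, seed = 5, cv_folds = 5, momentum = 0.9, clip_norm = 0.5)
  cv <- cross_validate(ds, cfg)
  expect_equal(sort(unique(cv$folds)), 1:5)
  expect_equal(length(cv$folds), nrow(ds$rows))
  expect_equal(nrow(cv$fold_metrics), 5)
  expect_identical(cross_validate(ds, cfg)$folds, cv$folds)

  # leaking the label as a feature forces near-perfect accuracy
  ds_leak <- ds
  ds_leak$rows$leak <- as.integer(ds$rows$label)
  ds_leak$rows$f1 <- rnorm(nrow(ds$rows))   # remove real signal from f1
  ds_leak$schema$features <- c("f1", "f2", "leak")
  ds_leak$schema$continuous <- c("f1", "f2", "leak")
  cv_leak <- cross_validate(ds_leak, cfg)
  expect_gte(unname(cv_leak$mean["accuracy"]), 0.99)
})

test_that("models survive a serialization round trip", {
  ds <- make_toy_dataset(30, seed = 17)
  m <- train_network(ds, train_config(epochs = 100, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  X <- as.matrix(ds$rows[, m$features])
  expect_equal(predict_proba(m2, X), predict_proba(m, X), tolerance = 1e-12)
  expect_equal(m2$features, m$features)
  expect_equal(m2$config$learning_rate, m$config$learning_rate)
})

test_that("exact probability ties are broken toward the normal class", {
  ds <- make_toy_dataset(10, seed = 1)
  m <- train_network(ds, train_config(epochs = 1, seed = 1))
  for (l in seq_along(m$net$layers)) {
    m$net$layers[[l]]$W[] <- 0
    m$net$layers[[l]]$b[] <- 0
  }
  pred <- predict_classes(m, ds$rows)      # all logits zero -> three-way tie
  expect_true(all(pred == "normal"))
})
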