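test_that("stratified split preserves class balance, is disjoint and seed-stable", {
  y <- rep(c(1, 0), c(10, 90))
  sp <- stratified_split(y, 0.8, seed = 4)
  expect_equal(sum(y[sp$train]), 8)
  expect_equal(length(sp$train), 80)
  expect_equal(sort(c(sp$train, sp$test)), 1:100)
  expect_equal(stratified_split(y, 0.8, seed = 4), sp)
  expect_false(identical(stratified_split(y, 0.8, seed = 5), sp))
  expect_error(stratified_split(rep(0, 50)), "unstratifiable")
  expect_error(stratified_split(c(1, rep(0, 50))), "unstratifiable")
})

test_that("scaler standardizes training columns and maps constants to zero", {
  x <- cbind(a = c(2, 4, 6), b = c(5, 5, 5))
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  expect_equal(xs[, "a"], c(-1.224744871, 0, 1.224744871),
               ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(xs[, "b"], c(0, 0, 0), ignore_attr = TRUE)

  withr::with_seed(1, big <- matrix(rpois(600, 3), 60, 10))
  scb <- fit_scaler(big)
  scaled <- apply_scaler(scb, big)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  expect_lt(max(abs(colMeans(scaled))), 1e-9)
  expect_lt(max(abs(apply(scaled, 2, pop_sd) - 1)), 1e-9)
  expect_error(apply_scaler(sc, matrix(0, 2, 3)), "feature count mismatch")
})

test_that("nested CV returns k winners; a dominant hyperparameter wins every fold", {
  fx <- small_planted()
  x <- apply_scaler(fit_scaler(as.matrix(fx$dataset$features[-1])),
                    as.matrix(fx$dataset$features[-1]))
  y <- fx$dataset$labels$class_1

  one <- nested_cv_grid_search(x, y, "LR",
                               tidyr::expand_grid(C = 1, penalty = "l2"),
                               k = 3, seed = 2)
  expect_equal(nrow(one), 3)
  expect_true(all(one$combo == 1))

  # C = 1 strictly dominates a near-zero regularization budget on a planted
  # separable signal: an l1 model at C = 1e-4 shrinks every coefficient away
  grid <- tidyr::expand_grid(C = c(1e-4, 1), penalty = "l1")
  cv <- nested_cv_grid_search(x, y, "LR", grid, k = 3, seed = 2)
  expect_equal(cv$combo, rep(2L, 3))
  expect_true(all(cv$outer_mcc > 0.8))

  # stratification arithmetic: 9 positives across 3 outer folds
  y9 <- rep(c(1, 0), c(9, 51))
  folds <- kotrait:::stratified_folds(y9, 3, seed = 1)
  expect_equal(as.integer(table(folds[y9 == 1])), c(3L, 3L, 3L))

  expect_error(nested_cv_grid_search(x, rep(c(1, 0), c(2, 58)), "LR", grid),
               "fewer folds")
  expect_error(nested_cv_grid_search(x, y, "LR", grid[0, ]), "empty")
})

test_that("all four backends learn a separable signal; errors are explicit", {
  fx <- small_planted()
  x <- as.matrix(fx$dataset$features[-1])
  y <- fx$dataset$labels$class_2
  sc <- fit_scaler(x)
  xs <- apply_scaler(sc, x)
  for (alg in c("LR", "RF", "SVM", "NN")) {
    hp <- tiny_grids()[[alg]][1, ]
    model <- train_class_model(xs, y, alg, hp, seed = 3)
    expect_equal(mcc_vec(y, predict(model, xs)), 1, tolerance = 0.05,
                 label = paste(alg, "training MCC"))
  }
  expect_error(train_class_model(xs, y, "GBM", list()), "backend missing")
})

test_that("held-out MCC stays near zero when labels are independent of features", {
  fx <- small_planted()
  x <- as.matrix(fx$dataset$features[-1])
  mccs <- vapply(1:20, function(i) {
    withr::with_seed(1000 + i, y <- sample(rep(c(1, 0), c(18, 42))))
    sp <- stratified_split(y, 0.8, seed = i)
    sc <- fit_scaler(x[sp$train, ])
    m <- train_class_model(apply_scaler(sc, x[sp$train, ]), y[sp$train],
                           "LR", list(C = 1, penalty = "l2"), seed = i)
    mcc_vec(y[sp$test], predict(m, apply_scaler(sc, x[sp$test, ])))
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.3)
  expect_true(all(abs(mccs) <= 1))
})

test_that("RF and NN fits are deterministic per seed", {
  fx <- small_planted()
  x <- apply_scaler(fit_scaler(as.matrix(fx$dataset$features[-1])),
                    as.matrix(fx$dataset$features[-1]))
  y <- fx$dataset$labels$class_1
  for (alg in c("RF", "NN")) {
    hp <- tiny_grids()[[alg]][1, ]
    m1 <- train_class_model(x, y, alg, hp, seed = 5)
    m2 <- train_class_model(x, y, alg, hp, seed = 5)
    expect_equal(predict(m1, x), predict(m2, x), label = alg)
  }
})

test_that("model selection takes the MCC argmax with the fixed tie order", {
  fx <- small_planted()
  x <- apply_scaler(fit_scaler(as.matrix(fx$dataset$features[-1])),
                    as.matrix(fx$dataset$features[-1]))
  y <- fx$dataset$labels$class_1
  mods <- tibble::tibble(
    algorithm = c("RF", "LR", "SVM"),
    model = list(
      train_class_model(x, y, "RF", tiny_grids()$RF[1, ], 1),
      train_class_model(x, y, "LR", tiny_grids()$LR[1, ], 1),
      train_class_model(x, y, "SVM", tiny_grids()$SVM[1, ], 1)
    ),
    hp = list(tiny_grids()$RF[1, ], tiny_grids()$LR[1, ], tiny_grids()$SVM[1, ])
  )
  ranked <- select_best(mods, x, y)
  expect_equal(ranked$test_mcc[1], max(ranked$test_mcc))
  # on a perfectly separable fixture all three tie at 1; LR wins the tie
  expect_equal(ranked$algorithm[1], "LR")
  expect_equal(ranked$test_mcc, sort(ranked$test_mcc, decreasing = TRUE))
})

test_that("the NN is selected where linear models fail (XOR-structured labels)", {
  withr::with_seed(9, {
    base <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
    x <- base[rep(1:4, 40), ] + matrix(rnorm(320, 0, 0.1), 160, 2)
  })
  colnames(x) <- c("a", "b")
  y <- as.integer(x[, 1] * x[, 2] > 0)
  sp <- stratified_split(y, 0.8, seed = 1)
  sc <- fit_scaler(x[sp$train, ])
  xtr <- apply_scaler(sc, x[sp$train, ])
  xte <- apply_scaler(sc, x[sp$test, ])
  cands <- tibble::tibble(
    algorithm = c("LR", "NN"),
    model = list(
      train_class_model(xtr, y[sp$train], "LR", list(C = 1, penalty = "l2"), 1),
      train_class_model(xtr, y[sp$train], "NN", list(units = 8, decay = 1e-3), 1)
    ),
    hp = list(list(C = 1, penalty = "l2"), list(units = 8, decay = 1e-3))
  )
  ranked <- select_best(cands, xte, y[sp$test])
  expect_equal(ranked$algorithm[1], "NN")
  expect_gt(ranked$test_mcc[1], 0.9)
  expect_lt(ranked$test_mcc[ranked$algorithm == "LR"], 0.5)
})

test_that("registry training produces one bundle per class with honest manifests", {
  fx <- small_planted()
  cfg <- trait_config(seed = 2, algorithms = c("LR", "SVM"), grids = tiny_grids())
  reg <- suppressMessages(train_registry(fx$dataset, cfg))
  expect_named(reg$bundles, fx$dataset$class_names)
  td <- tidy(reg)
  expect_true(all(td$test_mcc >= 0.9))
  expect_equal(reg$manifest$dataset_hash, dataset_hash(fx$dataset))
  expect_equal(glance(reg)$n_classes, 2)

  # an unstratifiable class is skipped with a reason, not fatal
  labels2 <- fx$dataset$labels
  labels2$rare <- c(1L, rep(0L, nrow(labels2) - 1))
  ds2 <- trait_dataset(fx$dataset$features, labels2)
  expect_message(reg2 <- train_registry(ds2, cfg), "skipping class 'rare'")
  expect_false("rare" %in% names(reg2$bundles))
  expect_true("rare" %in% reg2$manifest$skipped)
})

test_that("no test-set leakage: test labels never touch scaler or model", {
  fx <- small_planted()
  x <- as.matrix(fx$dataset$features[-1])
  y <- fx$dataset$labels$class_1
  sp <- stratified_split(y, 0.8, seed = 6)
  fit_with_test_labels <- function(y_test) {
    yy <- y
    yy[sp$test] <- y_test
    sc <- fit_scaler(x[sp$train, ])
    m <- train_class_model(apply_scaler(sc, x[sp$train, ]), yy[sp$train],
                           "LR", list(C = 1, penalty = "l2"), seed = 6)
    list(scaler = sc, coefs = as.numeric(coef(m$fit)))
  }
  a <- fit_with_test_labels(y[sp$test])
  b <- fit_with_test_labels(withr::with_seed(1, sample(y[sp$test])))
  expect_identical(a$scaler, b$scaler)
  expect_identical(a$coefs, b$coefs)
})

test_that("registry round-trips through disk with identical predictions", {
  fx <- small_planted()
  cfg <- trait_config(seed = 2, algorithms = c("LR", "RF"), grids = tiny_grids())
  reg <- suppressMessages(train_registry(fx$dataset, cfg))
  dir <- withr::local_tempdir()
  persist_registry(reg, dir)
  back <- load_registry(dir)
  expect_equal(back$manifest$dataset_hash, reg$manifest$dataset_hash)
  expect_equal(back$manifest$seed, reg$manifest$seed)

  queries <- dataset_queries(fx$dataset)
  suppressMessages({
    r1 <- predict_functions(reg, queries)
    r2 <- predict_functions(back, queries)
  })
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  # corruption and version mismatch fail loudly
  writeLines("garbage", file.path(dir, "registry.rds"))
  expect_error(load_registry(dir), "corrupted")
  expect_error(load_registry(withr::local_tempdir()), "no registry")
})
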