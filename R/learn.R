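# Per-class classifier training: stratified splitting, per-class
# standardization, nested cross-validated grid search, the four model
# backends, MCC-based selection and registry assembly.

#' Training configuration
#'
#' @param seed Global seed propagated to the split, CV folds, random forest
#'   and neural-network initialization.
#' @param train_fraction Fraction of genomes in the training split.
#' @param folds Folds for both the outer and inner cross-validation loops.
#' @param min_positives Minimum positives for a class to be trained.
#' @param mcc_success_threshold MCC above which a classifier is flagged
#'   successful in reports.
#' @param algorithms Algorithms to tune per class, among `"LR"`, `"RF"`,
#'   `"SVM"`, `"NN"`.
#' @param grids Named list of hyperparameter grids (tibbles), as from
#'   [default_grids()]; any entry may be overridden.
#' @param nn_repeats Restarts of the neural-network tuning (best kept).
#' @return A `trait_config` list.
#' @export
trait_config <- function(seed = 1,
                         train_fraction = 0.8,
                         folds = 3,
                         min_positives = 3,
                         mcc_success_threshold = 0.7,
                         algorithms = c("LR", "RF", "SVM", "NN"),
                         grids = default_grids(),
                         nn_repeats = 5) {
  algorithms <- match.arg(algorithms, c("LR", "RF", "SVM", "NN"), several.ok = TRUE)
  structure(
    list(
      seed = as.integer(seed), train_fraction = train_fraction,
      folds = as.integer(folds), min_positives = as.integer(min_positives),
      mcc_success_threshold = mcc_success_threshold,
      algorithms = algorithms, grids = grids, nn_repeats = as.integer(nn_repeats)
    ),
    class = "trait_config"
  )
}

#' Default hyperparameter grids
#'
#' Logistic regression tunes regularization strength C and penalty; random
#' forest the number of trees and the feature-subset rule; SVM the kernel
#' and C; the neural network the hidden-layer width and weight decay.
#'
#' @return Named list of tibbles, one per algorithm.
#' @export
default_grids <- function() {
  list(
    LR = tidyr::expand_grid(C = c(0.01, 0.1, 1, 10, 100), penalty = c("l1", "l2")),
    RF = tidyr::expand_grid(n_trees = c(100, 300, 500), max_features_rule = c("sqrt", "log2")),
    SVM = tidyr::expand_grid(kernel = c("linear", "rbf"), C = c(0.1, 1, 10)),
    NN = tidyr::expand_grid(units = c(2, 8, 16), decay = c(1e-3, 1e-2, 1e-1))
  )
}

#' Stratified train/test split
#'
#' Samples each label stratum separately so the positive proportion in the
#' two splits differs from the overall one by at most one genome; disjoint,
#' exhaustive, deterministic per seed.
#'
#' @param labels Binary label vector for one class.
#' @param train_fraction Fraction assigned to training.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(labels, train_fraction = 0.8, seed = 1) {
  labels <- as.integer(labels)
  stopf(sum(labels == 1) >= 2, "unstratifiable class: fewer than 2 positives")
  stopf(sum(labels == 0) >= 2, "unstratifiable class: fewer than 2 negatives")
  withr::with_seed(seed, {
    train <- unlist(lapply(c(0L, 1L), function(s) {
      idx <- which(labels == s)
      sample(idx, round(train_fraction * length(idx)))
    }), use.names = FALSE)
  })
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}

# Stratified fold assignment (1..k) for a binary label vector.
stratified_folds <- function(labels, k, seed) {
  stopf(sum(labels == 1) >= k,
        "a fold would hold zero positives; use fewer folds or exclude the class")
  folds <- integer(length(labels))
  withr::with_seed(seed, {
    for (s in c(0L, 1L)) {
      idx <- sample(which(labels == s))
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Fit per-feature standardization parameters
#'
#' Fit only on the training partition.  Uses the population standard
#' deviation (divisor n), the usual convention for feature standardization,
#' so a column (2, 4, 6) maps to (-1.2247, 0, 1.2247).  Constant columns
#' store a standard deviation of 1 so scaling maps them to 0 rather than
#' NaN.
#'
#' @param x Numeric training matrix (genomes x features).
#' @return A `scaler_params` list with `mean` and `sd` aligned to columns.
#' @export
fit_scaler <- function(x) {
  m <- colMeans(x)
  s <- sqrt(colMeans(sweep(x, 2, m, "-")^2))
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = m, sd = s), class = "scaler_params")
}

#' Apply standardization parameters
#'
#' @param scaler A `scaler_params`.
#' @param x Numeric matrix with the same columns the scaler was fit on.
#' @return Matrix of z-scores (constant training columns map to 0).
#' @export
apply_scaler <- function(scaler, x) {
  stopf(ncol(x) == length(scaler$mean),
        "feature count mismatch: scaler has %d, data has %d",
        length(scaler$mean), ncol(x))
  sweep(sweep(x, 2, scaler$mean, "-"), 2, scaler$sd, "/")
}

rf_mtry <- function(rule, p) {
  switch(rule,
    sqrt = max(1L, floor(sqrt(p))),
    log2 = max(1L, floor(log2(p))),
    rlang::abort(sprintf("unknown max_features_rule: %s", rule))
  )
}

#' Fit one binary classifier
#'
#' Backends: logistic regression via glmnet (C and l1/l2 penalty mapped to
#' a single-lambda elastic net, lambda = 1/(C n)); random forest via ranger
#' (impurity importance retained); SVM via e1071 (linear or RBF kernel);
#' neural network via nnet (one hidden layer, logistic output,
#' cross-entropy, weight-decay regularization).  Probabilistic backends
#' decide at probability 0.5.
#'
#' @param x Scaled numeric feature matrix.
#' @param y Binary label vector.
#' @param algorithm One of `"LR"`, `"RF"`, `"SVM"`, `"NN"`.
#' @param hp One-row tibble (or list) of hyperparameters for that algorithm.
#' @param seed Integer seed (RF bootstrap, NN initialization).
#' @return A `trait_model`.
#' @export
train_class_model <- function(x, y, algorithm, hp, seed = 1) {
  y <- as.integer(y)
  hp <- as.list(hp)
  colnames(x) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  fit <- switch(algorithm,
    # glmnet warns about small classes on every inner-CV fit of a rare
    # trait; that is the expected regime here, so silence just that warning
    LR = withCallingHandlers(
      glmnet::glmnet(
        x, factor(y, levels = c(0, 1)), family = "binomial",
        alpha = if (hp$penalty == "l1") 1 else 0,
        lambda = 1 / (hp$C * nrow(x)), standardize = FALSE
      ),
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    ),
    RF = ranger::ranger(
      x = as.data.frame(x), y = factor(y, levels = c(0, 1)),
      num.trees = hp$n_trees, mtry = rf_mtry(hp$max_features_rule, ncol(x)),
      probability = TRUE, importance = "impurity",
      seed = seed, num.threads = 1
    ),
    SVM = e1071::svm(
      x = x, y = factor(y, levels = c(0, 1)),
      kernel = if (hp$kernel == "rbf") "radial" else hp$kernel,
      cost = hp$C, scale = FALSE
    ),
    NN = withr::with_seed(seed, nnet::nnet(
      x = x, y = y, size = hp$units, decay = hp$decay,
      entropy = TRUE, maxit = 200, MaxNWts = 20000, trace = FALSE
    )),
    rlang::abort(sprintf("backend missing for algorithm '%s'", algorithm))
  )
  structure(
    list(algorithm = algorithm, fit = fit, hp = hp,
         features = colnames(x), decision_threshold = 0.5),
    class = "trait_model"
  )
}

#' Binary calls from a fitted trait model
#'
#' @param object A `trait_model`.
#' @param newdata Scaled feature matrix with the training columns.
#' @param ... Unused.
#' @return Integer vector of 0/1 calls.
#' @export
predict.trait_model <- function(object, newdata, ...) {
  colnames(newdata) <- colnames(newdata) %||% object$features
  thr <- object$decision_threshold
  switch(object$algorithm,
    LR = as.integer(predict(object$fit, newdata, type = "response")[, 1] >= thr),
    RF = as.integer(predict(object$fit, as.data.frame(newdata),
                            num.threads = 1)$predictions[, "1"] >= thr),
    SVM = as.integer(as.character(predict(object$fit, newdata)) == "1"),
    NN = as.integer(predict(object$fit, newdata)[, 1] >= thr)
  )
}

# Fit + score one hp combination on a train/validation split.
score_hp <- function(x_tr, y_tr, x_va, y_va, algorithm, hp, seed) {
  model <- train_class_model(x_tr, y_tr, algorithm, hp, seed)
  mcc_vec(y_va, predict(model, x_va))
}

#' Nested cross-validated grid search
#'
#' For each of k outer folds, an inner k-fold grid search picks the
#' hyperparameter combination with the highest inner mean MCC (ties go to
#' the first combination in grid order); that winner is refit on the outer
#' training portion and scored on the held-out outer fold.  The outer loop
#' thus estimates generalization without tuning leakage.
#'
#' @param x Scaled training feature matrix.
#' @param y Binary training labels.
#' @param algorithm Backend name.
#' @param grid Tibble of hyperparameter combinations.
#' @param k Folds for both loops (default 3).
#' @param seed Integer seed.
#' @return Tibble with one row per outer fold: `fold`, `combo` (grid row
#'   index), `hp` (list column), `inner_mean_mcc`, `outer_mcc`.
#' @export
nested_cv_grid_search <- function(x, y, algorithm, grid, k = 3, seed = 1) {
  stopf(nrow(grid) >= 1, "empty hyperparameter grid")
  y <- as.integer(y)
  outer <- stratified_folds(y, k, seed)
  rows <- lapply(seq_len(k), function(f) {
    tr <- which(outer != f)
    te <- which(outer == f)
    inner <- stratified_folds(y[tr], k, seed + f)
    inner_scores <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(k), function(j) {
        it <- tr[inner != j]
        iv <- tr[inner == j]
        score_hp(x[it, , drop = FALSE], y[it], x[iv, , drop = FALSE], y[iv],
                 algorithm, grid[g, ], seed)
      }, numeric(1)))
    }, numeric(1))
    best <- which.max(inner_scores) # ties -> first in grid order
    outer_mcc <- score_hp(x[tr, , drop = FALSE], y[tr],
                          x[te, , drop = FALSE], y[te],
                          algorithm, grid[best, ], seed)
    tibble::tibble(
      fold = f, combo = best, hp = list(as.list(grid[best, ])),
      inner_mean_mcc = inner_scores[[best]], outer_mcc = outer_mcc
    )
  })
  dplyr::bind_rows(rows)
}

# Final hp choice from the k nested-CV winners: highest outer MCC, ties by
# highest inner mean, then grid order.
choose_hp <- function(cv_results) {
  ord <- order(-cv_results$outer_mcc, -cv_results$inner_mean_mcc, cv_results$combo)
  cv_results$hp[[ord[[1]]]]
}

# Repeated-restart tuning for the neural network: hyperparameters are
# scored on a stratified validation slice of the training split (the test
# split is never touched), the whole search is restarted `repeats` times
# and the best (combo, restart) pair wins.
tune_nn <- function(x, y, grid, repeats, seed) {
  split <- stratified_split(y, 0.8, seed + 17)
  best <- list(score = -Inf, hp = NULL, seed = seed)
  for (r in seq_len(repeats)) {
    for (g in seq_len(nrow(grid))) {
      s <- seed + 1000L * r + g
      score <- score_hp(
        x[split$train, , drop = FALSE], y[split$train],
        x[split$test, , drop = FALSE], y[split$test],
        "NN", grid[g, ], s
      )
      if (score > best$score) best <- list(score = score, hp = as.list(grid[g, ]), seed = s)
    }
  }
  best
}

ALGO_PREFERENCE <- c(LR = 1, SVM = 2, RF = 3, NN = 4)

#' Select the best candidate model by held-out MCC
#'
#' Each candidate (already refit on the full training split with its chosen
#' hyperparameters) is scored on the held-out test split; the argmax wins.
#' Exact ties break by a fixed preference order LR > SVM > RF > NN, which
#' favors models whose feature importances are directly interpretable.
#'
#' @param candidates Tibble with columns `algorithm`, `model` (list of
#'   `trait_model`), `hp` (list).
#' @param x_test,y_test Scaled held-out features and labels.
#' @return The `candidates` tibble with a `test_mcc` column, ordered best
#'   first.
#' @export
select_best <- function(candidates, x_test, y_test) {
  candidates$test_mcc <- vapply(candidates$model, function(m) {
    mcc_vec(y_test, predict(m, x_test))
  }, numeric(1))
  ord <- order(-candidates$test_mcc, ALGO_PREFERENCE[candidates$algorithm])
  candidates[ord, , drop = FALSE]
}

# Train one class end to end; returns a classifier_bundle.
train_one_class <- function(dataset, class_name, config) {
  y <- as.integer(dataset$labels[[class_name]])
  x <- feature_mat(dataset)
  split <- stratified_split(y, config$train_fraction, config$seed)
  scaler <- fit_scaler(x[split$train, , drop = FALSE])
  x_tr <- apply_scaler(scaler, x[split$train, , drop = FALSE])
  x_te <- apply_scaler(scaler, x[split$test, , drop = FALSE])
  y_tr <- y[split$train]
  y_te <- y[split$test]
  candidates <- dplyr::bind_rows(lapply(config$algorithms, function(alg) {
    if (alg == "NN") {
      tuned <- tune_nn(x_tr, y_tr, config$grids$NN, config$nn_repeats, config$seed)
      hp <- tuned$hp
      fit_seed <- tuned$seed
    } else {
      cv <- nested_cv_grid_search(x_tr, y_tr, alg, config$grids[[alg]],
                                  k = config$folds, seed = config$seed)
      hp <- choose_hp(cv)
      fit_seed <- config$seed
    }
    model <- train_class_model(x_tr, y_tr, alg, hp, fit_seed)
    tibble::tibble(algorithm = alg, model = list(model),
                   hp = list(hp), fit_seed = fit_seed)
  }))
  ranked <- select_best(candidates, x_te, y_te)
  structure(
    list(
      class_name = class_name,
      algorithm = ranked$algorithm[[1]],
      hp = ranked$hp[[1]],
      scaler = scaler,
      model = ranked$model[[1]],
      feature_order = dataset$feature_order,
      test_mcc = ranked$test_mcc[[1]],
      decision_threshold = 0.5,
      train_idx = split$train,
      test_idx = split$test,
      seed = config$seed,
      alternatives = tibble::tibble(
        algorithm = ranked$algorithm, test_mcc = ranked$test_mcc,
        hp = ranked$hp, fit_seed = ranked$fit_seed
      )
    ),
    class = "classifier_bundle"
  )
}

#' @exportS3Method base::print
print.classifier_bundle <- function(x, ...) {
  cat(sprintf("<classifier_bundle> %s: %s, test MCC %.3f\n",
              x$class_name, x$algorithm, x$test_mcc))
  invisible(x)
}

#' Train one classifier per functional class
#'
#' For every class in the dataset: stratified 80/20 split, per-class scaler
#' fit on the training split, nested cross-validated grid search per
#' algorithm (repeated-restart tuning for the neural network), refit on the
#' full training split, and MCC-based selection on the held-out test split.
#' Classes that cannot be trained (e.g. unstratifiable) are skipped with a
#' logged reason rather than aborting the run.
#'
#' @param dataset A `trait_dataset` (already through [filter_classes()]).
#' @param config A [trait_config()].
#' @return A `model_registry`: bundles keyed by class plus a training
#'   manifest (dataset hash, seed, config).
#' @export
train_registry <- function(dataset, config = trait_config()) {
  stopf(inherits(dataset, "trait_dataset"), "not a trait_dataset")
  bundles <- list()
  skipped <- character()
  for (cl in dataset$class_names) {
    res <- tryCatch(train_one_class(dataset, cl, config), error = function(e) e)
    if (inherits(res, "error")) {
      rlang::inform(sprintf("skipping class '%s': %s", cl, conditionMessage(res)))
      skipped <- c(skipped, cl)
    } else {
      bundles[[cl]] <- res
    }
  }
  stopf(length(bundles) > 0, "no class could be trained")
  structure(
    list(
      bundles = bundles,
      manifest = list(
        version = REGISTRY_VERSION,
        created = format(Sys.time(), tz = "UTC"),
        seed = config$seed,
        config = unclass(config)[setdiff(names(config), "grids")],
        grids = lapply(config$grids, as.data.frame),
        dataset_hash = dataset_hash(dataset),
        feature_order = dataset$feature_order,
        skipped = skipped
      )
    ),
    class = "model_registry"
  )
}

REGISTRY_VERSION <- "1"

#' @exportS3Method base::print
print.model_registry <- function(x, ...) {
  cat(sprintf("<model_registry> %d classifiers (seed %d)\n",
              length(x$bundles), x$manifest$seed))
  invisible(x)
}

#' One row per trained classifier
#'
#' @param x A `model_registry`.
#' @param ... Unused.
#' @return Tibble with class, selected algorithm, test MCC and a success
#'   flag at the configured threshold.
#' @export
tidy.model_registry <- function(x, ...) {
  thr <- x$manifest$config$mcc_success_threshold %||% 0.7
  tibble::tibble(
    class = names(x$bundles),
    algorithm = vapply(x$bundles, function(b) b$algorithm, character(1)),
    test_mcc = vapply(x$bundles, function(b) b$test_mcc, numeric(1)),
    successful = vapply(x$bundles, function(b) b$test_mcc > thr, logical(1))
  )
}

#' Registry-level summary
#'
#' @param x A `model_registry`.
#' @param ... Unused.
#' @export
glance.model_registry <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_classes = nrow(td),
    mean_test_mcc = mean(td$test_mcc),
    n_successful = sum(td$successful),
    n_skipped = length(x$manifest$skipped)
  )
}

#' Persist / load a model registry
#'
#' The registry is written as a directory holding a JSON manifest and a
#' serialized bundle store; loading verifies the artifact version and
#' reproduces bit-for-bit predictions for deterministic backends.
#'
#' @param registry A `model_registry`.
#' @param path Directory to create or read.
#' @return `load_registry()` returns the `model_registry`;
#'   `persist_registry()` returns `path` invisibly.
#' @export
persist_registry <- function(registry, path) {
  stopf(inherits(registry, "model_registry"), "not a model_registry")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    registry$manifest[setdiff(names(registry$manifest), "grids")],
    file.path(path, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  saveRDS(registry, file.path(path, "registry.rds"))
  invisible(path)
}

#' @rdname persist_registry
#' @export
load_registry <- function(path) {
  rds <- file.path(path, "registry.rds")
  stopf(file.exists(rds), "no registry at %s", path)
  registry <- tryCatch(readRDS(rds), error = function(e) {
    rlang::abort(sprintf("corrupted registry at %s: %s", path, conditionMessage(e)))
  })
  stopf(inherits(registry, "model_registry"), "corrupted registry at %s", path)
  stopf(identical(registry$manifest$version, REGISTRY_VERSION),
        "registry version %s does not match code version %s",
        registry$manifest$version, REGISTRY_VERSION)
  registry
}
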