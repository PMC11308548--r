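# Applying a trained registry to query genomes: feature-space alignment,
# prediction, evaluation against known labels, superclass aggregation and
# extraction of function-associated genes from the fitted models.

#' Align a query KO vector to a registry's feature space
#'
#' KOs absent from the query score 0; query KOs outside the training
#' feature space are dropped (their count is reported via a message so the
#' loss is visible); output order follows `feature_order` regardless of the
#' input order.
#'
#' @param query KO vector tibble (`ko`, `count`).
#' @param feature_order Character vector of training KO ids.
#' @return Numeric vector of length `length(feature_order)`.
#' @export
align_features <- function(query, feature_order) {
  v <- setNames(numeric(length(feature_order)), feature_order)
  hit <- query$ko %in% feature_order
  if (any(!hit)) {
    rlang::inform(sprintf("%d query KO(s) outside the training feature space dropped",
                          sum(!hit)))
  }
  if (any(hit)) {
    agg <- tapply(query$count[hit], query$ko[hit], sum)
    v[names(agg)] <- as.numeric(agg)
  }
  unname(v)
}

# Queries (list of KO tibbles or one long tibble) -> genomes x feature_order
# matrix with genome_id rownames.
align_query_matrix <- function(queries, feature_order) {
  if (is.data.frame(queries)) {
    queries <- split(queries[c("ko", "count")], queries$genome_id)
  }
  ids <- names(queries)
  if (is.null(ids)) {
    ids <- vapply(queries, function(q) unique(q$genome_id)[1], character(1))
  }
  stopf(!anyDuplicated(ids), "duplicate query genome ids")
  m <- do.call(rbind, lapply(queries, align_features, feature_order = feature_order))
  rownames(m) <- ids
  m
}

#' Predict functional traits for query genomes
#'
#' For each class the query matrix is aligned to the registry's feature
#' space, standardized with that class's scaler and passed to its fitted
#' model.  A genome may be positive for none or many classes.
#'
#' @param registry A `model_registry`.
#' @param queries Named list of KO vector tibbles (names are genome ids) or
#'   one long tibble with `genome_id`, `ko`, `count`.
#' @return A `prediction_report`: tibble with `genome_id` plus one 0/1
#'   column per class.
#' @export
predict_functions <- function(registry, queries) {
  stopf(inherits(registry, "model_registry"), "not a model_registry")
  stopf(length(registry$bundles) > 0, "empty registry")
  feats <- registry$manifest$feature_order
  m <- align_query_matrix(queries, feats)
  calls <- tibble::tibble(genome_id = rownames(m))
  for (cl in names(registry$bundles)) {
    b <- registry$bundles[[cl]]
    xs <- apply_scaler(b$scaler, m)
    calls[[cl]] <- predict(b$model, xs)
  }
  structure(calls, class = c("prediction_report", class(calls)))
}

#' Evaluate predictions against known labels
#'
#' Classes are intersected between the report and the truth table; genomes
#' must match exactly.  Classes with zero truth positives get their
#' confusion matrix but an `NA` MCC by default, since the statistic is
#' uninformative there; `strict_zero = TRUE` reports 0 instead for
#' compatibility with tools that use that convention.
#'
#' @param report A `prediction_report` (or calls tibble).
#' @param truth Tibble with `genome_id` plus 0/1 truth columns.
#' @param strict_zero Report MCC 0 (not NA) for zero-positive classes.
#' @return Tibble with `class`, `tp`, `fp`, `fn`, `tn`, `mcc`.
#' @export
evaluate_predictions <- function(report, truth, strict_zero = FALSE) {
  missing <- setdiff(report$genome_id, truth$genome_id)
  stopf(length(missing) == 0, "genomes missing from truth: %s",
        paste(missing, collapse = ", "))
  truth <- truth[match(report$genome_id, truth$genome_id), , drop = FALSE]
  classes <- intersect(setdiff(names(report), "genome_id"),
                       setdiff(names(truth), "genome_id"))
  stopf(length(classes) > 0, "no classes shared between report and truth")
  rows <- lapply(classes, function(cl) {
    cc <- confusion_counts(truth[[cl]], report[[cl]])
    mcc <- if (cc[["tp"]] + cc[["fn"]] == 0 && !strict_zero) {
      NA_real_
    } else {
      compute_mcc(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]])
    }
    tibble::tibble(class = cl, tp = cc[["tp"]], fp = cc[["fp"]],
                   fn = cc[["fn"]], tn = cc[["tn"]], mcc = mcc)
  })
  dplyr::bind_rows(rows)
}

#' The seven default superclass names
#'
#' Functional classes are conventionally grouped into seven biological
#' superclasses; a handful of idiosyncratic functions stay ungrouped.
#'
#' @export
superclass_names <- function() {
  c("carbon metabolism", "nitrogen metabolism", "sulfur metabolism",
    "parasites or symbionts", "phototrophy", "arsenic ions metabolism",
    "metals metabolisms")
}

#' Aggregate per-class evaluations into superclasses
#'
#' Member-class confusion counts are pooled (summed) per superclass and a
#' single MCC is computed on the pooled confusion, giving a biologically
#' contextualized performance value.  Functions absent from the map are
#' ungrouped and excluded; superclasses with no member present are skipped
#' with a warning.
#'
#' @param evaluation Tibble from [evaluate_predictions()].
#' @param map Tibble with `class` and `superclass` columns.
#' @return Tibble with `superclass`, pooled `tp`, `fp`, `fn`, `tn`, `mcc`.
#' @export
aggregate_superclasses <- function(evaluation, map) {
  merged <- dplyr::inner_join(evaluation, map, by = "class")
  absent <- setdiff(unique(map$superclass), merged$superclass)
  if (length(absent) > 0) {
    rlang::warn(sprintf("superclass(es) with no member present skipped: %s",
                        paste(absent, collapse = ", ")))
  }
  pooled <- dplyr::summarise(
    dplyr::group_by(merged, .data$superclass),
    tp = sum(.data$tp), fp = sum(.data$fp),
    fn = sum(.data$fn), tn = sum(.data$tn),
    .groups = "drop"
  )
  pooled$mcc <- purrr::pmap_dbl(
    pooled[c("tp", "fp", "fn", "tn")],
    function(tp, fp, fn, tn) compute_mcc(tp, fp, fn, tn)
  )
  pooled
}

# Signed importance scores (named by feature) for a fitted trait model.
model_scores <- function(model) {
  switch(model$algorithm,
    LR = {
      co <- as.matrix(coef(model$fit))[, 1]
      setNames(co[-1], model$features)
    },
    RF = ranger::importance(model$fit),
    SVM = {
      stopf(model$hp$kernel == "linear",
            "importance needs a linear kernel; retrain a linear surrogate first")
      w <- t(model$fit$coefs) %*% model$fit$SV
      # e1071 orders levels 0 then 1, so the hyperplane points toward the
      # negative class; flip so positive scores favor the positive class
      setNames(-as.numeric(w), model$features)
    },
    rlang::abort(sprintf("no direct importance for algorithm '%s'", model$algorithm))
  )
}

#' Extract function-associated genes from a classifier
#'
#' Model-dependent scores: logistic-regression coefficients; random-forest
#' impurity importances; linear-SVM hyperplane weights.  For an RBF-kernel
#' SVM a linear-kernel SVM is retrained on the same training split purely
#' for importance; for a neural network the class's second-best classical
#' model (by held-out MCC) is retrained and used.  Either surrogate is
#' flagged in the `source_algorithm` attribute.  Zero scores are filtered;
#' when more rows than `max_rows` survive, only the top and bottom
#' `trunc_fraction` of the signed-score ranking are kept.
#'
#' @param bundle A `classifier_bundle`.
#' @param dataset The `trait_dataset` the bundle was trained on (needed
#'   when a surrogate must be retrained).
#' @param max_rows Row count above which the table is truncated.
#' @param trunc_fraction Fraction kept at each extreme when truncating.
#' @return Tibble `ko`, `score`, `rank` (by decreasing absolute score) with
#'   attributes `class_name` and `source_algorithm`.
#' @export
extract_importance <- function(bundle, dataset = NULL,
                               max_rows = 1000, trunc_fraction = 0.1) {
  stopf(inherits(bundle, "classifier_bundle"), "not a classifier_bundle")
  source_algorithm <- bundle$algorithm
  model <- bundle$model

  retrain <- function(algorithm, hp, seed) {
    stopf(!is.null(dataset),
          "dataset needed to retrain a surrogate model for importance")
    x <- feature_mat(dataset)[bundle$train_idx, , drop = FALSE]
    y <- as.integer(dataset$labels[[bundle$class_name]][bundle$train_idx])
    train_class_model(apply_scaler(bundle$scaler, x), y, algorithm, hp, seed)
  }

  if (bundle$algorithm == "NN") {
    alt <- bundle$alternatives[bundle$alternatives$algorithm != "NN", , drop = FALSE]
    stopf(nrow(alt) > 0, "no classical model available for the NN fallback")
    model <- retrain(alt$algorithm[[1]], alt$hp[[1]], alt$fit_seed[[1]])
    source_algorithm <- alt$algorithm[[1]]
  }
  if (model$algorithm == "SVM" && model$hp$kernel != "linear") {
    model <- retrain("SVM", utils::modifyList(model$hp, list(kernel = "linear")),
                     bundle$seed %||% 1)
    source_algorithm <- "SVM(linear surrogate)"
  }
  scores <- model_scores(model)
  scores <- scores[scores != 0]
  out <- tibble::tibble(ko = names(scores), score = as.numeric(scores))
  if (nrow(out) > max_rows) {
    keep <- max(1L, floor(trunc_fraction * nrow(out)))
    ord <- order(out$score, decreasing = TRUE)
    out <- out[sort(unique(c(head(ord, keep), tail(ord, keep)))), , drop = FALSE]
  }
  out <- out[order(-abs(out$score)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  attr(out, "class_name") <- bundle$class_name
  attr(out, "source_algorithm") <- source_algorithm
  out
}
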