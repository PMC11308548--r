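# User-curated refinement of a functional class: replace (or create) one
# class's positive set from user-supplied annotated genomes, with
# conflict-removal semantics so no genome is ever both a positive and a
# negative example of the refined class.

#' Build a refined trait dataset around one curated class
#'
#' Semantics: (1) if `class_name` already exists, all of its previous
#' positives become negatives for that class; (2) a user genome already
#' present in the base dataset is removed from the base rows and re-enters
#' only as a new-class positive, so it cannot sit on both sides of the
#' class; (3) holdout genomes are removed from every row (e.g. kept aside
#' for validation); (4) KOs of the new genomes outside the base feature
#' space are appended as new columns, zero elsewhere.  New genomes default
#' to label 0 for every other class; a message lists the other classes so a
#' label override can be supplied when that default is wrong.
#'
#' @param base A `trait_dataset`.
#' @param class_name Name of the class to refine or create.
#' @param new_vectors Named list of KO vector tibbles (names are genome
#'   ids) for the curated positive genomes, e.g. from
#'   [parse_annotation_table()].
#' @param holdout_ids Genome ids excluded from the refined dataset
#'   entirely.
#' @param min_positives Minimum positives the refined class must keep.
#' @return A `trait_dataset` with the refined class.
#' @export
build_refined_dataset <- function(base, class_name, new_vectors,
                                  holdout_ids = character(),
                                  min_positives = 3) {
  stopf(inherits(base, "trait_dataset"), "not a trait_dataset")
  stopf(length(new_vectors) > 0, "new_positive_genomes must be non-empty")
  new_ids <- names(new_vectors)
  stopf(!is.null(new_ids) && all(nzchar(new_ids)), "new_vectors must be named by genome id")
  stopf(length(intersect(new_ids, holdout_ids)) == 0,
        "holdout ids overlap the provided positives: %s",
        paste(intersect(new_ids, holdout_ids), collapse = ", "))

  features <- base$features
  labels <- base$labels
  drop <- union(holdout_ids, new_ids)
  keep <- !features$genome_id %in% drop
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep, , drop = FALSE]

  if (class_name %in% base$class_names) {
    labels[[class_name]] <- 0L # previous positives become negatives
  } else {
    labels[[class_name]] <- 0L
    other <- setdiff(base$class_names, class_name)
    if (length(other) > 0) {
      rlang::inform(sprintf(
        "new genomes default to label 0 for the %d other class(es); supply a label override if any should be positive",
        length(other)
      ))
    }
  }

  long <- dplyr::bind_rows(lapply(new_ids, function(id) {
    v <- new_vectors[[id]]
    tibble::tibble(genome_id = id, ko = v$ko, count = as.integer(v$count))
  }))
  new_kos <- setdiff(unique(long$ko), base$feature_order)
  for (k in new_kos) features[[k]] <- 0L
  order_all <- c("genome_id", base$feature_order, new_kos)
  new_rows <- tibble::tibble(genome_id = new_ids)
  for (k in c(base$feature_order, new_kos)) new_rows[[k]] <- 0L
  if (nrow(long) > 0) {
    for (i in seq_len(nrow(long))) {
      new_rows[match(long$genome_id[[i]], new_ids), long$ko[[i]]] <- long$count[[i]]
    }
  }
  features <- dplyr::bind_rows(features[order_all], new_rows[order_all])

  new_labels <- tibble::tibble(genome_id = new_ids)
  for (cl in setdiff(names(labels), "genome_id")) new_labels[[cl]] <- 0L
  new_labels[[class_name]] <- 1L
  labels <- dplyr::bind_rows(labels, new_labels)

  refined <- trait_dataset(features, labels)
  stopf(sum(refined$labels[[class_name]]) >= min_positives,
        "refined class '%s' has fewer than %d positives", class_name, min_positives)
  refined
}

#' Train a refined classifier for one class
#'
#' Runs the standard training path ([train_registry()] semantics) on the
#' refined dataset, restricted to the refined class, and returns that
#' class's bundle.  The bundle carries the refined feature order and can be
#' used standalone or merged into an existing registry; query genomes are
#' aligned by the usual feature-alignment semantics.
#'
#' @param refined A `trait_dataset` from [build_refined_dataset()].
#' @param class_name The refined class.
#' @param config A [trait_config()].
#' @return A `classifier_bundle`.
#' @export
train_refined_classifier <- function(refined, class_name, config = trait_config()) {
  stopf(class_name %in% refined$class_names,
        "class '%s' not present in the refined dataset", class_name)
  train_one_class(refined, class_name, config)
}
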