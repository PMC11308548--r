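# Assembly of the training dataset: KO copy-number feature matrix from
# eggNOG-mapper-style annotation tables, and the binary genome-by-function
# label matrix propagated down the taxonomy from taxon-function memberships.

KO_PATTERN <- "^K\\d{5}$"

#' Parse an eggNOG-mapper-style annotation table into KO copy numbers
#'
#' The table is tab-delimited, one row per gene, with a `KEGG_ko` column
#' holding `-`, a single K-number, or a comma-separated list of K-numbers
#' prefixed `ko:`.  Each listed K-number increments that KO's copy number by
#' one (a gene listing n KOs contributes one copy to each).  Header and
#' comment lines (leading `#`) are skipped; the last `#`-header before the
#' data names the columns.
#'
#' @param file Path to the annotation table.
#' @param genome_id Genome identifier; defaults to the file name without
#'   extension.
#' @return Tibble with columns `genome_id`, `ko`, `count` (a "KO vector").
#' @export
parse_annotation_table <- function(file, genome_id = NULL) {
  stopf(file.exists(file), "cannot read annotation file: %s", file)
  genome_id <- genome_id %||% sub("\\.[^.]*$", "", basename(file))
  lines <- readr::read_lines(file)
  headers <- lines[startsWith(lines, "#")]
  data <- lines[!startsWith(lines, "#") & nzchar(lines)]
  ko_col <- NA_integer_
  if (length(headers) > 0) {
    cols <- strsplit(sub("^#+", "", headers[[length(headers)]]), "\t", fixed = TRUE)[[1]]
    ko_col <- match("KEGG_ko", stringr::str_trim(cols))
  }
  if (is.na(ko_col) && length(data) > 0) {
    # fall back: the column whose values look like KO lists
    probe <- strsplit(data[[1]], "\t", fixed = TRUE)[[1]]
    ko_col <- which(grepl("^ko:K\\d{5}", probe) | grepl(KO_PATTERN, probe))[1]
  }
  if (length(data) == 0) {
    return(tibble::tibble(genome_id = character(), ko = character(), count = integer()))
  }
  stopf(!is.na(ko_col), "no KO column detected in %s", file)
  values <- vapply(strsplit(data, "\t", fixed = TRUE), function(f) {
    if (length(f) >= ko_col) f[[ko_col]] else "-"
  }, character(1))
  kos <- unlist(strsplit(values[values != "-"], ",", fixed = TRUE), use.names = FALSE)
  kos <- sub("^ko:", "", stringr::str_trim(kos))
  kos <- kos[grepl(KO_PATTERN, kos)]
  if (length(kos) == 0) {
    return(tibble::tibble(genome_id = character(), ko = character(), count = integer()))
  }
  counts <- table(kos)
  tibble::tibble(
    genome_id = genome_id,
    ko = names(counts),
    count = as.integer(counts)
  )
}

#' Build the genome-by-KO copy-number matrix
#'
#' Columns are the union of all observed KO ids in lexicographic order; a KO
#' absent from a genome scores 0.  Values are raw copy numbers;
#' standardization happens at training time.
#'
#' @param vectors A list of KO vectors (tibbles from
#'   [parse_annotation_table()]) or a single long tibble with `genome_id`,
#'   `ko`, `count`.
#' @return Tibble with a `genome_id` column followed by one integer column
#'   per KO.
#' @export
build_feature_matrix <- function(vectors) {
  long <- if (is.data.frame(vectors)) vectors else dplyr::bind_rows(vectors)
  stopf(nrow(long) > 0 || length(vectors) > 0, "no KO vectors supplied")
  ids <- if (is.data.frame(vectors)) unique(long$genome_id) else {
    unlist(lapply(vectors, function(v) unique(v$genome_id)), use.names = FALSE)
  }
  stopf(!anyDuplicated(ids), "duplicate genome_id: %s",
        paste(unique(ids[duplicated(ids)]), collapse = ", "))
  wide <- tidyr::pivot_wider(
    long,
    id_cols = "genome_id", names_from = "ko", values_from = "count",
    values_fill = 0L, names_sort = TRUE
  )
  # genomes with zero annotated KOs still get a (all-zero) row
  missing <- setdiff(ids, wide$genome_id)
  if (length(missing) > 0) {
    pad <- tibble::tibble(genome_id = missing)
    for (k in setdiff(names(wide), "genome_id")) pad[[k]] <- 0L
    wide <- dplyr::bind_rows(wide, pad)
  }
  wide[match(ids, wide$genome_id), , drop = FALSE]
}

#' Assign function labels to genomes by lineage propagation
#'
#' A genome is positive for a function when any taxid on its lineage (its
#' own or any ancestor) equals the matched taxid of a member taxon of that
#' function's group: taxon-function links are taken to mean every organism
#' within the taxon can perform the function.  Propagation is strictly
#' downward; a genome may be positive for many functions.
#'
#' @param genomes Tibble with `genome_id` and `taxid` columns.
#' @param taxon_matrix Taxon-by-function tibble from
#'   [build_taxon_function_matrix()].
#' @param matches Tibble from [match_taxon_names()] keyed by taxon leaf name
#'   (its `query` column must cover `taxon_leaf()` of the matrix's taxa).
#' @param index A `taxonomy_index`.
#' @return Tibble with `genome_id` plus one 0/1 integer column per function.
#' @export
assign_labels <- function(genomes, taxon_matrix, matches, index) {
  fun_names <- setdiff(names(taxon_matrix), "taxon")
  leafs <- taxon_leaf(taxon_matrix$taxon)
  taxid_of <- matches$taxid[match(leafs, matches$query)]
  lineages <- lapply(unique(genomes$taxid), function(id) lineage(index, id)$taxid)
  names(lineages) <- as.character(unique(genomes$taxid))
  bad <- genomes$genome_id[!as.character(genomes$taxid) %in% names(lineages)]
  stopf(length(bad) == 0, "genomes with unknown taxid: %s", paste(bad, collapse = ", "))
  out <- tibble::tibble(genome_id = genomes$genome_id)
  for (f in fun_names) {
    member_ids <- taxid_of[taxon_matrix[[f]] == 1]
    member_ids <- member_ids[!is.na(member_ids)]
    out[[f]] <- vapply(as.character(genomes$taxid), function(id) {
      as.integer(any(lineages[[id]] %in% member_ids))
    }, integer(1), USE.NAMES = FALSE)
  }
  out
}

#' Bundle features and labels into a trait dataset
#'
#' @param features Genome-by-KO tibble (`genome_id` first column).
#' @param labels Genome-by-function 0/1 tibble (`genome_id` first column),
#'   with rows for exactly the same genomes.
#' @return A `trait_dataset` with aligned rows, `feature_order` and
#'   `class_names`.
#' @export
trait_dataset <- function(features, labels) {
  stopf(setequal(features$genome_id, labels$genome_id),
        "features and labels cover different genomes")
  labels <- labels[match(features$genome_id, labels$genome_id), , drop = FALSE]
  lab_mat <- as.matrix(labels[setdiff(names(labels), "genome_id")])
  stopf(all(lab_mat %in% c(0L, 1L)), "labels must be binary")
  structure(
    list(
      features = features,
      labels = labels,
      feature_order = setdiff(names(features), "genome_id"),
      class_names = setdiff(names(labels), "genome_id")
    ),
    class = "trait_dataset"
  )
}

#' @exportS3Method base::print
print.trait_dataset <- function(x, ...) {
  cat(sprintf(
    "<trait_dataset> %d genomes x %d KOs, %d classes\n",
    nrow(x$features), length(x$feature_order), length(x$class_names)
  ))
  invisible(x)
}

# Numeric matrix view of the features (genomes x KOs).
feature_mat <- function(dataset) {
  m <- as.matrix(dataset$features[dataset$feature_order])
  rownames(m) <- dataset$features$genome_id
  storage.mode(m) <- "double"
  m
}

#' Drop functional classes with too few positive genomes
#'
#' Classes backed by fewer than `min_positives` positive genomes cannot
#' support a stratified train/test split and are removed (genomes are never
#' dropped).  Dropped class names are reported via a message.
#'
#' @param dataset A `trait_dataset`.
#' @param min_positives Minimum positives per retained class (default 3).
#' @return A `trait_dataset` with the surviving classes.
#' @export
filter_classes <- function(dataset, min_positives = 3) {
  stopf(inherits(dataset, "trait_dataset"), "not a trait_dataset")
  npos <- vapply(dataset$class_names, function(cl) sum(dataset$labels[[cl]]), numeric(1))
  keep <- names(npos)[npos >= min_positives]
  dropped <- setdiff(dataset$class_names, keep)
  stopf(length(keep) > 0, "all classes have fewer than %d positives", min_positives)
  if (length(dropped) > 0) {
    rlang::inform(sprintf(
      "dropping %d class(es) with < %d positives: %s",
      length(dropped), min_positives, paste(dropped, collapse = ", ")
    ))
  }
  trait_dataset(dataset$features, dataset$labels[c("genome_id", keep)])
}

#' Content hash of a trait dataset
#'
#' Stable across sessions; recorded in training manifests so registries can
#' be traced to the exact dataset that produced them.
#'
#' @param dataset A `trait_dataset`.
#' @export
dataset_hash <- function(dataset) {
  rlang::hash(list(dataset$features, dataset$labels))
}
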