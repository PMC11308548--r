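# NCBI-taxonomy-dump handling: lineage lookup, name matching with an
# imperfect-match cascade, descendant expansion, genome selection under a
# per-species cap, and the genome quality filter.

# Split one .dmp line into fields.  The dump dialect separates fields with
# "\t|\t" and terminates lines with "\t|".
split_dmp <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  strsplit(lines, "\t|\t", fixed = TRUE)
}

read_dmp <- function(path, n_fields, what) {
  stopf(file.exists(path), "no such file: %s", path)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  fields <- split_dmp(lines)
  bad <- which(vapply(fields, length, integer(1)) < n_fields)
  stopf(length(bad) == 0, "%s: malformed row at line %d", what,
        if (length(bad) > 0) bad[[1]] else 0L)
  fields
}

#' Load an NCBI-style taxonomy dump
#'
#' Reads `names.dmp`, `nodes.dmp` and optionally `merged.dmp` in the
#' pipe-and-tab dump dialect and builds an index supporting id-to-lineage
#' and name-to-id queries.  Synonym name classes are indexed alongside
#' scientific names; merged (retired) ids redirect in one hop.
#'
#' @param names_path,nodes_path,merged_path Paths to the dump tables;
#'   `merged_path` may be `NULL`.
#' @return A `taxonomy_index`.
#' @export
load_taxonomy <- function(names_path, nodes_path, merged_path = NULL) {
  nf <- read_dmp(nodes_path, 3, "nodes table")
  stopf(length(nf) > 0, "nodes table is empty")
  nodes <- tibble::tibble(
    taxid = as.integer(vapply(nf, `[[`, character(1), 1)),
    parent = as.integer(vapply(nf, `[[`, character(1), 2)),
    rank = vapply(nf, `[[`, character(1), 3)
  )
  mf <- read_dmp(names_path, 4, "names table")
  names_tbl <- tibble::tibble(
    taxid = as.integer(vapply(mf, `[[`, character(1), 1)),
    name = vapply(mf, `[[`, character(1), 2),
    name_class = vapply(mf, `[[`, character(1), 4)
  )
  merged <- if (!is.null(merged_path)) {
    gf <- read_dmp(merged_path, 2, "merged table")
    tibble::tibble(
      old = as.integer(vapply(gf, `[[`, character(1), 1)),
      new = as.integer(vapply(gf, `[[`, character(1), 2))
    )
  } else {
    tibble::tibble(old = integer(), new = integer())
  }
  sci <- names_tbl[names_tbl$name_class == "scientific name", ]
  structure(
    list(
      nodes = nodes,
      names = names_tbl,
      merged = merged,
      parent_of = setNames(nodes$parent, nodes$taxid),
      rank_of = setNames(nodes$rank, nodes$taxid),
      sci_name_of = setNames(sci$name, sci$taxid)
    ),
    class = "taxonomy_index"
  )
}

#' @exportS3Method base::print
print.taxonomy_index <- function(x, ...) {
  cat(sprintf(
    "<taxonomy_index> %d nodes, %d names, %d merged ids\n",
    nrow(x$nodes), nrow(x$names), nrow(x$merged)
  ))
  invisible(x)
}

#' Resolve a possibly-merged taxid to its current id
#'
#' @param index A `taxonomy_index`.
#' @param taxid Integer taxid(s).
#' @export
resolve_taxid <- function(index, taxid) {
  i <- match(taxid, index$merged$old)
  out <- ifelse(is.na(i), taxid, index$merged$new[i])
  as.integer(out)
}

#' Lineage of a taxid, root first
#'
#' @param index A `taxonomy_index`.
#' @param taxid A single taxid (merged ids are redirected first).
#' @return Tibble with columns `taxid`, `rank`, `name`, ordered root to node.
#' @export
lineage <- function(index, taxid) {
  id <- resolve_taxid(index, taxid)
  stopf(as.character(id) %in% names(index$parent_of), "unknown taxid: %s", taxid)
  chain <- integer()
  while (TRUE) {
    chain <- c(id, chain)
    parent <- index$parent_of[[as.character(id)]]
    if (parent == id) break
    id <- parent
  }
  tibble::tibble(
    taxid = chain,
    rank = unname(index$rank_of[as.character(chain)]),
    name = unname(index$sci_name_of[as.character(chain)])
  )
}

normalize_name <- function(x) {
  x <- gsub("\\[[^]]*\\]", " ", x)          # strip bracketed qualifiers
  x <- stringr::str_squish(x)
  tolower(x)
}

# One cascade stage: value -> candidate taxids.  Returns integer(0) on miss,
# NA on ambiguity.
match_stage <- function(keys, ids, query) {
  hits <- unique(ids[keys == query])
  hits <- hits[!is.na(hits)]
  if (length(hits) > 1) NA_integer_ else hits
}

#' Match taxon leaf names to taxonomy ids
#'
#' Perfect matches are exact string equality against scientific names.
#' Imperfect matches are tried in a fixed cascade: case-insensitive
#' scientific name, exact match against any name class (synonyms, equivalent
#' names, ...), then match after stripping bracketed qualifiers, collapsing
#' whitespace and case-folding, against all name classes.  The first
#' successful stage wins.  A name hitting more than one distinct taxid at
#' its first successful stage is returned unmatched with a logged ambiguity.
#'
#' @param queries Character vector of leaf names.
#' @param index A `taxonomy_index`.
#' @return Tibble with columns `query`, `taxid` (NA when unmatched),
#'   `match_type` (`perfect`, `imperfect`, `unmatched`) and `matched_name`.
#' @export
match_taxon_names <- function(queries, index) {
  sci <- index$names[index$names$name_class == "scientific name", ]
  all_names <- index$names
  sci_lower <- tolower(sci$name)
  all_norm <- normalize_name(all_names$name)
  rows <- lapply(queries, function(q) {
    stages <- list(
      list(type = "perfect", hit = match_stage(sci$name, sci$taxid, q)),
      list(type = "imperfect", hit = match_stage(sci_lower, sci$taxid, tolower(q))),
      list(type = "imperfect", hit = match_stage(all_names$name, all_names$taxid, q)),
      list(type = "imperfect", hit = match_stage(all_norm, all_names$taxid, normalize_name(q)))
    )
    for (s in stages) {
      if (length(s$hit) == 1 && is.na(s$hit)) {
        rlang::warn(sprintf("'%s' is ambiguous (multiple taxids); left unmatched", q))
        return(tibble::tibble(query = q, taxid = NA_integer_,
                              match_type = "unmatched", matched_name = NA_character_))
      }
      if (length(s$hit) == 1) {
        id <- resolve_taxid(index, s$hit)
        return(tibble::tibble(query = q, taxid = id, match_type = s$type,
                              matched_name = unname(index$sci_name_of[as.character(id)])))
      }
    }
    tibble::tibble(query = q, taxid = NA_integer_,
                   match_type = "unmatched", matched_name = NA_character_)
  })
  dplyr::bind_rows(rows)
}

#' All descendants of a taxid, including itself
#'
#' @param index A `taxonomy_index`.
#' @param taxid A single taxid.
#' @return Integer vector of taxids in ascending order.
#' @export
expand_descendants <- function(index, taxid) {
  id <- resolve_taxid(index, taxid)
  stopf(as.character(id) %in% names(index$parent_of), "unknown taxid: %s", taxid)
  kids <- split(index$nodes$taxid, index$nodes$parent)
  out <- integer()
  queue <- id
  while (length(queue) > 0) {
    node <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, node)
    ch <- kids[[as.character(node)]]
    ch <- ch[ch != node] # the root is its own parent
    queue <- c(queue, ch)
  }
  sort(unique(out))
}

#' Filter genome records on completeness and contamination
#'
#' Keeps records with completeness of at least `min_completeness` percent
#' and contamination of at most `max_contamination` percent (the customary
#' 90%/5% quality gate for training genomes).  Records missing either value
#' are rejected with reason `"unscored"`.
#'
#' @param records Tibble with numeric `completeness` and `contamination`
#'   columns (percent).
#' @param min_completeness,max_contamination Thresholds in percent.
#' @return List with tibbles `kept` and `rejected` (the latter gains a
#'   `reason` column); the two partition `records`.
#' @export
qc_filter <- function(records, min_completeness = 90, max_contamination = 5) {
  unscored <- is.na(records$completeness) | is.na(records$contamination)
  keep <- !unscored &
    records$completeness >= min_completeness &
    records$contamination <= max_contamination
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- dplyr::case_when(
    unscored[!keep] ~ "unscored",
    rejected$completeness < min_completeness ~ "low_completeness",
    TRUE ~ "high_contamination"
  )
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Select genomes under a per-species cap
#'
#' Within each species (grouped on `species_taxid`), keeps everything when
#' the candidate count is at or below the cap; otherwise complete assemblies
#' are prioritized (sampling among them if they alone exceed the cap) and
#' the remaining slots are filled by uniform sampling without replacement
#' from the non-complete candidates.  Deterministic for a given seed.
#'
#' @param records Tibble of candidates with `accession`, `species_taxid` and
#'   `assembly_level` (`"complete"` or anything else) columns.
#' @param cap Maximum genomes per species (default 30).
#' @param prioritize_complete Keep complete assemblies first.
#' @param seed Integer seed for the sampling.
#' @return Tibble of selected records (row order: by species, then accession).
#' @export
select_genomes <- function(records, cap = 30, prioritize_complete = TRUE, seed = 1) {
  stopf(cap >= 1, "cap must be >= 1")
  records <- dplyr::arrange(records, .data$species_taxid, .data$accession)
  withr::with_seed(seed, {
    picked <- lapply(split(records, records$species_taxid), function(sp) {
      if (nrow(sp) <= cap) return(sp)
      complete <- sp[sp$assembly_level == "complete", , drop = FALSE]
      draft <- sp[sp$assembly_level != "complete", , drop = FALSE]
      if (!prioritize_complete) {
        return(sp[sort(sample.int(nrow(sp), cap)), , drop = FALSE])
      }
      if (nrow(complete) >= cap) {
        return(complete[sort(sample.int(nrow(complete), cap)), , drop = FALSE])
      }
      fill <- draft[sort(sample.int(nrow(draft), cap - nrow(complete))), , drop = FALSE]
      dplyr::bind_rows(complete, fill)
    })
    dplyr::bind_rows(picked)
  })
}

#' Distribution of genomes across ancestors at a given rank
#'
#' Walks each record's lineage up to the ancestor carrying `target_rank`;
#' records whose lineage lacks that rank are bucketed as `"unranked"`.
#'
#' @param records Tibble with a `taxid` column.
#' @param index A `taxonomy_index`.
#' @param target_rank Rank name, e.g. `"phylum"`.
#' @return Tibble with `ancestor`, `n` and `pct` (percentages sum to 100 up
#'   to rounding).
#' @export
rank_distribution <- function(records, index, target_rank) {
  anc <- vapply(records$taxid, function(id) {
    lin <- lineage(index, id)
    hit <- lin$name[lin$rank == target_rank]
    if (length(hit) == 0) "unranked" else hit[[length(hit)]]
  }, character(1))
  out <- dplyr::count(tibble::tibble(ancestor = anc), .data$ancestor, name = "n")
  out$pct <- 100 * out$n / sum(out$n)
  dplyr::arrange(out, dplyr::desc(.data$n))
}
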