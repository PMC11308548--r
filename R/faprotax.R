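# Parsing of FAPROTAX-style flat-text databases: functional groups listing
# member taxonomic paths (asterisk-delimited) plus set-operation directives
# referencing other groups (add/subtract/intersect).

DIRECTIVE_RE <- "^(add|subtract|intersect)_group:\\s*(\\S.*?)\\s*$"

#' Canonical form of a taxon path
#'
#' FAPROTAX member entries delimit taxonomic levels with `*` characters,
#' which also mark possible omitted higher or lower levels.  The canonical
#' identity of a taxon strips the leading/trailing wildcards, keeps interior
#' level boundaries as `;`, and trims whitespace; case is preserved (name
#' matching handles case downstream).
#'
#' @param path Character vector of raw member strings.
#' @return Character vector of canonical taxon paths.
#' @export
canonical_taxon <- function(path) {
  x <- stringr::str_trim(path)
  x <- gsub("^\\*+|\\*+$", "", x)
  x <- gsub("\\s*\\*+\\s*", ";", x)
  stringr::str_trim(x)
}

#' Deepest named level of a taxon path
#'
#' The leaf (the deepest, rightmost named level) is what gets matched
#' against taxonomy names.  Accepts raw (asterisk-delimited) or canonical
#' (semicolon-delimited) paths; paths without separators are their own leaf.
#'
#' @param path Character vector of taxon paths.
#' @return Character vector of leaf names.
#' @export
taxon_leaf <- function(path) {
  parts <- strsplit(canonical_taxon(path), ";", fixed = TRUE)
  vapply(parts, function(p) {
    p <- stringr::str_trim(p)
    p <- p[nzchar(p)]
    if (length(p) == 0) "" else p[[length(p)]]
  }, character(1))
}

#' Parse a FAPROTAX-format functional group database
#'
#' A group begins at a header line `name<TAB>annotation`; all subsequent
#' member lines (taxonomic paths starting with `*`) and directive lines
#' (`add_group:NAME`, `subtract_group:NAME`, `intersect_group:NAME`) belong
#' to it until the next header.  Comment lines (leading `#`) and blank lines
#' are permitted anywhere.  Members are stored without within-group
#' repetition (repetition judged on the wildcard-stripped canonical form);
#' directives are kept in file order.  Unknown line types are skipped with a
#' warning.
#'
#' @param text Either a single string holding the whole file, or a character
#'   vector of lines.
#' @param source_version Version string recorded on the returned set.
#' @return A `faprotax_set`: list with `groups` (named list of
#'   `faprotax_group`) and `source_version`.
#' @export
parse_faprotax <- function(text, source_version = "unknown") {
  lines <- if (length(text) == 1 && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  groups <- list()
  current <- NULL
  flush <- function(g) {
    if (!is.null(g)) groups[[g$name]] <<- g
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(stringr::str_trim(line)) || startsWith(line, "#")) next
    if (grepl(DIRECTIVE_RE, line)) {
      if (is.null(current)) {
        rlang::warn(sprintf("line %d: directive outside any group skipped", i))
        next
      }
      op <- sub("_group:.*$", "", line)
      target <- sub(DIRECTIVE_RE, "\\2", line)
      current$directives <- dplyr::bind_rows(
        current$directives,
        tibble::tibble(operation = op, target = target)
      )
    } else if (grepl("^[a-z]+_group:", line)) {
      rlang::warn(sprintf("line %d: unknown directive skipped: %s", i, line))
    } else if (startsWith(line, "*")) {
      if (is.null(current)) {
        rlang::warn(sprintf("line %d: member line outside any group skipped", i))
        next
      }
      member <- stringr::str_trim(line)
      key <- canonical_taxon(member)
      if (!nzchar(key)) {
        rlang::warn(sprintf("line %d: empty member skipped", i))
        next
      }
      if (!key %in% canonical_taxon(current$members)) {
        current$members <- c(current$members, member)
      }
    } else {
      flush(current)
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
      name <- stringr::str_trim(fields[[1]])
      stopf(nzchar(name), "line %d: empty group name", i)
      stopf(!name %in% names(groups), "line %d: duplicate group name '%s'", i, name)
      current <- structure(
        list(
          name = name,
          members = character(),
          directives = tibble::tibble(operation = character(), target = character()),
          annotation = paste(fields[-1], collapse = "\t")
        ),
        class = "faprotax_group"
      )
    }
  }
  flush(current)
  set <- structure(
    list(groups = groups, source_version = source_version),
    class = "faprotax_set"
  )
  undefined <- setdiff(
    unlist(lapply(groups, function(g) g$directives$target)),
    names(groups)
  )
  stopf(length(undefined) == 0,
        "directives reference undefined group(s): %s",
        paste(undefined, collapse = ", "))
  directive_order(set) # errors on cycles
  set
}

#' Read a FAPROTAX database file
#'
#' @param path Path to the flat-text database.
#' @inheritParams parse_faprotax
#' @export
read_faprotax <- function(path, source_version = basename(path)) {
  stopf(file.exists(path), "no such file: %s", path)
  parse_faprotax(readr::read_lines(path), source_version = source_version)
}

#' Serialize a parsed group set back to FAPROTAX text
#'
#' Inverse of [parse_faprotax()]: parsing the returned lines yields an
#' identical set.
#'
#' @param set A `faprotax_set`.
#' @return Character vector of lines.
#' @export
write_faprotax <- function(set) {
  stopf(inherits(set, "faprotax_set"), "not a faprotax_set")
  unlist(lapply(set$groups, function(g) {
    c(
      paste0(g$name, "\t", g$annotation),
      g$members,
      if (nrow(g$directives) > 0) {
        paste0(g$directives$operation, "_group:", g$directives$target)
      }
    )
  }), use.names = FALSE)
}

#' @exportS3Method base::print
print.faprotax_set <- function(x, ...) {
  cat(sprintf(
    "<faprotax_set> %d groups (version %s)\n",
    length(x$groups), x$source_version
  ))
  invisible(x)
}

# Topological order of groups under the directive dependency graph.
# Errors with the offending cycle if one exists.
directive_order <- function(set) {
  deps <- lapply(set$groups, function(g) unique(g$directives$target))
  order <- character()
  state <- setNames(rep("new", length(deps)), names(deps))
  visit <- function(name, stack) {
    if (state[[name]] == "done") return(invisible())
    if (state[[name]] == "visiting") {
      cyc <- c(stack[which(stack == name):length(stack)], name)
      rlang::abort(sprintf(
        "cycle in group set operations: %s", paste(cyc, collapse = " -> ")
      ), call = NULL)
    }
    state[[name]] <<- "visiting"
    for (d in deps[[name]]) visit(d, c(stack, name))
    state[[name]] <<- "done"
    order <<- c(order, name)
  }
  for (nm in names(deps)) visit(nm, character())
  order
}

#' Resolve group set operations to final taxon memberships
#'
#' Each group's membership starts from its literal members (canonical form)
#' and applies its directives in file order: `add` is set union, `subtract`
#' set difference, `intersect` set intersection.  Referenced groups are
#' resolved first (topological order), so directives always see final
#' memberships.
#'
#' @param set A `faprotax_set`.
#' @return Named list mapping group name to a character vector of canonical
#'   taxon paths.
#' @export
resolve_groups <- function(set) {
  stopf(inherits(set, "faprotax_set"), "not a faprotax_set")
  resolved <- list()
  for (nm in directive_order(set)) {
    g <- set$groups[[nm]]
    members <- unique(canonical_taxon(g$members))
    if (nrow(g$directives) > 0) {
      for (j in seq_len(nrow(g$directives))) {
        other <- resolved[[g$directives$target[[j]]]]
        members <- switch(g$directives$operation[[j]],
          add = union(members, other),
          subtract = setdiff(members, other),
          intersect = intersect(members, other)
        )
      }
    }
    resolved[[nm]] <- members
  }
  resolved[names(set$groups)]
}

#' Build the binary taxon-by-function membership matrix
#'
#' Rows are the union of all resolved memberships (taxa emptied out by
#' subtraction never appear); columns are groups.  Both are ordered
#' lexicographically for determinism.
#'
#' @param memberships Named list from [resolve_groups()].
#' @return A tibble with a `taxon` column followed by one 0/1 integer column
#'   per functional group.
#' @export
build_taxon_function_matrix <- function(memberships) {
  stopf(length(memberships) >= 1, "no resolved groups")
  taxa <- sort(unique(unlist(memberships, use.names = FALSE)))
  cols <- lapply(memberships[sort(names(memberships))], function(m) {
    as.integer(taxa %in% m)
  })
  dplyr::bind_cols(tibble::tibble(taxon = taxa), tibble::as_tibble(cols))
}

#' Summary report of a group set
#'
#' @param x A `faprotax_set`.
#' @param ... Unused.
#' @return A tibble with one row per group: name, literal member count,
#'   directive count and annotation.
#' @export
tidy.faprotax_set <- function(x, ...) {
  tibble::tibble(
    name = names(x$groups),
    n_members = vapply(x$groups, function(g) length(g$members), integer(1)),
    n_directives = vapply(x$groups, function(g) nrow(g$directives), integer(1)),
    annotation = vapply(x$groups, function(g) g$annotation, character(1))
  )
}
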