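# Simulated genome fragmentation: random segment removal down to a target
# completeness, emulating the incompleteness of metagenome-assembled
# genomes.  Completeness is length-based relative to a reference genome
# size, so gene content is affected only indirectly.

parse_frag_name <- function(nm) {
  m <- regmatches(nm, regexec("^(.*):(\\d+)-(\\d+)$", nm))
  stopf(all(vapply(m, length, integer(1)) == 4), "malformed fragment name")
  tibble::tibble(
    parent = vapply(m, `[[`, character(1), 2),
    start = as.integer(vapply(m, `[[`, character(1), 3)),
    end = as.integer(vapply(m, `[[`, character(1), 4))
  )
}

#' Fragment a genome down to a target completeness
#'
#' Repeatedly draws a removal length from Normal(`removal_mean`,
#' `removal_sd`) truncated to at least 1 bp and at most the remaining
#' excess over the target, picks a contig with probability proportional to
#' its length and a uniform start position, and excises the segment,
#' splitting the contig in two (empty pieces are discarded).  Removal stops
#' once the retained length is at most
#' `target_completeness * reference_size * (1 + tolerance)`; because the
#' last removal is clipped to the excess, the achieved completeness always
#' lands in `[target, target * (1 + tolerance)]`.  Every output sequence is
#' an exact substring of an input sequence; names record the parent contig
#' and 0-based half-open coordinates as `parent:start-end`.
#'
#' @param seqs Named character vector of contig sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param target_completeness Fraction in (0, 1].
#' @param reference_size Reference (species) genome size in bp; defaults to
#'   the genome's own total length.
#' @param removal_mean,removal_sd Removal-length distribution in bp.
#' @param tolerance Acceptable overshoot fraction above the target.
#' @param seed Integer seed; the procedure is deterministic per seed.
#' @return Named character vector of retained fragments, with attributes
#'   `removed_lengths` and `achieved_completeness`.
#' @export
fragment_genome <- function(seqs, target_completeness,
                            reference_size = NULL,
                            removal_mean = 5000, removal_sd = 1500,
                            tolerance = 0.01, seed = 1) {
  if (inherits(seqs, "DNAStringSet")) {
    seqs <- setNames(as.character(seqs), names(seqs))
  }
  stopf(length(seqs) > 0 && all(nchar(seqs) > 0), "sequences must be non-empty")
  stopf(!is.null(names(seqs)) && !anyDuplicated(names(seqs)),
        "contigs must have unique names")
  stopf(target_completeness > 0 && target_completeness <= 1,
        "target_completeness must be in (0, 1]")
  stopf(removal_sd > 0, "removal_sd must be > 0")
  stopf(removal_mean > 0, "removal_mean must be > 0")
  stopf(tolerance >= 0, "tolerance must be >= 0")

  frags <- tibble::tibble(
    parent = names(seqs),
    start = 0L,
    seq = unname(seqs)
  )
  total <- sum(nchar(seqs))
  reference_size <- reference_size %||% total
  target_len <- target_completeness * reference_size
  retained <- total
  stopf(retained >= target_len,
        "genome (%d bp) is already below the target retained length (%.0f bp)",
        retained, target_len)
  removed <- integer()
  withr::with_seed(seed, {
    while (retained > target_len * (1 + tolerance)) {
      lens <- nchar(frags$seq)
      i <- sample.int(nrow(frags), 1, prob = lens)
      excess <- retained - target_len
      len <- round(rnorm(1, removal_mean, removal_sd))
      len <- max(1L, as.integer(floor(min(len, excess, lens[[i]]))))
      start <- sample.int(lens[[i]] - len + 1, 1) - 1L # 0-based
      left <- substr(frags$seq[[i]], 1, start)
      right <- substr(frags$seq[[i]], start + len + 1, lens[[i]])
      pieces <- tibble::tibble(
        parent = frags$parent[[i]],
        start = c(frags$start[[i]], frags$start[[i]] + start + len),
        seq = c(left, right)
      )
      pieces <- pieces[nchar(pieces$seq) > 0, , drop = FALSE]
      frags <- dplyr::bind_rows(frags[-i, , drop = FALSE], pieces)
      removed <- c(removed, as.integer(len))
      retained <- retained - len
    }
  })
  out <- setNames(
    frags$seq,
    sprintf("%s:%d-%d", frags$parent, frags$start, frags$start + nchar(frags$seq))
  )
  attr(out, "removed_lengths") <- removed
  attr(out, "achieved_completeness") <- retained / reference_size
  out
}

# Deterministic per-genome seed derived from a master seed, a genome id and
# a completeness level; kept below 2^31.
derive_seed <- function(master, genome_id, level) {
  s <- (as.numeric(master) %% 1e6) * 1009 +
    sum(utf8ToInt(genome_id)) * 131 +
    round(level * 1000)
  as.integer(s %% 2147483647L) + 1L
}

#' Build simulated-fragmented-genome collections at several levels
#'
#' One collection per completeness level (default 90%, 70% and 50%,
#' i.e. 10%, 30% and 50% of genome length removed); per-genome seeds are
#' derived deterministically from the master seed, the genome id and the
#' level.  A genome that cannot be fragmented at a level is skipped there
#' with a logged reason.
#'
#' @param genomes Named list of genomes (each a named character vector of
#'   contigs).
#' @param levels Target completeness fractions.
#' @param reference_sizes Optional named numeric vector of reference genome
#'   sizes per genome id.
#' @param seed Master integer seed.
#' @param out_dir If given, each fragmented genome is also written as an
#'   80-column-wrapped FASTA under `out_dir/<level>/<genome>.fasta`.
#' @param ... Passed on to [fragment_genome()].
#' @return List with `collections` (per level, a named list of fragmented
#'   genomes) and `manifest` (tibble: genome, level, achieved completeness,
#'   contigs out, seed).
#' @export
build_sfg_dataset <- function(genomes, levels = c(0.9, 0.7, 0.5),
                              reference_sizes = NULL, seed = 1,
                              out_dir = NULL, ...) {
  stopf(length(names(genomes)) == length(genomes), "genomes must be named")
  collections <- list()
  manifest <- list()
  for (lev in levels) {
    key <- sprintf("%g", lev)
    collections[[key]] <- list()
    for (g in names(genomes)) {
      gseed <- derive_seed(seed, g, lev)
      ref <- if (!is.null(reference_sizes)) reference_sizes[[g]] else NULL
      frag <- tryCatch(
        fragment_genome(genomes[[g]], lev, reference_size = ref, seed = gseed, ...),
        error = function(e) e
      )
      if (inherits(frag, "error")) {
        rlang::inform(sprintf("skipping %s at level %g: %s",
                              g, lev, conditionMessage(frag)))
        next
      }
      collections[[key]][[g]] <- frag
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        genome = g, level = lev,
        achieved_completeness = attr(frag, "achieved_completeness"),
        n_contigs_out = length(frag), seed = gseed
      )
      if (!is.null(out_dir)) {
        dir <- file.path(out_dir, key)
        dir.create(dir, recursive = TRUE, showWarnings = FALSE)
        write_genome_fasta(frag, file.path(dir, paste0(g, ".fasta")))
      }
    }
  }
  list(collections = collections, manifest = dplyr::bind_rows(manifest))
}

#' Surviving gene copies after fragmentation
#'
#' A gene survives when its interval is fully contained in one retained
#' fragment of its contig (coordinates 0-based half-open, as written by
#' [fragment_genome()]).  Used to emulate re-annotation of fragmented
#' genomes when the gene coordinates are known.
#'
#' @param fragments Named character vector from [fragment_genome()].
#' @param gene_map Tibble with `ko`, `contig`, `start`, `end` columns.
#' @return KO vector tibble (`ko`, `count`) of surviving gene copies.
#' @export
surviving_ko_counts <- function(fragments, gene_map) {
  coords <- parse_frag_name(names(fragments))
  alive <- vapply(seq_len(nrow(gene_map)), function(i) {
    any(coords$parent == gene_map$contig[[i]] &
          coords$start <= gene_map$start[[i]] &
          gene_map$end[[i]] <= coords$end)
  }, logical(1))
  if (!any(alive)) return(tibble::tibble(ko = character(), count = integer()))
  counts <- table(gene_map$ko[alive])
  tibble::tibble(ko = names(counts), count = as.integer(counts))
}

#' Read / write genome FASTA
#'
#' Thin wrappers over Biostrings keeping genomes as named character
#' vectors; output is wrapped at 80 columns.
#'
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 80
  )
  invisible(path)
}
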