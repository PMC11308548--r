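# Synthetic-data generators with known ground truth.  Every generator is a
# pure function of its parameters and seed and returns its own ground
# truth, so the rest of the package is testable without any downloads.

GREEK <- c("Alpha", "Beta", "Gamma", "Delta", "Epsilon", "Zeta", "Eta",
           "Theta", "Iota", "Kappa", "Lambda", "Mu")

synth_species_names <- function(n) {
  genus <- paste0(GREEK[(seq_len(n) - 1) %% length(GREEK) + 1], "bacter")
  sprintf("%s species%02d", genus, seq_len(n))
}

#' Generate a FAPROTAX-format fixture with ground truth
#'
#' Emits a syntactically valid flat-text database (groups, asterisk-wrapped
#' member paths, optional acyclic add/subtract/intersect directives) plus
#' the expected parse, so parser tests can compare structure directly.
#'
#' @param n_groups Number of groups.
#' @param taxa_per_group Literal members per group.
#' @param n_set_ops Number of directive lines spread over the groups (each
#'   references an earlier group, keeping the graph acyclic).
#' @param seed Integer seed.
#' @return List with `text` (character lines) and `set` (the ground-truth
#'   `faprotax_set`).
#' @export
synth_faprotax <- function(n_groups, taxa_per_group = 4, n_set_ops = 0, seed = 1) {
  stopf(n_groups >= 1, "n_groups must be >= 1")
  pool <- synth_species_names(max(2 * taxa_per_group, n_groups * taxa_per_group))
  withr::with_seed(seed, {
    groups <- list()
    op_groups <- if (n_set_ops > 0 && n_groups > 1) {
      sample(2:n_groups, min(n_set_ops, n_groups - 1), replace = FALSE)
    } else {
      integer()
    }
    for (i in seq_len(n_groups)) {
      name <- sprintf("group_%02d", i)
      members <- paste0("*", sample(pool, taxa_per_group), "*")
      directives <- tibble::tibble(operation = character(), target = character())
      if (i %in% op_groups) {
        directives <- tibble::tibble(
          operation = sample(c("add", "subtract", "intersect"), 1),
          target = sprintf("group_%02d", sample.int(i - 1, 1))
        )
      }
      groups[[name]] <- structure(
        list(name = name, members = members, directives = directives,
             annotation = sprintf("synthetic group %d", i)),
        class = "faprotax_group"
      )
    }
  })
  set <- structure(
    list(groups = groups, source_version = "synthetic"),
    class = "faprotax_set"
  )
  list(text = write_faprotax(set), set = set)
}

#' Generate an NCBI-style taxonomy dump fixture
#'
#' Builds a five-level tree (root, phylum, genus, species, optional
#' strains) whose species names follow the same pool used by
#' [synth_faprotax()], so label propagation across the two fixtures can be
#' exercised.  Each run includes one merged-id redirect and one synonym
#' row.
#'
#' @param n_species Number of species.
#' @param strains_per_species Strains under each species (0 for leaf
#'   species).
#' @param seed Integer seed.
#' @return List with `names`, `nodes`, `merged` (dmp-dialect lines) and
#'   `tree` (tibble: taxid, parent, rank, name).
#' @export
synth_taxonomy <- function(n_species, strains_per_species = 0, seed = 1) {
  stopf(n_species >= 1, "n_species must be >= 1")
  species <- synth_species_names(n_species)
  genera <- unique(vapply(strsplit(species, " "), `[[`, character(1), 1))
  rows <- list(tibble::tibble(taxid = 1L, parent = 1L, rank = "no rank", name = "root"),
               tibble::tibble(taxid = 2L, parent = 1L, rank = "phylum", name = "Synthophyla"))
  nid <- 2L
  genus_id <- setNames(integer(length(genera)), genera)
  for (g in genera) {
    nid <- nid + 1L
    genus_id[[g]] <- nid
    rows[[length(rows) + 1]] <- tibble::tibble(
      taxid = nid, parent = 2L, rank = "genus", name = g
    )
  }
  species_id <- setNames(integer(length(species)), species)
  for (s in species) {
    nid <- nid + 1L
    species_id[[s]] <- nid
    rows[[length(rows) + 1]] <- tibble::tibble(
      taxid = nid, parent = genus_id[[strsplit(s, " ")[[1]][1]]],
      rank = "species", name = s
    )
    if (strains_per_species > 0) {
      for (k in seq_len(strains_per_species)) {
        nid <- nid + 1L
        rows[[length(rows) + 1]] <- tibble::tibble(
          taxid = nid, parent = species_id[[s]], rank = "strain",
          name = sprintf("%s strain %d", s, k)
        )
      }
    }
  }
  tree <- dplyr::bind_rows(rows)
  withr::with_seed(seed, {
    syn_of <- sample(species, 1)
  })
  names_lines <- c(
    sprintf("%d\t|\t%s\t|\t\t|\tscientific name\t|", tree$taxid, tree$name),
    sprintf("%d\t|\t%s\t|\t\t|\tsynonym\t|",
            species_id[[syn_of]], paste0("Legacyus ", sub(".* ", "", syn_of)))
  )
  nodes_lines <- sprintf("%d\t|\t%d\t|\t%s\t|", tree$taxid, tree$parent, tree$rank)
  merged_lines <- sprintf("%d\t|\t%d\t|", nid + 1000L, species_id[[species[[1]]]])
  list(names = names_lines, nodes = nodes_lines, merged = merged_lines, tree = tree)
}

#' Generate a planted-signal trait dataset
#'
#' Each class plants a disjoint-by-default set of informative KOs: positive
#' genomes draw their copy numbers from Poisson(`effect`), negative genomes
#' from Poisson(0.1); background KOs come from Poisson(0.5) for everyone.
#' Every cell is independently perturbed with probability `noise_rate` by
#' redrawing it from the background distribution.  Annotation files in the
#' eggNOG-mapper layout are emitted for every genome, identical in dialect
#' to what [parse_annotation_table()] consumes, so ingest can be round-trip
#' tested.
#'
#' @param n_genomes Number of genomes.
#' @param n_classes Number of functional classes.
#' @param n_informative Informative KOs planted per class.
#' @param n_background_kos Background (uninformative) KOs.
#' @param class_size Positive genomes per class (classes may overlap).
#' @param effect Poisson mean of an informative KO in a positive genome.
#' @param noise_rate Per-cell perturbation probability in \[0, 0.5).
#' @param seed Integer seed.
#' @return List with `dataset` (a `trait_dataset`), `truth` (planted
#'   associations per class) and `annotations` (named list of annotation
#'   file lines per genome).
#' @export
synth_dataset <- function(n_genomes = 200, n_classes = 5, n_informative = 20,
                          n_background_kos = 500, class_size = 40,
                          effect = 5, noise_rate = 0.05, seed = 1) {
  stopf(noise_rate >= 0 && noise_rate < 0.5, "noise_rate must be in [0, 0.5)")
  stopf(class_size <= n_genomes, "class_size exceeds n_genomes")
  n_kos <- n_classes * n_informative + n_background_kos
  kos <- sprintf("K%05d", seq_len(n_kos))
  genomes <- sprintf("genome_%03d", seq_len(n_genomes))
  classes <- sprintf("class_%d", seq_len(n_classes))
  withr::with_seed(seed, {
    planted <- lapply(seq_len(n_classes), function(c) {
      kos[((c - 1) * n_informative + 1):(c * n_informative)]
    })
    names(planted) <- classes
    labels <- tibble::tibble(genome_id = genomes)
    for (cl in classes) {
      pos <- sample.int(n_genomes, class_size)
      labels[[cl]] <- as.integer(seq_len(n_genomes) %in% pos)
    }
    counts <- matrix(rpois(n_genomes * n_kos, 0.5), n_genomes, n_kos,
                     dimnames = list(genomes, kos))
    for (cl in classes) {
      ko_idx <- match(planted[[cl]], kos)
      pos <- labels[[cl]] == 1
      counts[pos, ko_idx] <- rpois(sum(pos) * length(ko_idx), effect)
      counts[!pos, ko_idx] <- rpois(sum(!pos) * length(ko_idx), 0.1)
    }
    if (noise_rate > 0) {
      flip <- matrix(stats::runif(length(counts)) < noise_rate,
                     nrow(counts), ncol(counts))
      counts[flip] <- rpois(sum(flip), 0.5)
    }
  })
  features <- dplyr::bind_cols(
    tibble::tibble(genome_id = genomes),
    tibble::as_tibble(as.data.frame(counts))
  )
  annotations <- lapply(genomes, function(g) {
    present <- counts[g, ] > 0
    gene_kos <- rep(kos[present], counts[g, present])
    c(
      "## synthetic eggNOG-mapper-style annotation",
      "#query\tseed_ortholog\tevalue\tKEGG_ko\tDescription",
      sprintf("%s_gene%04d\tseed\t1e-10\tko:%s\tsynthetic",
              g, seq_along(gene_kos), gene_kos),
      sprintf("%s_geneX\tseed\t1e-10\t-\tunannotated", g)
    )
  })
  names(annotations) <- genomes
  list(
    dataset = trait_dataset(features, labels),
    truth = list(planted = planted, effect = effect, noise_rate = noise_rate,
                 class_size = class_size, seed = seed),
    annotations = annotations
  )
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Generate a random multi-contig genome
#'
#' @param n_contigs Number of contigs (total length split evenly).
#' @param total_length Total genome length in bp.
#' @param gc Target GC content.
#' @param seed Integer seed.
#' @return Named character vector of contig sequences.
#' @export
synth_genome_fasta <- function(n_contigs, total_length, gc = 0.5, seed = 1) {
  stopf(total_length >= n_contigs, "total_length must be >= n_contigs")
  sizes <- rep(total_length %/% n_contigs, n_contigs)
  sizes[n_contigs] <- sizes[n_contigs] + total_length %% n_contigs
  withr::with_seed(seed, {
    setNames(
      vapply(sizes, random_dna, character(1), gc = gc),
      sprintf("contig_%02d", seq_len(n_contigs))
    )
  })
}

#' Lay a genome's KO gene complement onto synthetic contigs
#'
#' Every KO copy becomes one gene of fixed length, placed sequentially with
#' spacers across the contigs; the returned gene map (0-based half-open
#' coordinates) lets [surviving_ko_counts()] emulate re-annotation after
#' fragmentation.
#'
#' @param ko_vector KO vector tibble (`ko`, `count`).
#' @param gene_length,spacer Gene and intergenic lengths in bp.
#' @param n_contigs Number of contigs to spread genes over.
#' @param gc GC content of the sequence.
#' @param seed Integer seed.
#' @return List with `seqs` (named character contigs) and `gene_map`
#'   (tibble: gene_id, ko, contig, start, end).
#' @export
synth_genome_with_genes <- function(ko_vector, gene_length = 600, spacer = 200,
                                    n_contigs = 3, gc = 0.5, seed = 1) {
  gene_kos <- rep(ko_vector$ko, ko_vector$count)
  n_genes <- length(gene_kos)
  withr::with_seed(seed, {
    gene_kos <- sample(gene_kos)
    contig_of <- sort(rep_len(seq_len(n_contigs), n_genes))
    rows <- list()
    seqs <- character(n_contigs)
    for (ctg in seq_len(n_contigs)) {
      idx <- which(contig_of == ctg)
      pos <- spacer + (seq_along(idx) - 1) * (gene_length + spacer)
      if (length(idx) > 0) {
        rows[[ctg]] <- tibble::tibble(
          gene_id = sprintf("ctg%02d_g%04d", ctg, seq_along(idx)),
          ko = gene_kos[idx],
          contig = sprintf("contig_%02d", ctg),
          start = as.integer(pos),
          end = as.integer(pos + gene_length)
        )
      }
      len <- spacer + length(idx) * (gene_length + spacer)
      seqs[[ctg]] <- random_dna(len, gc)
    }
  })
  names(seqs) <- sprintf("contig_%02d", seq_len(n_contigs))
  list(seqs = seqs, gene_map = dplyr::bind_rows(rows))
}
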