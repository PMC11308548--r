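# Shared fixtures, built in code.  Expensive artifacts (the planted-signal
# dataset and the registry trained on it) are built once per test run and
# cached in this environment.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# Small ten-line database used across parser tests.
tiny_faprotax_lines <- function() {
  c(
    "# tiny fixture database",
    "A\tfirst group",
    "*Alphabacter species01*",
    "*Betabacter species02*",
    "",
    "B\tsecond group",
    "*Betabacter species02*",
    "C\tcombined group",
    "*Gammabacter species03*",
    "*Deltabacter species04*",
    "add_group:A",
    "subtract_group:B"
  )
}

# Taxonomy fixture written to temp files; returns the loaded index plus the
# generator's ground truth.
tiny_taxonomy <- function(n_species = 5, strains = 2, seed = 42) {
  tx <- synth_taxonomy(n_species, strains, seed = seed)
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  writeLines(tx$names, file.path(dir, "names.dmp"))
  writeLines(tx$nodes, file.path(dir, "nodes.dmp"))
  writeLines(tx$merged, file.path(dir, "merged.dmp"))
  list(
    index = load_taxonomy(file.path(dir, "names.dmp"),
                          file.path(dir, "nodes.dmp"),
                          file.path(dir, "merged.dmp")),
    tree = tx$tree,
    names = tx$names, nodes = tx$nodes, merged = tx$merged
  )
}

# A compact planted-signal dataset for fast learning tests.
small_planted <- function() {
  cached("small_planted", synth_dataset(
    n_genomes = 60, n_classes = 2, n_informative = 8, n_background_kos = 40,
    class_size = 18, effect = 5, noise_rate = 0, seed = 101
  ))
}

# Tiny grids so nested CV stays fast in unit tests.
tiny_grids <- function() {
  list(
    LR = tidyr::expand_grid(C = 1, penalty = "l2"),
    RF = tidyr::expand_grid(n_trees = 100, max_features_rule = "sqrt"),
    SVM = tidyr::expand_grid(kernel = "linear", C = 1),
    NN = tidyr::expand_grid(units = 4, decay = 1e-2)
  )
}

# Long-format KO queries for a dataset's own genomes.
dataset_queries <- function(dataset) {
  long <- tidyr::pivot_longer(dataset$features, -"genome_id",
                              names_to = "ko", values_to = "count")
  long[long$count > 0, ]
}

# The study-condition dataset and registry shared by the acceptance tests:
# 200 genomes, 5 classes, 20 informative KOs per class, effect 5, noise
# 0.05, fixed seed; classical algorithms with the default grids.
acceptance_dataset <- function() {
  cached("acceptance_dataset", synth_dataset(
    n_genomes = 200, n_classes = 5, n_informative = 20,
    n_background_kos = 500, class_size = 40, effect = 5,
    noise_rate = 0.05, seed = 20240808
  ))
}

acceptance_registry <- function() {
  cached("acceptance_registry", {
    fx <- acceptance_dataset()
    suppressMessages(train_registry(
      fx$dataset,
      trait_config(seed = 7, algorithms = c("LR", "SVM", "RF"))
    ))
  })
}
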