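# Shared fixtures, built once per test run and cached. The small corpus
# keeps unit tests fast; the default corpus backs the end-to-end recovery
# checks.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  .fixture_cache[[key]]
}

small_spec <- function(mutation_rate = 0.02) {
  synthetic_spec(n_genera = 3, phages_per_genus = 8, markers_per_genus = 2,
                 background_pool_size = 6, background_genes_per_phage = 2,
                 mutation_rate = mutation_rate, seed = 11)
}

small_corpus <- function() {
  cached_fixture("small_corpus", generate_corpus(small_spec()))
}

small_fit <- function() {
  cached_fixture("small_fit", {
    corp <- small_corpus()
    suppressWarnings(
      run_pipeline(corp$genomes, corp$labels,
                   config = phagehost_config(seed = 5))
    )
  })
}

# full study-condition run (5 genera x 40 phages, 3 markers, 0.02 mutation)
default_run <- function(mutation_rate = 0.02) {
  cached_fixture(paste0("default_run_", mutation_rate), {
    corp <- generate_corpus(synthetic_spec(mutation_rate = mutation_rate))
    fit <- suppressWarnings(
      run_pipeline(corp$genomes, corp$labels,
                   config = phagehost_config(seed = 42))
    )
    list(corpus = corp, fit = fit)
  })
}

# clusters that contain a planted marker gene of each genus (by coordinates)
marker_cluster_map <- function(fit, corpus) {
  called <- fit$genes[fit$genes$strand == "+",
                      c("genome_id", "start", "end", "protein_id")]
  truth <- corpus$truth[corpus$truth$role == "marker", ]
  matched <- dplyr::inner_join(truth, called,
                               by = c("genome_id", "start", "end"))
  dplyr::inner_join(matched, fit$cluster_db$membership, by = "protein_id") |>
    dplyr::distinct(genus, family, cluster_id)
}

benchmark_confusion_path <- function() {
  system.file("extdata", "benchmark_confusion.tsv", package = "phagehost")
}

read_benchmark_confusion <- function() {
  readr::read_tsv(benchmark_confusion_path(), col_types = "ciiii")
}
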