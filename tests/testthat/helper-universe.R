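# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, build(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_enzyme <- function() iib_enzyme("Toy", "ACGT", 2, 2)

# small universe for module-level tests: 12 species x 20 kb
tiny_universe <- function() {
  memo("tiny_universe", function() {
    build_toy_universe(n_species = 12, genome_length = 2e4, seed = 301)
  })
}

tiny_model <- function() {
  memo("tiny_model", function() {
    u <- tiny_universe()
    grid <- expand.grid(richness = c(5L, 10L), depth = c(20000L, 60000L),
                        mutation = c(0, 0.02), KEEP.OUT.ATTRS = FALSE)
    examples <- make_training_set(u$db, u$genomes,
                                  novel_genomes = u$novel_genomes,
                                  grid = grid, seed = 901)
    list(model = train_fp_model(examples, n_estimators = 150),
         examples = examples)
  })
}

# full-scale universe + classifier used by the acceptance suite
# (~100 species x 100 kb, disjoint training seed)
acceptance_universe <- function() {
  memo("acceptance_universe", function() {
    u <- build_toy_universe(n_species = 100, genome_length = 1e5, seed = 101)
    tr <- train_default_model(u, seed = 9101, n_estimators = 500)
    c(u, list(model = tr$model, examples = tr$examples))
  })
}

# genomes engineered to share tags: two species carrying an identical
# segment plus private sequence, one species fully private
shared_segment_genomes <- function(seg_len = 3000, priv_len = 9000, seed = 55) {
  set.seed(seed)
  base <- c("A", "C", "G", "T")
  rnd <- function(n) paste(sample(base, n, replace = TRUE), collapse = "")
  shared <- rnd(seg_len)
  list(
    genome_record("gA", "spA", paste0(rnd(priv_len), shared)),
    genome_record("gB", "spB", paste0(shared, rnd(priv_len))),
    genome_record("gC", "spC", rnd(priv_len + seg_len))
  )
}
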