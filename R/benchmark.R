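#' Scripted end-to-end benchmarks on the synthetic universe
#'
#' The benchmark harness reproduces, at desk scale, the simulation design
#' used to validate two-round tag profiling: a grid of communities varying
#' in species richness and sequencing depth (and optionally genome
#' divergence), each simulated, profiled and scored against its ground
#' truth.
#'
#' @name benchmark
NULL

#' Define a benchmark grid
#'
#' @param richness Integer vector of community richness levels.
#' @param depths Integer vector of read depths.
#' @param mutations Numeric vector of genome divergence rates.
#' @param replicates Replicates per cell; replicate seeds are
#'   `base_seed + replicate index` and are recorded in the report.
#' @param base_seed Integer base seed.
#' @return A `benchmark_grid` data.table with one row per run.
#' @export
benchmark_grid <- function(richness = c(10L, 20L, 50L),
                           depths = c(50000L, 200000L, 500000L),
                           mutations = 0, replicates = 3, base_seed = 1) {
  stopifnot(all(richness >= 1), all(depths >= 1), replicates >= 1)
  g <- CJ(richness = as.integer(richness), depth = as.integer(depths),
          mutation = mutations, replicate = seq_len(replicates))
  g[, seed := as.integer(base_seed) + replicate]
  class(g) <- c("benchmark_grid", class(g))
  g[]
}

#' Run a benchmark grid
#'
#' For every grid row: draw a log-normal community from the database
#' species, simulate reads, profile, evaluate. Fully deterministic given the
#' grid's seeds.
#'
#' @param db Preconstructed `tag_db`.
#' @param model Trained `fp_model`.
#' @param genomes Database [genome_record()]s (simulation sources).
#' @param grid A [benchmark_grid()].
#' @param outdir Optional directory for `report.tsv` and `summary.tsv`.
#' @param quiet Suppress per-run progress messages.
#' @return List with `runs` (one evaluation row per run) and `summary`
#'   (means of the five metrics over all runs).
#' @export
run_benchmark <- function(db, model, genomes, grid = benchmark_grid(),
                          outdir = NULL, quiet = TRUE) {
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    run_seed <- derive_seed(grid$seed[i], grid$richness[i] * 7919L +
                              grid$depth[i] %% 104729L + round(1e4 * grid$mutation[i]))
    truth <- sample_composition(genomes, grid$richness[i], seed = run_seed)
    cfg <- sim_config(depth = grid$depth[i], mutation_rate = grid$mutation[i],
                      seed = run_seed)
    sim <- simulate_reads(truth, genomes, cfg)
    res <- suppressWarnings(profile_sample(sim$reads, db, model))
    rows[[i]] <- evaluate_run(res$profile, truth,
                              run_info = grid[i, .(richness, depth, mutation,
                                                   replicate, seed)])
    if (!quiet) {
      message(sprintf("run %d/%d (richness %d, depth %d, mutation %g): F1 %.3f",
                      i, nrow(grid), grid$richness[i], grid$depth[i],
                      grid$mutation[i], rows[[i]]$f1))
    }
  }
  runs <- rbindlist(rows)
  metrics <- c("precision", "recall", "f1", "l2_similarity", "bc_similarity")
  summary <- runs[, lapply(.SD, mean), .SDcols = metrics]
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    fwrite(runs, file.path(outdir, "report.tsv"), sep = "\t")
    fwrite(summary, file.path(outdir, "summary.tsv"), sep = "\t")
  }
  list(runs = runs, summary = summary)
}

#' Profile a simulated equal-abundance mock community
#'
#' Emulates a defined mock standard: `n_species` database species at equal
#' taxonomic abundance, sequenced deeply, profiled end to end and scored,
#' with the false-positive count reported explicitly.
#'
#' @param db Preconstructed `tag_db`.
#' @param model Trained `fp_model`.
#' @param genomes Database [genome_record()]s.
#' @param n_species Mock richness (default 20, abundance 1/20 each).
#' @param depth Read depth.
#' @param seed Integer seed.
#' @return List with `profile`, `evaluation` (one-row table incl. `n_fp`)
#'   and `truth`.
#' @export
run_mock <- function(db, model, genomes, n_species = 20, depth = 500000,
                     seed = 1) {
  stopifnot(n_species <= nrow(db$species))
  pool <- data.table(
    species_id = vapply(genomes, `[[`, character(1), "species_id"),
    L = vapply(genomes, `[[`, numeric(1), "length")
  )[, .(L = sum(L)), by = species_id]
  set.seed(derive_seed(seed, 47L))
  chosen <- sort(sample(pool$species_id, n_species))
  truth <- pool[species_id %in% chosen]
  truth[, T_true := 1 / n_species]
  truth[, S_true := T_true * L / sum(T_true * L)]
  setcolorder(truth, c("species_id", "T_true", "S_true", "L"))
  class(truth) <- c("community_truth", class(truth))
  cfg <- sim_config(depth = depth, seed = derive_seed(seed, 53L))
  sim <- simulate_reads(truth, genomes, cfg)
  res <- suppressWarnings(profile_sample(sim$reads, db, model))
  evaluation <- evaluate_run(res$profile, truth,
                             run_info = list(n_species = n_species,
                                             depth = depth, seed = seed))
  list(profile = res$profile, evaluation = evaluation, truth = truth)
}

#' Build the toy evaluation universe
#'
#' A seeded synthetic universe: `n_species` random genomes, their
#' species-specific tag database under the synthetic benchmark enzyme, and a
#' pool of out-of-database mosaic genomes for classifier training.
#'
#' @param n_species Database species count (default 100).
#' @param genome_length Genome length (default 100 kb).
#' @param seed Integer seed.
#' @param enzyme An [iib_enzyme()]; default [synthetic_enzyme()].
#' @return List with `genomes`, `db`, `novel_genomes`, `enzyme`, `seed`.
#' @export
build_toy_universe <- function(n_species = 100, genome_length = 1e5,
                               seed = 1, enzyme = synthetic_enzyme()) {
  genomes <- generate_genomes(n_species, genome_length, seed = seed)
  db <- suppressWarnings(build_tag_db(genomes, enzyme))
  # shared segments scale with genome size (~2% each, 3 donors = 6% mosaic)
  novel <- generate_novel_genomes(genomes, n = 12, genome_length = genome_length,
                                  segment_length = max(200, round(genome_length / 50)),
                                  seed = derive_seed(seed, 59L))
  list(genomes = genomes, db = db, novel_genomes = novel,
       enzyme = enzyme, seed = seed)
}

#' Train the default classifier for a universe
#'
#' Runs [make_training_set()] on the default grid over the universe's
#' database and mosaic pool, then [train_fp_model()].
#'
#' @param universe From [build_toy_universe()].
#' @param seed Training-simulation seed (keep disjoint from evaluation
#'   seeds).
#' @param ... Passed to [train_fp_model()].
#' @return List with `model` and `examples`.
#' @export
train_default_model <- function(universe, seed = 9000, ...) {
  examples <- make_training_set(universe$db, universe$genomes,
                                novel_genomes = universe$novel_genomes,
                                seed = seed)
  model <- train_fp_model(examples, ...)
  list(model = model, examples = examples)
}
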