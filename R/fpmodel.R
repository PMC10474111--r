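#' False-positive recognition model
#'
#' Candidate species emerging from the first profiling round are either
#' genuinely present or spurious hits on shared sequence. A tree ensemble
#' trained on the four log-transformed features (coverage, taxonomic count,
#' sequence count, G-score) separates the two. Training data come from the
#' package's own simulator: communities with known composition -- including
#' out-of-database mosaic species that generate realistic false-positive
#' candidates -- are profiled, and every first-round candidate is labeled by
#' ground-truth membership.
#'
#' @name fpmodel
NULL

FP_MODEL_VERSION <- "1"

#' Default simulation grid for classifier training
#'
#' Two richness levels, two depths and two genome divergence levels (so the
#' model sees mutation-degraded coverage), each community carrying three
#' out-of-database mosaic species.
#' @return data.frame of grid cells.
#' @export
default_training_grid <- function() {
  expand.grid(richness = c(10L, 50L), depth = c(50000L, 200000L),
              mutation = c(0, 0.02), KEEP.OUT.ATTRS = FALSE)
}

#' Generate a labeled training set from simulations
#'
#' For each grid cell a community of database species plus `n_novel`
#' out-of-database mosaic species is simulated, profiled through the first
#' round, and every candidate labeled `true_positive` when it belongs to the
#' community's database species and `false_positive` otherwise.
#'
#' @param db The preconstructed `tag_db`.
#' @param genomes Database [genome_record()]s (read simulation sources).
#' @param novel_genomes Mosaic genomes from [generate_novel_genomes()];
#'   generated internally when NULL.
#' @param grid data.frame with columns `richness`, `depth`, `mutation`.
#' @param n_novel Out-of-database species per community.
#' @param seed Integer seed (all cells derive their own streams from it).
#' @return data.table of examples: `sample_id`, `species_id`, the four
#'   log-features and `label`. Warns if either class is absent.
#' @export
make_training_set <- function(db, genomes, grid = default_training_grid(),
                              novel_genomes = NULL, n_novel = 3, seed = 1) {
  stopifnot(inherits(db, "tag_db"))
  if (is.null(novel_genomes) && n_novel > 0) {
    novel_genomes <- generate_novel_genomes(genomes, n = max(10, 3 * n_novel),
                                            seed = derive_seed(seed, 29L))
  }
  db_species <- db$species$species_id
  examples <- vector("list", nrow(grid))
  for (cell in seq_len(nrow(grid))) {
    cell_seed <- derive_seed(seed, 1000L + cell)
    novel_chosen <- if (n_novel > 0) {
      set.seed(derive_seed(cell_seed, 31L))
      sample(novel_genomes, min(n_novel, length(novel_genomes)))
    } else list()
    novel_ids <- vapply(novel_chosen, `[[`, character(1), "species_id")
    pool <- c(genomes, novel_chosen)
    richness <- min(grid$richness[cell], length(db_species))
    truth <- sample_composition(pool, richness + length(novel_ids),
                                seed = cell_seed, include = novel_ids)
    cfg <- sim_config(depth = grid$depth[cell],
                      mutation_rate = grid$mutation[cell], seed = cell_seed)
    sim <- simulate_reads(truth, pool, cfg)
    counts <- digest_reads(sim$reads, db$enzyme)
    feats <- first_round(counts, db)
    if (nrow(feats) == 0) next
    present <- intersect(truth$species_id, db_species)
    feats[, label := ifelse(species_id %in% present,
                            "true_positive", "false_positive")]
    feats[, sample_id := sprintf("cell%02d_r%d_d%d_m%g", cell,
                                 grid$richness[cell], grid$depth[cell],
                                 grid$mutation[cell])]
    examples[[cell]] <- feats[, c("sample_id", "species_id", FEATURE_ORDER,
                                  "label"), with = FALSE]
  }
  out <- rbindlist(examples)
  classes <- unique(out$label)
  if (length(classes) < 2) {
    warning("training set contains a single class (", paste(classes, collapse = ""),
            "); extend the grid or add novel species")
  }
  out[]
}

#' Train the false-positive classifier
#'
#' Fits a random-forest ensemble on the four log-features with inverse-class
#' weighting. A 20% stratified holdout is scored first and its accuracy
#' recorded in the model metadata; the returned forest is refit on all
#' examples.
#'
#' @param examples Training table from [make_training_set()].
#' @param seed RNG seed controlling bootstrap and split (default 42).
#' @param n_estimators Number of trees (default 500).
#' @param threshold Default decision threshold stored with the model.
#' @return An `fp_model`: list with the fitted `forest`, `feature_order`,
#'   `seed`, `n_estimators`, `threshold`, `holdout_accuracy`,
#'   `training_fingerprint` and `version`.
#' @export
train_fp_model <- function(examples, seed = 42, n_estimators = 500,
                           threshold = 0.5) {
  stopifnot(n_estimators >= 1)
  examples <- as.data.table(examples)
  if (anyNA(examples[, FEATURE_ORDER, with = FALSE])) {
    stop("NA/NaN feature values in training examples")
  }
  y <- factor(examples$label, levels = c("false_positive", "true_positive"))
  if (nlevels(droplevels(y)) < 2) {
    stop("training requires both classes; got only ",
         paste(unique(examples$label), collapse = ", "))
  }
  x <- as.data.frame(examples[, FEATURE_ORDER, with = FALSE])
  classwt <- as.vector(length(y) / (2 * table(y)))
  fit_rf <- function(xi, yi) {
    randomForest::randomForest(x = xi, y = yi, ntree = n_estimators,
                               mtry = 2, classwt = classwt)
  }
  # stratified 80/20 holdout for the recorded accuracy
  set.seed(derive_seed(seed, 37L))
  hold <- unlist(lapply(split(seq_along(y), y), function(i)
    sample(i, max(1, round(0.2 * length(i))))))
  set.seed(derive_seed(seed, 41L))
  fit_hold <- fit_rf(x[-hold, , drop = FALSE], droplevels(y[-hold]))
  pred_hold <- predict(fit_hold, x[hold, , drop = FALSE])
  holdout_accuracy <- mean(as.character(pred_hold) == as.character(y[hold]))
  set.seed(derive_seed(seed, 43L))
  forest <- fit_rf(x, y)
  structure(
    list(forest = forest, feature_order = FEATURE_ORDER,
         seed = as.integer(seed), n_estimators = as.integer(n_estimators),
         threshold = threshold, holdout_accuracy = holdout_accuracy,
         training_fingerprint = object_md5(examples),
         version = FP_MODEL_VERSION),
    class = "fp_model"
  )
}

#' @export
print.fp_model <- function(x, ...) {
  cat(sprintf("<fp_model> %d trees on (%s); holdout accuracy %.3f\n",
              x$n_estimators, paste(x$feature_order, collapse = ", "),
              x$holdout_accuracy))
  invisible(x)
}

#' Predict true-positive probabilities for candidate species
#'
#' @param model An `fp_model`.
#' @param features data.frame/data.table containing the model's feature
#'   columns (order is taken from the model metadata; missing or NaN values
#'   are an error).
#' @return Numeric vector of true-positive probabilities in \[0, 1\].
#' @export
predict_fp <- function(model, features) {
  stopifnot(inherits(model, "fp_model"))
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_order, names(features))
  if (length(missing) > 0) {
    stop("feature column(s) missing (order/naming mismatch with model): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(features) == 0) return(numeric(0))
  x <- features[, model$feature_order, drop = FALSE]
  if (anyNA(x)) {
    bad <- which(rowSums(is.na(x)) > 0)
    stop("NA/NaN feature values for row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  unname(predict(model$forest, x, type = "prob")[, "true_positive"])
}

#' Save / load the classifier
#'
#' A versioned directory: serialized forest plus a JSON metadata file
#' (feature order, seed, tree count, threshold, holdout accuracy, training
#' fingerprint). Loading enforces version and feature order, and a reloaded
#' model predicts bit-identically.
#'
#' @param model An `fp_model`.
#' @param path Directory.
#' @return `save_fp_model` returns `path` invisibly; `load_fp_model` the model.
#' @export
save_fp_model <- function(model, path) {
  stopifnot(inherits(model, "fp_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$forest, file.path(path, "forest.rds"))
  meta <- model[setdiff(names(model), "forest")]
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_fp_model
#' @export
load_fp_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "metadata.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$version), FP_MODEL_VERSION)) {
    stop("fp_model version mismatch: found ", meta$version,
         ", expected ", FP_MODEL_VERSION)
  }
  if (!identical(meta$feature_order, FEATURE_ORDER)) {
    stop("fp_model feature order mismatch: ",
         paste(meta$feature_order, collapse = ","))
  }
  model <- c(list(forest = readRDS(file.path(path, "forest.rds"))), meta)
  model$seed <- as.integer(model$seed)
  model$n_estimators <- as.integer(model$n_estimators)
  class(model) <- "fp_model"
  model
}
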