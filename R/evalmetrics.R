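#' Profiling evaluation metrics
#'
#' Identification is scored set-wise: precision is the fraction of
#' identified species that are truly present, recall the fraction of truly
#' present species identified, F1 their harmonic mean. Abundance estimation
#' is scored on relative-abundance vectors aligned on the union of species
#' (absentees as zero, each side renormalized): L2 similarity is 1 minus the
#' Euclidean distance (can be negative, down to 1 - sqrt(2)), Bray-Curtis
#' similarity is 1 minus the BC dissimilarity, which on normalized vectors
#' equals `sum(abs(u - v))/2`.
#'
#' @name evalmetrics
NULL

#' Species-identification metrics
#'
#' @param predicted_species Character vector of identified species.
#' @param truth_species Non-empty character vector of species truly present.
#' @return List with `precision`, `recall`, `f1`, and the `tp`, `fp`, `fn`
#'   species vectors.
#' @examples
#' identification_metrics(c("A", "B", "C"), c("A", "B"))
#' @export
identification_metrics <- function(predicted_species, truth_species) {
  truth_species <- unique(truth_species)
  if (length(truth_species) == 0) {
    stop("empty truth set: recall is undefined")
  }
  predicted_species <- unique(predicted_species)
  tp <- intersect(predicted_species, truth_species)
  fp <- setdiff(predicted_species, truth_species)
  fn <- setdiff(truth_species, predicted_species)
  precision <- if (length(predicted_species) == 0) 0 else
    length(tp) / length(predicted_species)
  recall <- length(tp) / length(truth_species)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn)
}

#' Abundance-similarity metrics
#'
#' @param predicted Named numeric vector of relative abundances.
#' @param truth Named numeric vector of relative abundances.
#' @return List with `l2_similarity` (1 - Euclidean distance, not clamped)
#'   and `bc_similarity` (1 - Bray-Curtis dissimilarity, in \[0, 1\]).
#' @examples
#' abundance_similarity(c(A = 1), c(B = 1))  # l2 = 1 - sqrt(2), bc = 0
#' @export
abundance_similarity <- function(predicted, truth) {
  if (any(predicted < 0) || any(truth < 0)) stop("negative abundance")
  species <- union(names(predicted), names(truth))
  u <- stats::setNames(rep(0, length(species)), species)
  v <- u
  u[names(predicted)] <- predicted
  v[names(truth)] <- truth
  if (sum(u) > 0) u <- u / sum(u)
  if (sum(v) > 0) v <- v / sum(v)
  list(l2_similarity = 1 - sqrt(sum((u - v)^2)),
       bc_similarity = 1 - sum(abs(u - v)) / 2)
}

#' Evaluate a profiling run against its ground truth
#'
#' @param profile Profile table (data.frame with `species_id` and `T`) or a
#'   TSV path as written by [write_profile_tsv()].
#' @param truth Truth table (data.frame with `species_id` and `T_true`) or a
#'   TSV path as written by [simulate_reads()].
#' @param run_info Optional named list (depth, richness, mutation, seed...)
#'   prepended to the report row.
#' @return One-row data.table with the run info, `precision`, `recall`,
#'   `f1`, `l2_similarity`, `bc_similarity`, `n_tp`, `n_fp`, `n_fn`;
#'   `attr(, "details")` keeps the tp/fp/fn species lists.
#' @export
evaluate_run <- function(profile, truth, run_info = NULL) {
  if (is.character(profile)) {
    profile <- tryCatch(fread(profile, colClasses = list(character = "species_id")),
                        error = function(e) stop("cannot parse profile TSV: ",
                                                 conditionMessage(e), call. = FALSE))
  }
  if (is.character(truth)) truth <- read_truth(truth)
  profile <- as.data.table(profile)
  truth <- as.data.table(truth)
  id <- identification_metrics(profile$species_id, truth$species_id)
  ab <- abundance_similarity(
    stats::setNames(profile$T, profile$species_id),
    stats::setNames(truth$T_true, truth$species_id)
  )
  row <- data.table(
    precision = id$precision, recall = id$recall, f1 = id$f1,
    l2_similarity = ab$l2_similarity, bc_similarity = ab$bc_similarity,
    n_tp = length(id$tp), n_fp = length(id$fp), n_fn = length(id$fn)
  )
  if (!is.null(run_info)) row <- cbind(as.data.table(run_info), row)
  setattr(row, "details", id[c("tp", "fp", "fn")])
  row[]
}
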