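#' Two-round taxonomic profiling
#'
#' The first, qualitative round matches sample tags against the
#' preconstructed species-specific tag database and computes, for every
#' candidate species i with at least one matched specific tag:
#' \deqn{C_i = U_i / E_i}{C = U/E} (genome coverage),
#' \deqn{\tilde{Q}_i = Q_i / C_i}{Qt = Q/C} (inferred sequenced specific tags),
#' \deqn{N_i = \tilde{Q}_i / E_i = Q_i / U_i}{N = Qt/E = Q/U} (taxonomic count),
#' \deqn{R_i = \tilde{Q}_i / R = Q_i E_i / (U_i R)}{Rseq = Qt/R} (sequence count) and
#' \deqn{G_i = \sqrt{Q_i U_i}}{G = sqrt(Q U)} (G-score),
#' where Q is the number of matched specific-tag instances, U the number of
#' distinct matched specific tags, E the species' specific-tag count in the
#' database and R the total read count. The log-transformed features feed a
#' classifier that eliminates false-positive candidates. The second,
#' quantitative round re-matches the sample against a sample-specific
#' database restricted to the identified species (which enlarges each
#' species' specific-tag set) and estimates the taxonomic abundance
#' \deqn{T_i = (Q_i/H_i) / \sum_j (Q_j/H_j)}{T = (Q/H) / sum(Q/H)}
#' together with the second-round coverage \eqn{O_i = U_i/E'_i}.
#'
#' @name profiler
NULL

FEATURE_ORDER <- c("logC", "logN", "logR", "logG")

#' First-round candidate detection and feature computation
#'
#' @param tag_counts A `tag_counts` object from [digest_reads()] (or a
#'   data.table of `tag`, `count`, then `total_reads` is required).
#' @param db A `tag_db`.
#' @param total_reads Total read count R; defaults to the one recorded in
#'   `tag_counts`.
#' @return A data.table with one row per candidate species (at least one
#'   matched specific tag): `species_id`, `Q`, `U`, `E`, `C`, `Q_tilde`,
#'   `N`, `R_seq`, `G` and the log-features `logC`, `logN`, `logR`, `logG`.
#' @export
first_round <- function(tag_counts, db, total_reads = NULL) {
  stopifnot(inherits(db, "tag_db"))
  if (inherits(tag_counts, "tag_counts")) {
    if (!identical(tag_counts$enzyme, db$enzyme$name)) {
      stop("tag counts were produced with enzyme '", tag_counts$enzyme,
           "' but the database uses '", db$enzyme$name, "'")
    }
    total_reads <- total_reads %||% tag_counts$total_reads
    tag_counts <- tag_counts$tags
  }
  if (is.null(total_reads) || total_reads < 1) {
    if (is.null(total_reads) || nrow(tag_counts) > 0) {
      stop("total_reads (R) must be provided and >= 1")
    }
    return(empty_features())  # legitimately empty input (R = 0, no tags)
  }
  hits <- db$index[tag_counts, on = "tag", nomatch = NULL]
  if (nrow(hits) == 0) {
    return(empty_features())
  }
  f <- hits[, .(Q = as.numeric(sum(count)), U = .N), by = species_id]
  f <- db$species[, .(species_id, E)][f, on = "species_id"]
  f[, C := U / E]
  f[, Q_tilde := Q / C]
  f[, N := Q / U]
  f[, R_seq := Q * E / (U * as.numeric(total_reads))]
  f[, G := sqrt(Q * as.numeric(U))]
  f[, `:=`(logC = log(C), logN = log(N), logR = log(R_seq), logG = log(G))]
  setorder(f, species_id)
  f[]
}

empty_features <- function() {
  data.table(species_id = character(0), E = integer(0), Q = integer(0),
             U = integer(0), C = numeric(0), Q_tilde = numeric(0),
             N = numeric(0), R_seq = numeric(0), G = numeric(0),
             logC = numeric(0), logN = numeric(0), logR = numeric(0),
             logG = numeric(0))
}

#' Eliminate false-positive candidates with the trained classifier
#'
#' @param features First-round feature table from [first_round()].
#' @param model A `fp_model` from [train_fp_model()].
#' @param threshold True-positive probability cutoff; defaults to the
#'   model's stored threshold (0.5).
#' @return The feature table with columns `prob` and `kept` added;
#'   `attr(, "species")` holds the identified species_ids.
#' @export
identify_species <- function(features, model, threshold = NULL) {
  threshold <- threshold %||% model$threshold
  features <- copy(features)
  if (nrow(features) == 0) {
    features[, `:=`(prob = numeric(0), kept = logical(0))]
    setattr(features, "species", character(0))
    return(features[])
  }
  features[, prob := predict_fp(model, features)]
  features[, kept := prob >= threshold]
  setattr(features, "species", features$species_id[features$kept])
  features[]
}

#' Second-round quantification against the sample-specific database
#'
#' @param tag_counts The sample's `tag_counts` (same digestion as round 1).
#' @param sample_db A `tag_db` restricted to the identified species (from
#'   [build_sample_specific_db()]).
#' @param source_stats The preconstructed database's species table, whose
#'   `H` (total in-silico tags per species) normalizes the matched counts.
#' @param coverage_corrected If TRUE, divide each species' second-round Q by
#'   its observed coverage O before normalizing (coverage-corrected
#'   abundance variant).
#' @return A `profile` data.table sorted by decreasing abundance:
#'   `species_id`, `lineage`, `T` (taxonomic abundance, sums to 1), `O`
#'   (second-round coverage), `Q2`, `U2`, `E2`.
#' @export
second_round <- function(tag_counts, sample_db, source_stats,
                         coverage_corrected = FALSE) {
  stopifnot(inherits(sample_db, "tag_db"))
  if (inherits(tag_counts, "tag_counts")) tag_counts <- tag_counts$tags
  hits <- sample_db$index[tag_counts, on = "tag", nomatch = NULL]
  prof <- hits[, .(Q2 = sum(count), U2 = .N), by = species_id]
  missing <- setdiff(sample_db$species$species_id, prof$species_id)
  if (length(missing) > 0) {
    prof <- rbind(prof, data.table(species_id = missing, Q2 = 0L, U2 = 0L))
  }
  prof <- sample_db$species[, .(species_id, lineage, E2 = E)][prof, on = "species_id"]
  h <- source_stats[, .(species_id, H)]
  if (anyNA(match(prof$species_id, h$species_id))) {
    stop("identified species missing from source statistics (DB desync)")
  }
  prof <- h[prof, on = "species_id"]
  prof[, O := U2 / E2]
  w <- if (coverage_corrected) {
    ifelse(prof$O > 0, prof$Q2 / prof$O, 0) / prof$H
  } else {
    prof$Q2 / prof$H
  }
  prof[, T := if (sum(w) > 0) w / sum(w) else 0]
  setorderv(prof, c("T", "species_id"), c(-1L, 1L))
  setcolorder(prof, c("species_id", "lineage", "T", "O", "Q2", "U2", "E2", "H"))
  prof[]
}

#' Profile a sample end to end
#'
#' Orchestrates digestion, first-round feature computation, false-positive
#' elimination, sample-specific database rebuild and second-round abundance
#' estimation.
#'
#' @param reads Character vector of read sequences or FASTQ path(s).
#' @param db The preconstructed `tag_db`.
#' @param model A trained `fp_model`.
#' @param threshold Optional classifier cutoff override.
#' @param coverage_corrected Passed to [second_round()].
#' @return List with `profile` (final abundance table), `features`
#'   (first-round features with classifier probability and keep flag, for
#'   auditability) and `total_reads`. Zero identified species yields an
#'   empty profile with a warning.
#' @export
profile_sample <- function(reads, db, model, threshold = NULL,
                           coverage_corrected = FALSE) {
  counts <- if (inherits(reads, "tag_counts")) reads else digest_reads(reads, db$enzyme)
  features <- first_round(counts, db)
  features <- identify_species(features, model, threshold)
  identified <- attr(features, "species")
  if (length(identified) == 0) {
    warning("no species identified; returning empty profile")
    return(list(profile = empty_profile(), features = features,
                total_reads = counts$total_reads))
  }
  sample_db <- build_sample_specific_db(db, identified)
  profile <- second_round(counts, sample_db, db$species,
                          coverage_corrected = coverage_corrected)
  profile <- merge(profile, features[, .(species_id, prob)],
                   by = "species_id", sort = FALSE)
  list(profile = profile, features = features, total_reads = counts$total_reads)
}

empty_profile <- function() {
  data.table(species_id = character(0), lineage = character(0),
             T = numeric(0), O = numeric(0), Q2 = integer(0),
             U2 = integer(0), E2 = integer(0), H = integer(0),
             prob = numeric(0))
}

#' Write profile / feature tables as TSV
#' @param x Table returned in [profile_sample()] output.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(x, path) {
  fwrite(x, path, sep = "\t")
  invisible(path)
}
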