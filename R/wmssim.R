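#' Ground-truth shotgun metagenome simulator
#'
#' Generates random genomes, log-normal community compositions carrying a
#' dual ground truth (taxonomic abundance, the cell fraction, and sequence
#' abundance, the DNA fraction: S* is proportional to T* times genome
#' length), genome-wide substitution divergence, and short reads with
#' per-base substitution errors. Everything is deterministic given a seed.
#'
#' @name wmssim
NULL

# Random DNA string of length n at the given GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

seven_rank_lineage <- function(species_name) {
  paste0("k__SynKingdom|p__SynPhylum|c__SynClass|o__SynOrder|",
         "f__SynFamily|g__SynGenus|s__", species_name)
}

#' Generate a universe of random genomes, one per synthetic species
#'
#' @param n_species Number of species.
#' @param genome_length Genome length in bp (single contig).
#' @param gc GC content in \[0, 1\].
#' @param seed Integer seed; the generator is deterministic per seed.
#' @return List of [genome_record()]s with generated 7-rank lineages.
#' @export
generate_genomes <- function(n_species, genome_length = 1e5, gc = 0.5, seed = 1) {
  stopifnot(n_species >= 1, genome_length >= 1)
  set.seed(derive_seed(seed, 11L))
  lapply(seq_len(n_species), function(i) {
    sp <- sprintf("sp%03d", i)
    genome_record(sprintf("g%03d", i), sp, random_dna(genome_length, gc),
                  lineage = seven_rank_lineage(sp))
  })
}

#' Apply genome-wide substitution divergence
#'
#' Each base is independently replaced by a uniformly chosen different base
#' with probability `r`; length is preserved. Models the divergence between
#' a sampled strain and its database representative.
#'
#' @param genome A [genome_record()] or a single DNA string.
#' @param r Per-base substitution rate in \[0, 0.25\] (or up to 1 for
#'   degenerate forced-substitution cases).
#' @param seed Integer seed.
#' @return Same type as `genome`, mutated.
#' @export
mutate_genome <- function(genome, r, seed = 1) {
  stopifnot(r >= 0, r <= 1)
  if (inherits(genome, "genome_record")) {
    set.seed(derive_seed(seed, 13L))
    genome$sequences <- vapply(genome$sequences, mutate_dna_chr, character(1), r = r)
    return(genome)
  }
  set.seed(derive_seed(seed, 13L))
  mutate_dna_chr(genome, r)
}

# Substitution mutation on one string under the current RNG stream.
mutate_dna_chr <- function(s, r) {
  if (r == 0) return(s)
  n <- nchar(s)
  pos <- which(runif(n) < r)
  if (length(pos) == 0) return(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  old <- match(chars[pos], DNA_BASES)
  shift <- sample.int(3L, length(pos), replace = TRUE)
  new_idx <- ((old - 1L + shift) %% 4L) + 1L
  # positions holding non-ACGT characters are replaced by a uniform base
  new_idx[is.na(new_idx)] <- sample.int(4L, sum(is.na(new_idx)), replace = TRUE)
  chars[pos] <- DNA_BASES[new_idx]
  paste(chars, collapse = "")
}

#' Generate out-of-database "novel" species as mosaic genomes
#'
#' Real false-positive identifications arise from sequence shared between an
#' absent organism and database species (conserved regions, transferred
#' segments). Independent random genomes cannot produce them, so novel
#' species are emulated as mosaics: a random backbone carrying a few short,
#' slightly diverged segments copied from randomly chosen database genomes.
#' Reads from a mosaic hit the donor species' specific tags inside the
#' shared segments only, producing the characteristic false-positive
#' signature (low genome coverage, saturating taxonomic count).
#'
#' @param genomes Database [genome_record()]s to donate segments.
#' @param n Number of novel species.
#' @param segment_donors Donor species per novel genome.
#' @param segment_length Length of each shared segment (bp).
#' @param divergence Substitution rate applied to copied segments.
#' @param genome_length Novel genome length.
#' @param gc Backbone GC content.
#' @param seed Integer seed.
#' @return List of [genome_record()]s with species_ids `novel###`.
#' @export
generate_novel_genomes <- function(genomes, n, segment_donors = 3,
                                   segment_length = 2000, divergence = 0.01,
                                   genome_length = 1e5, gc = 0.5, seed = 1) {
  stopifnot(n >= 1, segment_donors >= 1,
            segment_length * segment_donors < genome_length)
  set.seed(derive_seed(seed, 17L))
  lapply(seq_len(n), function(i) {
    backbone <- random_dna(genome_length, gc)
    donors <- sample(genomes, segment_donors)
    # non-overlapping insertion slots
    slot_starts <- (seq_len(segment_donors) - 1L) *
      (genome_length %/% segment_donors) +
      sample.int(genome_length %/% segment_donors - segment_length,
                 segment_donors)
    for (j in seq_len(segment_donors)) {
      src <- donors[[j]]$sequences[[1]]
      from <- sample.int(nchar(src) - segment_length + 1L, 1L)
      seg <- mutate_dna_chr(substring(src, from, from + segment_length - 1L),
                            divergence)
      substr(backbone, slot_starts[j], slot_starts[j] + segment_length - 1L) <- seg
    }
    sp <- sprintf("novel%03d", i)
    genome_record(sprintf("ng%03d", i), sp, backbone,
                  lineage = seven_rank_lineage(sp))
  })
}

#' Draw a community composition with dual ground truth
#'
#' Taxonomic abundances are normalized draws from a log-normal distribution
#' with meanlog 0 and sdlog 1; sequence abundances follow as
#' S* proportional to T* times genome length, renormalized.
#'
#' @param genomes Species pool as a list of [genome_record()]s.
#' @param richness Number of species to draw (without replacement).
#' @param seed Integer seed.
#' @param include Optional species_ids that must be in the community.
#' @return A `community_truth` data.table with columns `species_id`,
#'   `T_true`, `S_true`, `L`, both abundance columns summing to 1.
#' @export
sample_composition <- function(genomes, richness, seed = 1, include = NULL) {
  pool <- data.table(
    species_id = vapply(genomes, `[[`, character(1), "species_id"),
    L = vapply(genomes, `[[`, numeric(1), "length")
  )
  pool <- pool[, .(L = sum(L)), by = species_id]
  if (richness > nrow(pool)) {
    stop("richness (", richness, ") exceeds species pool size (", nrow(pool), ")")
  }
  set.seed(derive_seed(seed, 19L))
  chosen <- union(include, sample(setdiff(pool$species_id, include),
                                  richness - length(include)))
  truth <- pool[species_id %in% chosen]
  raw <- rlnorm(nrow(truth), meanlog = 0, sdlog = 1)
  truth[, T_true := raw / sum(raw)]
  truth[, S_true := T_true * L / sum(T_true * L)]
  setcolorder(truth, c("species_id", "T_true", "S_true", "L"))
  setorder(truth, species_id)
  class(truth) <- c("community_truth", class(truth))
  truth[]
}

#' Simulation configuration
#'
#' @param depth Total number of reads.
#' @param read_length Read length in bp.
#' @param error_rate Per-base substitution sequencing-error probability.
#' @param mutation_rate Genome-wide substitution divergence applied to each
#'   community genome before read sampling (strain-vs-reference model).
#' @param paired Emit read pairs (mates from opposite strands of a fragment
#'   of `insert_size`); `depth` still counts individual reads.
#' @param insert_size Fragment length for paired mode.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(depth, read_length = 100, error_rate = 0.001,
                       mutation_rate = 0, paired = FALSE, insert_size = 300,
                       seed = 1) {
  stopifnot(depth >= 0, read_length >= 1,
            error_rate >= 0, error_rate <= 1,
            mutation_rate >= 0, mutation_rate <= 1)
  structure(list(depth = as.integer(depth), read_length = as.integer(read_length),
                 error_rate = error_rate, mutation_rate = mutation_rate,
                 paired = isTRUE(paired), insert_size = as.integer(insert_size),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Vectorised substitution errors on a read vector.
apply_read_errors <- function(reads, read_length, error_rate) {
  if (error_rate == 0 || length(reads) == 0) return(reads)
  n_err <- rbinom(length(reads), read_length, error_rate)
  for (j in seq_len(max(n_err, 0L))) {
    idx <- which(n_err >= j)
    if (length(idx) == 0) break
    pos <- sample.int(read_length, length(idx), replace = TRUE)
    old <- match(substr(reads[idx], pos, pos), DNA_BASES)
    shift <- sample.int(3L, length(idx), replace = TRUE)
    new_idx <- ((old - 1L + shift) %% 4L) + 1L
    new_idx[is.na(new_idx)] <- sample.int(4L, sum(is.na(new_idx)), replace = TRUE)
    substr(reads[idx], pos, pos) <- DNA_BASES[new_idx]
  }
  reads
}

#' Simulate shotgun reads from a community
#'
#' Reads are allocated to species by a multinomial draw on the sequence
#' abundance S*, positioned uniformly on the (optionally mutated) genome
#' with uniform strand, and degraded with independent per-base substitution
#' errors. Paired mode emits mates from the two ends of a fragment.
#'
#' @param truth A `community_truth` from [sample_composition()].
#' @param genomes List of [genome_record()]s covering the community.
#' @param config A [sim_config()].
#' @param out Optional output prefix; writes `<out>.fastq` (or `_1/_2` when
#'   paired) and `<out>.truth.tsv` with the seed recorded in its header.
#' @return List with `reads` (character), `read_species` (per-read source),
#'   `truth`, `config`, and `files` when `out` was given.
#' @export
simulate_reads <- function(truth, genomes, config, out = NULL) {
  stopifnot(inherits(config, "sim_config"))
  by_id <- stats::setNames(genomes, vapply(genomes, `[[`, character(1), "species_id"))
  missing <- setdiff(truth$species_id, names(by_id))
  if (length(missing) > 0) stop("no genome for: ", paste(missing, collapse = ", "))
  rl <- config$read_length
  set.seed(derive_seed(config$seed, 23L))
  n_units <- if (config$paired) config$depth %/% 2L else config$depth
  counts <- if (n_units > 0)
    as.vector(rmultinom(1, n_units, truth$S_true)) else rep(0L, nrow(truth))
  reads <- character(0)
  read_species <- character(0)
  for (k in seq_len(nrow(truth))) {
    if (counts[k] == 0) next
    g <- by_id[[truth$species_id[k]]]
    s <- g$sequences[[1]]
    if (config$mutation_rate > 0) {
      s <- mutate_dna_chr(s, config$mutation_rate)
    }
    L <- nchar(s)
    span <- if (config$paired) config$insert_size else rl
    if (L < span) stop("genome of ", g$species_id, " shorter than read/fragment span")
    start <- sample.int(L - span + 1L, counts[k], replace = TRUE)
    fwd <- runif(counts[k]) < 0.5
    if (config$paired) {
      m1 <- substring(s, start, start + rl - 1L)
      m2 <- revcomp(substring(s, start + span - rl, start + span - 1L))
      r1 <- ifelse(fwd, m1, m2)
      r2 <- ifelse(fwd, m2, m1)
      new_reads <- c(rbind(r1, r2))
      sp <- rep(truth$species_id[k], 2L * counts[k])
    } else {
      new_reads <- substring(s, start, start + rl - 1L)
      new_reads[!fwd] <- revcomp(new_reads[!fwd])
      sp <- rep(truth$species_id[k], counts[k])
    }
    reads <- c(reads, new_reads)
    read_species <- c(read_species, sp)
  }
  reads <- apply_read_errors(reads, rl, config$error_rate)
  res <- list(reads = reads, read_species = read_species,
              truth = truth, config = config)
  if (!is.null(out)) {
    res$files <- write_simulation(res, out)
  }
  res
}

# FASTQ (constant Q40 qualities) + truth TSV with seed header.
write_simulation <- function(sim, out_prefix) {
  dir.create(dirname(out_prefix), showWarnings = FALSE, recursive = TRUE)
  qual <- strrep("I", sim$config$read_length)
  ids <- sprintf("r%07d_%s", seq_along(sim$reads), sim$read_species)
  fq_lines <- function(i) {
    as.vector(rbind(paste0("@", ids[i]), sim$reads[i], "+", qual))
  }
  files <- character(0)
  if (sim$config$paired) {
    i1 <- seq(1, length(sim$reads), by = 2)
    i2 <- seq(2, length(sim$reads), by = 2)
    f1 <- paste0(out_prefix, "_1.fastq"); f2 <- paste0(out_prefix, "_2.fastq")
    writeLines(fq_lines(i1), f1)
    writeLines(fq_lines(i2), f2)
    files <- c(files, f1, f2)
  } else {
    f <- paste0(out_prefix, ".fastq")
    writeLines(fq_lines(seq_along(sim$reads)), f)
    files <- c(files, f)
  }
  tf <- paste0(out_prefix, ".truth.tsv")
  header <- c(sprintf("# seed=%d depth=%d read_length=%d error_rate=%g mutation_rate=%g",
                      sim$config$seed, sim$config$depth, sim$config$read_length,
                      sim$config$error_rate, sim$config$mutation_rate))
  writeLines(header, tf)
  fwrite(sim$truth, tf, sep = "\t", append = TRUE, col.names = TRUE)
  c(files, tf)
}

#' Read a simulation truth TSV
#' @param path Path written by [simulate_reads()] (comment headers allowed).
#' @return A `community_truth` data.table.
#' @export
read_truth <- function(path) {
  truth <- fread(file = path, skip = "species_id",
                 colClasses = list(character = "species_id"))
  class(truth) <- c("community_truth", class(truth))
  truth[]
}
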