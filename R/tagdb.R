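#' Genome records and species-specific tag databases
#'
#' A genome collection is a list of `genome_record` objects (one genome
#' each, possibly several per species). Digesting every genome and comparing
#' tag sets across species yields, for species i, the total tag count H_i
#' and the set of E_i species-specific tags: canonical tags present in at
#' least one of its genomes, single-copy within every conspecific genome
#' where they occur, and absent from all genomes of every other species.
#' Those unique tags, indexed for exact matching, are the profiling markers.
#'
#' @name tagdb
NULL

#' Create a genome record
#'
#' @param genome_id Unique genome identifier.
#' @param species_id Species identifier (shared by conspecific genomes).
#' @param sequences Character vector of DNA sequences (contigs).
#' @param lineage 7-rank taxonomy string (kingdom to species), `|`-separated
#'   GTDB-style prefixes accepted.
#' @return A `genome_record` with fields `genome_id`, `species_id`,
#'   `lineage`, `sequences` and total `length` in bp.
#' @export
genome_record <- function(genome_id, species_id, sequences, lineage = NA_character_) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences))) {
    names(sequences) <- paste0(genome_id, "_ctg", seq_along(sequences))
  }
  structure(
    list(genome_id = as.character(genome_id),
         species_id = as.character(species_id),
         lineage = as.character(lineage),
         sequences = sequences,
         length = sum(nchar(sequences))),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s (%s): %d seq, %d bp\n",
              x$genome_id, x$species_id, length(x$sequences), x$length))
  invisible(x)
}

#' Read a genome collection from FASTA files and a taxonomy table
#'
#' @param fasta_paths Character vector of (multi-)FASTA files, one genome
#'   per file; the genome_id is the file name without extension.
#' @param taxonomy_tsv TSV with columns `genome_id`, `species_id` and
#'   optionally `lineage`.
#' @return List of [genome_record()]s.
#' @export
read_genomes <- function(fasta_paths, taxonomy_tsv) {
  tax <- fread(taxonomy_tsv, colClasses = "character")
  if (!all(c("genome_id", "species_id") %in% names(tax))) {
    stop("taxonomy table must have columns genome_id and species_id")
  }
  lapply(fasta_paths, function(p) {
    gid <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(p))
    row <- tax[tax$genome_id == gid]
    if (nrow(row) != 1) stop("genome '", gid, "' not resolvable in taxonomy table")
    seqs <- Biostrings::readDNAStringSet(p)
    genome_record(gid, row$species_id[1], stats::setNames(as.character(seqs), names(seqs)),
                  lineage = if ("lineage" %in% names(row)) row$lineage[1] else NA_character_)
  })
}

#' Write a genome collection as FASTA files plus a taxonomy TSV
#'
#' @param genomes List of [genome_record()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the taxonomy table path.
#' @export
write_genomes <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genomes) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(g$sequences),
                                file.path(dir, paste0(g$genome_id, ".fasta")))
  }
  tax <- rbindlist(lapply(genomes, function(g) {
    data.table(genome_id = g$genome_id, species_id = g$species_id,
               lineage = g$lineage, length = g$length)
  }))
  path <- file.path(dir, "taxonomy.tsv")
  fwrite(tax, path, sep = "\t")
  invisible(path)
}

# Digest one genome into a per-genome canonical tag table with genomic
# multiplicity: data.table(genome_id, species_id, tag, count).
digest_genome_tags <- function(record, enzyme) {
  tags <- unlist(lapply(record$sequences, function(s) {
    extract_tags_chr(sanitize_dna(s), enzyme)$tag
  }), use.names = FALSE)
  if (length(tags) == 0) {
    return(data.table(genome_id = character(0), species_id = character(0),
                      tag = character(0), count = integer(0)))
  }
  dt <- data.table(tag = tags)[, .(count = .N), by = tag]
  dt[, `:=`(genome_id = record$genome_id, species_id = record$species_id)]
  setcolorder(dt, c("genome_id", "species_id", "tag", "count"))
  dt
}

# Uniqueness call over a per-genome tag table restricted to a species
# universe: a tag is specific to species i iff it occurs in genomes of no
# other species and is single-copy in every conspecific genome where it
# occurs.
unique_tag_index <- function(genome_tags) {
  per_tag <- genome_tags[, .(n_species = uniqueN(species_id),
                             max_copy = max(count),
                             species_id = species_id[1]), by = tag]
  idx <- per_tag[n_species == 1L & max_copy == 1L, .(tag, species_id)]
  setkey(idx, tag)
  idx
}

# Assemble a tag_db object from cached per-genome tag tables.
tag_db_from_genome_tags <- function(genome_tags, enzyme, taxonomy,
                                    h_mode = "occurrences", provenance = list()) {
  idx <- unique_tag_index(genome_tags)
  h <- switch(h_mode,
    occurrences = genome_tags[, .(H = sum(count)), by = species_id],
    distinct = genome_tags[, .(H = uniqueN(tag)), by = species_id],
    stop("h_mode must be 'occurrences' or 'distinct'")
  )
  e <- idx[, .(E = .N), by = species_id]
  stats <- merge(taxonomy, h, by = "species_id", all.x = TRUE)
  stats <- merge(stats, e, by = "species_id", all.x = TRUE)
  stats[is.na(H), H := 0L]
  stats[is.na(E), E := 0L]
  if (any(stats$E == 0L)) {
    warning("species with no specific tags (unidentifiable): ",
            paste(stats$species_id[stats$E == 0L], collapse = ", "))
  }
  setorder(stats, species_id)
  structure(
    list(enzyme = provenance$enzyme, species = stats, index = idx,
         genome_tags = genome_tags, h_mode = h_mode, provenance = provenance),
    class = "tag_db"
  )
}

#' Build the species-specific 2b-tag database from a genome collection
#'
#' Every genome is digested in silico; a canonical tag is recorded as
#' specific to its species when it occurs in no other species' genomes and
#' is single-copy within each conspecific genome where it occurs.
#'
#' @param genomes List of [genome_record()]s (at least one species).
#' @param enzyme An [iib_enzyme()].
#' @param h_mode How the per-species total tag count H is counted:
#'   `"occurrences"` (default; with genomic multiplicity, the genome-size-like
#'   normalizer used in abundance estimation) or `"distinct"`.
#' @return A `tag_db` with fields `enzyme`, `species` (data.table:
#'   `species_id`, `lineage`, `L`, `H`, `E`), `index` (data.table keyed by
#'   `tag`, mapping each species-specific tag to its species),
#'   `genome_tags` (cached per-genome digestion) and `provenance`.
#' @export
build_tag_db <- function(genomes, enzyme, h_mode = "occurrences") {
  stopifnot(inherits(enzyme, "iib_enzyme"), length(genomes) >= 1)
  ids <- vapply(genomes, `[[`, character(1), "genome_id")
  if (anyDuplicated(ids)) {
    stop("duplicate genome_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genome_tags <- rbindlist(lapply(genomes, digest_genome_tags, enzyme = enzyme))
  taxonomy <- rbindlist(lapply(genomes, function(g) {
    data.table(species_id = g$species_id, lineage = g$lineage, L = g$length)
  }))[, .(lineage = lineage[1], L = sum(L)), by = species_id]
  provenance <- list(
    enzyme = enzyme,
    n_genomes = length(genomes),
    genome_hash = object_md5(lapply(genomes, function(g)
      list(g$genome_id, g$species_id, unname(g$sequences)))),
    h_mode = h_mode,
    built = "iibprofiler"
  )
  tag_db_from_genome_tags(genome_tags, enzyme, taxonomy, h_mode, provenance)
}

#' @export
print.tag_db <- function(x, ...) {
  cat(sprintf("<tag_db> %d species, %d specific tags indexed [%s, %s]\n",
              nrow(x$species), nrow(x$index), x$enzyme$name, x$h_mode))
  invisible(x)
}

#' Rebuild a sample-specific database restricted to identified species
#'
#' Identical uniqueness computation to [build_tag_db()] but with the
#' comparison universe restricted to a species subset. Shrinking the
#' universe can only release tags that were shared with dropped species, so
#' every retained species ends up with at least as many specific tags
#' (E' >= E), which is what makes the second, quantitative round of
#' profiling more precise.
#'
#' @param db A `tag_db` built from the full collection (its cached
#'   per-genome digestion is reused), or a list of [genome_record()]s (then
#'   `enzyme` is required and genomes are re-digested).
#' @param species_subset Non-empty character vector of species to retain.
#' @param enzyme Required only when `db` is a genome list.
#' @return A `tag_db` over the subset universe.
#' @export
build_sample_specific_db <- function(db, species_subset, enzyme = NULL) {
  if (length(species_subset) == 0) stop("empty species subset: nothing to quantify")
  if (inherits(db, "tag_db")) {
    genome_tags <- db$genome_tags
    taxonomy <- db$species[, .(species_id, lineage, L)]
    enzyme <- db$enzyme
    h_mode <- db$h_mode
    provenance <- modifyList(db$provenance, list(subset = sort(species_subset)))
  } else {
    stopifnot(inherits(enzyme, "iib_enzyme"))
    genome_tags <- rbindlist(lapply(db, digest_genome_tags, enzyme = enzyme))
    taxonomy <- rbindlist(lapply(db, function(g) {
      data.table(species_id = g$species_id, lineage = g$lineage, L = g$length)
    }))[, .(lineage = lineage[1], L = sum(L)), by = species_id]
    h_mode <- "occurrences"
    provenance <- list(enzyme = enzyme, subset = sort(species_subset))
  }
  known <- unique(taxonomy$species_id)
  missing <- setdiff(species_subset, known)
  if (length(missing) > 0) {
    stop("species not in source collection: ", paste(missing, collapse = ", "))
  }
  tag_db_from_genome_tags(genome_tags[species_id %in% species_subset],
                          enzyme, taxonomy[species_id %in% species_subset],
                          h_mode, provenance)
}

TAGDB_FORMAT_VERSION <- "1"

#' Save / load a tag database
#'
#' The on-disk format is a directory of TSV tables (`species.tsv`,
#' `index.tsv`, `genome_tags.tsv`) plus a JSON manifest recording the format
#' version, the enzyme, provenance and per-file md5 checksums. Loading
#' verifies version and checksums and reproduces the in-memory object
#' exactly.
#'
#' @param db A `tag_db`.
#' @param path Directory to write to / read from.
#' @return `save_tag_db` returns `path` invisibly; `load_tag_db` returns the
#'   `tag_db`.
#' @export
save_tag_db <- function(db, path) {
  stopifnot(inherits(db, "tag_db"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- c(species = "species.tsv", index = "index.tsv",
             genome_tags = "genome_tags.tsv")
  fwrite(db$species, file.path(path, files["species"]), sep = "\t", na = "NA")
  fwrite(db$index, file.path(path, files["index"]), sep = "\t", na = "NA")
  fwrite(db$genome_tags, file.path(path, files["genome_tags"]), sep = "\t", na = "NA")
  manifest <- list(
    format_version = TAGDB_FORMAT_VERSION,
    enzyme = db$enzyme[c("name", "recognition", "left_flank", "right_flank")],
    h_mode = db$h_mode,
    provenance = db$provenance[setdiff(names(db$provenance), "enzyme")],
    checksums = as.list(vapply(files, function(f)
      unname(tools::md5sum(file.path(path, f))), character(1)))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_tag_db
#' @export
load_tag_db <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop("no manifest.json under ", path)
  manifest <- jsonlite::read_json(mf)
  if (!identical(as.character(manifest$format_version), TAGDB_FORMAT_VERSION)) {
    stop("tag_db format version mismatch: found ", manifest$format_version,
         ", expected ", TAGDB_FORMAT_VERSION)
  }
  for (f in names(manifest$checksums)) {
    fp <- file.path(path, paste0(f, ".tsv"))
    sum_now <- unname(tools::md5sum(fp))
    if (is.na(sum_now) || !identical(sum_now, manifest$checksums[[f]])) {
      stop("checksum mismatch for ", fp, " (corrupt or truncated database)")
    }
  }
  enzyme <- iib_enzyme(manifest$enzyme$name, manifest$enzyme$recognition,
                       manifest$enzyme$left_flank, manifest$enzyme$right_flank)
  species <- fread(file.path(path, "species.tsv"),
                   colClasses = list(character = c("species_id", "lineage")))
  index <- fread(file.path(path, "index.tsv"), colClasses = "character")
  setkey(index, tag)
  genome_tags <- fread(file.path(path, "genome_tags.tsv"),
                       colClasses = list(character = c("genome_id", "species_id", "tag"),
                                         integer = "count"))
  provenance <- c(list(enzyme = enzyme),
                  lapply(manifest$provenance, function(x)
                    if (is.list(x)) unlist(x, use.names = FALSE) else x))
  setkey(species, species_id)
  structure(list(enzyme = enzyme, species = species, index = index,
                 genome_tags = genome_tags, h_mode = manifest$h_mode,
                 provenance = provenance),
            class = "tag_db")
}
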