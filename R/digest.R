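#' In-silico digestion of DNA into fixed-length canonical 2b tags
#'
#' The digestion engine locates recognition sites of a Type IIB enzyme on
#' both strands of a sequence and excises the fixed-length window the
#' enzyme's cut geometry defines. Windows are reported in forward-strand,
#' 0-based coordinates and canonicalized (lexicographic minimum of the
#' window and its reverse complement) so matching is strand-insensitive.
#'
#' @name iibdigest
NULL

# Uppercase and replace anything that is not an IUPAC nucleotide code with N
# (such characters can then never produce an emitted tag, because windows
# containing non-ACGT bases are dropped).
sanitize_dna <- function(s) {
  s <- toupper(s)
  if (grepl("[^ACGTRYSWKMBDHVN]", s)) s <- gsub("[^ACGTRYSWKMBDHVN]", "N", s)
  s
}

# Degenerate both-strand site scan on a single sanitized character string.
# Returns a data.table(position (1-based match start), strand).
scan_sites_chr <- function(s, enzyme) {
  subj <- Biostrings::DNAString(s)
  m <- nchar(enzyme$recognition)
  hit_starts <- function(pattern) {
    if (nchar(s) < m) return(integer(0))
    Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(pattern), subj, fixed = "subject"))
  }
  fwd <- hit_starts(enzyme$recognition)
  rev <- if (is_self_revcomp(enzyme)) integer(0) else
    hit_starts(iupac_revcomp(enzyme$recognition))
  sites <- data.table(
    position = c(fwd, rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev)))
  )
  if (nrow(sites) == 0) return(sites)
  # recognition window itself must be unambiguous sequence
  rec <- substring(s, sites$position, sites$position + m - 1L)
  sites <- sites[grepl("^[ACGT]+$", rec)]
  setorderv(sites, c("position", "strand"), c(1L, -1L))  # "+" before "-"
  sites
}

#' Scan a sequence for Type IIB recognition sites on both strands
#'
#' Finds every (possibly overlapping) match of the enzyme's IUPAC
#' recognition pattern on the forward strand, and of its reverse complement
#' (reported as strand "-"), in forward-strand coordinates. For
#' self-reverse-complementary patterns each physical site is reported once,
#' on "+".
#'
#' @param sequence A DNA string. Characters outside the IUPAC alphabet never
#'   match; recognition matches containing ambiguous bases are discarded.
#' @param enzyme An [iib_enzyme()].
#' @return A data.frame with columns `position` (0-based match start) and
#'   `strand` ("+"/"-"), sorted by position with "+" before "-".
#' @examples
#' scan_recognition_sites("GGACGTCC", iib_enzyme("Toy", "ACGT", 2, 2))
#' @export
scan_recognition_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "iib_enzyme"), is.character(sequence),
            length(sequence) == 1, nchar(sequence) >= 1)
  sites <- scan_sites_chr(sanitize_dna(sequence), enzyme)
  data.frame(position = sites$position - 1L,
             strand = if (nrow(sites)) sites$strand else character(0),
             stringsAsFactors = FALSE)
}

# Core window extraction shared by genome and read digestion. Operates on a
# sanitized string; returns data.table(tag, position (1-based window start),
# strand) with canonical tags. Windows that would extend past either end of
# the sequence, or that contain a non-ACGT base, are dropped.
extract_tags_chr <- function(s, enzyme) {
  sites <- scan_sites_chr(s, enzyme)
  m <- nchar(enzyme$recognition)
  if (nrow(sites) == 0) {
    return(data.table(tag = character(0), position = integer(0),
                      strand = character(0)))
  }
  # a "-" site's window is the mirror image of the "+" geometry
  win_start <- ifelse(sites$strand == "+",
                      sites$position - enzyme$left_flank,
                      sites$position - enzyme$right_flank)
  win_end <- win_start + enzyme$tag_length - 1L
  keep <- win_start >= 1L & win_end <= nchar(s)
  if (!any(keep)) {
    return(data.table(tag = character(0), position = integer(0),
                      strand = character(0)))
  }
  win_start <- win_start[keep]
  win_end <- win_end[keep]
  strand <- sites$strand[keep]
  tag <- substring(s, win_start, win_end)
  ok <- !grepl("[^ACGT]", tag)
  data.table(tag = canonical_tags(tag[ok]),
             position = as.integer(win_start[ok]),
             strand = strand[ok])
}

#' Extract canonical 2b tags from a sequence
#'
#' One tag per recognition site whose full window
#' `[site - left_flank, site + nchar(recognition) + right_flank)` lies
#' entirely within the sequence and contains only A/C/G/T. Overlapping sites
#' each emit a tag.
#'
#' @inheritParams scan_recognition_sites
#' @param source_id Identifier recorded for each occurrence.
#' @return A data.frame with columns `tag` (canonical, fixed length),
#'   `source_id`, `position` (0-based window start on the forward strand)
#'   and `strand`.
#' @examples
#' extract_tags("GGACGTCC", iib_enzyme("Toy", "ACGT", 2, 2))
#' @export
extract_tags <- function(sequence, enzyme, source_id = "seq") {
  stopifnot(inherits(enzyme, "iib_enzyme"), is.character(sequence),
            length(sequence) == 1)
  occ <- extract_tags_chr(sanitize_dna(sequence), enzyme)
  data.frame(tag = occ$tag, source_id = rep(source_id, nrow(occ)),
             position = occ$position - 1L, strand = occ$strand,
             stringsAsFactors = FALSE)
}

# Digest a vector of sequences (reads) efficiently: sequences are joined
# with an N spacer of exactly tag_length so no window can bridge two reads,
# and a single scan is run per ~20-Mb chunk. Equivalent to per-read
# digestion because bridging windows necessarily contain N and are dropped.
digest_read_vector <- function(reads, enzyme) {
  empty <- data.table(tag = character(0), count = integer(0))
  if (length(reads) == 0) return(empty)
  reads <- vapply(reads, sanitize_dna, character(1), USE.NAMES = FALSE)
  spacer <- strrep("N", enzyme$tag_length)
  chunks <- split(reads, ceiling(cumsum(nchar(reads) + nchar(spacer)) / 2e7))
  tags <- lapply(chunks, function(ch) {
    extract_tags_chr(paste(ch, collapse = spacer), enzyme)$tag
  })
  tags <- unlist(tags, use.names = FALSE)
  if (length(tags) == 0) return(empty)
  dt <- data.table(tag = tags)[, .(count = .N), by = tag]
  setkey(dt, tag)
  dt[]
}

#' Digest sequencing reads into a canonical tag count table
#'
#' Aggregates [extract_tags()] over every read. Reads with no site
#' contribute nothing to the table but still count toward the total read
#' number `R` (paired mates are digested independently and each counts as
#' one read).
#'
#' @param reads Character vector of read sequences, or path(s) to FASTQ
#'   files (plain or gzipped; two paths are treated as a read pair).
#' @param enzyme An [iib_enzyme()].
#' @return An object of class `tag_counts`: a list with `tags` (data.table
#'   of `tag`, `count`), `total_reads` and `enzyme` (the enzyme name).
#' @examples
#' digest_reads("GGACGTCC", iib_enzyme("Toy", "ACGT", 2, 2))
#' @export
digest_reads <- function(reads, enzyme) {
  stopifnot(inherits(enzyme, "iib_enzyme"))
  if (length(reads) > 0 && all(file.exists(reads))) {
    reads <- unlist(lapply(reads, read_fastq_sequences), use.names = FALSE)
  }
  structure(
    list(tags = digest_read_vector(reads, enzyme),
         total_reads = length(reads),
         enzyme = enzyme$name),
    class = "tag_counts"
  )
}

#' @export
print.tag_counts <- function(x, ...) {
  cat(sprintf("<tag_counts> %d distinct tags (%d occurrences) from %d reads [%s]\n",
              nrow(x$tags), sum(x$tags$count), x$total_reads, x$enzyme))
  invisible(x)
}

# FASTQ sequences as a character vector (plain or gz), via Biostrings.
read_fastq_sequences <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  as.character(seqs)
}
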