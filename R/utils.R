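#' @import data.table
#' @importFrom randomForest randomForest
#' @importFrom stats predict rbinom rlnorm rmultinom runif
#' @importFrom utils head modifyList packageVersion
NULL

DNA_BASES <- c("A", "C", "G", "T")

IUPAC_EXPAND <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of an IUPAC pattern string
#' @param pattern IUPAC nucleotide string.
#' @return Reverse-complemented pattern string.
#' @keywords internal
iupac_revcomp <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_COMPLEMENT))
  if (length(bad) > 0) {
    stop("non-IUPAC character(s) in pattern: ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

#' Reverse complement plain ACGT sequences (vectorised)
#' @param x character vector of A/C/G/T strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Canonicalize tags: lexicographic min of a tag and its reverse complement
#'
#' Tags are double-stranded fragments; the canonical form makes matching
#' strand-insensitive.
#' @param tags character vector of A/C/G/T strings (iso-length).
#' @return character vector of canonical tags.
#' @export
canonical_tags <- function(tags) {
  if (length(tags) == 0) return(character(0))
  rc <- revcomp(tags)
  ifelse(tags <= rc, tags, rc)
}

# Derive a reproducible 31-bit child seed from a base seed and a stream offset.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset) * 69621) %% 2147483563L) + 1L
}

# md5 of an in-memory object, via a temporary file (base tools only).
object_md5 <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
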