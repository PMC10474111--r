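# Independent brute-force oracles for the digestion engine.
# Deliberately naive (O(n*m) sliding window, own IUPAC tables, own reverse
# complement) and shares no code with the package internals.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", s),
                     "", fixed = TRUE)[[1]]), collapse = "")
}

# all 0-based positions where the degenerate pattern matches exactly
# (subject window must be concrete ACGT)
oracle_match_positions <- function(s, pattern) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  m <- length(pat)
  n <- length(chars)
  hits <- integer(0)
  if (n < m) return(hits)
  for (i in seq_len(n - m + 1)) {
    win <- chars[i:(i + m - 1)]
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!(win[j] %in% c("A", "C", "G", "T")) ||
          !(win[j] %in% ORACLE_IUPAC[[pat[j]]])) {
        ok <- FALSE
        break
      }
    }
    if (ok) hits <- c(hits, i - 1L)
  }
  hits
}

# both-strand site scan, package output convention
oracle_scan <- function(s, enzyme) {
  s <- toupper(s)
  fwd <- oracle_match_positions(s, enzyme$recognition)
  rc_pat <- oracle_revcomp(enzyme$recognition)
  rev <- if (identical(rc_pat, enzyme$recognition)) integer(0) else
    oracle_match_positions(s, rc_pat)
  df <- data.frame(position = c(fwd, rev),
                   strand = rep(c("+", "-"), c(length(fwd), length(rev))),
                   stringsAsFactors = FALSE)
  df[order(df$position, df$strand == "-"), , drop = FALSE]
}

# sorted multiset of canonical tags
oracle_tags <- function(s, enzyme) {
  s <- toupper(s)
  sites <- oracle_scan(s, enzyme)
  if (nrow(sites) == 0) return(character(0))
  out <- character(0)
  for (k in seq_len(nrow(sites))) {
    start0 <- if (sites$strand[k] == "+") {
      sites$position[k] - enzyme$left_flank
    } else {
      sites$position[k] - enzyme$right_flank
    }
    end0 <- start0 + enzyme$tag_length  # half-open
    if (start0 < 0 || end0 > nchar(s)) next
    w <- substr(s, start0 + 1, end0)
    if (grepl("[^ACGT]", w)) next
    rc <- oracle_revcomp(w)
    out <- c(out, if (w <= rc) w else rc)
  }
  sort(out)
}

# seeded random ACGT string, independent of the package generator
oracle_random_dna <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
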