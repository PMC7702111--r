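# Internal sequence/numeric helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Hamming distance between two equal-length sequences
#'
#' Number of positions at which two strings differ. Sequences must have the
#' same length; this is the distance used throughout the denoiser, where
#' amplicons are fixed-length.
#'
#' @param a,b Character scalars (DNA strings).
#' @return Integer substitution count.
#' @export
hamming <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  if (length(ra) != length(rb)) {
    stop("hamming() requires equal-length sequences; got ",
         length(ra), " and ", length(rb))
  }
  sum(ra != rb)
}

# Prefix-anchored distance for unequal lengths: mismatches over the shared
# prefix, terminal overhang tolerated. This is the documented dialect for
# comparing merged reads whose lengths differ by a few terminal bases.
prefix_distance <- function(a, b) {
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  n <- min(length(ra), length(rb))
  sum(ra[seq_len(n)] != rb[seq_len(n)])
}

seq_distance <- function(a, b) {
  if (nchar(a) == nchar(b)) hamming(a, b) else prefix_distance(a, b)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of sequences over A/C/G/T/N.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Phred+33 encode/decode
phred_decode <- function(qual) utf8ToInt(qual) - 33L
phred_encode <- function(q) intToUtf8(pmin(q, 93L) + 33L)

random_dna <- function(length) {
  paste(sample(DNA_BASES, length, replace = TRUE), collapse = "")
}

# substitute the bases at `pos` with uniformly chosen different bases
substitute_bases <- function(seq, pos) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  for (p in pos) {
    ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    stopifnot(!is.na(seed))
    set.seed(seed)
  }
  invisible(seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Bray-Curtis between two non-negative count vectors
bc_pair <- function(x, y) {
  s <- sum(x) + sum(y)
  if (s == 0) stop("Bray-Curtis undefined for two all-zero samples")
  sum(abs(x - y)) / s
}

# Incidence-based Jaccard dissimilarity
jaccard_pair <- function(x, y) {
  px <- x > 0
  py <- y > 0
  u <- sum(px | py)
  if (u == 0) stop("Jaccard undefined for two all-zero samples")
  1 - sum(px & py) / u
}

pair_metric <- function(metric) {
  switch(metric, bray = bc_pair, jaccard = jaccard_pair,
         stop("unknown metric: ", metric))
}
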