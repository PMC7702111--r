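# Synthetic amplicon reads with a known error structure.
#
# The generator is the inverse of the denoiser's error model: PCR
# substitutions are *propagating* (they arise on an amplification tree and
# are inherited by descendant molecules), sequencing substitutions are
# *non-propagating* (independent per read), and chimeras are two-parent
# splices at a uniform internal breakpoint.

#' Amplicon error model
#'
#' Parameters of the simulated sequencing experiment. `pcr_error_rate` is the
#' per-base, per-duplication substitution probability (propagating errors);
#' `seq_error_rate` the per-base substitution probability at the sequencing
#' step (non-propagating); `chimera_rate` the probability that a read is a
#' two-parent splice instead of a faithful copy.
#'
#' @param pcr_error_rate Per-base per-PCR-cycle substitution probability.
#' @param pcr_cycles Number of PCR cycles.
#' @param seq_error_rate Per-base sequencing substitution probability.
#' @param chimera_rate Probability that a read is chimeric.
#' @return An object of class `error_model`.
#' @export
error_model <- function(pcr_error_rate = 1e-5, pcr_cycles = 30L,
                        seq_error_rate = 1e-3, chimera_rate = 0) {
  rates <- c(pcr_error_rate, seq_error_rate, chimera_rate)
  if (any(rates < 0) || any(rates >= 1)) {
    stop("error rates must lie in [0, 1)")
  }
  pcr_cycles <- as.integer(pcr_cycles)
  if (is.na(pcr_cycles) || pcr_cycles < 0) stop("pcr_cycles must be >= 0")
  structure(list(pcr_error_rate = pcr_error_rate,
                 pcr_cycles = pcr_cycles,
                 seq_error_rate = seq_error_rate,
                 chimera_rate = chimera_rate),
            class = "error_model")
}

#' Simulate true genotype sequences
#'
#' Draws `n` random fixed-length DNA sequences whose pairwise Hamming
#' distances are all at least `min_dist`, by bounded rejection sampling.
#' These act as the "true" amplicon genotypes whose recovery the denoiser
#' is benchmarked against.
#'
#' @param n Number of genotypes (>= 1).
#' @param length Amplicon length in bases.
#' @param min_dist Minimum pairwise Hamming distance (ignored for n = 1).
#' @param seed Optional integer seed.
#' @param max_tries Rejection-sampling bound per genotype.
#' @return Named character vector of sequences (`gt001`, `gt002`, ...).
#' @export
simulate_genotypes <- function(n, length = 250L, min_dist = 5L, seed = NULL,
                               max_tries = 1000L) {
  stopifnot(n >= 1, min_dist >= 1, length > min_dist)
  maybe_set_seed(seed)
  out <- character(n)
  out[1] <- random_dna(length)
  if (n > 1) {
    for (i in 2:n) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        cand <- random_dna(length)
        if (all(vapply(out[seq_len(i - 1)],
                       function(s) hamming(s, cand), 0L) >= min_dist)) {
          out[i] <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place genotype ", i, " at min_dist = ", min_dist,
             " within ", max_tries, " tries; relax the constraints")
      }
    }
  }
  names(out) <- sprintf("gt%03d", seq_len(n))
  out
}

# Amplify one template by `cycles` rounds of duplication. The molecule pool
# is a set of (haplotype, abundance) pairs: every cycle each molecule is
# copied, new copies acquire substitutions as a Poisson arrival process at
# rate `abundance * (1 - (1-rate)^L)`, and the pool is rescaled
# proportionally back to `cap` when it overflows (PCR growth is treated as
# deterministic per lineage: with realistic template numbers molecule
# counts are huge and demographic drift of lineage frequencies is
# negligible, so resampling noise would only create artificial abundance
# jackpots). Errors are genuinely shared by descendants: a mutant
# haplotype keeps replicating in later cycles, so an error arising in
# cycle c is carried by about 2^-c of the final pool (relative to its
# template).
amplify_template <- function(seq, model, n_templates = 20000L, cap = 65536L) {
  haps <- seq
  counts <- as.numeric(n_templates)
  L <- nchar(seq)
  p_mut <- 1 - (1 - model$pcr_error_rate)^L
  for (cy in seq_len(model$pcr_cycles)) {
    n0 <- length(counts)
    m <- stats::rpois(n0, counts * p_mut)
    counts <- 2 * counts - m
    tot_m <- sum(m)
    if (tot_m > 0) {
      parent_idx <- rep.int(seq_len(n0), m)
      new_seqs <- vapply(haps[parent_idx],
                         function(s) substitute_bases(s, sample.int(L, 1L)),
                         character(1), USE.NAMES = FALSE)
      haps <- c(haps, new_seqs)
      counts <- c(counts, rep.int(1, tot_m))
    }
    tot <- sum(counts)
    if (tot > cap) {
      counts <- counts * (cap / tot)
      keep <- counts > 1e-6
      haps <- haps[keep]
      counts <- counts[keep]
    }
  }
  list(haps = haps, counts = counts)
}

#' Simulate reads from genotypes under an explicit error model
#'
#' Each genotype is amplified over `model$pcr_cycles` duplications on a
#' bounded amplification tree (propagating errors), reads are drawn from the
#' final molecule pool, and independent per-base sequencing errors are then
#' applied. With probability `model$chimera_rate` a read is instead spliced
#' from two distinct parent genotypes at a uniform internal breakpoint
#' (and still receives sequencing errors). Quality strings are constant-Q
#' with Q = -10 log10(seq_error_rate).
#'
#' @param genotypes Named character vector of true sequences (equal length).
#' @param abundances Positive integer vector of read counts per genotype.
#' @param model An [error_model()].
#' @param seed Optional integer seed.
#' @param n_templates Template molecules per genotype entering PCR.
#' @param pool_cap Molecule-pool cap of the amplification tree.
#' @return A list with `reads` (data.frame: id, seq, qual) and `truth`
#'   (data.frame: read_id, genotype_id, partner_id, is_chimera, breakpoint).
#' @export
simulate_reads <- function(genotypes, abundances, model = error_model(),
                           seed = NULL, n_templates = 20000L,
                           pool_cap = 65536L) {
  if (length(genotypes) == 0) stop("empty genotype list")
  stopifnot(length(abundances) == length(genotypes), all(abundances > 0))
  if (is.null(names(genotypes))) {
    names(genotypes) <- sprintf("gt%03d", seq_along(genotypes))
  }
  L <- unique(nchar(genotypes))
  if (length(L) != 1) stop("genotypes must have equal length")
  maybe_set_seed(seed)

  n_reads <- sum(abundances)
  gid <- rep(names(genotypes), abundances)
  is_chim <- stats::runif(n_reads) < model$chimera_rate
  seqs <- character(n_reads)
  partner <- rep(NA_character_, n_reads)
  breakpoint <- rep(NA_integer_, n_reads)

  # non-chimeric reads: drawn from each genotype's amplified pool
  for (g in names(genotypes)) {
    take <- which(gid == g & !is_chim)
    if (length(take) == 0) next
    if (model$pcr_error_rate > 0 && model$pcr_cycles > 0) {
      pool <- amplify_template(genotypes[[g]], model, n_templates, pool_cap)
      idx <- sample.int(length(pool$counts), length(take), replace = TRUE,
                        prob = pool$counts)
      seqs[take] <- pool$haps[idx]
    } else {
      seqs[take] <- genotypes[[g]]
    }
  }

  # chimeric reads: splice of two distinct parents' true sequences
  chim_idx <- which(is_chim)
  if (length(chim_idx) > 0 && length(genotypes) < 2) {
    stop("chimera_rate > 0 requires at least two genotypes")
  }
  for (i in chim_idx) {
    pair <- sample(seq_along(genotypes), 2L, prob = abundances)
    b <- sample.int(L - 1L, 1L)
    seqs[i] <- paste0(substr(genotypes[[pair[1]]], 1L, b),
                      substr(genotypes[[pair[2]]], b + 1L, L))
    gid[i] <- names(genotypes)[pair[1]]
    partner[i] <- names(genotypes)[pair[2]]
    breakpoint[i] <- b
  }

  # non-propagating sequencing errors, independent per read and base
  if (model$seq_error_rate > 0) {
    n_err <- stats::rbinom(n_reads, L, model$seq_error_rate)
    for (i in which(n_err > 0)) {
      seqs[i] <- substitute_bases(seqs[i], sample.int(L, n_err[i]))
    }
  }

  q <- if (model$seq_error_rate > 0) {
    as.integer(round(-10 * log10(model$seq_error_rate)))
  } else 40L
  qual <- strrep(substr(phred_encode(q), 1, 1), L)
  read_id <- sprintf("read%06d", seq_len(n_reads))

  list(
    reads = data.frame(id = read_id, seq = seqs, qual = qual,
                       stringsAsFactors = FALSE),
    truth = data.frame(read_id = read_id, genotype_id = gid,
                       partner_id = partner, is_chimera = is_chim,
                       breakpoint = breakpoint, stringsAsFactors = FALSE)
  )
}

#' Split full-length reads into overlapping forward/reverse pairs
#'
#' Emulates paired-end sequencing of a fixed-length amplicon: the forward
#' read is the first `fwd_len` bases, the reverse read the reverse
#' complement of the last `rev_len` bases; the pair overlaps by
#' `fwd_len + rev_len - L` bases.
#'
#' @param reads Read data.frame as returned by [simulate_reads()].
#' @param fwd_len,rev_len Read lengths; must overlap by at least 1 base.
#' @return List with `fwd` and `rev` read data.frames.
#' @export
paired_reads <- function(reads, fwd_len = 180L, rev_len = 180L) {
  L <- unique(nchar(reads$seq))
  if (length(L) != 1) stop("reads must have equal length")
  if (fwd_len + rev_len <= L) stop("fwd_len + rev_len must exceed read length")
  if (fwd_len > L || rev_len > L) stop("read lengths exceed amplicon length")
  fwd <- data.frame(id = reads$id,
                    seq = substr(reads$seq, 1L, fwd_len),
                    qual = substr(reads$qual, 1L, fwd_len),
                    stringsAsFactors = FALSE)
  rev <- data.frame(id = reads$id,
                    seq = revcomp(substr(reads$seq, L - rev_len + 1L, L)),
                    qual = reverse_string(substr(reads$qual, L - rev_len + 1L, L)),
                    stringsAsFactors = FALSE)
  list(fwd = fwd, rev = rev)
}
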