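# Probabilistic amplicon denoising.
#
# The pipeline mirrors a UNOISE-style in-house chain: paired-read merging,
# an expected-errors quality filter, exact dereplication with singleton
# removal, and abundance-ordered probabilistic clustering in which each
# query sequence is either explained as an error child of a more abundant
# "parent" genotype or accepted as a new genotype, after an internal
# two-parent chimera check against the whole data set.

#' Denoiser parameters
#'
#' The error model gives the effective per-base substitution rate
#' `eff = seq_error_rate + (pcr_cycles / 2) * pcr_error_rate` (the mean
#' molecule age under exponential amplification is about half the cycle
#' number). A query at Hamming distance d from a parent with N reads is
#' expected to receive `mu = N * (eff / 3)^d` error reads; it is accepted as
#' a new genotype only when its observed count is too high to be explained
#' that way under a one-sided Poisson test at level `alpha` for every
#' candidate parent.
#'
#' @param pcr_error_rate,pcr_cycles,seq_error_rate As in [error_model()].
#' @param alpha Significance level of the new-genotype test (0 < alpha < 1).
#' @param max_parent_dist Maximal parent search distance in substitutions;
#'   beyond it `mu` underflows and queries are automatic genotypes.
#' @param min_count Minimal dereplicated count kept after singleton removal.
#' @param min_parent_skew Chimera parents must be at least this many times
#'   more abundant than the query.
#' @param method `"poisson"` (default) or `"unoise"`, an alternative
#'   UNOISE-style skew threshold beta(d) = 1 / 2^(unoise_alpha * d + 1).
#' @param unoise_alpha Alpha of the UNOISE skew rule.
#' @return An object of class `denoise_params`.
#' @export
denoise_params <- function(pcr_error_rate = 1e-5, pcr_cycles = 30L,
                           seq_error_rate = 1e-3, alpha = 1e-20,
                           max_parent_dist = 10L, min_count = 2L,
                           min_parent_skew = 2,
                           method = c("poisson", "unoise"),
                           unoise_alpha = 2) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (max_parent_dist < 1) stop("max_parent_dist must be >= 1")
  structure(list(pcr_error_rate = pcr_error_rate,
                 pcr_cycles = as.integer(pcr_cycles),
                 seq_error_rate = seq_error_rate,
                 alpha = alpha,
                 max_parent_dist = as.integer(max_parent_dist),
                 min_count = as.integer(min_count),
                 min_parent_skew = min_parent_skew,
                 method = match.arg(method),
                 unoise_alpha = unoise_alpha),
            class = "denoise_params")
}

effective_error_rate <- function(params) {
  params$seq_error_rate + (params$pcr_cycles / 2) * params$pcr_error_rate
}

# ---- paired-read merging ---------------------------------------------------

merge_one_pair <- function(fs, fq, rs, rq, min_overlap, max_mismatch_frac) {
  r_seq <- revcomp(rs)
  r_qual <- reverse_string(rq)
  fr <- charToRaw(fs); fqr <- charToRaw(fq)
  rr <- charToRaw(r_seq); rqr <- charToRaw(r_qual)
  n1 <- length(fr); n2 <- length(rr)
  o_max <- min(n1, n2)
  if (o_max < min_overlap) return(NULL)
  best_o <- 0L; best_id <- -1
  for (o in min_overlap:o_max) {
    a <- fr[(n1 - o + 1L):n1]
    b <- rr[1:o]
    ident <- 1 - sum(a != b) / o
    if (ident > best_id + 1e-12) { best_id <- ident; best_o <- o }
  }
  if (best_id < 1 - max_mismatch_frac) return(NULL)
  o <- best_o
  ia <- (n1 - o + 1L):n1
  a <- fr[ia]; aq <- fqr[ia]
  b <- rr[1:o]; bq <- rqr[1:o]
  take_f <- aq >= bq              # base with the higher Phred wins
  cons <- b
  cons[take_f] <- a[take_f]
  consq <- bq                     # merged quality: the higher of the two
  consq[take_f] <- aq[take_f]
  merged_seq <- rawToChar(c(fr[seq_len(n1 - o)], cons,
                            if (o < n2) rr[(o + 1L):n2] else raw(0)))
  merged_qual <- rawToChar(c(fqr[seq_len(n1 - o)], consq,
                             if (o < n2) rqr[(o + 1L):n2] else raw(0)))
  list(seq = merged_seq, qual = merged_qual)
}

#' Merge overlapping paired-end reads
#'
#' For each pair the reverse read is reverse-complemented and the best
#' ungapped overlap of at least `min_overlap` bases is chosen by maximal
#' identity; within the overlap the base with the higher Phred score is
#' retained and the merged quality is the higher of the two. Pairs whose
#' best overlap identity falls below `1 - max_mismatch_frac` are rejected
#' (counted, not fatal).
#'
#' @param fwd,rev Read data.frames (id, seq, qual), matched by row.
#' @param min_overlap Minimal overlap length in bases.
#' @param max_mismatch_frac Maximal mismatch fraction tolerated in the
#'   overlap.
#' @return List with `merged` (read data.frame), `n_rejected` and
#'   `rejected_ids`.
#' @export
merge_pairs <- function(fwd, rev, min_overlap = 30L,
                        max_mismatch_frac = 0.25) {
  stopifnot(nrow(fwd) == nrow(rev))
  if (nrow(fwd) == 0) stop("empty read set")
  out_seq <- character(nrow(fwd))
  out_qual <- character(nrow(fwd))
  keep <- logical(nrow(fwd))
  for (i in seq_len(nrow(fwd))) {
    m <- merge_one_pair(fwd$seq[i], fwd$qual[i], rev$seq[i], rev$qual[i],
                        min_overlap, max_mismatch_frac)
    if (!is.null(m)) {
      keep[i] <- TRUE
      out_seq[i] <- m$seq
      out_qual[i] <- m$qual
    }
  }
  list(merged = data.frame(id = fwd$id[keep], seq = out_seq[keep],
                           qual = out_qual[keep], stringsAsFactors = FALSE),
       n_rejected = sum(!keep),
       rejected_ids = fwd$id[!keep])
}

# ---- quality filter --------------------------------------------------------

#' Expected number of errors of a read
#'
#' `EE = sum_b 10^(-Q_b / 10)` over the Phred+33 quality string; an empty
#' read has EE = 0.
#'
#' @param qual Character vector of quality strings.
#' @return Numeric vector of expected error counts.
#' @export
expected_errors <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0) return(0)
    sum(10^(-phred_decode(q) / 10))
  }, 0, USE.NAMES = FALSE)
}

#' Filter reads by maximum expected errors
#'
#' Keeps reads with `EE <= max_ee`; the default 0.5 is the conventional
#' strict quality-control cutoff for denoising.
#'
#' @param reads Read data.frame (id, seq, qual).
#' @param max_ee Maximal expected errors per read.
#' @return The kept subset, with attribute `n_removed`.
#' @export
filter_reads <- function(reads, max_ee = 0.5) {
  ee <- expected_errors(reads$qual)
  kept <- reads[ee <= max_ee, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "n_removed") <- nrow(reads) - nrow(kept)
  kept
}

# ---- dereplication ---------------------------------------------------------

#' Dereplicate reads into unique sequences
#'
#' Collapses exact duplicates, sorts by decreasing count with ties broken
#' lexicographically by sequence, and (optionally) tracks per-sample counts.
#'
#' @param seqs Character vector of merged, filtered read sequences.
#' @param sample Optional character vector of sample ids, same length as
#'   `seqs`; when given, a uniques x samples count matrix is attached as
#'   attribute `sample_counts`.
#' @return data.frame (seq, count) sorted by decreasing count.
#' @export
dereplicate <- function(seqs, sample = NULL) {
  if (length(seqs) == 0) {
    return(data.frame(seq = character(0), count = integer(0)))
  }
  tab <- table(seqs)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  ord <- order(-out$count, out$seq)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(sample)) {
    stopifnot(length(sample) == length(seqs))
    sc <- table(factor(seqs, levels = out$seq), sample)
    m <- matrix(as.integer(sc), nrow = nrow(sc),
                dimnames = list(rownames(sc), colnames(sc)))
    attr(out, "sample_counts") <- m
  }
  out
}

#' Remove singleton unique sequences
#'
#' @param uniques Output of [dereplicate()].
#' @param min_count Minimal count kept (default 2: exclude singletons).
#' @return Filtered uniques; removed read count in attribute
#'   `n_reads_removed`.
#' @export
remove_singletons <- function(uniques, min_count = 2L) {
  keep <- uniques$count >= min_count
  out <- uniques[keep, , drop = FALSE]
  rownames(out) <- NULL
  sc <- attr(uniques, "sample_counts")
  if (!is.null(sc)) attr(out, "sample_counts") <- sc[keep, , drop = FALSE]
  attr(out, "n_reads_removed") <- sum(uniques$count[!keep])
  out
}

# ---- parent/child probability ---------------------------------------------

#' Expected error-child read count under the denoiser's model
#'
#' The per-read probability of observing the d specific substitutions that
#' turn the parent into the child is `p = (eff / 3)^d`; the expected child
#' count is `mu = parent_count * p`.
#'
#' @param parent_bases Parent sequence.
#' @param parent_count Parent read count.
#' @param child_bases Child (query) sequence.
#' @param params A [denoise_params()].
#' @return List with `distance`, `p_read` and `mu`.
#' @export
child_probability <- function(parent_bases, parent_count, child_bases,
                              params = denoise_params()) {
  d <- seq_distance(parent_bases, child_bases)
  if (d == 0) stop("child is identical to parent (d = 0): not a child")
  if (d > params$max_parent_dist) {
    stop("distance ", d, " exceeds max_parent_dist = ",
         params$max_parent_dist)
  }
  p <- (effective_error_rate(params) / 3)^d
  list(distance = d, p_read = p, mu = parent_count * p)
}

# ---- chimera check ---------------------------------------------------------

raw_lcp <- function(qa, pa) {
  n <- min(length(qa), length(pa))
  neq <- which(qa[seq_len(n)] != pa[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

raw_lcs <- function(qa, pa) {
  n <- min(length(qa), length(pa))
  neq <- which(rev(qa)[seq_len(n)] != rev(pa)[seq_len(n)])
  if (length(neq) == 0) n else neq[1] - 1L
}

#' Internal two-parent chimera check
#'
#' A query is chimeric when some breakpoint 0 < b < L and two distinct
#' accepted genotypes A and B exist such that the query equals A over
#' \[1, b\] and B over (b, L\], the query differs from both parents overall,
#' and both parents are at least `min_parent_skew` times more abundant than
#' the query. Only single-crossover chimeras with exact segment matches are
#' considered.
#'
#' @param query_seq,query_count The query sequence and its read count.
#' @param genotype_seqs,genotype_counts Accepted genotypes (sequences and
#'   funneled total counts).
#' @param min_parent_skew Minimal parent/query abundance ratio.
#' @return List with `is_chimera`, `left_parent`, `right_parent` (indices
#'   into the genotype vectors, NA when not chimeric) and `breakpoint`.
#' @export
chimera_check <- function(query_seq, query_count, genotype_seqs,
                          genotype_counts, min_parent_skew = 2) {
  no <- list(is_chimera = FALSE, left_parent = NA_integer_,
             right_parent = NA_integer_, breakpoint = NA_integer_)
  if (length(genotype_seqs) < 2) return(no)
  qa <- charToRaw(query_seq)
  L <- length(qa)
  elig <- which(genotype_counts >= min_parent_skew * query_count)
  if (length(elig) < 2) return(no)
  lcp <- vapply(genotype_seqs[elig], function(s) raw_lcp(qa, charToRaw(s)),
                0L, USE.NAMES = FALSE)
  lcs <- vapply(genotype_seqs[elig], function(s) raw_lcs(qa, charToRaw(s)),
                0L, USE.NAMES = FALSE)
  # a left parent needs a non-trivial exact prefix, a right parent a
  # non-trivial exact suffix; lcp/lcs < L excludes identity to the query
  left <- which(lcp >= 1L & lcp < L)
  right <- which(lcs >= 1L & lcs < L)
  if (length(left) == 0 || length(right) == 0) return(no)
  by_lcp <- left[order(-lcp[left])]
  by_lcs <- right[order(-lcs[right])]
  # the optimum is attained at the best prefix parent paired with the best
  # distinct suffix parent (or vice versa); only those pairs need testing
  pairs <- if (by_lcp[1] != by_lcs[1]) {
    list(c(by_lcp[1], by_lcs[1]))
  } else {
    list(if (length(by_lcs) > 1) c(by_lcp[1], by_lcs[2]),
         if (length(by_lcp) > 1) c(by_lcp[2], by_lcs[1]))
  }
  for (p in pairs) {
    if (is.null(p)) next
    a <- p[1]; b <- p[2]
    if (lcp[a] + lcs[b] >= L) {
      bp <- min(max(1L, L - lcs[b]), lcp[a])
      return(list(is_chimera = TRUE,
                  left_parent = elig[a], right_parent = elig[b],
                  breakpoint = as.integer(bp)))
    }
  }
  no
}

# ---- denoising -------------------------------------------------------------

#' Denoise unique sequences into genotypes
#'
#' Processes uniques in decreasing-abundance order. The most abundant
#' sequence is always a genotype. Each later query is compared against all
#' previously accepted genotypes within `max_parent_dist` substitutions; the
#' most likely parent maximizes the one-sided upper-tail probability
#' `P(X >= count | X ~ Poisson(mu))`. The query becomes a new genotype only
#' when that probability is below `alpha` for every candidate (its count is
#' too high to be error-derived), and only if it passes the internal chimera
#' check; otherwise its reads funnel into the best parent's total count
#' (transitively, to the ultimate ancestor). Chimeric queries are discarded
#' and their reads are not funneled.
#'
#' @param uniques Output of [dereplicate()] (singletons typically removed),
#'   optionally carrying a `sample_counts` attribute for per-sample output.
#' @param params A [denoise_params()].
#' @return List with `genotypes` (id, seq, own count, funneled total_count),
#'   `assignments` (one row per unique: status genotype/merged/chimera,
#'   parent, distance, p_value, breakpoint), `otu_table` (genotypes x
#'   samples, when sample counts were tracked) and `params`.
#' @export
denoise <- function(uniques, params = denoise_params()) {
  sc <- attr(uniques, "sample_counts")
  n <- nrow(uniques)
  empty_gt <- data.frame(id = character(0), seq = character(0),
                         count = integer(0), total_count = integer(0))
  if (n == 0) {
    return(list(genotypes = empty_gt, assignments = uniques,
                otu_table = NULL, params = params))
  }
  ord <- order(-uniques$count, uniques$seq)
  uniques <- uniques[ord, , drop = FALSE]
  if (!is.null(sc)) sc <- sc[ord, , drop = FALSE]

  eff <- effective_error_rate(params)
  gt_seq <- character(0)
  gt_total <- numeric(0)
  gt_raw <- list()
  gt_sc <- NULL
  if (!is.null(sc)) gt_sc <- matrix(0L, 0, ncol(sc),
                                    dimnames = list(NULL, colnames(sc)))

  status <- character(n)
  parent <- rep(NA_integer_, n)
  distance <- rep(NA_integer_, n)
  p_value <- rep(NA_real_, n)
  breakpoint <- rep(NA_integer_, n)

  for (i in seq_len(n)) {
    q <- uniques$seq[i]
    cnt <- uniques$count[i]
    accept <- TRUE
    if (length(gt_seq) > 0) {
      qa <- charToRaw(q)
      d <- vapply(gt_raw, function(g) {
        if (length(qa) == length(g)) sum(qa != g) else {
          m <- min(length(qa), length(g))
          sum(qa[seq_len(m)] != g[seq_len(m)])
        }
      }, 0L)
      cand <- which(d >= 1L & d <= params$max_parent_dist)
      if (any(d == 0L)) {
        # exact duplicate of an accepted genotype (possible with unequal
        # lengths under the prefix dialect): funnel without a test
        j <- which(d == 0L)[1]
        status[i] <- "merged"; parent[i] <- j; distance[i] <- 0L
        gt_total[j] <- gt_total[j] + cnt
        if (!is.null(sc)) gt_sc[j, ] <- gt_sc[j, ] + sc[i, ]
        next
      }
      if (length(cand) > 0) {
        if (params$method == "poisson") {
          mu <- gt_total[cand] * (eff / 3)^d[cand]
          pv <- stats::ppois(cnt - 1, mu, lower.tail = FALSE)
          best <- which.max(pv)
          p_value[i] <- pv[best]
          if (pv[best] >= params$alpha) {
            accept <- FALSE
            j <- cand[best]
            status[i] <- "merged"; parent[i] <- j; distance[i] <- d[cand[best]]
            gt_total[j] <- gt_total[j] + cnt
            if (!is.null(sc)) gt_sc[j, ] <- gt_sc[j, ] + sc[i, ]
          } else {
            distance[i] <- d[cand[best]]
          }
        } else {  # UNOISE-style skew rule
          beta <- 1 / 2^(params$unoise_alpha * d[cand] + 1)
          skew <- cnt / gt_total[cand]
          ok <- skew <= beta
          if (any(ok)) {
            accept <- FALSE
            j <- cand[ok][which.max(gt_total[cand][ok])]
            status[i] <- "merged"; parent[i] <- j
            distance[i] <- d[j]
            gt_total[j] <- gt_total[j] + cnt
            if (!is.null(sc)) gt_sc[j, ] <- gt_sc[j, ] + sc[i, ]
          }
        }
      }
    }
    if (accept) {
      chim <- chimera_check(q, cnt, gt_seq, gt_total,
                            min_parent_skew = params$min_parent_skew)
      if (chim$is_chimera) {
        status[i] <- "chimera"
        breakpoint[i] <- chim$breakpoint
        parent[i] <- chim$left_parent
        next
      }
      gt_seq <- c(gt_seq, q)
      gt_total <- c(gt_total, cnt)
      gt_raw[[length(gt_raw) + 1L]] <- charToRaw(q)
      if (!is.null(sc)) gt_sc <- rbind(gt_sc, sc[i, , drop = FALSE])
      status[i] <- "genotype"
      parent[i] <- length(gt_seq)
    }
  }

  own <- uniques$count[status == "genotype"]
  gt <- data.frame(id = sprintf("gt%03d", seq_along(gt_seq)),
                   seq = gt_seq, count = own,
                   total_count = as.integer(gt_total),
                   stringsAsFactors = FALSE)
  assignments <- data.frame(seq = uniques$seq, count = uniques$count,
                            status = status,
                            parent = ifelse(is.na(parent), NA_character_,
                                            sprintf("gt%03d", parent)),
                            distance = distance, p_value = p_value,
                            breakpoint = breakpoint,
                            stringsAsFactors = FALSE)
  otu_table <- NULL
  if (!is.null(gt_sc) && nrow(gt) > 0) {
    otu_table <- gt_sc
    rownames(otu_table) <- gt$id
  }
  list(genotypes = gt, assignments = assignments, otu_table = otu_table,
       params = params)
}
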