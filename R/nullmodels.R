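# Null-model community-assembly statistics: abundance-based Raup-Crick,
# the normalized stochasticity ratio (NST) and its occupancy-stratified
# variant.
#
# Null algorithm (proportional-fixed): each null community preserves the
# observed richness of its sample; species identities are drawn without
# replacement with probability proportional to their occurrence frequency
# across samples; each drawn species receives one individual and the
# remaining individuals are assigned multinomially with probability
# proportional to regional relative abundance restricted to the drawn set.

#' Null-model configuration
#'
#' @param n_reps Number of null draws (>= 100; default 1000).
#' @param metric Dissimilarity metric: `"bray"` (abundance, default) or
#'   `"jaccard"` (incidence).
#' @param species_weighting Species-identity draw weights:
#'   `"occurrence"` (frequency-weighted, default) or `"equiprobable"`.
#' @param seed Optional integer seed recorded with results.
#' @return An object of class `null_model_config`.
#' @export
null_model_config <- function(n_reps = 1000L, metric = c("bray", "jaccard"),
                              species_weighting = c("occurrence",
                                                    "equiprobable"),
                              seed = NULL) {
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 100L) stop("n_reps must be >= 100")
  structure(list(n_reps = n_reps, metric = match.arg(metric),
                 species_weighting = match.arg(species_weighting),
                 seed = seed),
            class = "null_model_config")
}

#' Regional species pool of an OTU table
#'
#' Occurrence frequencies (number of samples in which each OTU occurs) and
#' regional relative abundances (pooled read fractions), both derived from
#' the analyzed table itself.
#'
#' @param table OTU table (OTUs x samples).
#' @return List with `freq` and `relabund`, named by OTU.
#' @export
regional_pool <- function(table) {
  validate_otu_table(table)
  list(freq = rowSums(table > 0), relabund = rowSums(table) / sum(table))
}

# one null community on the pool's support; x is the observed count vector
draw_null_sample <- function(S, N, pool, config) {
  P <- length(pool$freq)
  if (S > P) stop("regional pool smaller than observed richness")
  w <- switch(config$species_weighting,
              occurrence = pool$freq,
              equiprobable = rep(1, P))
  sp <- sample.int(P, S, replace = FALSE, prob = w)
  x <- numeric(P)
  x[sp] <- 1
  if (N > S) {
    q <- pool$relabund[sp]
    if (sum(q) == 0) q <- rep(1, S)
    x[sp] <- x[sp] + stats::rmultinom(1, N - S, q)[, 1]
  }
  x
}

#' Null dissimilarity distribution for one sample pair
#'
#' Draws `config$n_reps` pairs of null communities preserving each sample's
#' observed richness and abundance total, and returns the vector of their
#' dissimilarities under `config$metric`.
#'
#' @param x,y Observed count vectors on the pool's support.
#' @param pool Regional pool as returned by [regional_pool()].
#' @param config A [null_model_config()].
#' @return Numeric vector of length `config$n_reps`.
#' @export
null_dissimilarity_distribution <- function(x, y, pool, config) {
  maybe_set_seed(config$seed)
  met <- pair_metric(config$metric)
  Sx <- sum(x > 0); Nx <- sum(x)
  Sy <- sum(y > 0); Ny <- sum(y)
  if (Sx == 0 && Sy == 0) stop("degenerate pair: both samples empty")
  vapply(seq_len(config$n_reps), function(r) {
    met(draw_null_sample(Sx, Nx, pool, config),
        draw_null_sample(Sy, Ny, pool, config))
  }, 0)
}

# Shared engine: one null draw per sample per rep, pairwise dissimilarities
# for all pairs in one pass. Returns observed and null dissimilarities.
null_ensemble <- function(table, config) {
  validate_otu_table(table)
  n <- ncol(table)
  if (n < 2) stop("need at least two samples")
  empty <- colSums(table) == 0
  if (any(empty)) {
    warning("excluding empty sample(s): ",
            paste(colnames(table)[empty], collapse = ", "))
    table <- table[, !empty, drop = FALSE]
    n <- ncol(table)
  }
  pool <- regional_pool(table)
  met <- pair_metric(config$metric)
  S <- colSums(table > 0)
  N <- colSums(table)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  d_obs <- apply(pairs, 1, function(ij) met(table[, ij[1]], table[, ij[2]]))
  maybe_set_seed(config$seed)
  d_null <- matrix(0, nrow(pairs), config$n_reps)
  for (r in seq_len(config$n_reps)) {
    nulls <- vapply(seq_len(n),
                    function(j) draw_null_sample(S[j], N[j], pool, config),
                    numeric(nrow(table)))
    d_null[, r] <- apply(pairs, 1,
                         function(ij) met(nulls[, ij[1]], nulls[, ij[2]]))
  }
  list(samples = colnames(table), pairs = pairs, d_obs = d_obs,
       d_null = d_null, config = config)
}

#' Raup-Crick index from an observed value and its null distribution
#'
#' `RC = 2 * ((#\{D_null < D_obs\} + 0.5 * #\{D_null = D_obs\}) / n_reps) - 1`,
#' bounded in \[-1, 1\]; ties count half.
#'
#' @param d_obs Observed dissimilarity.
#' @param d_null Vector of null dissimilarities.
#' @param tol Tie tolerance.
#' @return RC value in \[-1, 1\].
#' @export
rc_index <- function(d_obs, d_null, tol = 1e-12) {
  less <- sum(d_null < d_obs - tol)
  ties <- sum(abs(d_null - d_obs) <= tol)
  2 * ((less + 0.5 * ties) / length(d_null)) - 1
}

#' Abundance-based Raup-Crick matrix
#'
#' For every sample pair, compares the observed dissimilarity with its
#' richness-preserving null distribution. RC near +1 flags pairs less
#' similar than expected by chance, near -1 more similar; the middle band
#' \[-0.95, 0.95\] is consistent with stochastic assembly.
#'
#' @param table OTU table (OTUs x samples).
#' @param config A [null_model_config()].
#' @return Symmetric RC matrix (diagonal NA) with the config as attribute.
#' @export
raup_crick <- function(table, config = null_model_config()) {
  ens <- null_ensemble(table, config)
  n <- length(ens$samples)
  rc <- matrix(NA_real_, n, n, dimnames = list(ens$samples, ens$samples))
  for (k in seq_len(nrow(ens$pairs))) {
    i <- ens$pairs[k, 1]; j <- ens$pairs[k, 2]
    rc[i, j] <- rc[j, i] <- rc_index(ens$d_obs[k], ens$d_null[k, ])
  }
  attr(rc, "config") <- config
  rc
}

#' Classify Raup-Crick values into the three interpretation bins
#'
#' @param rc RC matrix (as from [raup_crick()]) or vector of RC values.
#' @return Named vector of percentages: `pct_below` (RC < -0.95, more
#'   similar than chance), `pct_middle` (stochastic band), `pct_above`
#'   (RC > 0.95, less similar than chance). Sums to 100.
#' @export
classify_rc <- function(rc) {
  v <- if (is.matrix(rc)) rc[upper.tri(rc)] else rc
  v <- v[!is.na(v)]
  if (length(v) == 0) stop("no RC values to classify")
  c(pct_below = 100 * mean(v < -0.95),
    pct_middle = 100 * mean(v >= -0.95 & v <= 0.95),
    pct_above = 100 * mean(v > 0.95))
}

#' Stochasticity ratio of one pair
#'
#' Selection strength `SS = (E - D) / E` when the observed dissimilarity D
#' falls below the null expectation E, else `SS = (D - E) / (D_max - E)`;
#' the pair's stochasticity ratio is `ST = 1 - SS`. Null-indistinguishable
#' pairs (D = E) give ST = 1; maximally divergent pairs (D = D_max) give
#' ST = 0.
#'
#' @param d_obs Observed dissimilarity (vectorized).
#' @param e_null Null expectation (mean null dissimilarity).
#' @param d_max Maximal dissimilarity of the metric (1 for Bray-Curtis).
#' @return ST values in \[0, 1\].
#' @export
stochasticity_ratio <- function(d_obs, e_null, d_max = 1) {
  if (any(e_null > d_max + 1e-12)) stop("null expectation exceeds d_max")
  ss <- numeric(length(d_obs))
  deg <- abs(e_null - d_max) < 1e-12
  if (any(deg)) {
    warning("pair(s) with E = d_max: selection strength set to 1")
    ss[deg] <- 1
  }
  lo <- !deg & d_obs < e_null
  hi <- !deg & !lo
  ss[lo] <- (e_null[lo] - d_obs[lo]) / e_null[lo]
  ss[hi] <- (d_obs[hi] - e_null[hi]) / (d_max - e_null[hi])
  1 - pmin(pmax(ss, 0), 1)
}

#' Normalized stochasticity ratio (NST) per group and between groups
#'
#' NST is 100 times the mean pairwise stochasticity ratio over the pairs in
#' scope: within each group, and over between-group pairs for the A-vs-B
#' contrast. Values above 50% indicate dominance of stochastic assembly,
#' below 50% of deterministic assembly. A bootstrap over samples within
#' groups provides a two-sided difference test between the two groups.
#'
#' @param table OTU table (OTUs x samples).
#' @param groups Grouping factor over samples (each group >= 3 samples for
#'   a stable mean).
#' @param config A [null_model_config()].
#' @param n_boot Bootstrap draws for the group-difference test (0 skips it).
#' @return List of class `nst_result`: `nst` (named percentages per group
#'   plus `"between"`), `pair_st` (per-pair data.frame), `boot_p`
#'   (bootstrap p for group1 vs group2, two-sided), `config`.
#' @export
nst <- function(table, groups, config = null_model_config(), n_boot = 999) {
  groups <- as.factor(groups)
  stopifnot(length(groups) == ncol(table))
  if (any(table(groups) < 3)) {
    warning("group(s) with fewer than 3 samples: NST means may be unstable")
  }
  ens <- null_ensemble(table, config)
  groups <- groups[match(ens$samples, colnames(table))]
  e_null <- rowMeans(ens$d_null)
  st <- stochasticity_ratio(ens$d_obs, e_null, d_max = 1)
  g1 <- groups[ens$pairs[, 1]]
  g2 <- groups[ens$pairs[, 2]]
  scope <- ifelse(g1 == g2, as.character(g1), "between")
  nst_vals <- vapply(split(st, scope), function(v) 100 * mean(v), 0)

  boot_p <- NA_real_
  if (n_boot > 0 && nlevels(groups) == 2) {
    lv <- levels(groups)
    idx1 <- which(groups == lv[1])
    idx2 <- which(groups == lv[2])
    pair_key <- matrix(0L, length(groups), length(groups))
    pair_key[ens$pairs] <- seq_len(nrow(ens$pairs))
    pair_key <- pair_key + t(pair_key)
    group_nst_boot <- function(idx) {
      take <- idx[sample.int(length(idx), length(idx), replace = TRUE)]
      ks <- pair_key[t(utils::combn(take, 2))]
      ks <- ks[ks > 0]  # drop self-pairs created by resampling duplicates
      if (length(ks) == 0) return(NA_real_)
      100 * mean(st[ks])
    }
    diffs <- vapply(seq_len(n_boot), function(b) {
      group_nst_boot(idx1) - group_nst_boot(idx2)
    }, 0)
    diffs <- diffs[!is.na(diffs)]
    p_lo <- (1 + sum(diffs <= 0)) / (1 + length(diffs))
    p_hi <- (1 + sum(diffs >= 0)) / (1 + length(diffs))
    boot_p <- min(1, 2 * min(p_lo, p_hi))
  }

  structure(list(nst = nst_vals,
                 pair_st = data.frame(
                   sample_1 = ens$samples[ens$pairs[, 1]],
                   sample_2 = ens$samples[ens$pairs[, 2]],
                   d_obs = ens$d_obs, e_null = e_null, st = st,
                   scope = scope, stringsAsFactors = FALSE),
                 boot_p = boot_p, config = config),
            class = "nst_result")
}

#' @export
print.nst_result <- function(x, ...) {
  cat("NST (%):\n")
  print(round(x$nst, 1))
  if (!is.na(x$boot_p)) {
    cat("bootstrap group-difference p =", signif(x$boot_p, 3), "\n")
  }
  invisible(x)
}

#' Occupancy of each OTU
#'
#' Number of samples (ponds, when run on a pooled pond-level table) in
#' which each OTU occurs.
#'
#' @param table OTU table (OTUs x samples).
#' @return Named integer vector.
#' @export
occupancy <- function(table) {
  validate_otu_table(table)
  rowSums(table > 0)
}

#' NST stratified by OTU occupancy
#'
#' For each occupancy level k, restricts the table to OTUs occurring in at
#' least k samples (`mode = "at_least"`, cumulative) or exactly k samples
#' (`mode = "exactly"`) and recomputes NST within each group. At k = 1 the
#' cumulative curve equals the unstratified NST.
#'
#' @param table Pooled pond-level OTU table.
#' @param groups Grouping factor over samples.
#' @param config A [null_model_config()].
#' @param mode Cumulative (`"at_least"`) or exact (`"exactly"`) occupancy
#'   classes.
#' @param k_max Highest occupancy level evaluated (defaults to the maximum
#'   observed occupancy).
#' @return data.frame (k, group, nst, n_otus); levels whose subset is
#'   degenerate (< 2 OTUs or empty samples) are skipped with a warning.
#' @export
nst_by_occupancy <- function(table, groups, config = null_model_config(),
                             mode = c("at_least", "exactly"), k_max = NULL) {
  mode <- match.arg(mode)
  occ <- occupancy(table)
  if (is.null(k_max)) k_max <- max(occ)
  rows <- list()
  for (k in seq_len(k_max)) {
    keep <- if (mode == "at_least") occ >= k else occ == k
    sub <- table[keep, , drop = FALSE]
    if (nrow(sub) < 2) {
      warning("occupancy level ", k, " skipped: fewer than 2 OTUs")
      next
    }
    if (any(colSums(sub) == 0)) {
      warning("occupancy level ", k, " skipped: empty sample(s)")
      next
    }
    res <- nst(sub, groups, config, n_boot = 0)
    vals <- res$nst
    rows[[length(rows) + 1L]] <-
      data.frame(k = k, group = names(vals), nst = unname(vals),
                 n_otus = nrow(sub), stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no usable occupancy level")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
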