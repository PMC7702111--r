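# betaMNTD / betaNTI phylogenetic turnover.
#
# betaMNTD(k, m) is the abundance-weighted mean patristic distance from
# each taxon in one community to its nearest taxon in the other;
# betaNTI is its z-score against a null obtained by shuffling tip labels
# across the whole tree. |betaNTI| < 2 is read as phylogenetically random
# turnover; betaNTI > 2 as over-dispersion, < -2 as clustering.

patristic_for_table <- function(table, tree) {
  validate_otu_table(table)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  missing <- setdiff(rownames(table), tree$tip.label)
  if (length(missing) > 0) {
    stop("OTUs missing from the tree: ", paste(missing, collapse = ", "))
  }
  tree <- ape::keep.tip(tree, rownames(table))
  d <- stats::cophenetic(tree)
  d[rownames(table), rownames(table)]
}

# core: betaMNTD matrix from a patristic distance matrix and a weight
# matrix F (taxa x samples, columns summing to 1 on the present taxa)
bmntd_core <- function(dmat, Fw, present) {
  n <- ncol(Fw)
  min_d <- vapply(seq_len(n), function(j) {
    J <- present[[j]]
    if (length(J) == 1) dmat[, J] else {
      do.call(pmin.int, lapply(J, function(jj) dmat[, jj]))
    }
  }, numeric(nrow(dmat)))
  A <- crossprod(Fw, min_d)     # A[k, m] = sum_i f_ik * min_{j in m} d_ij
  0.5 * (A + t(A))
}

weight_matrix <- function(table, abundance_weighted) {
  if (abundance_weighted) {
    sweep(table, 2, colSums(table), "/")
  } else {
    pa <- (table > 0) * 1
    sweep(pa, 2, colSums(pa), "/")
  }
}

#' Between-community mean nearest taxon distance (betaMNTD)
#'
#' `betaMNTD(k, m) = 0.5 * [sum_i f_ik min_j d_ij + sum_j f_jm min_i d_ij]`
#' with f relative abundances (or presence weights) and d patristic
#' distances; a taxon present in both communities has nearest-taxon
#' distance zero, so identical communities give betaMNTD = 0.
#'
#' @param table OTU table (OTUs x samples); all OTUs must be tree tips.
#' @param tree Rooted `phylo` tree with branch lengths.
#' @param abundance_weighted Weight by relative read abundance (default)
#'   rather than presence.
#' @return Symmetric labeled betaMNTD matrix.
#' @export
beta_mntd <- function(table, tree, abundance_weighted = TRUE) {
  if (any(colSums(table) == 0)) stop("empty sample(s) in table")
  dmat <- patristic_for_table(table, tree)
  Fw <- weight_matrix(table, abundance_weighted)
  present <- apply(table > 0, 2, which, simplify = FALSE)
  out <- bmntd_core(dmat, Fw, present)
  dimnames(out) <- list(colnames(table), colnames(table))
  out
}

#' Beta nearest taxon index (betaNTI)
#'
#' z-score of the observed betaMNTD against `n_reps` null values obtained
#' by shuffling taxon labels across the whole phylogeny (equivalently,
#' jointly permuting rows and columns of the patristic distance matrix)
#' while holding the community matrix fixed.
#'
#' @param table OTU table (OTUs x samples).
#' @param tree Rooted `phylo` tree with branch lengths covering all OTUs.
#' @param n_reps Number of tip-label shuffles (default 999).
#' @param seed Optional integer seed.
#' @param abundance_weighted Weight by relative abundance (default).
#' @return List of class `bnti_result` with `bnti` (z-score matrix;
#'   pairs with zero null standard deviation are NA and reported),
#'   `bmntd_obs`, `null_mean`, `null_sd`, `n_reps`, `seed`.
#' @export
beta_nti <- function(table, tree, n_reps = 999, seed = NULL,
                     abundance_weighted = TRUE) {
  if (any(colSums(table) == 0)) stop("empty sample(s) in table")
  dmat <- patristic_for_table(table, tree)
  Fw <- weight_matrix(table, abundance_weighted)
  present <- apply(table > 0, 2, which, simplify = FALSE)
  obs <- bmntd_core(dmat, Fw, present)
  maybe_set_seed(seed)
  n <- ncol(table)
  S <- nrow(table)
  acc <- matrix(0, n, n)
  acc2 <- matrix(0, n, n)
  for (r in seq_len(n_reps)) {
    perm <- sample.int(S)
    bm <- bmntd_core(dmat[perm, perm], Fw, present)
    acc <- acc + bm
    acc2 <- acc2 + bm^2
  }
  null_mean <- acc / n_reps
  null_sd <- sqrt(pmax(acc2 / n_reps - null_mean^2, 0) * n_reps / (n_reps - 1))
  bnti <- (obs - null_mean) / null_sd
  bnti[null_sd == 0] <- NA_real_
  diag(bnti) <- NA_real_
  if (any(null_sd[upper.tri(null_sd)] == 0)) {
    warning("pair(s) with zero null standard deviation: betaNTI undefined")
  }
  dimnames(bnti) <- list(colnames(table), colnames(table))
  dimnames(obs) <- dimnames(bnti)
  structure(list(bnti = bnti, bmntd_obs = obs, null_mean = null_mean,
                 null_sd = null_sd, n_reps = n_reps, seed = seed),
            class = "bnti_result")
}

#' @export
print.bnti_result <- function(x, ...) {
  v <- x$bnti[upper.tri(x$bnti)]
  v <- v[!is.na(v)]
  cat("betaNTI over", length(v), "pairs:",
      "mean", signif(mean(v), 3),
      "| % in (-2, 2):", round(100 * mean(abs(v) < 2), 1), "\n")
  invisible(x)
}
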