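# OTU-table construction, normalization and beta-diversity comparisons.
#
# Convention used throughout the package and its files: OTUs are rows,
# samples are columns, cells are non-negative integer read counts.

validate_otu_table <- function(table) {
  if (!is.matrix(table)) stop("OTU table must be a matrix (OTUs x samples)")
  if (any(table < 0)) stop("OTU table contains negative cells")
  if (is.null(rownames(table)) || is.null(colnames(table))) {
    stop("OTU table must carry OTU and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(table)) || anyDuplicated(colnames(table))) {
    stop("duplicate OTU or sample ids")
  }
  invisible(table)
}

#' Build an OTU table from per-sample genotype counts
#'
#' @param counts Long-format data.frame with columns `otu`, `sample`,
#'   `count`.
#' @param samples Optional sample ordering (defaults to first appearance).
#' @return Integer matrix, OTUs as rows and samples as columns.
#' @export
build_table <- function(counts, samples = NULL) {
  stopifnot(all(c("otu", "sample", "count") %in% names(counts)))
  if (is.null(samples)) samples <- unique(counts$sample)
  otus <- unique(counts$otu)
  tab <- matrix(0L, length(otus), length(samples),
                dimnames = list(otus, samples))
  idx <- cbind(match(counts$otu, otus), match(counts$sample, samples))
  if (anyNA(idx[, 2])) stop("sample in counts not present in `samples`")
  tab[idx] <- tab[idx] + as.integer(counts$count)
  validate_otu_table(tab)
  tab
}

#' Pool replicate samples into ponds
#'
#' Sums integer counts over the replicates of each pond; the output column
#' order follows the order of first appearance of pond ids in the map.
#'
#' @param table OTU table (OTUs x samples).
#' @param replicate_map data.frame with columns `sample_id`, `pond_id`
#'   partitioning the samples.
#' @return Pooled OTU table (OTUs x ponds).
#' @export
pool_replicates <- function(table, replicate_map) {
  validate_otu_table(table)
  stopifnot(all(c("sample_id", "pond_id") %in% names(replicate_map)))
  unknown <- setdiff(colnames(table), replicate_map$sample_id)
  if (length(unknown) > 0) {
    stop("samples missing from replicate map: ",
         paste(unknown, collapse = ", "))
  }
  ponds <- unique(replicate_map$pond_id)
  out <- sapply(ponds, function(p) {
    cols <- replicate_map$sample_id[replicate_map$pond_id == p]
    cols <- intersect(cols, colnames(table))
    if (length(cols) == 0) stop("pond ", p, " has no samples in the table")
    rowSums(table[, cols, drop = FALSE])
  })
  storage.mode(out) <- "integer"
  rownames(out) <- rownames(table)
  out
}

#' Rarefy an OTU table by multinomial resampling (with replacement)
#'
#' Each sample column is replaced by a multinomial draw of `depth` reads
#' with probabilities proportional to the original counts — i.e. random
#' subsampling *with replacement*, the behaviour of
#' phyloseq-style `rarefy_even_depth(..., replace = TRUE)`. Samples whose
#' total is zero are dropped with a warning; OTU rows that end up all-zero
#' are removed.
#'
#' @param table OTU table (OTUs x samples).
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional integer seed.
#' @param replace Use with-replacement (multinomial) sampling; `FALSE`
#'   switches to classical without-replacement subsampling and requires
#'   every sample total to be at least `depth`.
#' @return Rarefied integer OTU table.
#' @export
rarefy <- function(table, depth, seed = NULL, replace = TRUE) {
  validate_otu_table(table)
  if (depth < 1) stop("depth must be >= 1")
  maybe_set_seed(seed)
  totals <- colSums(table)
  if (any(totals == 0)) {
    warning("dropping ", sum(totals == 0), " sample(s) with zero total")
    table <- table[, totals > 0, drop = FALSE]
  }
  out <- vapply(seq_len(ncol(table)), function(j) {
    x <- table[, j]
    if (replace) {
      stats::rmultinom(1, depth, x)[, 1]
    } else {
      if (sum(x) < depth) stop("sample total below depth; cannot subsample ",
                               "without replacement")
      picked <- sample(rep.int(seq_along(x), x), depth)
      tabulate(picked, nbins = length(x))
    }
  }, numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table),
                dimnames = list(rownames(table), colnames(table)))
  out <- out[rowSums(out) > 0, , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `D(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`; the similarity used in
#' reporting is `1 - D`.
#'
#' @param table OTU table (OTUs x samples), at least two samples.
#' @return Symmetric labeled dissimilarity matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  validate_otu_table(table)
  if (ncol(table) < 2) stop("need at least two samples")
  if (any(colSums(table) == 0)) {
    stop("Bray-Curtis undefined for all-zero samples")
  }
  as.matrix(vegan::vegdist(t(table), method = "bray"))
}

#' SIMPER: per-OTU contribution to between-group dissimilarity
#'
#' The contribution of OTU i to a between-group pair (x, y) is
#' `|x_i - y_i| / sum_j (x_j + y_j)`, averaged over all between-group
#' pairs; contributions sum to the average between-group Bray-Curtis
#' dissimilarity. Significance is assessed by group-label permutation
#' (vegan's `simper`).
#'
#' @param table OTU table (OTUs x samples).
#' @param groups Two-level factor over samples.
#' @param n_perm Label permutations for per-OTU significance.
#' @param seed Optional integer seed.
#' @return data.frame (otu, average, p) sorted by decreasing contribution,
#'   with the mean between-group dissimilarity as attribute
#'   `overall_dissimilarity`.
#' @export
simper_contrib <- function(table, groups, n_perm = 999, seed = NULL) {
  validate_otu_table(table)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) stop("simper requires exactly two groups")
  if (any(table(groups) < 1)) stop("each group needs at least one sample")
  maybe_set_seed(seed)
  sp <- vegan::simper(t(table), group = groups, permutations = n_perm)
  s <- sp[[1]]
  out <- data.frame(otu = s$species, average = s$average, p = s$p,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$average), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "overall_dissimilarity") <- sum(s$average)
  out
}

#' PERMANOVA on a dissimilarity matrix
#'
#' Pseudo-F from total and within-group sums of squared dissimilarities
#' with a permutation p-value using the +1 correction, as implemented by
#' vegan's `adonis2`.
#'
#' @param dm Symmetric dissimilarity matrix or `dist`.
#' @param groups Grouping factor (>= 2 groups, each >= 2 members).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List of class `pond_test` with `statistic` (pseudo-F), `R2`,
#'   `p_value`, `n_perm`, `seed`.
#' @export
permanova <- function(dm, groups, n_perm = 9999, seed = NULL) {
  d <- stats::as.dist(dm)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("singleton group: PERMANOVA undefined")
  if (all(d == 0)) stop("all samples identical: zero total variance, ",
                        "pseudo-F undefined")
  maybe_set_seed(seed)
  df <- data.frame(.group = groups)
  fit <- vegan::adonis2(d ~ .group, data = df, permutations = n_perm)
  structure(list(statistic = fit$F[1], R2 = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1], n_perm = n_perm, seed = seed,
                 method = "PERMANOVA"),
            class = "pond_test")
}

#' Mantel test between two dissimilarity matrices
#'
#' Correlates the vectorized upper triangles (Spearman by default) with a
#' permutation p-value obtained by jointly permuting rows/columns of the
#' second matrix.
#'
#' @param dm1,dm2 Labeled dissimilarity matrices over the same samples.
#' @param method Correlation method (`"spearman"` or `"pearson"`).
#' @param n_perm Number of permutations.
#' @param seed Optional integer seed.
#' @return List of class `pond_test` with `statistic` (rho), `p_value`,
#'   `n_perm`, `seed`.
#' @export
mantel_test <- function(dm1, dm2, method = "spearman", n_perm = 9999,
                        seed = NULL) {
  dm1 <- as.matrix(dm1)
  dm2 <- as.matrix(dm2)
  if (!identical(dim(dm1), dim(dm2))) stop("dissimilarity matrices differ in size")
  if (!is.null(rownames(dm1)) && !is.null(rownames(dm2))) {
    if (!setequal(rownames(dm1), rownames(dm2))) {
      stop("matrices cover different samples")
    }
    dm2 <- dm2[rownames(dm1), rownames(dm1)]
  }
  maybe_set_seed(seed)
  fit <- vegan::mantel(stats::as.dist(dm1), stats::as.dist(dm2),
                       method = method, permutations = n_perm)
  structure(list(statistic = fit$statistic, p_value = fit$signif,
                 n_perm = n_perm, seed = seed, method = "Mantel"),
            class = "pond_test")
}

#' @export
print.pond_test <- function(x, ...) {
  cat(x$method, ": statistic = ", signif(x$statistic, 4), sep = "")
  if (!is.null(x$R2)) cat(", R2 = ", signif(x$R2, 4), sep = "")
  cat(", p = ", signif(x$p_value, 4),
      " (", x$n_perm, " permutations)\n", sep = "")
  invisible(x)
}
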