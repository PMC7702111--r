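toy_table <- function() {
  m <- matrix(c(5L, 0L, 3L, 2L,
                1L, 4L, 0L, 6L,
                2L, 2L, 2L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(paste0("otu", 1:3), paste0("s", 1:4)))
  m
}

test_that("build_table and pool_replicates sum counts conservatively", {
  long <- data.frame(otu = c("o1", "o1", "o2", "o2"),
                     sample = c("r1", "r2", "r1", "r2"),
                     count = c(3L, 1L, 0L, 2L))
  tab <- build_table(long)
  expect_equal(tab["o1", "r1"], 3L)
  pooled <- pool_replicates(tab, data.frame(sample_id = c("r1", "r2"),
                                            pond_id = c("p1", "p1")))
  expect_equal(unname(pooled[, "p1"]), c(4L, 2L))
  expect_equal(sum(pooled), sum(tab))  # pooling preserves total reads

  expect_error(pool_replicates(tab, data.frame(sample_id = "r1",
                                               pond_id = "p1")),
               "missing from replicate map")
})

test_that("rarefaction draws multinomially to the target depth", {
  tab <- toy_table()
  expect_error(rarefy(tab, 0), "depth")
  r <- rarefy(tab, 50, seed = 1)
  expect_true(all(colSums(r) == 50))
  expect_identical(r, rarefy(tab, 50, seed = 1))  # bit-reproducible

  # a single-OTU sample puts all depth on that OTU
  solo <- matrix(c(7L, 0L, 0L, 9L), 2, 2,
                 dimnames = list(c("a", "b"), c("x", "y")))
  rs <- rarefy(solo, 25, seed = 2)
  expect_equal(unname(rs["a", "x"]), 25)

  # expectation oracle: mean rarefied count ~ depth * c_i / sum(c)
  x <- c(10L, 30L, 60L)
  tab1 <- matrix(x, 3, 1, dimnames = list(paste0("o", 1:3), "s"))
  acc <- rowSums(vapply(1:1000, function(i) {
    out <- rarefy(tab1, 20, seed = 100 + i)
    full <- setNames(numeric(3), paste0("o", 1:3))
    full[rownames(out)] <- out[, 1]
    full
  }, numeric(3))) / 1000
  expected <- 20 * x / sum(x)
  se <- sqrt(20 * (x / sum(x)) * (1 - x / sum(x)) / 1000)
  expect_true(all(abs(acc - expected) < 4 * se))

  # without-replacement mode requires sufficient depth
  expect_error(rarefy(tab, 1000, seed = 3, replace = FALSE),
               "without replacement")
})

test_that("Bray-Curtis matches its definition", {
  tab <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  rownames(tab) <- paste0("o", 1:3)
  d <- bray_curtis(tab)
  expect_equal(d["a", "b"], 4 / 12)
  expect_equal(diag(d), c(a = 0, b = 0))

  same <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  rownames(same) <- paste0("o", 1:3)
  expect_equal(bray_curtis(same)["a", "b"], 0)

  disj <- cbind(a = c(5, 0), b = c(0, 7))
  rownames(disj) <- paste0("o", 1:2)
  expect_equal(bray_curtis(disj)["a", "b"], 1)

  zero <- cbind(a = c(0, 0), b = c(1, 1))
  rownames(zero) <- paste0("o", 1:2)
  expect_error(bray_curtis(zero), "all-zero")
})

test_that("SIMPER contributions decompose the between-group dissimilarity", {
  set.seed(3)
  tab <- matrix(rpois(3 * 4, 20), 3, 4,
                dimnames = list(paste0("o", 1:3), paste0("s", 1:4)))
  storage.mode(tab) <- "integer"
  grp <- c("A", "A", "B", "B")
  res <- simper_contrib(tab, grp, n_perm = 99, seed = 4)

  # brute-force oracle: average per-OTU contribution over the 4
  # between-group pairs
  pairs <- expand.grid(i = 1:2, j = 3:4)
  contrib <- sapply(seq_len(nrow(pairs)), function(k) {
    x <- tab[, pairs$i[k]]; y <- tab[, pairs$j[k]]
    abs(x - y) / sum(x + y)
  })
  oracle <- rowMeans(contrib)
  expect_equal(res$average[match(names(oracle), res$otu)],
               unname(oracle), tolerance = 1e-10)

  # contributions sum to the mean between-group dissimilarity
  mean_d <- mean(sapply(seq_len(nrow(pairs)), function(k) {
    bc_oracle(tab[, pairs$i[k]], tab[, pairs$j[k]])
  }))
  expect_equal(attr(res, "overall_dissimilarity"), mean_d,
               tolerance = 1e-10)

  # a single differing OTU carries 100% of the dissimilarity
  tab1 <- matrix(c(10L, 5L, 10L, 5L, 10L, 9L, 10L, 9L), 2, 4,
                 dimnames = list(c("same", "driver"), paste0("s", 1:4)))
  res1 <- simper_contrib(tab1, grp, n_perm = 99, seed = 5)
  expect_equal(res1$average[res1$otu == "driver"],
               attr(res1, "overall_dissimilarity"), tolerance = 1e-10)
})

test_that("PERMANOVA detects separation and rejects degenerate input", {
  set.seed(6)
  a <- matrix(rpois(40, 5), 10, 4)
  b <- matrix(rpois(40, 5) + matrix(c(30, rep(0, 9)), 10, 4), 10, 4)
  tab <- cbind(a, b)
  dimnames(tab) <- list(paste0("o", 1:10), paste0("s", 1:8))
  storage.mode(tab) <- "integer"
  grp <- rep(c("A", "B"), each = 4)
  res <- permanova(bray_curtis(tab), grp, n_perm = 999, seed = 7)
  expect_s3_class(res, "pond_test")
  expect_gt(res$statistic, 1)
  expect_lt(res$p_value, 0.05)
  expect_true(res$p_value >= 1 / 1000)  # +1 correction: never exactly zero

  same <- matrix(rep(c(1, 2), 4), 2, 4,
                 dimnames = list(c("o1", "o2"), paste0("s", 1:4)))
  expect_error(permanova(bray_curtis(same), c("A", "A", "B", "B"),
                         n_perm = 99),
               "identical")
  expect_error(permanova(bray_curtis(tab), c("A", rep("B", 7)),
                         n_perm = 99),
               "singleton")
})

test_that("PERMANOVA p-values are calibrated under a true null", {
  set.seed(8)
  ps <- replicate(100, {
    tab <- matrix(rpois(10 * 8, 10), 10, 8,
                  dimnames = list(paste0("o", 1:10), paste0("s", 1:8)))
    storage.mode(tab) <- "integer"
    permanova(bray_curtis(tab), rep(c("A", "B"), each = 4),
              n_perm = 199)$p_value
  })
  # type-I error at 0.05 within 4-sigma binomial error
  expect_lt(abs(mean(ps <= 0.05) - 0.05), 4 * sqrt(0.05 * 0.95 / 100) + 0.01)
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("Mantel statistics respect rank invariance and label matching", {
  set.seed(9)
  tab <- matrix(rpois(10 * 6, 10), 10, 6,
                dimnames = list(paste0("o", 1:10), paste0("s", 1:6)))
  storage.mode(tab) <- "integer"
  d1 <- bray_curtis(tab)
  res <- mantel_test(d1, d1, n_perm = 99, seed = 10)
  expect_equal(res$statistic, 1)

  # a monotone transform leaves Spearman's rho at 1
  d2 <- d1^3 + 0.1 * d1
  diag(d2) <- 0
  res2 <- mantel_test(d1, d2, n_perm = 99, seed = 11)
  expect_equal(res2$statistic, 1)

  expect_error(mantel_test(d1, d1[1:5, 1:5], n_perm = 99), "size")
})
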