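test_that("merge_pairs joins exact overlaps and applies the quality rule", {
  # perfectly complementary 50 bp overlap: merged length = n1 + n2 - 50
  set.seed(1)
  full <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE),
                collapse = "")
  fwd <- data.frame(id = "r1", seq = substr(full, 1, 100),
                    qual = strrep("I", 100), stringsAsFactors = FALSE)
  rev <- data.frame(id = "r1", seq = revcomp(substr(full, 51, 150)),
                    qual = strrep("I", 100), stringsAsFactors = FALSE)
  m <- merge_pairs(fwd, rev, min_overlap = 30)
  expect_equal(m$n_rejected, 0)
  expect_equal(nchar(m$merged$seq), 150)
  expect_identical(m$merged$seq, full)

  # one mismatch in the overlap: the Q40 base must win over the Q10 base
  fwd2 <- fwd
  substr(fwd2$seq, 60, 60) <- if (substr(full, 60, 60) == "A") "C" else "A"
  q <- strrep("I", 100)                      # fwd all Q40
  rev2 <- rev
  rev2$qual <- strrep("+", 100)              # rev all Q10
  m2 <- merge_pairs(fwd2, rev2, min_overlap = 30)
  expect_identical(substr(m2$merged$seq, 60, 60), substr(fwd2$seq, 60, 60))
  # and the other way around
  fwd3 <- fwd2
  fwd3$qual <- strrep("+", 100)
  rev3 <- rev
  m3 <- merge_pairs(fwd3, rev3, min_overlap = 30)
  expect_identical(substr(m3$merged$seq, 60, 60), substr(full, 60, 60))

  # irreconcilable pair is rejected, not fatal
  junk <- data.frame(id = "r1", seq = strrep("A", 100),
                     qual = strrep("I", 100), stringsAsFactors = FALSE)
  junk2 <- data.frame(id = "r1", seq = strrep("G", 100),
                      qual = strrep("I", 100), stringsAsFactors = FALSE)
  m4 <- merge_pairs(junk, junk2, min_overlap = 30,
                    max_mismatch_frac = 0.1)
  expect_equal(m4$n_rejected, 1)
})

test_that("simulated pairs overwhelmingly merge to the true length", {
  g <- simulate_genotypes(5, length = 250, min_dist = 5, seed = 20)
  sim <- simulate_reads(g, rep(200, 5), error_model(), seed = 21)
  pr <- paired_reads(sim$reads, 180, 180)
  m <- merge_pairs(pr$fwd, pr$rev, min_overlap = 30)
  ok <- nchar(m$merged$seq) == 250
  expect_gte(sum(ok) / nrow(pr$fwd), 0.99)
})

test_that("expected errors follow the Phred arithmetic and 0.5 cutoff", {
  q20_10 <- strrep("5", 10)    # Q20 = ASCII 53 = '5'
  q20_100 <- strrep("5", 100)
  expect_equal(expected_errors(q20_10), 0.1)
  expect_equal(expected_errors(q20_100), 1.0)
  expect_equal(expected_errors(""), 0)

  reads <- data.frame(id = c("a", "b"),
                      seq = c(strrep("A", 10), strrep("A", 100)),
                      qual = c(q20_10, q20_100), stringsAsFactors = FALSE)
  kept <- filter_reads(reads, max_ee = 0.5)
  expect_identical(kept$id, "a")
  expect_equal(attr(kept, "n_removed"), 1)
})

test_that("dereplication counts, sorts and drops singletons", {
  seqs <- c(rep("ACGT", 3), rep("ACGA", 2), "TTTT")
  u <- dereplicate(seqs)
  expect_identical(u$seq, c("ACGT", "ACGA", "TTTT"))
  expect_identical(u$count, c(3L, 2L, 1L))
  expect_equal(sum(u$count), length(seqs))
  u2 <- remove_singletons(u)
  expect_equal(nrow(u2), 2)
  expect_equal(attr(u2, "n_reads_removed"), 1)

  # equal counts break ties lexicographically by sequence
  ut <- dereplicate(c("TT", "TT", "AA", "AA"))
  expect_identical(ut$seq, c("AA", "TT"))

  # per-sample tracking sums to the pooled counts
  us <- dereplicate(c("AA", "AA", "CC"), sample = c("s1", "s2", "s1"))
  sc <- attr(us, "sample_counts")
  expect_equal(unname(rowSums(sc)), us$count)
})

test_that("child_probability implements mu = N * (eff/3)^d", {
  p <- denoise_params(seq_error_rate = 3e-3, pcr_error_rate = 0)
  parent <- strrep("A", 100)
  child <- paste0("C", strrep("A", 99))
  res <- child_probability(parent, 1000, child, p)
  expect_equal(res$distance, 1)
  expect_equal(res$p_read, 1e-3)
  expect_equal(res$mu, 1.0)

  # identical sequence is not a child
  expect_error(child_probability(parent, 1000, parent, p), "d = 0")

  # doubling the cycles doubles the PCR term of eff, so mu rises
  p1 <- denoise_params(pcr_error_rate = 1e-5, pcr_cycles = 30)
  p2 <- denoise_params(pcr_error_rate = 1e-5, pcr_cycles = 60)
  mu1 <- child_probability(parent, 1000, child, p1)$mu
  mu2 <- child_probability(parent, 1000, child, p2)$mu
  expect_gt(mu2, mu1)
  eff1 <- 1e-3 + 15 * 1e-5
  eff2 <- 1e-3 + 30 * 1e-5
  expect_equal(mu2 / mu1, eff2 / eff1)
})

test_that("denoise applies the Poisson tail decision rule", {
  parent <- strrep("A", 100)
  child <- paste0("C", strrep("A", 99))
  # mu = 1.0 for this configuration (hand arithmetic above)
  p <- denoise_params(seq_error_rate = 3e-3, pcr_error_rate = 0,
                      alpha = 1e-3)

  # P(X >= 2 | mu = 1) = 1 - 2/e = 0.264 > alpha: merged
  u2 <- data.frame(seq = c(parent, child), count = c(1000L, 2L),
                   stringsAsFactors = FALSE)
  d2 <- denoise(u2, p)
  expect_equal(nrow(d2$genotypes), 1)
  expect_equal(d2$genotypes$total_count, 1002L)
  expect_equal(d2$assignments$status[2], "merged")
  expect_equal(d2$assignments$p_value[2], 1 - exp(-1) * 2,
               tolerance = 1e-10)

  # P(X >= 30 | mu = 1) << alpha: promoted to a new genotype
  u30 <- data.frame(seq = c(parent, child), count = c(1000L, 30L),
                    stringsAsFactors = FALSE)
  d30 <- denoise(u30, p)
  expect_equal(nrow(d30$genotypes), 2)

  # degenerate single input
  d1 <- denoise(data.frame(seq = parent, count = 5L,
                           stringsAsFactors = FALSE), p)
  expect_equal(nrow(d1$genotypes), 1)
  expect_equal(d1$genotypes$total_count, 5L)

  # empty input
  d0 <- denoise(data.frame(seq = character(0), count = integer(0)), p)
  expect_equal(nrow(d0$genotypes), 0)
})

test_that("zero-error input is recovered exactly with conservation", {
  g <- simulate_genotypes(6, length = 150, min_dist = 5, seed = 22)
  ab <- c(500L, 400L, 300L, 200L, 100L, 50L)
  sim <- simulate_reads(g, ab, error_model(0, 0, 0, 0), seed = 23)
  u <- dereplicate(sim$reads$seq)
  dn <- denoise(u, denoise_params())
  expect_setequal(dn$genotypes$seq, unname(g))
  expect_equal(sort(dn$genotypes$total_count), sort(ab))
})

test_that("read counts are conserved across the denoising ledger", {
  g <- simulate_genotypes(5, length = 200, min_dist = 5, seed = 24)
  sim <- simulate_reads(g, rep(2000, 5), error_model(chimera_rate = 0.01),
                        seed = 25)
  u <- dereplicate(sim$reads$seq)
  kept <- remove_singletons(u)
  dn <- denoise(kept, denoise_params())
  chim_reads <- sum(dn$assignments$count[dn$assignments$status == "chimera"])
  expect_equal(sum(dn$genotypes$total_count) + chim_reads +
                 attr(kept, "n_reads_removed"),
               sum(u$count))
})

test_that("raising alpha or lowering skew moves calls monotonically", {
  g <- simulate_genotypes(5, length = 200, min_dist = 5, seed = 26)
  sim <- simulate_reads(g, rep(2000, 5), error_model(chimera_rate = 0.02),
                        seed = 27)
  kept <- remove_singletons(dereplicate(sim$reads$seq))
  n_geno <- function(alpha) {
    nrow(denoise(kept, denoise_params(alpha = alpha))$genotypes)
  }
  n_chim <- function(skew) {
    dn <- denoise(kept, denoise_params(min_parent_skew = skew))
    sum(dn$assignments$status == "chimera")
  }
  g_low <- n_geno(1e-20); g_mid <- n_geno(1e-6); g_high <- n_geno(1e-2)
  expect_true(g_low <= g_mid && g_mid <= g_high)
  c2 <- n_chim(2); c50 <- n_chim(50); c1e6 <- n_chim(1e6)
  expect_true(c2 >= c50 && c50 >= c1e6)
})

test_that("the UNOISE-style skew rule is available behind a flag", {
  parent <- strrep("A", 100)
  child <- paste0("C", strrep("A", 99))
  pu <- denoise_params(method = "unoise", unoise_alpha = 2)
  # beta(1) = 1/8: a 100-read child of a 1000-read parent (skew 0.1 < 1/8)
  # is merged, a 200-read child (skew 0.2) is promoted
  dm <- denoise(data.frame(seq = c(parent, child), count = c(1000L, 100L),
                           stringsAsFactors = FALSE), pu)
  expect_equal(nrow(dm$genotypes), 1)
  dp <- denoise(data.frame(seq = c(parent, child), count = c(1000L, 200L),
                           stringsAsFactors = FALSE), pu)
  expect_equal(nrow(dp$genotypes), 2)
})

test_that("chimera check finds exact two-parent splices", {
  # the textbook case: AAAACCCC from AAAAAAAA and CCCCCCCC at b = 4
  res <- chimera_check("AAAACCCC", 10,
                       c("AAAAAAAA", "CCCCCCCC"), c(900, 800))
  expect_true(res$is_chimera)
  expect_equal(res$left_parent, 1L)
  expect_equal(res$right_parent, 2L)
  expect_equal(res$breakpoint, 4L)

  # a query identical to a parent is never chimeric
  res2 <- chimera_check("AAAAAAAA", 10,
                        c("AAAAAAAA", "CCCCCCCC"), c(900, 800))
  expect_false(res2$is_chimera)

  # insufficient parent skew blocks the call
  res3 <- chimera_check("AAAACCCC", 500,
                        c("AAAAAAAA", "CCCCCCCC"), c(900, 800))
  expect_false(res3$is_chimera)

  # breakpoint can sit anywhere the segments match exactly
  res4 <- chimera_check("ACCCCCCC", 10,
                        c("AAAAAAAA", "CCCCCCCC"), c(900, 800))
  expect_true(res4$is_chimera)
  expect_equal(res4$breakpoint, 1L)
})

test_that("denoise discards chimeric queries without funneling their reads", {
  A <- strrep("A", 40)
  B <- strrep("C", 40)
  chim <- paste0(strrep("A", 20), strrep("C", 20))
  u <- data.frame(seq = c(A, B, chim), count = c(900L, 800L, 10L),
                  stringsAsFactors = FALSE)
  dn <- denoise(u, denoise_params())
  expect_equal(nrow(dn$genotypes), 2)
  expect_equal(dn$assignments$status[dn$assignments$seq == chim], "chimera")
  expect_equal(sum(dn$genotypes$total_count), 1700L)
})
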