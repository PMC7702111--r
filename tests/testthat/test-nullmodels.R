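test_that("rc_index honours the extreme and tie conventions exactly", {
  # observed larger than every null value: RC = +1 (less similar than chance)
  expect_equal(rc_index(0.9, rep(0.5, 200)), 1)
  # observed below every null value: RC = -1
  expect_equal(rc_index(0.1, rep(0.5, 200)), -1)
  # observed equal to every null value: ties count half, RC = 0
  expect_equal(rc_index(0.5, rep(0.5, 200)), 0)
  # half below, half above: RC = 0
  expect_equal(rc_index(0.5, c(rep(0.4, 100), rep(0.6, 100))), 0)
})

test_that("null model configuration enforces its invariants", {
  expect_error(null_model_config(n_reps = 50), "n_reps")
  cfg <- null_model_config(n_reps = 100, metric = "jaccard")
  expect_equal(cfg$metric, "jaccard")
})

test_that("forced species identity leaves only abundance variability", {
  # pool of exactly the observed species, richness = pool size: every null
  # community contains the same species set
  tab <- matrix(c(5L, 3L, 2L, 4L, 4L, 2L), 3, 2,
                dimnames = list(paste0("o", 1:3), c("x", "y")))
  pool <- regional_pool(tab)
  cfg <- null_model_config(n_reps = 200, seed = 1)
  d <- null_dissimilarity_distribution(tab[, 1], tab[, 2], pool, cfg)
  expect_length(d, 200)
  # with all species forced present, dissimilarities stay well below 1
  expect_true(all(d < 1))
  draws <- replicate(50,
    sum(pondassembly:::draw_null_sample(3, 10, pool, cfg) > 0))
  expect_true(all(draws == 3))
})

test_that("Monte-Carlo null distributions match exhaustive enumeration", {
  # 3-species pool, richness 2, small individual counts: the full outcome
  # space can be enumerated exactly
  freq <- c(2, 1, 1)
  relab <- c(0.5, 0.3, 0.2)
  names(freq) <- names(relab) <- paste0("o", 1:3)
  oracle <- enumerate_null_pair_d(Sx = 2, Nx = 4, Sy = 2, Ny = 3,
                                  freq = freq, relab = relab)
  tab <- matrix(c(2L, 2L, 0L, 1L, 0L, 2L), 3, 2,
                dimnames = list(names(freq), c("x", "y")))
  pool <- list(freq = freq, relabund = relab)
  n_reps <- 4000
  cfg <- null_model_config(n_reps = n_reps, seed = 2)
  d <- null_dissimilarity_distribution(tab[, 1], tab[, 2], pool, cfg)

  # mean within 3 Monte-Carlo standard errors of the exact mean
  se <- oracle$sd / sqrt(n_reps)
  expect_lt(abs(mean(d) - oracle$mean), 3 * se)

  # tail probability at the exact median within 3 MC standard errors
  t0 <- median(rep(oracle$d, round(oracle$prob * 1e6)))
  p_exact <- sum(oracle$prob[oracle$d <= t0 + 1e-12])
  p_mc <- mean(d <= t0 + 1e-12)
  expect_lt(abs(p_mc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / n_reps))
})

test_that("null draws fail when the pool cannot cover observed richness", {
  pool <- list(freq = c(1, 1), relabund = c(0.5, 0.5))
  cfg <- null_model_config(n_reps = 100, seed = 3)
  expect_error(null_dissimilarity_distribution(c(1, 1, 1), c(1, 1, 0),
                                               list(freq = c(1, 1),
                                                    relabund = c(.5, .5)),
                                               cfg))
})

test_that("raup_crick returns a bounded symmetric matrix with proper bins", {
  mc <- simulate_metacommunity(metacommunity_config(n_sites = 6), seed = 4)
  rc <- raup_crick(mc$table, null_model_config(n_reps = 150, seed = 5))
  v <- rc[upper.tri(rc)]
  expect_true(all(v >= -1 & v <= 1))
  expect_equal(rc, t(rc))
  bins <- classify_rc(rc)
  expect_equal(sum(bins), 100)
  expect_true(all(bins >= 0))
})

test_that("RC Monte-Carlo noise shrinks like one over sqrt(reps)", {
  tab <- matrix(c(6L, 3L, 1L, 2L, 5L, 2L), 3, 2,
                dimnames = list(paste0("o", 1:3), c("x", "y")))
  pool <- regional_pool(tab)
  rc_at <- function(reps, seed) {
    cfg <- null_model_config(n_reps = reps, seed = seed)
    d <- null_dissimilarity_distribution(tab[, 1], tab[, 2], pool, cfg)
    rc_index(bc_oracle(tab[, 1], tab[, 2]), d)
  }
  sd_small <- sd(vapply(1:40, function(s) rc_at(100, s), 0))
  sd_large <- sd(vapply(1:40, function(s) rc_at(400, 1000 + s), 0))
  # quadrupling reps should halve the Monte-Carlo sd (loose band)
  expect_gt(sd_small / sd_large, 1.3)
  expect_lt(sd_small / sd_large, 3.2)
})

test_that("stochasticity ratio hits its calibration anchors", {
  # null-indistinguishable: D = E gives ST = 1 (NST 100%)
  expect_equal(stochasticity_ratio(0.4, 0.4), 1)
  # maximal divergence: D = D_max = 1 with E < 1 gives ST = 0
  expect_equal(stochasticity_ratio(1, 0.6), 0)
  # degenerate E = D_max is flagged and set to SS = 1
  expect_warning(st <- stochasticity_ratio(0.5, 1), "d_max")
  expect_equal(st, 0)
  expect_true(all(stochasticity_ratio(runif(50), runif(50, 0.1, 0.9))
                  >= 0))
})

test_that("NST stays within [0, 100] and separates its scopes", {
  mc <- simulate_metacommunity(metacommunity_config(n_sites = 8), seed = 6)
  res <- nst(mc$table, mc$metadata$pond_type,
             null_model_config(n_reps = 150, seed = 7), n_boot = 99)
  expect_true(all(res$nst >= 0 & res$nst <= 100))
  expect_setequal(names(res$nst), c("polygonal", "trough", "between"))
  expect_true(is.na(res$boot_p) || (res$boot_p > 0 && res$boot_p <= 1))
  # per-pair table covers all sample pairs
  expect_equal(nrow(res$pair_st), choose(8, 2))
})

test_that("occupancy counts and cumulative stratification behave", {
  tab <- matrix(c(1L, 0L, 2L, 3L, 0L, 0L, 1L, 1L, 1L), 3, 3,
                dimnames = list(paste0("o", 1:3), paste0("s", 1:3)))
  expect_equal(unname(occupancy(tab)), c(3L, 1L, 2L))

  mc <- simulate_metacommunity(metacommunity_config(n_sites = 6), seed = 8)
  tab_occ <- mc$table[rowSums(mc$table) > 0, , drop = FALSE]
  cfg <- null_model_config(n_reps = 150, seed = 9)
  curve <- suppressWarnings(
    nst_by_occupancy(tab_occ, mc$metadata$pond_type, cfg, k_max = 3))
  expect_true(all(curve$nst >= 0 & curve$nst <= 100))
  # cumulative mode at k = 1 keeps the full community, matching nst()
  full <- nst(tab_occ, mc$metadata$pond_type, cfg, n_boot = 0)
  k1 <- curve[curve$k == 1, ]
  expect_equal(sort(k1$nst), sort(unname(full$nst)), tolerance = 1e-10)
  # exact mode is available
  curve_ex <- suppressWarnings(
    nst_by_occupancy(mc$table, mc$metadata$pond_type, cfg,
                     mode = "exactly", k_max = 3))
  expect_true(all(curve_ex$k %in% 1:3))
})
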