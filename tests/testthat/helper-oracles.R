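# Shared fixtures and independent oracles used across test files.

# rank-ordered lognormal regional abundance vector
ranked_lognormal <- function(S, sdlog) {
  p <- sort(qlnorm(ppoints(S), 0, sdlog), decreasing = TRUE)
  p / sum(p)
}

# brute-force Bray-Curtis for oracle comparisons
bc_oracle <- function(x, y) sum(abs(x - y)) / sum(x + y)

# Exhaustive enumeration of the richness-fixed, occurrence-weighted,
# abundance-proportional null community distribution on a tiny pool.
# Returns a list of (prob, counts) pairs.
enumerate_null_communities <- function(S, N, freq, relab) {
  P <- length(freq)
  stopifnot(S <= P, S <= 2)  # sequential-draw probabilities coded for S <= 2
  subsets <- utils::combn(P, S, simplify = FALSE)
  out <- list()
  for (sub in subsets) {
    # probability of drawing this unordered subset by sequential weighted
    # sampling without replacement
    if (S == 1) {
      p_sub <- freq[sub] / sum(freq)
    } else {
      a <- sub[1]; b <- sub[2]; W <- sum(freq)
      p_sub <- freq[a] / W * freq[b] / (W - freq[a]) +
        freq[b] / W * freq[a] / (W - freq[b])
    }
    # compositions of the remaining N - S individuals over the subset
    q <- relab[sub] / sum(relab[sub])
    extra <- N - S
    comps <- if (S == 1) matrix(extra, 1, 1) else
      cbind(0:extra, extra - (0:extra))
    for (r in seq_len(nrow(comps))) {
      k <- comps[r, ]
      p_comp <- dmultinom(k, prob = q)
      counts <- numeric(P)
      counts[sub] <- 1 + k
      out[[length(out) + 1]] <- list(prob = p_sub * p_comp, counts = counts)
    }
  }
  out
}

# exact null dissimilarity distribution for a pair of samples, by full
# enumeration over both communities' outcomes
enumerate_null_pair_d <- function(Sx, Nx, Sy, Ny, freq, relab) {
  ex <- enumerate_null_communities(Sx, Nx, freq, relab)
  ey <- enumerate_null_communities(Sy, Ny, freq, relab)
  d <- numeric(0)
  p <- numeric(0)
  for (a in ex) {
    for (b in ey) {
      d <- c(d, bc_oracle(a$counts, b$counts))
      p <- c(p, a$prob * b$prob)
    }
  }
  stopifnot(abs(sum(p) - 1) < 1e-9)
  list(d = d, prob = p,
       mean = sum(d * p),
       sd = sqrt(sum(d^2 * p) - sum(d * p)^2))
}

# substitute specific positions of a sequence with a different random base
substitute_at <- function(s, pos) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# constructed mixture for the occupancy-stratified NST check:
# widespread niche-sorted core taxa plus low-occupancy drifting neutral taxa
occupancy_mixture <- function(seed) {
  nicher <- simulate_metacommunity(
    metacommunity_config(pool_size = 40, niche_weight = 1,
                         niche_breadth = 0.4, individuals_per_site = 400,
                         drift_theta = Inf), seed = seed)
  neut <- simulate_metacommunity(
    metacommunity_config(pool_size = 400, niche_weight = 0,
                         individuals_per_site = 800, drift_theta = 20,
                         regional_abundances = ranked_lognormal(400, 0.5)),
    seed = seed + 500)
  tab <- rbind(
    `rownames<-`(nicher$table, paste0("core", rownames(nicher$table))),
    `rownames<-`(neut$table, paste0("rare", rownames(neut$table))))
  list(table = tab, groups = rep("all", ncol(tab)),
       metadata = nicher$metadata)
}
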