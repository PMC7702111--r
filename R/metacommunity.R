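# Neutral / niche metacommunity simulation and a pure-birth phylogeny.
#
# The generator embodies the stochastic-vs-deterministic contrast the null
# models are meant to detect: each site recruits a fixed number of
# individuals from a shared regional pool, a tunable fraction `niche_weight`
# of them deterministically (Gaussian suitability on one environmental
# axis), the rest by neutral lottery proportional to regional abundance.

#' Metacommunity generator configuration
#'
#' @param pool_size Number of species in the regional pool.
#' @param n_sites Number of sites (split evenly over the two types unless
#'   `site_type` is given).
#' @param site_type Character vector of length `n_sites` with exactly two
#'   levels, e.g. polygonal vs trough pond origin.
#' @param individuals_per_site Individuals recruited per site.
#' @param niche_weight Fraction `w` in \[0, 1\] of individuals recruited
#'   deterministically by environmental suitability.
#' @param niche_breadth Gaussian niche breadth (gradient units, > 0).
#' @param env_values Environmental value per site; defaults to -1 for the
#'   first site type and +1 for the second (two habitat clusters).
#' @param regional_abundances Probability vector over the pool; defaults to
#'   a rank-ordered lognormal abundance distribution (sdlog = 2).
#' @param drift_theta Strength of ecological drift in the neutral lottery:
#'   each site's neutral recruitment weights are drawn from a Dirichlet
#'   distribution with concentration `drift_theta * regional_abundances`,
#'   so small values produce strong site-to-site drift (taxa missing from
#'   many sites despite regional abundance, as in field occupancy
#'   patterns) and `Inf` recovers a pure shared-pool multinomial lottery.
#' @return An object of class `metacommunity_config`.
#' @export
metacommunity_config <- function(pool_size = 400L, n_sites = 12L,
                                 site_type = NULL,
                                 individuals_per_site = 1000L,
                                 niche_weight = 0, niche_breadth = 0.5,
                                 env_values = NULL,
                                 regional_abundances = NULL,
                                 drift_theta = 100) {
  stopifnot(pool_size >= 2, n_sites >= 2, individuals_per_site >= 1)
  if (niche_weight < 0 || niche_weight > 1) stop("niche_weight must be in [0, 1]")
  if (niche_breadth <= 0) stop("niche_breadth must be > 0")
  if (drift_theta <= 0) stop("drift_theta must be > 0 (Inf for no drift)")
  if (is.null(site_type)) {
    if (n_sites %% 2 != 0) stop("give site_type explicitly for odd n_sites")
    site_type <- rep(c("polygonal", "trough"), each = n_sites / 2)
  }
  stopifnot(length(site_type) == n_sites)
  if (length(unique(site_type)) != 2) stop("site_type must have two levels")
  if (is.null(env_values)) {
    env_values <- ifelse(site_type == unique(site_type)[1], -1, 1)
  }
  stopifnot(length(env_values) == n_sites)
  if (is.null(regional_abundances)) {
    p <- sort(stats::qlnorm(stats::ppoints(pool_size), 0, 2),
              decreasing = TRUE)
    regional_abundances <- p / sum(p)
  }
  stopifnot(length(regional_abundances) == pool_size,
            all(regional_abundances >= 0))
  if (abs(sum(regional_abundances) - 1) > 1e-8) {
    stop("regional_abundances must sum to 1")
  }
  structure(list(pool_size = as.integer(pool_size),
                 n_sites = as.integer(n_sites),
                 site_type = site_type,
                 individuals_per_site = as.integer(individuals_per_site),
                 niche_weight = niche_weight,
                 niche_breadth = niche_breadth,
                 env_values = env_values,
                 regional_abundances = regional_abundances,
                 drift_theta = drift_theta),
            class = "metacommunity_config")
}

#' Simulate a metacommunity with a tunable niche/neutral mix
#'
#' Species' environmental optima are drawn uniformly over the environmental
#' range (fixed per species for the whole metacommunity). At each site,
#' `round(w * J)` individuals are recruited with weight proportional to
#' `regional_abundance * exp(-(env - optimum)^2 / (2 sigma^2))` and the
#' remaining individuals by neutral lottery with weight proportional to
#' regional abundance, perturbed per site by ecological drift
#' (Dirichlet, see [metacommunity_config()]). Row sums always equal
#' `individuals_per_site`.
#'
#' @param config A [metacommunity_config()].
#' @param seed Optional integer seed.
#' @return List with `table` (species x sites integer matrix), `metadata`
#'   (sample_id, pond_id, pond_type, replicate), `optima` and `config`.
#' @export
simulate_metacommunity <- function(config, seed = NULL) {
  stopifnot(inherits(config, "metacommunity_config"))
  maybe_set_seed(seed)
  S <- config$pool_size
  n <- config$n_sites
  J <- config$individuals_per_site
  w <- config$niche_weight
  sigma <- config$niche_breadth
  env <- config$env_values
  reg <- config$regional_abundances

  optima <- stats::runif(S, min(env) - sigma, max(env) + sigma)
  tab <- matrix(0L, nrow = S, ncol = n,
                dimnames = list(sprintf("otu%04d", seq_len(S)),
                                sprintf("S%02d", seq_len(n))))
  n_det <- round(w * J)
  for (j in seq_len(n)) {
    counts <- numeric(S)
    if (n_det > 0) {
      suit <- reg * exp(-(env[j] - optima)^2 / (2 * sigma^2))
      if (sum(suit) == 0) suit <- reg  # pathological sigma; fall back
      counts <- counts + stats::rmultinom(1, n_det, suit)[, 1]
    }
    if (J - n_det > 0) {
      w_neutral <- if (is.finite(config$drift_theta)) {
        g <- stats::rgamma(S, shape = config$drift_theta * reg)
        if (sum(g) == 0) reg else g / sum(g)
      } else reg
      counts <- counts + stats::rmultinom(1, J - n_det, w_neutral)[, 1]
    }
    tab[, j] <- as.integer(counts)
  }
  metadata <- data.frame(sample_id = colnames(tab),
                         pond_id = colnames(tab),
                         pond_type = config$site_type,
                         replicate = 1L,
                         stringsAsFactors = FALSE)
  list(table = tab, metadata = metadata, optima = optima, config = config)
}

#' Simulate a pure-birth phylogeny over OTUs
#'
#' A Yule (pure-birth) tree with strictly positive branch lengths, tips
#' labelled with OTU ids, standing in for an inferred amplicon phylogeny in
#' the betaNTI stage.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @param tip_labels Optional character vector of tip labels (length
#'   `n_taxa`); defaults to `otu0001`, `otu0002`, ...
#' @return An `ape::phylo` object; serialize with [write_newick()].
#' @export
simulate_tree <- function(n_taxa, seed = NULL, tip_labels = NULL) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  maybe_set_seed(seed)
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  if (is.null(tip_labels)) tip_labels <- sprintf("otu%04d", seq_len(n_taxa))
  stopifnot(length(tip_labels) == n_taxa)
  tree$tip.label <- tip_labels
  tree
}

#' Simulate a headspace gas-measurement table linked to methanotrophs
#'
#' Generates per-pond dissolved CO2 and CH4 concentrations, with log CH4
#' decreasing in the methanotroph read fraction (the functional link the
#' geochemistry stage is meant to recover), then forward-simulates the
#' 40 ml water / 20 ml air headspace equilibration so that the table can be
#' inverted with [headspace_to_insitu()].
#'
#' @param methanotroph_fraction Methanotroph read fraction per pond, in
#'   \[0, 1\]; names are used as sample ids.
#' @param temp_c Water temperature (recycled).
#' @param seed Optional integer seed.
#' @param ch4_slope Decrease of log CH4 per unit scaled methanotroph
#'   fraction.
#' @param noise_sd Lognormal noise on concentrations.
#' @return List with `gas_table` (TSV-shaped measurement data.frame) and
#'   `truth` (the simulated in-situ concentrations in uM).
#' @export
simulate_gas_table <- function(methanotroph_fraction, temp_c = 15.5,
                               seed = NULL, ch4_slope = 40, noise_sd = 0.3) {
  stopifnot(all(methanotroph_fraction >= 0), all(methanotroph_fraction <= 1))
  maybe_set_seed(seed)
  n <- length(methanotroph_fraction)
  ids <- names(methanotroph_fraction) %||% sprintf("S%02d", seq_len(n))
  temp_c <- rep_len(temp_c, n)

  co2 <- gas_spec("CO2")
  ch4 <- gas_spec("CH4")
  co2_true <- equilibrium_concentration(co2, temp_c) *
    exp(stats::rnorm(n, 0, 1))                     # wide auto/heterotrophy range
  ch4_true <- 5 * exp(-ch4_slope * methanotroph_fraction +
                        stats::rnorm(n, 0, noise_sd))

  rows <- list()
  for (g in c("CO2", "CH4")) {
    spec <- if (g == "CO2") co2 else ch4
    ctrue <- if (g == "CO2") co2_true else ch4_true
    p_eq <- vapply(seq_len(n), function(i) {
      equilibrate_headspace(spec, ctrue[i], temp_c[i])
    }, 0)
    rows[[g]] <- data.frame(sample_id = ids, gas = g,
                            temperature_C = temp_c,
                            headspace_ppm = p_eq * 1e6,
                            ambient_ppm = spec$atm_mixing_ratio * 1e6,
                            V_water_ml = 40, V_head_ml = 20,
                            stringsAsFactors = FALSE)
  }
  list(gas_table = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       truth = data.frame(sample_id = ids, co2_uM = co2_true,
                          ch4_uM = ch4_true, stringsAsFactors = FALSE))
}
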