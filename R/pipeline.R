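# End-to-end demo pipeline: simulate -> merge/filter -> denoise -> OTU
# table -> rarefy -> null models -> phylogenetic turnover -> geochemistry,
# with a manifest recording seeds, parameters and per-stage read counts.

default_run_config <- function() {
  list(
    seed = 42L,
    genotypes = list(n = 24L, length = 250L, min_dist = 5L),
    reads = list(per_sample = 1200L, pcr_error_rate = 1e-5,
                 pcr_cycles = 30L, seq_error_rate = 1e-3,
                 chimera_rate = 0.005, fwd_len = 180L, rev_len = 180L,
                 n_templates = 8192L, pool_cap = 16384L),
    metacommunity = list(n_sites = 8L, individuals_per_site = 1000L,
                         niche_weight = 0.5, niche_breadth = 0.5),
    denoise = list(alpha = 1e-20, max_ee = 0.5, min_overlap = 30L,
                   max_parent_dist = 10L, min_count = 2L,
                   min_parent_skew = 2),
    rarefy = list(depth = 800L),
    nullmodel = list(n_reps = 200L, metric = "bray"),
    bnti = list(n_reps = 199L),
    geochem = list(n_methanotroph_otus = 3L,
                   total_cells_per_ml = 6.1e6)
  )
}

merge_config <- function(defaults, user, path = "config") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]])) {
      defaults[[k]] <- merge_config(defaults[[k]], as.list(user[[k]]),
                                    paste0(path, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Bundled demo configuration
#'
#' @return The default pipeline configuration as a named list; pass a
#'   modified copy (or a YAML file with the same keys) to
#'   [run_pipeline()].
#' @export
demo_config <- function() default_run_config()

#' Run the full synthetic-to-summary pipeline
#'
#' Simulates genotypes, a niche/neutral metacommunity and per-sample
#' paired reads; merges, filters, dereplicates and denoises them; builds
#' and rarefies the OTU table; computes Raup-Crick, NST (overall and
#' occupancy-stratified) and betaNTI; simulates and inverts a linked
#' headspace gas table; and writes all artifacts plus a manifest to
#' `out_dir`. Fully deterministic given `config$seed`: every stage seed is
#' derived from it.
#'
#' @param config Configuration list (see [demo_config()]) or path to a
#'   YAML file with the same structure; unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results and the
#'   manifest.
#' @export
run_pipeline <- function(config = demo_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_run_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)

  ## ground truth
  gt <- simulate_genotypes(config$genotypes$n, config$genotypes$length,
                           config$genotypes$min_dist, seed = seed + 1L)
  mc_cfg <- metacommunity_config(
    pool_size = config$genotypes$n,
    n_sites = config$metacommunity$n_sites,
    individuals_per_site = config$metacommunity$individuals_per_site,
    niche_weight = config$metacommunity$niche_weight,
    niche_breadth = config$metacommunity$niche_breadth)
  mc <- simulate_metacommunity(mc_cfg, seed = seed + 2L)
  names(gt) <- rownames(mc$table)
  model <- error_model(config$reads$pcr_error_rate, config$reads$pcr_cycles,
                       config$reads$seq_error_rate, config$reads$chimera_rate)

  ## per-sample reads: simulate, split into pairs, merge, filter
  all_seq <- character(0)
  all_sample <- character(0)
  truth <- list()
  n_in <- n_merged <- n_filtered <- 0L
  for (j in seq_len(ncol(mc$table))) {
    sid <- colnames(mc$table)[j]
    ab <- stats::rmultinom(1, config$reads$per_sample, mc$table[, j])[, 1]
    sel <- ab > 0
    sim <- simulate_reads(gt[sel], ab[sel], model, seed = seed + 10L + j,
                          n_templates = config$reads$n_templates,
                          pool_cap = config$reads$pool_cap)
    sim$reads$id <- paste0(sid, ":", sim$reads$id)
    sim$truth$read_id <- paste0(sid, ":", sim$truth$read_id)
    sim$truth$sample_id <- sid
    pr <- paired_reads(sim$reads, config$reads$fwd_len, config$reads$rev_len)
    mg <- merge_pairs(pr$fwd, pr$rev, min_overlap = config$denoise$min_overlap)
    fl <- filter_reads(mg$merged, max_ee = config$denoise$max_ee)
    n_in <- n_in + nrow(sim$reads)
    n_merged <- n_merged + nrow(mg$merged)
    n_filtered <- n_filtered + nrow(fl)
    all_seq <- c(all_seq, fl$seq)
    all_sample <- c(all_sample, rep(sid, nrow(fl)))
    truth[[sid]] <- sim$truth
  }
  truth <- do.call(rbind, truth)

  ## dereplicate + denoise (pooled, with per-sample count tracking)
  uniques <- dereplicate(all_seq, all_sample)
  kept <- remove_singletons(uniques, config$denoise$min_count)
  n_singleton_reads <- attr(kept, "n_reads_removed")
  params <- denoise_params(
    pcr_error_rate = config$reads$pcr_error_rate,
    pcr_cycles = config$reads$pcr_cycles,
    seq_error_rate = config$reads$seq_error_rate,
    alpha = config$denoise$alpha,
    max_parent_dist = config$denoise$max_parent_dist,
    min_count = config$denoise$min_count,
    min_parent_skew = config$denoise$min_parent_skew)
  dn <- denoise(kept, params)
  chim_reads <- sum(dn$assignments$count[dn$assignments$status == "chimera"])
  conserved <- sum(dn$genotypes$total_count) + chim_reads +
    n_singleton_reads == sum(uniques$count)

  ## OTU table on true ids where the genotype sequence matches the truth
  otu_tab <- dn$otu_table
  hit <- match(dn$genotypes$seq, gt)
  rownames(otu_tab) <- ifelse(is.na(hit), paste0("novel_", dn$genotypes$id),
                              names(gt)[hit])
  otu_tab <- otu_tab[, mc$metadata$sample_id, drop = FALSE]

  ## normalize and analyse
  rt <- rarefy(otu_tab, config$rarefy$depth, seed = seed + 3L)
  tree <- simulate_tree(nrow(rt), seed = seed + 4L,
                        tip_labels = rownames(rt))
  groups <- mc$metadata$pond_type[match(colnames(rt),
                                        mc$metadata$sample_id)]
  nm_cfg <- null_model_config(n_reps = config$nullmodel$n_reps,
                              metric = config$nullmodel$metric,
                              seed = seed + 5L)
  rc <- raup_crick(rt, nm_cfg)
  nm_cfg_nst <- null_model_config(n_reps = config$nullmodel$n_reps,
                                  metric = config$nullmodel$metric,
                                  seed = seed + 6L)
  nst_res <- nst(rt, groups, nm_cfg_nst, n_boot = 199)
  nm_cfg_occ <- null_model_config(n_reps = config$nullmodel$n_reps,
                                  metric = config$nullmodel$metric,
                                  seed = seed + 7L)
  occ_curve <- suppressWarnings(
    nst_by_occupancy(rt, groups, nm_cfg_occ))
  bnti <- beta_nti(rt, tree, n_reps = config$bnti$n_reps, seed = seed + 8L)

  ## linked geochemistry: designate mid-rank OTUs as methanotrophs so the
  ## read fractions land in the realistic few-percent range
  n_meth <- config$geochem$n_methanotroph_otus
  start <- min(ceiling(nrow(mc$table) / 3), nrow(mc$table) - n_meth + 1L)
  meth <- rownames(mc$table)[start:(start + n_meth - 1L)]
  meth <- intersect(meth, rownames(rt))
  frac <- if (length(meth) > 0) {
    colSums(rt[meth, , drop = FALSE]) / colSums(rt)
  } else {
    stats::setNames(rep(0, ncol(rt)), colnames(rt))
  }
  gas <- simulate_gas_table(frac, seed = seed + 9L)
  gas_proc <- process_gas_table(gas$gas_table)
  ch4 <- gas_proc[gas_proc$gas == "CH4", ]
  cells <- methanotroph_abundance(frac, config$geochem$total_cells_per_ml)
  usable <- frac > 0 & ch4$concentration_uM > 0
  gas_fit <- if (sum(usable) >= 4) {
    boxcox_regress(ch4$concentration_uM[usable], cells[usable])
  } else NULL

  ## Table-2-style assembly summary
  lv <- unique(groups)
  gidx <- lapply(lv, function(g) which(groups == g))
  rc_scope <- function(idx1, idx2 = idx1) {
    v <- rc[idx1, idx2]
    if (identical(idx1, idx2)) v <- v[upper.tri(v)]
    v[!is.na(v)]
  }
  bnti_scope <- function(idx1, idx2 = idx1) {
    v <- bnti$bnti[idx1, idx2]
    if (identical(idx1, idx2)) v <- v[upper.tri(v)]
    mean(v[!is.na(v)])
  }
  summarise_scope <- function(rcv, nst_val, bnti_val) {
    b <- classify_rc(rcv)
    c(NST = unname(nst_val), `RC < -0.95` = unname(b["pct_below"]),
      `-0.95 < RC < 0.95` = unname(b["pct_middle"]),
      `RC > 0.95` = unname(b["pct_above"]), bNTI = bnti_val)
  }
  summary_tab <- cbind(
    summarise_scope(rc_scope(gidx[[1]]), nst_res$nst[lv[1]],
                    bnti_scope(gidx[[1]])),
    summarise_scope(rc_scope(gidx[[2]]), nst_res$nst[lv[2]],
                    bnti_scope(gidx[[2]])),
    summarise_scope(rc_scope(gidx[[1]], gidx[[2]]), nst_res$nst["between"],
                    bnti_scope(gidx[[1]], gidx[[2]])))
  colnames(summary_tab) <- c(lv, "between")

  ## artifacts
  write_genotype_fasta(dn$genotypes, file.path(out_dir, "genotypes.fasta"))
  utils::write.table(dn$assignments, file.path(out_dir, "assignments.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_otu_table(otu_tab, file.path(out_dir, "otu_table.tsv"))
  write_otu_table(rt, file.path(out_dir, "otu_table_rarefied.tsv"))
  utils::write.table(mc$metadata, file.path(out_dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(tree, file.path(out_dir, "tree.nwk"))
  write_tsv_matrix(round(rc, 6), file.path(out_dir, "raup_crick.tsv"),
                   "sample_id")
  write_tsv_matrix(round(summary_tab, 4),
                   file.path(out_dir, "assembly_summary.tsv"), "index")
  utils::write.table(occ_curve, file.path(out_dir, "nst_occupancy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_tsv_matrix(round(bnti$bnti, 6), file.path(out_dir, "bnti.tsv"),
                   "sample_id")
  utils::write.table(gas_proc, file.path(out_dir, "gas_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_truth_table(truth, file.path(out_dir, "read_truth.tsv"))

  manifest <- list(
    package = "pondassembly",
    version = as.character(utils::packageVersion("pondassembly")),
    config = config,
    counts = list(reads_in = n_in, pairs_merged = n_merged,
                  reads_after_filter = n_filtered,
                  unique_sequences = nrow(uniques),
                  singleton_reads_removed = n_singleton_reads,
                  uniques_denoised = nrow(kept),
                  genotypes = nrow(dn$genotypes),
                  chimera_uniques = sum(dn$assignments$status == "chimera"),
                  chimera_reads = chim_reads),
    read_count_conservation = conserved,
    nst = as.list(round(nst_res$nst, 4)),
    nst_boot_p = nst_res$boot_p,
    rc_bins = as.list(round(classify_rc(rc), 4)),
    gas_regression = if (is.null(gas_fit)) NULL else
      list(slope = gas_fit$slope, r_squared = gas_fit$r_squared,
           p_value = gas_fit$p_value, lambda_y = gas_fit$lambda_y,
           lambda_x = gas_fit$lambda_x))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))

  invisible(list(genotypes = dn$genotypes, otu_table = otu_tab,
                 rarefied = rt, rc = rc, nst = nst_res,
                 occupancy_curve = occ_curve, bnti = bnti,
                 gas = gas_proc, gas_fit = gas_fit, truth = truth,
                 summary = summary_tab, manifest = manifest))
}
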