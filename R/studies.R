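# Simulation studies: scripted recovery and calibration experiments run
# under the package's reference study conditions. Each returns the raw
# per-simulation outcomes alongside the headline rate so callers can apply
# their own acceptance bands.

#' Type-I error of the permutation-significant threshold
#'
#' Simulates null (unlinked, iid normal) traits on a fixed RI panel, derives
#' per-trait permutation thresholds, and reports how often the genome-wide
#' maximum LRS exceeds the significant (95th percentile) threshold — which
#' should happen for ~5% of null traits by construction.
#'
#' @param n_sim number of null traits.
#' @param n_strains panel size.
#' @param n_perm permutations per trait.
#' @param seed master seed.
#' @return list with `rate`, `n_exceed`, `n_sim`, and the per-sim logical
#'   vector `exceed`.
#' @export
study_type1_error <- function(n_sim = 500, n_strains = 40, n_perm = 1000,
                              seed = 1L) {
  spec <- architecture_spec(n_strains = n_strains, seed = seed)
  geno <- simulate_ri_genotypes(spec, seed = seed)
  set.seed(seed + 1L)
  sim_seeds <- sample.int(1e8, n_sim)
  exceed <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    set.seed(sim_seeds[i])
    y <- stats::rnorm(n_strains)
    names(y) <- geno$strains
    thr <- permutation_thresholds(y, geno, n_perm = n_perm,
                                  seed = sim_seeds[i] + 1L)
    exceed[i] <- max(eqtl_scan(y, geno)$lrs) > thr$significant
  }
  list(rate = mean(exceed), n_exceed = sum(exceed), n_sim = n_sim,
       exceed = exceed)
}

#' Recovery of a planted cis eQTL
#'
#' Plants a cis effect strong enough to explain well over 40% of the
#' strain-mean variance (additive effect 0.3 log2 units against the default
#' variance components), maps the PC1-reconstructed probe-set profile, and
#' counts the simulations whose peak is classified cis — i.e. lies within
#' the 10 Mb window around the cognate gene.
#'
#' @param n_sim simulations.
#' @param n_strains panel size.
#' @param cis_effect planted additive effect (log2 units).
#' @param n_perm permutations for thresholds.
#' @param seed master seed.
#' @return list with `rate`, `n_cis`, `n_sim`, per-sim `cis` flags.
#' @export
study_cis_recovery <- function(n_sim = 100, n_strains = 60,
                               cis_effect = 0.3, n_perm = 1000, seed = 1L) {
  set.seed(seed)
  sim_seeds <- sample.int(1e8, n_sim)
  genes <- data.frame(symbol = "geneA", chr = "3", start_mb = 24.2,
                      end_mb = 24.26, cis_effect = cis_effect,
                      h2_target = NA, module_loading = 0)
  cis <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    spec <- architecture_spec(n_strains = n_strains, genes = genes,
                              regions = "coding_exon",
                              seed = sim_seeds[i])
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    prof <- summarize_panel(pan$expr, pan$annot)$profiles[1, ]
    thr <- permutation_thresholds(prof, geno, n_perm = n_perm,
                                  seed = sim_seeds[i] + 1L)
    pk <- peak_and_classify(eqtl_scan(prof, geno), gene = spec$genes[1, ],
                            thresholds = thr)
    cis[i] <- !is.null(pk) && identical(pk$classification, "cis")
  }
  list(rate = mean(cis), n_cis = sum(cis), n_sim = n_sim, cis = cis)
}

#' Effect of variant-probe filtering on spurious cis signals
#'
#' Plants a probe set with no true genetic effect but three
#' variant-overlapping probes (artifact depth `delta`), then contrasts the
#' unfiltered mean summary — which inherits a spurious cis eQTL from the
#' hybridization artifact — with the filtered PC1 reconstruction.
#'
#' @param n_sim simulations.
#' @param delta artifact depth, log2 units.
#' @param n_perm permutations for thresholds.
#' @param seed master seed.
#' @return list with `unfiltered_sig_rate` (fraction of sims whose
#'   unfiltered cis LRS exceeds the significant threshold),
#'   `filtered_median_lrs`, `median_suggestive`, and the per-sim vectors.
#' @export
study_artifact_removal <- function(n_sim = 100, delta = 1.0, n_perm = 1000,
                                   seed = 1L) {
  set.seed(seed)
  sim_seeds <- sample.int(1e8, n_sim)
  genes <- data.frame(symbol = "geneA", chr = "3", start_mb = 24.2,
                      end_mb = 24.26, cis_effect = 0, h2_target = NA,
                      module_loading = 0)
  unfilt_lrs <- filt_lrs <- sig_thr <- sug_thr <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    spec <- architecture_spec(genes = genes, regions = "coding_exon",
                              variant_genes = "geneA", delta = delta,
                              seed = sim_seeds[i])
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    gene <- spec$genes[1, ]

    # unfiltered mean summary over all probes, artifact probes included
    sm_all <- strain_means(pan$expr)
    prof_unfilt <- colMeans(sm_all)
    unfilt_lrs[i] <- cis_lrs(prof_unfilt, geno, gene)
    thr_u <- permutation_thresholds(prof_unfilt, geno, n_perm = n_perm,
                                    seed = sim_seeds[i] + 1L)
    sig_thr[i] <- thr_u$significant

    # filtered PC1 reconstruction
    filt <- filter_snp_probes(pan$expr, pan$annot)
    prof_filt <- summarize_panel(filt$expr, pan$annot)$profiles[1, ]
    filt_lrs[i] <- cis_lrs(prof_filt, geno, gene)
    thr_f <- permutation_thresholds(prof_filt, geno, n_perm = n_perm,
                                    seed = sim_seeds[i] + 2L)
    sug_thr[i] <- thr_f$suggestive
  }
  list(unfiltered_sig_rate = mean(unfilt_lrs > sig_thr),
       filtered_median_lrs = stats::median(filt_lrs),
       median_suggestive = stats::median(sug_thr),
       unfiltered_lrs = unfilt_lrs, filtered_lrs = filt_lrs,
       significant = sig_thr, suggestive = sug_thr, n_sim = n_sim)
}

#' Recovery of a planted broad-sense heritability
#'
#' Plants `h2_target` on an effect-free single-probe gene (the polygenic SD
#' is solved from the estimator's population value) and averages the
#' broad-sense estimate over independent panels.
#'
#' @param n_seeds independent panels.
#' @param h2_target planted heritability (must exceed `1/n_replicates`).
#' @param n_strains,n_replicates panel dimensions.
#' @param seed master seed.
#' @return list with `mean_h2`, `h2` per panel, and the target.
#' @export
study_h2_recovery <- function(n_seeds = 50, h2_target = 0.6,
                              n_strains = 60, n_replicates = 3, seed = 1L) {
  set.seed(seed)
  sim_seeds <- sample.int(1e8, n_seeds)
  genes <- data.frame(symbol = "geneA", chr = "3", start_mb = 24.2,
                      end_mb = 24.26, cis_effect = 0,
                      h2_target = h2_target, module_loading = 0)
  h2 <- vapply(sim_seeds, function(s) {
    spec <- architecture_spec(n_strains = n_strains,
                              n_replicates = n_replicates, genes = genes,
                              regions = "coding_exon", probes_per_set = 1,
                              seed = s)
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    broad_sense_h2(pan$expr$values[1, ], pan$expr$strains)$h2
  }, numeric(1L))
  list(mean_h2 = mean(h2), h2 = h2, target = h2_target)
}

#' Ranking a true trans regulator against pure-linkage decoys
#'
#' The true regulator transmits its expression noise to the target, so its
#' correlation survives controlling for the peak-marker genotype; decoys
#' are cis-regulated at linked markers and correlate with the target only
#' through the locus. Reports how often the regulator takes rank 1 by
#' |partial r|.
#'
#' @param n_sim simulations.
#' @param n_strains panel size.
#' @param seed master seed.
#' @return list with `rate`, `wins`, `n_sim`, and the mean retained
#'   fraction of regulator and decoys.
#' @export
study_regulator_ranking <- function(n_sim = 100, n_strains = 60, seed = 1L) {
  spec <- architecture_spec(n_strains = n_strains, seed = seed)
  geno <- simulate_ri_genotypes(spec, seed = seed)
  G <- geno_codes(geno)
  peak_mk <- "M4_10"
  decoy_mks <- c("M4_08", "M4_09", "M4_11", "M4_12", "M4_13")
  set.seed(seed + 1L)
  wins <- logical(n_sim)
  rf_reg <- rf_dec <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    x <- 0.8 * G[, peak_mk] + stats::rnorm(n_strains, 0, 0.3)
    y <- 0.6 * x + stats::rnorm(n_strains, 0, 0.3)
    decoys <- vapply(decoy_mks, function(mk)
      0.8 * G[, mk] + stats::rnorm(n_strains, 0, 0.3), numeric(n_strains))
    tab <- data.frame(
      symbol = c("regulator", decoy_mks),
      r = c(stats::cor(x, y), apply(decoys, 2, stats::cor, y)),
      partial_r = c(partial_correlation(x, y, G[, peak_mk]),
                    apply(decoys, 2, partial_correlation, y,
                          G[, peak_mk])))
    rk <- rank_candidates(tab)
    wins[i] <- rk$symbol[1L] == "regulator"
    rf_reg[i] <- rk$retained_fraction[rk$symbol == "regulator"]
    rf_dec[i] <- mean(rk$retained_fraction[rk$symbol != "regulator"])
  }
  list(rate = mean(wins), wins = sum(wins), n_sim = n_sim,
       retained_fraction_regulator = mean(rf_reg),
       retained_fraction_decoys = mean(rf_dec))
}

#' Mapping a module eigengene back to its planted trans locus
#'
#' Simulates a module of genes loading on one latent factor driven by a
#' trans marker, extracts the eigengene from the PC1-summarized member
#' profiles, scans it, and counts the simulations whose genome-wide peak
#' falls exactly on the planted marker.
#'
#' @param n_sim simulations.
#' @param n_genes module size.
#' @param n_strains panel size.
#' @param seed master seed.
#' @return list with `rate`, `hits`, `n_sim`, and the mean eigengene
#'   variance fraction.
#' @export
study_module_mapping <- function(n_sim = 100, n_genes = 10,
                                 n_strains = 60, seed = 1L) {
  set.seed(seed)
  sim_seeds <- sample.int(1e8, n_sim)
  map <- default_marker_map()
  marker <- "M5_10"
  chrs <- setdiff(unique(map$chr), "5")
  genes <- data.frame(
    symbol = sprintf("mod%02d", seq_len(n_genes)),
    chr = chrs[((seq_len(n_genes) - 1L) %% length(chrs)) + 1L],
    start_mb = 22.2, end_mb = 22.26, cis_effect = 0, h2_target = NA,
    module_loading = 0.8)
  hits <- logical(n_sim)
  vf <- numeric(n_sim)
  for (i in seq_len(n_sim)) {
    spec <- architecture_spec(n_strains = n_strains, map = map,
                              genes = genes, regions = "coding_exon",
                              module = list(marker = marker, effect = 0.7,
                                            sd = 0.3),
                              seed = sim_seeds[i])
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    prof <- summarize_panel(pan$expr, pan$annot)$profiles
    me <- module_eigengene(prof)
    vf[i] <- me$variance_fraction
    curve <- eqtl_scan(me$scores, geno)
    hits[i] <- curve$marker[which.max(curve$lrs)] == marker
  }
  list(rate = mean(hits), hits = sum(hits), n_sim = n_sim,
       mean_variance_fraction = mean(vf))
}
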