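# Shared fixtures built in code: tiny genotype panels and one-gene
# architecture specs used across the module tests.

toy_geno <- function() {
  mk <- data.frame(marker = c("m1", "m2", "m3", "m4"),
                   chr = c("1", "1", "2", "2"),
                   pos_mb = c(10, 30, 5, 25))
  calls <- matrix(c("B", "D", "B", "D",
                    "D", "B", "B", "D",
                    "B", "B", "D", "D",
                    "D", "D", "B", "B",
                    "B", "D", "D", "B",
                    "D", "B", "D", "B"),
                  nrow = 6, byrow = TRUE)
  ri_geno(paste0("S", 1:6), mk, calls)
}

# single-marker panel for closed-form scan checks
one_marker_geno <- function(g_codes, strains = paste0("S", seq_along(g_codes))) {
  calls <- matrix(ifelse(g_codes > 0, "D", "B"), ncol = 1)
  ri_geno(strains, data.frame(marker = "m1", chr = "1", pos_mb = 0), calls)
}

# one gene on chr 3 near marker M3_06 (25 Mb); no effects unless given
single_gene_spec <- function(n_strains = 60, n_replicates = 3,
                             cis_effect = 0, h2_target = NA,
                             variant = FALSE, probes_per_set = 11,
                             n_variant_probes = 3,
                             regions = "coding_exon",
                             sigma_g = 0.2, sigma_e = 0.3, delta = 1,
                             seed = 1L) {
  genes <- data.frame(symbol = "geneA", chr = "3",
                      start_mb = 24.2, end_mb = 24.26,
                      cis_effect = cis_effect, h2_target = h2_target,
                      module_loading = 0)
  architecture_spec(n_strains = n_strains, n_replicates = n_replicates,
                    genes = genes, regions = regions,
                    probes_per_set = probes_per_set,
                    n_variant_probes = if (variant) n_variant_probes else 0,
                    variant_genes = if (variant) "geneA" else character(),
                    sigma_g = sigma_g, sigma_e = sigma_e, delta = delta,
                    seed = seed)
}

# brute-force Gaussian maximum-likelihood LRS oracle: explicit ML fits of
# the one-marker and null models, log-likelihoods summed with dnorm
lrs_likelihood_oracle <- function(y, g) {
  n <- length(y)
  fit1 <- stats::lm(y ~ g)
  s2_1 <- sum(stats::resid(fit1)^2) / n
  ll1 <- sum(stats::dnorm(y, stats::fitted(fit1), sqrt(s2_1), log = TRUE))
  s2_0 <- sum((y - mean(y))^2) / n
  ll0 <- sum(stats::dnorm(y, mean(y), sqrt(s2_0), log = TRUE))
  2 * (ll1 - ll0)
}
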