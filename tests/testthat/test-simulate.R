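test_that("RI recombination follows the Haldane map expansion", {
  # closed forms: R(0) = 0; unlinked r = 0.5 gives R = 4(0.5)/(1+3) = 0.5
  expect_equal(ri_expansion(haldane_r(0)), 0)
  expect_equal(ri_expansion(0.5), 0.5)

  # zero cM gap: no recombinants between adjacent markers
  map0 <- data.frame(marker = c("a", "b"), chr = "1",
                     pos_mb = c(0, 0), cm = c(0, 0))
  spec0 <- architecture_spec(n_strains = 200, map = map0,
                             genes = data.frame(symbol = "g", chr = "1",
                                                start_mb = 0, end_mb = 0.01),
                             seed = 11L)
  g0 <- simulate_ri_genotypes(spec0)
  expect_identical(g0$calls[, 1], g0$calls[, 2])

  # huge gap (effectively unlinked): recombinant fraction ~ 0.5 at n = 500
  mapU <- data.frame(marker = c("a", "b"), chr = "1",
                     pos_mb = c(0, 500), cm = c(0, 1e6))
  specU <- architecture_spec(n_strains = 500, map = mapU,
                             genes = data.frame(symbol = "g", chr = "1",
                                                start_mb = 0, end_mb = 0.01),
                             seed = 12L)
  gU <- simulate_ri_genotypes(specU)
  rec <- mean(gU$calls[, 1] != gU$calls[, 2])
  expect_gt(rec, 0.5 - 3 * sqrt(0.25 / 500))  # 3-sigma binomial band
  expect_lt(rec, 0.5 + 3 * sqrt(0.25 / 500))

  # per-marker D-allele frequency ~ 0.5 by symmetry
  spec <- single_gene_spec(n_strains = 500, seed = 13L)
  g <- simulate_ri_genotypes(spec)
  freq <- colMeans(g$calls == "D")
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.25 / 500)))
  expect_false(any(g$calls %in% c("H", "U")))
})

test_that("intermediate linkage matches R = 4r/(1+6r) within binomial CI", {
  d_cm <- 20
  r <- haldane_r(d_cm)
  R <- ri_expansion(r)
  map <- data.frame(marker = c("a", "b"), chr = "1",
                    pos_mb = c(0, 40), cm = c(0, d_cm))
  spec <- architecture_spec(n_strains = 1000, map = map,
                            genes = data.frame(symbol = "g", chr = "1",
                                               start_mb = 0, end_mb = 0.01),
                            seed = 21L)
  g <- simulate_ri_genotypes(spec)
  obs <- mean(g$calls[, 1] != g$calls[, 2])
  expect_lt(abs(obs - R), 3.3 * sqrt(R * (1 - R) / 1000))
})

test_that("null expression panel is iid noise around probe baselines", {
  spec <- single_gene_spec(n_strains = 40, n_replicates = 1,
                           sigma_g = 0, sigma_e = 0.3, seed = 31L,
                           probes_per_set = 6)
  geno <- simulate_ri_genotypes(spec)
  pan <- simulate_expression_panel(geno, spec)
  v <- pan$expr$values
  centered <- v - rowMeans(v)
  expect_lt(abs(stats::sd(as.numeric(centered)) - 0.3), 0.05)
  # probes share no strain-level signal: inter-probe correlations are weak
  cc <- stats::cor(t(v))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.6)
})

test_that("a planted cis effect separates genotype class means by 2a", {
  spec <- single_gene_spec(n_strains = 80, n_replicates = 1,
                           cis_effect = 1.0, sigma_g = 0, sigma_e = 1e-4,
                           probes_per_set = 4, seed = 41L)
  geno <- simulate_ri_genotypes(spec)
  pan <- simulate_expression_panel(geno, spec)
  sm <- strain_means(pan$expr)
  cis_mk <- pan$truth$genes[[1]]$cis_marker
  d <- geno$calls[, cis_mk] == "D"
  gap <- mean(sm[1, d]) - mean(sm[1, !d])
  expect_equal(gap, 2.0, tolerance = 1e-2)
})

test_that("variant-overlapping probes lose delta in D-carrying strains", {
  spec <- single_gene_spec(n_strains = 60, n_replicates = 1,
                           variant = TRUE, n_variant_probes = 2,
                           probes_per_set = 4, sigma_g = 0, sigma_e = 1e-4,
                           delta = 1.0, seed = 51L)
  geno <- simulate_ri_genotypes(spec)
  pan <- simulate_expression_panel(geno, spec)
  stopifnot(length(pan$truth$artifact_probes) == 2L)
  sm <- strain_means(pan$expr)
  d <- geno$calls[, pan$truth$genes[[1]]$cis_marker] == "D"
  art <- pan$truth$artifact_probes[1]
  clean <- setdiff(rownames(sm), pan$truth$artifact_probes)[1]
  expect_equal(mean(sm[art, !d]) - mean(sm[art, d]), 1.0, tolerance = 1e-2)
  expect_equal(mean(sm[clean, !d]) - mean(sm[clean, d]), 0, tolerance = 1e-2)
})

test_that("same seed gives identical outputs and truth survives JSON", {
  spec <- single_gene_spec(n_strains = 20, variant = TRUE, seed = 61L)
  g1 <- simulate_ri_genotypes(spec)
  g2 <- simulate_ri_genotypes(spec)
  expect_identical(g1, g2)
  p1 <- simulate_expression_panel(g1, spec)
  p2 <- simulate_expression_panel(g2, spec)
  expect_identical(p1$expr$values, p2$expr$values)

  path <- withr::local_tempfile(fileext = ".json")
  write_truth(p1$truth, path)
  tr <- read_truth(path)
  expect_equal(tr$genes[[1]]$cis_marker, p1$truth$genes[[1]]$cis_marker)
  expect_equal(tr$genes[[1]]$h2, p1$truth$genes[[1]]$h2)
  expect_equal(unlist(tr$artifact_probes), p1$truth$artifact_probes)
})

test_that("spec validation rejects impossible architectures", {
  expect_error(single_gene_spec(n_strains = 1), "n_strains")
  expect_error(architecture_spec(trans_loci = list(list(
    marker = "M1_01",
    targets = data.frame(symbol = "nope", region = NA, effect = 1)))),
    "not in gene list")
  # h2 target below the replicate-mean floor 1/r is unattainable
  spec <- single_gene_spec(h2_target = 0.2, n_replicates = 3)
  g <- simulate_ri_genotypes(spec)
  expect_error(simulate_expression_panel(g, spec), "h2_target")
})
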