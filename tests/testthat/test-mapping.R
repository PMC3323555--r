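test_that("broad-sense heritability hits its closed-form corners", {
  # identical replicates, differing strain means: all variance is genetic
  h <- broad_sense_h2(c(1, 1, 3, 3, 5, 5), c("a", "a", "b", "b", "c", "c"))
  expect_equal(h$h2, 1.0)
  # equal strain means, noisy replicates: no genetic variance
  h0 <- broad_sense_h2(c(1, 3, 1, 3, 1, 3), c("a", "a", "b", "b", "c", "c"))
  expect_equal(h0$h2, 0.0)
  expect_error(broad_sense_h2(rep(2, 4), c("a", "a", "b", "b")), "variance")
  expect_error(broad_sense_h2(1:4, rep("a", 4)), ">= 2 strains")
})

test_that("scan LRS equals -n ln(1 - r^2) and the likelihood oracle", {
  set.seed(10)
  for (rep in 1:30) {
    n <- sample(6:12, 1)
    repeat {
      g <- sample(c(-1, 1), n, replace = TRUE)
      if (length(unique(g)) == 2L) break
    }
    y <- 0.5 * g + rnorm(n)
    names(y) <- paste0("S", 1:n)
    geno <- one_marker_geno(g, names(y))
    lrs <- eqtl_scan(y, geno)$lrs
    r <- cor(y, g)
    expect_equal(lrs, -n * log(1 - r^2), tolerance = 1e-9)
    expect_equal(lrs, lrs_likelihood_oracle(y, g), tolerance = 1e-6)
  }
})

test_that("scan handles constant traits, class means and missing data", {
  g <- toy_geno()
  y <- rep(4, 6); names(y) <- g$strains
  expect_true(all(eqtl_scan(y, g)$lrs == 0))

  y2 <- c(1, 2, 3, 4, 5, 6); names(y2) <- g$strains
  curve <- eqtl_scan(y2, g)
  d <- g$calls[, "m1"] == "D"
  expect_equal(curve$additive[1], (mean(y2[d]) - mean(y2[!d])) / 2)
  expect_equal(curve$lod, curve$lrs / 4.61)

  names(y2)[1] <- "nope"
  expect_error(eqtl_scan(y2, g), "absent")

  # a marker with one genotype class is uninformative
  g1 <- one_marker_geno(rep(1, 5))
  y3 <- rnorm(5); names(y3) <- g1$strains
  sc <- eqtl_scan(y3, g1)
  expect_equal(sc$lrs, 0)
  expect_true(is.na(sc$additive))
})

test_that("LOD conversion divides by 4.61 and rejects negatives", {
  expect_identical(lod_from_lrs(4.61), 1.0)
  expect_identical(lod_from_lrs(0), 0)
  expect_equal(lod_from_lrs(69.15), 15.0)
  expect_error(lod_from_lrs(-1), ">= 0")
})

test_that("permutation thresholds are deterministic and ordered", {
  spec <- single_gene_spec(n_strains = 30, seed = 81L)
  geno <- simulate_ri_genotypes(spec)
  set.seed(99)
  y <- rnorm(30); names(y) <- geno$strains
  t1 <- permutation_thresholds(y, geno, n_perm = 200, seed = 7)
  t2 <- permutation_thresholds(y, geno, n_perm = 200, seed = 7)
  expect_identical(t1$significant, t2$significant)
  expect_identical(t1$max_lrs, t2$max_lrs)
  expect_lte(t1$suggestive, t1$significant)
  expect_error(permutation_thresholds(y, geno, n_perm = 50, seed = 7),
               "n_perm")
  expect_error(permutation_thresholds(y, geno, n_perm = 200), "seed")
})

test_that("the slow pairwise-complete path agrees with the fast path", {
  spec <- single_gene_spec(n_strains = 25, seed = 82L)
  geno <- simulate_ri_genotypes(spec)
  set.seed(100)
  y <- rnorm(25); names(y) <- geno$strains
  t_fast <- permutation_thresholds(y, geno, n_perm = 120, seed = 3)
  yna <- y; yna[1] <- NA  # forces the scan-per-permutation path
  t_slow <- permutation_thresholds(yna, geno, n_perm = 120, seed = 3)
  expect_lt(abs(t_fast$significant - t_slow$significant), 3)
})

test_that("peaks classify cis within 10 Mb of the gene span, else trans", {
  curve <- data.frame(marker = c("mA", "mB"), chr = c("11", "11"),
                      pos_mb = c(42.18, 90), lrs = c(30, 5),
                      lod = c(30, 5) / 4.61, additive = c(-0.4, 0.1),
                      n_informative = c(60L, 60L))
  class(curve) <- c("linkage_curve", "data.frame")
  thr <- list(significant = 15, suggestive = 9)
  gene <- data.frame(symbol = "Gabra1", chr = "11",
                     start_mb = 41.0, end_mb = 42.0)
  pk <- peak_and_classify(curve, gene, thr)
  expect_equal(pk$classification, "cis")
  expect_equal(pk$distance_mb, 0.18, tolerance = 1e-12)
  expect_equal(pk$allele_direction, "B_high")
  expect_true(pk$significant)

  # distance 10.1 Mb on the same chromosome: trans by the 10 Mb rule
  gene2 <- data.frame(symbol = "g2", chr = "11",
                      start_mb = 30.0, end_mb = 32.18)
  expect_equal(peak_and_classify(curve, gene2, thr)$classification, "cis")
  gene2b <- data.frame(symbol = "g2b", chr = "11",
                       start_mb = 30.0, end_mb = 32.07)
  expect_equal(peak_and_classify(curve, gene2b, thr)$classification,
               "trans")

  # different chromosome: always trans
  gene3 <- data.frame(symbol = "g3", chr = "5",
                      start_mb = 42.0, end_mb = 42.2)
  expect_equal(peak_and_classify(curve, gene3, thr)$classification, "trans")

  # sub-threshold curves yield no peak; classification without a gene errors
  thr_hi <- list(significant = 50, suggestive = 40)
  expect_null(peak_and_classify(curve, gene, thr_hi))
  expect_error(peak_and_classify(curve, NULL, thr, classify = TRUE),
               "gene annotation")

  # ties resolve to the lowest genomic coordinate
  curve$lrs <- c(30, 30)
  expect_equal(peak_and_classify(curve, gene, thr)$marker, "mA")
})

test_that("planted heritability is recovered from replicate panels", {
  ests <- vapply(1:10, function(s) {
    spec <- single_gene_spec(n_strains = 60, n_replicates = 3,
                             h2_target = 0.6, probes_per_set = 1,
                             seed = 200L + s)
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    broad_sense_h2(pan$expr$values[1, ], pan$expr$strains)$h2
  }, numeric(1))
  expect_lt(abs(mean(ests) - 0.6), 0.1)
})

test_that("allele direction matches the sign of the planted effect", {
  hits <- vapply(1:20, function(s) {
    eff <- if (s %% 2) 0.8 else -0.8
    spec <- single_gene_spec(n_strains = 50, cis_effect = eff,
                             probes_per_set = 4, seed = 300L + s)
    geno <- simulate_ri_genotypes(spec)
    pan <- simulate_expression_panel(geno, spec)
    prof <- summarize_panel(pan$expr, pan$annot)$profiles[1, ]
    pk <- peak_and_classify(eqtl_scan(prof, geno),
                            gene = spec$genes[1, ],
                            thresholds = list(significant = 15,
                                              suggestive = 9))
    identical(pk$allele_direction, if (eff > 0) "D_high" else "B_high")
  }, logical(1))
  expect_true(all(hits))
})
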