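test_that("correlation matrices match the brute-force covariance oracle", {
  x <- c(1, 3, 2, 5, 4, 7, 6, 9, 8, 10)
  m <- rbind(x, 2 * x + 1)
  colnames(m) <- paste0("S", 1:10)
  expect_equal(correlation_matrix(m)[1, 2], 1.0)

  # monotone nonlinear: Spearman 1, Pearson < 1
  m2 <- rbind(x, exp(x))
  expect_equal(correlation_matrix(m2, "spearman")[1, 2], 1.0)
  expect_lt(correlation_matrix(m2, "pearson")[1, 2], 1)

  set.seed(20)
  m3 <- matrix(rnorm(50), nrow = 5)
  r <- correlation_matrix(m3)
  # oracle: covariance formula computed by hand
  for (i in 1:4) for (j in (i + 1):5) {
    a <- m3[i, ]; b <- m3[j, ]
    oracle <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    expect_equal(r[i, j], oracle, tolerance = 1e-12)
  }
  expect_identical(r, t(r))

  # zero-variance profile: its pairs are reported missing
  m4 <- rbind(x, rep(1, 10))
  r4 <- correlation_matrix(m4)
  expect_true(is.na(r4[1, 2]))
  expect_error(correlation_matrix(m3[, 1:2]), ">= 3 strains")
})

test_that("probe-set collapsing merges by the field's AVG/PC1 rules", {
  set.seed(21)
  base <- rnorm(20)
  two <- rbind(ps_a = base + rnorm(20, 0, 0.2),
               ps_b = base + rnorm(20, 0, 0.2))
  colnames(two) <- paste0("S", 1:20)
  stopifnot(cor(two[1, ], two[2, ]) > 0.8)
  cl <- collapse_probesets(two)
  expect_equal(nrow(cl$profiles), 1L)
  expect_equal(cl$method, "average")
  z <- t(scale(t(two)))
  expect_equal(unname(cl$profiles[1, ]), unname(colMeans(z)))

  three <- rbind(two, ps_c = base + rnorm(20, 0, 0.2))
  cl3 <- collapse_probesets(three)
  expect_equal(cl3$method, "pc1")
  expect_gt(cor(cl3$profiles[1, ], base), 0.9)

  # discordant probe sets stay separate
  sep <- rbind(ps_a = base, ps_b = rnorm(20))
  colnames(sep) <- paste0("S", 1:20)
  cls <- collapse_probesets(sep)
  expect_equal(nrow(cls$profiles), 2L)
  expect_true(all(cls$method == "single"))
})

test_that("single-linkage closure joins chains and flags mixed groups", {
  set.seed(22)
  a <- rnorm(30)
  b <- 0.75 * a + sqrt(1 - 0.75^2) * rnorm(30)  # a~b moderate
  m <- rbind(ps1 = a, ps2 = a + rnorm(30, 0, 0.1), ps3 = b,
             ps4 = b + rnorm(30, 0, 0.1))
  colnames(m) <- paste0("S", 1:30)
  r <- cor(t(m))
  cl <- collapse_probesets(m)
  if (r["ps2", "ps3"] <= 0.8 && r["ps1", "ps3"] <= 0.8 &&
      r["ps1", "ps4"] <= 0.8 && r["ps2", "ps4"] <= 0.8) {
    expect_equal(nrow(cl$profiles), 2L)   # two tight pairs
    expect_false(any(cl$mixed))
  }
  # collapsing never merges pairs all below the threshold
  for (g in cl$groups) if (length(g) > 1) {
    sub <- r[g, g]
    expect_true(any(sub[upper.tri(sub)] > 0.8))
  }
})

test_that("network edges bin by |r| with half-open boundaries", {
  r <- diag(4)
  rownames(r) <- colnames(r) <- c("a", "b", "c", "d")
  r["a", "b"] <- r["b", "a"] <- 0.65   # normal
  r["a", "c"] <- r["c", "a"] <- -0.8   # bold, negative
  r["b", "c"] <- r["c", "b"] <- 0.2    # below floor
  r["a", "d"] <- r["d", "a"] <- 0.5    # boundary: normal
  r["b", "d"] <- r["d", "b"] <- 0.7    # boundary: bold
  r["c", "d"] <- r["d", "c"] <- 0.3    # boundary: dashed
  net <- build_network(r)
  e <- net$edges
  key <- function(a, b) which(e$node_a == a & e$node_b == b)
  expect_equal(e$bin[key("a", "b")], "normal")
  expect_equal(e$bin[key("a", "c")], "bold")
  expect_equal(e$sign[key("a", "c")], "negative")
  expect_length(key("b", "c"), 0L)
  expect_equal(e$bin[key("a", "d")], "normal")
  expect_equal(e$bin[key("b", "d")], "bold")
  expect_equal(e$bin[key("c", "d")], "dashed")
  expect_equal(nrow(e), 5L)
})

test_that("module eigengenes carry the planted variance structure", {
  base <- c(2, -1, 4, 0, 3, -2, 5, 1)
  m <- rbind(g1 = base, g2 = 3 * base + 2, g3 = -base)
  colnames(m) <- paste0("S", 1:8)
  me <- module_eigengene(m)
  expect_equal(me$variance_fraction, 1.0, tolerance = 1e-12)

  x1 <- c(1, -1, 1, -1, 1, -1, 1, -1)
  x2 <- c(1, 1, -1, -1, 1, 1, -1, -1)
  m2 <- rbind(x1, x1, x2, x2)
  colnames(m2) <- paste0("S", 1:8)
  expect_equal(module_eigengene(m2)$variance_fraction, 0.5,
               tolerance = 1e-12)

  expect_error(module_eigengene(m[1, , drop = FALSE]), ">= 2")
  expect_error(module_eigengene(matrix(1, 2, 8)), "degenerate")
})

test_that("region-specific trans loci reproduce the proximal-with-proximal
           coexpression pattern", {
  map <- default_marker_map()
  genes <- data.frame(symbol = c("geneA", "geneB"), chr = c("1", "2"),
                      start_mb = c(26.2, 51.2), end_mb = c(26.3, 51.3),
                      cis_effect = 0, h2_target = NA, module_loading = 0)
  trans <- list(
    list(marker = "M5_05",
         targets = data.frame(symbol = c("geneA", "geneB"),
                              region = "proximal_3utr",
                              effect = c(0.7, 0.7))),
    list(marker = "M6_15",
         targets = data.frame(symbol = c("geneA", "geneB"),
                              region = "distal_3utr",
                              effect = c(0.7, -0.7))))
  spec <- architecture_spec(n_strains = 60, map = map, genes = genes,
                            trans_loci = trans,
                            regions = c("proximal_3utr", "distal_3utr"),
                            sigma_g = 0.1, seed = 90L)
  geno <- simulate_ri_genotypes(spec)
  pan <- simulate_expression_panel(geno, spec)
  prof <- summarize_panel(pan$expr, pan$annot)$profiles
  r <- correlation_matrix(prof)
  # proximal regions of different genes cohere more than a gene's own
  # proximal and distal regions do
  expect_gt(r["geneA_proximal_3utr", "geneB_proximal_3utr"],
            r["geneA_proximal_3utr", "geneA_distal_3utr"])
  expect_gt(abs(r["geneA_distal_3utr", "geneB_distal_3utr"]),
            abs(r["geneB_proximal_3utr", "geneB_distal_3utr"]))
})
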