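test_that("interval genes intersect the peak window", {
  peak <- list(chr = "10", pos_mb = 86)
  genes <- data.frame(
    symbol = c("Nt5dc3", "edge", "far", "other_chr"),
    chr = c("10", "10", "10", "3"),
    start_mb = c(86.24, 80.5, 95, 86), end_mb = c(86.30, 81.2, 96, 86.1))
  hit <- interval_genes(peak, genes, half_width_mb = 5)
  expect_setequal(hit$symbol, c("Nt5dc3", "edge"))
  # boundary-spanning gene is included by the intersection rule
  genes2 <- rbind(genes, data.frame(symbol = "spans", chr = "10",
                                    start_mb = 90.9, end_mb = 91.5))
  expect_true("spans" %in% interval_genes(peak, genes2, 5)$symbol)
  expect_error(interval_genes(peak, genes, half_width_mb = 0), "> 0")
})

test_that("the five-criteria filter retains and logs exhaustively", {
  tab <- data.frame(
    symbol = c("good", "weak_cis", "weak_r", "mono", "silent", "noexpr"),
    cis_lrs = c(40, 14.9, 40, 40, 40, NA),
    r = c(0.5, 0.5, 0.25, 0.5, 0.5, NA),
    polymorphic = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE),
    expression_ok = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  fl <- filter_candidates(tab)
  expect_identical(fl$retained$symbol, "good")
  expect_setequal(c(fl$retained$symbol, fl$excluded$symbol), tab$symbol)
  reason <- function(s) fl$excluded$reason[fl$excluded$symbol == s]
  expect_equal(reason("weak_cis"), "cis-regulation")
  expect_equal(reason("weak_r"), "covariation")
  expect_equal(reason("mono"), "polymorphism")
  expect_equal(reason("silent"), "expression")
  expect_match(reason("noexpr"), "missing_expression")
  # boundary values are exclusive: LRS 15 and |r| 0.3 do not pass
  tb <- data.frame(symbol = "b", cis_lrs = 15, r = 0.3,
                   polymorphic = TRUE, expression_ok = TRUE)
  expect_equal(nrow(filter_candidates(tb)$retained), 0L)
  # negative correlations count by absolute value
  tn <- data.frame(symbol = "n", cis_lrs = 30, r = -0.52,
                   polymorphic = TRUE, expression_ok = TRUE)
  expect_equal(nrow(filter_candidates(tn)$retained), 1L)
})

test_that("partial correlation matches the residual-regression oracle", {
  set.seed(30)
  for (i in 1:50) {
    n <- 20
    z <- sample(c(-1, 1), n, replace = TRUE)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + 0.4 * x + rnorm(n)
    pr <- partial_correlation(x, y, z)
    oracle <- cor(resid(lm(x ~ z)), resid(lm(y ~ z)))
    expect_equal(pr, oracle, tolerance = 1e-12)
  }
  # control uncorrelated with both leaves r unchanged
  x <- rnorm(30); y <- 0.6 * x + rnorm(30)
  z0 <- rep(c(-1, 1), 15)
  rxz <- cor(x, z0); ryz <- cor(y, z0)
  expect_equal(partial_correlation(x, y, z0),
               (cor(x, y) - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)),
               tolerance = 1e-14)
  # x = y gives 1; collinearity with the control is undefined
  expect_equal(partial_correlation(x, x, z0), 1.0, tolerance = 1e-12)
  expect_true(is.na(partial_correlation(as.numeric(z0), y, z0)))
  expect_error(partial_correlation(1:3, 1:3, 1:3), ">= 4")
})

test_that("ranking orders by |partial r| with documented tie-breaks", {
  tab <- data.frame(symbol = c("a", "b"), r = c(0.6, 0.6),
                    partial_r = c(0.2, 0.5))
  rk <- rank_candidates(tab)
  expect_identical(rk$symbol, c("b", "a"))
  expect_equal(rk$rank, 1:2)
  expect_equal(rk$retained_fraction, c(0.5 / 0.6, 0.2 / 0.6))

  tie <- data.frame(symbol = c("zed", "amy", "bob"),
                    r = c(0.4, 0.8, 0.8), partial_r = c(0.5, 0.5, -0.5))
  rk2 <- rank_candidates(tie)
  expect_identical(rk2$symbol, c("amy", "bob", "zed"))

  empty <- rank_candidates(data.frame(symbol = character(),
                                      r = numeric(), partial_r = numeric()))
  expect_equal(nrow(empty), 0L)
})

test_that("a planted regulator out-ranks pure-linkage decoys", {
  spec <- single_gene_spec(n_strains = 60, seed = 95L)
  geno <- simulate_ri_genotypes(spec)
  G <- geno_codes(geno)
  peak_mk <- "M4_10"
  decoy_mks <- c("M4_08", "M4_09", "M4_11", "M4_12", "M4_13")
  set.seed(95)
  wins <- 0L
  n_sim <- 40L
  for (s in seq_len(n_sim)) {
    x <- 0.8 * G[, peak_mk] + rnorm(60, 0, 0.3)           # true regulator
    y <- 0.6 * x + rnorm(60, 0, 0.3)                      # target
    decoys <- vapply(decoy_mks, function(mk)
      0.8 * G[, mk] + rnorm(60, 0, 0.3), numeric(60))
    tab <- data.frame(
      symbol = c("regulator", decoy_mks),
      r = c(cor(x, y), apply(decoys, 2, cor, y)),
      partial_r = c(partial_correlation(x, y, G[, peak_mk]),
                    apply(decoys, 2, partial_correlation, y, G[, peak_mk])))
    if (rank_candidates(tab)$symbol[1] == "regulator") wins <- wins + 1L
  }
  expect_gte(wins, 0.9 * n_sim)
  # decoys also lose more of their correlation than the regulator keeps
  expect_gt(abs(partial_correlation(x, y, G[, peak_mk])) / abs(cor(x, y)),
            mean(abs(tab$partial_r[-1]) / abs(tab$r[-1])))
})

test_that("cross-species support applies the 3 human + 3 mouse rule", {
  tab <- data.frame(
    dataset = c("GN314", "GN234", "GN361", "GN110", "GN133", "GN268"),
    species = rep(c("human", "mouse"), each = 3),
    r = c(0.3, 0.45, -0.5, 0.31, 0.6, -0.33))
  cs <- cross_species_support(tab)
  expect_true(cs$consistent)  # |r| = 0.3 counts; sign flips count
  expect_equal(cs$count, 6L)

  tab2 <- tab; tab2$r[2] <- 0.29
  expect_false(cross_species_support(tab2)$consistent)

  expect_warning(cs3 <- cross_species_support(tab[-1, ]), "human")
  expect_false(cs3$consistent)
})
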