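# Small internal numerical helpers shared across modules.

# Population (divide-by-n) variance; the 2Z+8 convention and the broad-sense
# heritability estimator are both defined with population moments so that
# "SD of 2" and h2 in [0,1] hold exactly per row/trait.
pop_var <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

pop_sd <- function(x) sqrt(pop_var(x))

# First principal component of a rows x strains matrix, computed on
# row-standardized data (correlation-matrix PCA). Returns the per-strain
# score vector (population SD 1), the fraction of total variance carried by
# PC1, and whether the input was degenerate (all rows constant).
#
# Sign convention: PC1 is oriented so that it correlates positively with the
# across-row mean profile (falling back to the first non-constant row when
# the mean profile is itself constant). An unoriented PC1 would randomize
# downstream allele-direction calls.
pc1_scores <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("pc1_scores() needs at least 2 columns (strains)")
  sds <- apply(X, 1L, stats::sd)
  keep <- is.finite(sds) & sds > 0
  if (!any(keep)) {
    return(list(scores = rep(0, ncol(X)), variance_fraction = NA_real_,
                degenerate = TRUE, n_rows_used = 0L))
  }
  Z <- t(scale(t(X[keep, , drop = FALSE])))  # rows centered, unit sample SD
  if (nrow(Z) == 1L) {
    sc <- as.numeric(Z[1L, ])
    return(list(scores = sc / pop_sd(sc), variance_fraction = 1.0,
                degenerate = FALSE, n_rows_used = 1L))
  }
  sv <- svd(Z)
  scores <- sv$v[, 1L]
  vf <- sv$d[1L]^2 / sum(sv$d^2)
  ref <- colMeans(Z)
  orient <- sum(scores * ref)
  if (abs(orient) < sqrt(.Machine$double.eps)) orient <- sum(scores * Z[1L, ])
  if (orient < 0) scores <- -scores
  s <- pop_sd(scores)
  if (s > 0) scores <- (scores - mean(scores)) / s
  list(scores = scores, variance_fraction = vf, degenerate = FALSE,
       n_rows_used = nrow(Z))
}

# Chromosome rank in map order (order of first appearance in the marker map).
chrom_rank <- function(chr, chrom_levels) match(chr, chrom_levels)

`%||%` <- function(a, b) if (is.null(a)) b else a
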