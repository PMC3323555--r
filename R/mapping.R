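#' Broad-sense heritability from strain replicates
#'
#' For an inbred panel, broad-sense heritability is estimated as the genetic
#' variance — the variance among strain means — divided by the total
#' variance among all measurements. Both variances are population (divide by
#' n) variances and the ratio is clipped to `[0, 1]`.
#'
#' @param values numeric vector of replicate-level measurements.
#' @param strains strain label for each measurement.
#' @return object of class `"herit"`: list with `h2`, `var_strain_means`,
#'   `var_total`, `n_strains`, `n_total`.
#' @examples
#' broad_sense_h2(c(1, 1, 3, 3), c("a", "a", "b", "b"))$h2  # 1
#' @export
broad_sense_h2 <- function(values, strains) {
  values <- as.numeric(values)
  strains <- as.character(strains)
  if (length(values) != length(strains)) stop("length mismatch")
  ok <- is.finite(values)
  values <- values[ok]; strains <- strains[ok]
  if (length(unique(strains)) < 2L) stop("need >= 2 strains")
  vt <- pop_var(values)
  if (!is.finite(vt) || vt == 0) stop("zero total variance")
  sm <- tapply(values, strains, mean)
  vg <- pop_var(as.numeric(sm))
  structure(list(h2 = min(1, max(0, vg / vt)), var_strain_means = vg,
                 var_total = vt, n_strains = length(sm),
                 n_total = length(values)),
            class = "herit")
}

#' @export
print.herit <- function(x, ...) {
  cat(sprintf(
    "broad-sense h2 = %.3f  (Var strain means %.4g / Var total %.4g; %d strains, %d measurements)\n",
    x$h2, x$var_strain_means, x$var_total, x$n_strains, x$n_total))
  invisible(x)
}

#' Per-row heritability of an expression panel
#'
#' @param expr an [expr_panel()] with replicate columns.
#' @return data frame with one row per expression row: `id`, `h2`,
#'   `var_strain_means`, `var_total`.
#' @export
broad_sense_h2_panel <- function(expr) {
  stopifnot(inherits(expr, "expr_panel"))
  res <- lapply(seq_len(nrow(expr$values)), function(i)
    broad_sense_h2(expr$values[i, ], expr$strains))
  data.frame(id = rownames(expr$values),
             h2 = vapply(res, `[[`, numeric(1L), "h2"),
             var_strain_means = vapply(res, `[[`, numeric(1L),
                                       "var_strain_means"),
             var_total = vapply(res, `[[`, numeric(1L), "var_total"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-marker LRS scan
#'
#' Regresses a strain-mean trait on each marker in turn (genotypes coded
#' B = -1, H = 0, D = +1, unknowns dropped pairwise) and reports the
#' likelihood ratio statistic `LRS = n ln(RSS0/RSS1)`, the Gaussian
#' maximum-likelihood form, where RSS0 is the residual sum of squares about
#' the trait mean and n the informative strain count at the marker. The
#' additive effect is half the difference between the D- and B-class trait
#' means. Markers with a single genotype class, or fewer than 3 informative
#' strains, get LRS 0 and an undefined effect.
#'
#' @param trait named numeric vector of strain means; names must match
#'   panel strains.
#' @param geno an [ri_geno()] panel.
#' @return object of class `"linkage_curve"`: a data frame with columns
#'   `marker`, `chr`, `pos_mb`, `lrs`, `lod`, `additive`, `n_informative`.
#' @export
eqtl_scan <- function(trait, geno) {
  stopifnot(inherits(geno, "ri_geno"))
  if (is.null(names(trait))) stop("trait must be named by strain")
  miss <- setdiff(names(trait), geno$strains)
  if (length(miss))
    stop("trait strain(s) absent from genotypes: ",
         paste(utils::head(miss, 5), collapse = ", "))
  y <- as.numeric(trait[geno$strains])
  names(y) <- geno$strains
  G <- geno_codes(geno)

  M <- !is.na(G) & !is.na(y)       # informative strain x marker mask
  X <- G; X[!M] <- 0
  y0 <- ifelse(is.na(y), 0, y)
  nj <- colSums(M)
  Sx <- colSums(X)
  Sy <- colSums(M * y0)
  Sxx <- colSums(X^2) - Sx^2 / pmax(nj, 1)
  Sxy <- colSums(X * y0) - Sx * Sy / pmax(nj, 1)
  Syy <- colSums(M * y0^2) - Sy^2 / pmax(nj, 1)

  nB <- colSums(M & G == -1, na.rm = TRUE)
  nD <- colSums(M & G == 1, na.rm = TRUE)
  usable <- nj >= 3 & nB > 0 & nD > 0 & Sxx > 0 & Syy > 0

  rss1 <- pmax(Syy - Sxy^2 / ifelse(Sxx > 0, Sxx, 1), 0)
  lrs <- rep(0, ncol(G))
  lrs[usable] <- nj[usable] * log(Syy[usable] / pmax(rss1[usable],
                                                     .Machine$double.xmin))
  meanB <- colSums((M & G == -1) * y0) / pmax(nB, 1)
  meanD <- colSums((M & G == 1) * y0) / pmax(nD, 1)
  a <- rep(NA_real_, ncol(G))
  a[nB > 0 & nD > 0] <- (meanD - meanB)[nB > 0 & nD > 0] / 2

  out <- data.frame(marker = geno$markers$marker, chr = geno$markers$chr,
                    pos_mb = geno$markers$pos_mb, lrs = lrs,
                    lod = lrs / 4.61, additive = a, n_informative = nj,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("linkage_curve", "data.frame")
  out
}

#' @export
print.linkage_curve <- function(x, ...) {
  cat("LRS scan over", nrow(x), "markers on",
      length(unique(x$chr)), "chromosome(s)\n")
  top <- x[which.max(x$lrs), ]
  cat(sprintf("  max LRS %.2f (LOD %.2f) at %s (chr %s @ %.2f Mb), a = %s\n",
              top$lrs, top$lod, top$marker, top$chr, top$pos_mb,
              ifelse(is.na(top$additive), "NA",
                     sprintf("%.3f", top$additive))))
  invisible(x)
}

#' @export
summary.linkage_curve <- function(object, threshold = 0, ...) {
  per_chr <- do.call(rbind, lapply(split(as.data.frame(object), object$chr),
                                   function(d) d[which.max(d$lrs), ]))
  per_chr <- per_chr[order(-per_chr$lrs), ]
  per_chr[per_chr$lrs >= threshold, , drop = FALSE]
}

#' @export
plot.linkage_curve <- function(x, thresholds = NULL,
                               main = "genome scan", ...) {
  chrs <- unique(x$chr)
  offs <- c(0, cumsum(vapply(chrs, function(cc)
    max(x$pos_mb[x$chr == cc]) + 5, numeric(1L))))
  names(offs) <- c(chrs, "end")
  xx <- x$pos_mb + offs[x$chr]
  graphics::plot(xx, x$lrs, type = "n", xlab = "genome position (Mb)",
                 ylab = "LRS", main = main, xaxt = "n", ...)
  for (cc in chrs) {
    i <- x$chr == cc
    graphics::lines(xx[i], x$lrs[i], col = "steelblue4")
  }
  mid <- offs[seq_along(chrs)] + vapply(chrs, function(cc)
    max(x$pos_mb[x$chr == cc]) / 2, numeric(1L))
  graphics::axis(1, at = mid, labels = chrs)
  if (!is.null(thresholds)) {
    graphics::abline(h = thresholds$significant, col = "red")
    graphics::abline(h = thresholds$suggestive, col = "grey50")
  }
  invisible(x)
}

#' LOD score from an LRS score
#'
#' `LOD = LRS / 4.61`; the divisor is `2 ln(10)` rounded to two decimals,
#' the conversion used throughout RI-panel eQTL reporting.
#'
#' @param lrs numeric LRS value(s), >= 0.
#' @return LOD score(s).
#' @examples lod_from_lrs(4.61)  # 1
#' @export
lod_from_lrs <- function(lrs) {
  if (any(!is.finite(lrs)) || any(lrs < 0)) stop("LRS must be finite and >= 0")
  lrs / 4.61
}

#' Genome-wide permutation thresholds for an LRS scan
#'
#' Permutes the trait values over strains `n_perm` times, records the
#' genome-wide maximum LRS of each permuted scan, and returns the 95th
#' percentile of that null distribution as the significant threshold and
#' the 37th percentile as the suggestive threshold (genome-wide p = 0.63,
#' the conventional "expect one false linkage per scan" level).
#'
#' @param trait named numeric vector of strain means.
#' @param geno an [ri_geno()] panel.
#' @param n_perm number of permutations (>= 100; fewer makes the upper
#'   quantile unstable).
#' @param seed random seed (mandatory: thresholds must be reproducible).
#' @return object of class `"perm_thresholds"`: list with `significant`,
#'   `suggestive`, `n_perm`, `seed` and the null `max_lrs` vector.
#' @export
permutation_thresholds <- function(trait, geno, n_perm = 1000, seed) {
  stopifnot(inherits(geno, "ri_geno"))
  if (missing(seed)) stop("seed is required")
  if (n_perm < 100) stop("n_perm must be >= 100")
  set.seed(seed)
  y <- as.numeric(trait[geno$strains])
  G <- geno_codes(geno)
  if (!anyNA(y) && !anyNA(G)) {
    maxes <- .perm_max_lrs(y, G, n_perm)
  } else {
    maxes <- numeric(n_perm)
    for (p in seq_len(n_perm)) {
      yp <- sample(y)
      names(yp) <- geno$strains
      maxes[p] <- max(eqtl_scan(yp, geno)$lrs)
    }
  }
  q <- stats::quantile(maxes, c(0.95, 0.37), names = FALSE)
  structure(list(significant = q[1L], suggestive = q[2L],
                 n_perm = as.integer(n_perm), seed = seed,
                 max_lrs = maxes),
            class = "perm_thresholds")
}

# Fast complete-data path: for simple linear regression the scan statistic
# n ln(RSS0/RSS1) equals -n ln(1 - r^2), so all permutations reduce to one
# cross-product of standardized matrices. Markers with a single genotype
# class have zero variance and contribute LRS 0.
.perm_max_lrs <- function(y, G, n_perm) {
  n <- length(y)
  P <- matrix(0, n, n_perm)
  for (p in seq_len(n_perm)) P[, p] <- sample(y)
  sdG <- apply(G, 2L, stats::sd)
  keep <- sdG > 0
  Gs <- scale(G[, keep, drop = FALSE])
  Ps <- scale(P)
  ok <- attr(Ps, "scaled:scale") > 0
  r2 <- (crossprod(Ps, Gs) / (n - 1))^2
  r2 <- pmin(r2, 1 - 1e-15)
  lrs <- -n * log(1 - r2)
  out <- rep(0, n_perm)
  out[ok] <- apply(lrs[ok, , drop = FALSE], 1L, max)
  out
}

#' @export
print.perm_thresholds <- function(x, ...) {
  cat(sprintf(
    "permutation thresholds (%d perms, seed %s): significant LRS %.2f, suggestive LRS %.2f\n",
    x$n_perm, format(x$seed), x$significant, x$suggestive))
  invisible(x)
}

#' Peak extraction and cis/trans classification
#'
#' Takes the maximum-LRS marker of a scan (ties broken toward the lowest
#' genomic coordinate), keeps it only if it reaches the suggestive
#' threshold, and classifies it against the cognate gene: cis if the peak
#' lies on the gene's chromosome within `cis_window_mb` (default 10 Mb) of
#' the gene span, trans otherwise. The allele direction is `D_high` when
#' the additive effect is positive, `B_high` otherwise (a zero effect is
#' reported `B_high` with `zero_effect = TRUE`).
#'
#' @param curve a [eqtl_scan()] result.
#' @param gene single-row gene annotation (`symbol`, `chr`, `start_mb`,
#'   `end_mb`) or `NULL` to skip classification.
#' @param thresholds a [permutation_thresholds()] object, or a list/vector
#'   with elements `significant` and `suggestive`.
#' @param cis_window_mb maximum distance from peak to gene span for a cis
#'   call.
#' @param classify whether to apply the cis/trans rule (requires `gene`).
#' @return object of class `"eqtl_peak"` (list with marker, position, LRS,
#'   LOD, additive effect, allele direction, classification, distance to
#'   gene, thresholds), or `NULL` when no marker reaches the suggestive
#'   threshold.
#' @export
peak_and_classify <- function(curve, gene = NULL, thresholds,
                              cis_window_mb = 10,
                              classify = !is.null(gene)) {
  stopifnot(inherits(curve, "linkage_curve"), nrow(curve) >= 1L)
  if (classify && is.null(gene))
    stop("gene annotation required for cis/trans classification")
  sig <- thresholds$significant
  sug <- thresholds$suggestive
  i <- which(curve$lrs == max(curve$lrs))[1L]  # map order = genomic order
  if (curve$lrs[i] < sug) return(NULL)
  a <- curve$additive[i]
  zero <- is.na(a) || a == 0
  dir <- if (!is.na(a) && a > 0) "D_high" else "B_high"
  cls <- NA_character_
  dist <- NA_real_
  if (classify) {
    if (curve$chr[i] == gene$chr) {
      dist <- if (curve$pos_mb[i] < gene$start_mb)
        gene$start_mb - curve$pos_mb[i]
      else if (curve$pos_mb[i] > gene$end_mb)
        curve$pos_mb[i] - gene$end_mb
      else 0
      cls <- if (dist <= cis_window_mb) "cis" else "trans"
    } else {
      cls <- "trans"
    }
  }
  structure(list(marker = curve$marker[i], chr = curve$chr[i],
                 pos_mb = curve$pos_mb[i], lrs = curve$lrs[i],
                 lod = curve$lrs[i] / 4.61, additive = a,
                 allele_direction = dir, zero_effect = zero,
                 classification = cls, distance_mb = dist,
                 significant = curve$lrs[i] >= sig,
                 thresholds = list(significant = sig, suggestive = sug),
                 gene = if (is.null(gene)) NULL else gene$symbol),
            class = "eqtl_peak")
}

#' @export
print.eqtl_peak <- function(x, ...) {
  cat(sprintf("eQTL peak at %s (chr %s @ %.2f Mb): LRS %.2f (LOD %.2f), %s",
              x$marker, x$chr, x$pos_mb, x$lrs, x$lod, x$allele_direction))
  if (!is.na(x$classification)) {
    if (is.na(x$distance_mb))
      cat(sprintf(", %s (different chromosome than %s)", x$classification,
                  x$gene %||% "gene"))
    else
      cat(sprintf(", %s (%.2f Mb from %s)", x$classification, x$distance_mb,
                  x$gene %||% "gene"))
  }
  cat(if (x$significant) " [significant]\n" else " [suggestive]\n")
  invisible(x)
}
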