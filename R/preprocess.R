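#' Remove variant-overlapping probes
#'
#' Probes whose target sequence overlaps a sequence variant segregating in
#' the panel hybridize differentially by genotype and produce spurious cis
#' signals; they are removed before probe-set summarization. Probe sets
#' losing every probe are flagged unusable rather than summarized. The
#' operation is idempotent.
#'
#' @param expr probe-level [expr_panel()].
#' @param annot probe annotation data frame covering every probe row (see
#'   [read_probe_annotation()]).
#' @return list with `expr` (filtered panel), `removed` (character vector of
#'   dropped probe ids), `unusable_probesets` (probe sets with zero
#'   surviving probes) and `n_removed` / `n_kept` counts.
#' @export
filter_snp_probes <- function(expr, annot) {
  stopifnot(inherits(expr, "expr_panel"))
  ids <- rownames(expr$values)
  miss <- setdiff(ids, annot$probe_id)
  if (length(miss))
    stop("unannotated probe(s): ", paste(utils::head(miss, 5), collapse = ", "))
  an <- annot[match(ids, annot$probe_id), ]
  drop <- an$overlaps_variant
  kept <- expr$values[!drop, , drop = FALSE]
  all_sets <- unique(an$probeset_id)
  surviving <- unique(an$probeset_id[!drop])
  out_expr <- expr_panel(kept, strains = expr$strains, reps = expr$reps,
                         scale = expr$scale)
  list(expr = out_expr,
       removed = ids[drop],
       unusable_probesets = setdiff(all_sets, surviving),
       n_removed = sum(drop), n_kept = sum(!drop))
}

#' Probe-set value reconstruction from the first principal component
#'
#' Summarizes the surviving probes of one probe set into a single per-strain
#' profile: probes are centered and unit-scaled across strains
#' (correlation-matrix PCA) and the first principal component's strain
#' scores, sign-oriented to correlate positively with the mean probe
#' profile, become the probe-set value. The reported profile is re-expressed
#' on the log2 scale as `mean expression + score * mean probe SD`, so it is
#' comparable to a plain probe-set mean. A single surviving probe is passed
#' through unchanged with a variance fraction of 1.
#'
#' @param probes numeric matrix, probes x strains (strain means), of one
#'   probe set; needs >= 3 strains.
#' @param probeset_id,gene_symbol,region metadata copied to the result.
#' @param n_probes_removed number of probes dropped before summarization
#'   (bookkeeping only).
#' @return object of class `"probeset_summary"`: list with `probeset_id`,
#'   `gene_symbol`, `region`, `values` (named per-strain profile),
#'   `pc1_variance_fraction`, `n_probes_used`, `n_probes_removed`,
#'   `mean_expression`, `fold_change`, `degenerate`, `method`.
#' @export
summarize_probeset_pc1 <- function(probes, probeset_id = "probeset",
                                   gene_symbol = NA_character_,
                                   region = NA_character_,
                                   n_probes_removed = 0L) {
  probes <- as.matrix(probes)
  if (nrow(probes) < 1L) stop("probe set has no probes")
  if (ncol(probes) < 3L) stop("need >= 3 strains")
  strains <- colnames(probes)
  mean_expr <- mean(probes)
  if (nrow(probes) == 1L) {
    vals <- as.numeric(probes[1L, ])
    names(vals) <- strains
    return(structure(list(probeset_id = probeset_id,
                          gene_symbol = gene_symbol, region = region,
                          values = vals, pc1_variance_fraction = 1.0,
                          n_probes_used = 1L,
                          n_probes_removed = as.integer(n_probes_removed),
                          mean_expression = mean_expr,
                          fold_change = fold_change(vals),
                          degenerate = pop_sd(vals) == 0,
                          method = "single_probe"),
                     class = "probeset_summary"))
  }
  pc <- pc1_scores(probes)
  if (pc$degenerate) {
    vals <- rep(mean_expr, ncol(probes))
    names(vals) <- strains
    return(structure(list(probeset_id = probeset_id,
                          gene_symbol = gene_symbol, region = region,
                          values = vals, pc1_variance_fraction = NA_real_,
                          n_probes_used = nrow(probes),
                          n_probes_removed = as.integer(n_probes_removed),
                          mean_expression = mean_expr, fold_change = 1.0,
                          degenerate = TRUE, method = "degenerate_constant"),
                     class = "probeset_summary"))
  }
  probe_sds <- apply(probes, 1L, pop_sd)
  vals <- mean_expr + pc$scores * mean(probe_sds)
  names(vals) <- strains
  structure(list(probeset_id = probeset_id, gene_symbol = gene_symbol,
                 region = region, values = vals,
                 pc1_variance_fraction = pc$variance_fraction,
                 n_probes_used = nrow(probes),
                 n_probes_removed = as.integer(n_probes_removed),
                 mean_expression = mean_expr,
                 fold_change = fold_change(vals),
                 degenerate = FALSE, method = "pc1_correlation"),
            class = "probeset_summary")
}

#' @export
print.probeset_summary <- function(x, ...) {
  cat("probe set ", x$probeset_id,
      if (!is.na(x$gene_symbol)) paste0(" (", x$gene_symbol, ", ", x$region, ")"),
      ": ", x$n_probes_used, " probes used, ", x$n_probes_removed,
      " removed\n", sep = "")
  cat(sprintf("  PC1 variance fraction %.3f | mean expression %.2f | FC %.2f\n",
              x$pc1_variance_fraction, x$mean_expression, x$fold_change))
  invisible(x)
}

#' Summarize every probe set of a filtered panel
#'
#' Convenience wrapper: computes strain means, groups probes by probe set
#' and applies [summarize_probeset_pc1()] to each. Probe sets whose mean
#' log2 expression falls below `floor` are marked `expressed = FALSE` and
#' are excluded from mapping/network stages by default (platform-dependent
#' detection floor; 8 is typical for 3'-biased arrays, 10 for exon arrays).
#'
#' @param expr probe-level [expr_panel()] (already variant-filtered).
#' @param annot probe annotation covering the panel.
#' @param floor expression floor on the mean log2 value.
#' @param removed_counts optional named count of probes removed per probe
#'   set (from [filter_snp_probes()] bookkeeping).
#' @return list with `summaries` (list of `probeset_summary`), `profiles`
#'   (probe sets x strains matrix of reconstructed values) and `info`
#'   (data frame of per-set metadata including `expressed`).
#' @export
summarize_panel <- function(expr, annot, floor = 8, removed_counts = NULL) {
  sm <- strain_means(expr)
  ids <- rownames(sm)
  an <- annot[match(ids, annot$probe_id), ]
  if (anyNA(an$probeset_id)) stop("unannotated probe(s) in panel")
  sets <- unique(an$probeset_id)
  summaries <- vector("list", length(sets))
  names(summaries) <- sets
  for (s in sets) {
    rows <- which(an$probeset_id == s)
    nrem <- if (!is.null(removed_counts) && s %in% names(removed_counts))
      removed_counts[[s]] else 0L
    summaries[[s]] <- summarize_probeset_pc1(
      sm[rows, , drop = FALSE], probeset_id = s,
      gene_symbol = an$gene_symbol[rows[1L]],
      region = an$region[rows[1L]], n_probes_removed = nrem)
  }
  profiles <- do.call(rbind, lapply(summaries, `[[`, "values"))
  rownames(profiles) <- sets
  info <- data.frame(
    probeset_id = sets,
    gene_symbol = vapply(summaries, `[[`, character(1L), "gene_symbol"),
    region = vapply(summaries, `[[`, character(1L), "region"),
    pc1_variance_fraction = vapply(summaries, `[[`, numeric(1L),
                                   "pc1_variance_fraction"),
    n_probes_used = vapply(summaries, `[[`, integer(1L), "n_probes_used"),
    mean_expression = vapply(summaries, `[[`, numeric(1L),
                             "mean_expression"),
    fold_change = vapply(summaries, `[[`, numeric(1L), "fold_change"),
    stringsAsFactors = FALSE, row.names = NULL)
  info$expressed <- info$mean_expression >= floor
  list(summaries = summaries, profiles = profiles, info = info)
}

#' 2Z+8 standardization
#'
#' Rescales every row to a z-score across columns (population SD) and maps
#' it to mean 8, SD 2 — the standard presentation scale for log2 expression
#' summaries. Constant rows cannot be standardized; they are set to 8 with
#' a warning. Idempotent up to numerical tolerance.
#'
#' @param x numeric matrix (rows standardized across columns) or an
#'   [expr_panel()].
#' @return same shape as the input; an `expr_panel` gets scale tag
#'   `"standardized_2z8"`.
#' @export
standardize_2z8 <- function(x) {
  if (inherits(x, "expr_panel")) {
    v <- standardize_2z8(x$values)
    return(expr_panel(v, strains = x$strains, reps = x$reps,
                      scale = "standardized_2z8"))
  }
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("values must be finite")
  out <- x
  constant <- logical(nrow(x))
  for (i in seq_len(nrow(x))) {
    s <- pop_sd(x[i, ])
    if (s == 0) {
      out[i, ] <- 8
      constant[i] <- TRUE
    } else {
      out[i, ] <- (x[i, ] - mean(x[i, ])) / s * 2 + 8
    }
  }
  if (any(constant))
    warning(sum(constant), " constant row(s) set to 8")
  out
}

#' Fold change across strains on the log2 scale
#'
#' `FC = 2^(max - min)` of the per-strain values; 1 for a constant profile.
#'
#' @param x numeric vector of log2 strain values (>= 2 strains).
#' @return fold change, >= 1.
#' @export
fold_change <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) stop("need >= 2 strains")
  2^(max(x) - min(x))
}

#' Collapse replicate arrays to strain means
#'
#' @param expr an [expr_panel()].
#' @return numeric rows x strains matrix of within-strain replicate means
#'   (single-replicate columns pass through).
#' @export
strain_means <- function(expr) {
  stopifnot(inherits(expr, "expr_panel"))
  strains <- unique(expr$strains)
  out <- matrix(NA_real_, nrow = nrow(expr$values), ncol = length(strains),
                dimnames = list(rownames(expr$values), strains))
  for (k in seq_along(strains)) {
    cols <- which(expr$strains == strains[k])
    out[, k] <- rowMeans(expr$values[, cols, drop = FALSE], na.rm = TRUE)
  }
  out
}
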