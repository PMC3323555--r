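#' Genes inside a trans-eQTL interval
#'
#' Returns the genes whose span intersects the window
#' `[peak - half_width_mb, peak + half_width_mb]` on the peak chromosome.
#'
#' @param peak an [peak_and_classify()] result (or any list with `chr` and
#'   `pos_mb`).
#' @param genes gene annotation data frame (`symbol`, `chr`, `start_mb`,
#'   `end_mb`).
#' @param half_width_mb half-width of the interval, megabases (> 0).
#' @return subset of `genes` intersecting the interval.
#' @export
interval_genes <- function(peak, genes, half_width_mb = 5) {
  if (half_width_mb <= 0) stop("half_width_mb must be > 0")
  lo <- peak$pos_mb - half_width_mb
  hi <- peak$pos_mb + half_width_mb
  genes[genes$chr == peak$chr & genes$end_mb >= lo & genes$start_mb <= hi, ,
        drop = FALSE]
}

#' Five-criteria candidate filter
#'
#' Applies the candidate-regulator criteria to the genes of a trans-eQTL
#' interval: strong cis regulation of the candidate itself (LRS > 15),
#' covariation with the target transcript (|r| > 0.3), a B6-vs-D2
#' polymorphism in the candidate locus, detectable expression in the
#' tissue, and (when supplied) overlapping anatomical expression from an
#' external atlas annotation. Every exclusion is logged with all failed
#' criteria.
#'
#' @param table data frame with one row per interval gene and columns
#'   `symbol`, `cis_lrs`, `r` (correlation with the target profile),
#'   `polymorphic` (logical), `expression_ok` (logical) and optionally
#'   `atlas_ok` (logical; `NA` = no annotation, criterion skipped). A gene
#'   with missing `cis_lrs` or `r` (no usable expression) is excluded with
#'   reason `"missing_expression"`.
#' @param lrs_min cis-regulation gate (strictly greater than).
#' @param r_min covariation gate on |r| (strictly greater than).
#' @return list with `retained` (data frame subset) and `excluded` (data
#'   frame with `symbol` and comma-separated `reason`); the two partition
#'   the input.
#' @export
filter_candidates <- function(table, lrs_min = 15, r_min = 0.3) {
  need <- c("symbol", "cis_lrs", "r", "polymorphic", "expression_ok")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  has_atlas <- "atlas_ok" %in% names(table)
  reasons <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    rs <- character()
    if (is.na(table$cis_lrs[i]) || is.na(table$r[i])) {
      rs <- "missing_expression"
    } else {
      if (table$cis_lrs[i] <= lrs_min) rs <- c(rs, "cis-regulation")
      if (abs(table$r[i]) <= r_min) rs <- c(rs, "covariation")
    }
    if (!isTRUE(as.logical(table$polymorphic[i]))) rs <- c(rs, "polymorphism")
    if (!isTRUE(as.logical(table$expression_ok[i]))) rs <- c(rs, "expression")
    if (has_atlas && !is.na(table$atlas_ok[i]) &&
        !isTRUE(as.logical(table$atlas_ok[i]))) rs <- c(rs, "atlas")
    reasons[[i]] <- rs
  }
  fail <- lengths(reasons) > 0
  list(retained = table[!fail, , drop = FALSE],
       excluded = data.frame(
         symbol = table$symbol[fail],
         reason = vapply(reasons[fail], paste, character(1L),
                         collapse = ","),
         stringsAsFactors = FALSE, row.names = NULL))
}

#' First-order partial correlation controlling for a marker genotype
#'
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))` — the
#' correlation between two expression profiles after removing the linear
#' contribution of the genotype at the peak trans-QTL marker (coded
#' -1/0/+1). Identical to the correlation of the residuals from regressing
#' each profile on the control. Undefined (NA) when either profile is
#' collinear with the control.
#'
#' @param x,y numeric expression profiles over strains.
#' @param z control variable (genotype codes at the peak marker).
#' @return partial correlation in `[-1, 1]`, or `NA` when undefined.
#' @export
partial_correlation <- function(x, y, z) {
  ok <- is.finite(x) & is.finite(y) & is.finite(z)
  if (sum(ok) < 4L) stop("need >= 4 complete strain triples")
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  rxy <- stats::cor(x, y)
  rxz <- stats::cor(x, z)
  ryz <- stats::cor(y, z)
  if (any(is.na(c(rxy, rxz, ryz)))) return(NA_real_)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12) return(NA_real_)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Rank retained candidates by marker-controlled partial correlation
#'
#' A pure-linkage decoy loses its correlation with the target once the
#' shared marker genotype is controlled, while a biologically coupled
#' regulator retains it; candidates are therefore ranked by |partial r|
#' descending (ties: higher |r| wins, then lexicographic symbol). The
#' retained fraction |partial r| / |r| is reported alongside.
#'
#' @param table data frame with columns `symbol`, `r` and `partial_r`.
#' @return object of class `"candidate_report"`: the table ordered by rank
#'   with added `retained_fraction` and `rank` columns.
#' @export
rank_candidates <- function(table) {
  if (nrow(table) == 0L) {
    out <- cbind(table, retained_fraction = numeric(0), rank = integer(0))
    class(out) <- c("candidate_report", "data.frame")
    return(out)
  }
  need <- c("symbol", "r", "partial_r")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ord <- order(-abs(table$partial_r), -abs(table$r), table$symbol)
  out <- table[ord, , drop = FALSE]
  out$retained_fraction <- abs(out$partial_r) / abs(out$r)
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("candidate_report", "data.frame")
  out
}

#' @export
print.candidate_report <- function(x, ...) {
  cat("candidate regulators, ranked by |partial r| (marker-controlled):\n")
  print.data.frame(x, digits = 3)
  invisible(x)
}

#' Cross-species coexpression support
#'
#' Counts the independent datasets in which the candidate-target
#' correlation reaches `|r| >= 0.3` (sign-free criterion) and calls the
#' association consistent when at least three human and three mouse
#' datasets reach it.
#'
#' @param table data frame with columns `dataset`, `species` (`"human"` or
#'   `"mouse"`) and `r`.
#' @param r_min support threshold on |r|.
#' @param n_required datasets per species required for consistency.
#' @return list with `count` (total supporting datasets), `by_species`,
#'   and `consistent` (logical). Fewer than `n_required` datasets supplied
#'   for a species yields `consistent = FALSE` with a warning.
#' @export
cross_species_support <- function(table, r_min = 0.3, n_required = 3) {
  stopifnot(all(c("dataset", "species", "r") %in% names(table)))
  sp <- tolower(table$species)
  hit <- abs(table$r) >= r_min
  by_species <- tapply(hit, sp, sum)
  for (s in c("human", "mouse")) {
    if (sum(sp == s) < n_required)
      warning("fewer than ", n_required, " ", s, " dataset(s) supplied")
  }
  consistent <- sum(hit[sp == "human"]) >= n_required &&
    sum(hit[sp == "mouse"]) >= n_required
  list(count = sum(hit), by_species = as.list(by_species),
       consistent = consistent)
}
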