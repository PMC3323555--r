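#' Pairwise correlation matrix of expression profiles
#'
#' @param profiles numeric rows x strains matrix (>= 3 strains); rows are
#'   probe-set or gene profiles.
#' @param method `"pearson"` or `"spearman"` (Pearson on average ranks).
#' @return symmetric correlation matrix with unit diagonal; pairs involving
#'   a zero-variance profile are `NA`.
#' @export
correlation_matrix <- function(profiles, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3L) stop("need >= 3 strains")
  r <- suppressWarnings(stats::cor(t(profiles), method = method,
                                   use = "pairwise.complete.obs"))
  diag(r) <- 1
  r
}

#' Collapse a gene's probe sets into consensus profiles
#'
#' Probe sets of one gene whose pairwise correlation exceeds `r_merge`
#' (single-linkage closure) are merged: pairs are averaged, groups of three
#' or more are replaced by their sign-oriented first principal component,
#' and singletons (including discordant 3' UTR probe sets) pass through.
#' All profiles are standardized (z-scored across strains) before grouping
#' and merging.
#'
#' @param profiles probe sets x strains matrix for a single gene.
#' @param r_merge merge threshold on pairwise Pearson r (strictly greater
#'   than).
#' @return list with `profiles` (collapsed rows x strains), `groups` (list
#'   of member probe-set ids per output row), `method` per output row
#'   (`"single"`, `"average"`, `"pc1"`), and `mixed` flag per group (TRUE
#'   when the single-linkage closure joined pairs at or below the
#'   threshold).
#' @export
collapse_probesets <- function(profiles, r_merge = 0.8) {
  profiles <- as.matrix(profiles)
  if (is.null(rownames(profiles)))
    rownames(profiles) <- paste0("ps", seq_len(nrow(profiles)))
  k <- nrow(profiles)
  Z <- t(scale(t(profiles)))
  if (k == 1L) {
    return(list(profiles = Z, groups = list(rownames(profiles)),
                method = "single", mixed = FALSE))
  }
  r <- stats::cor(t(profiles))
  # single-linkage components of the graph {i ~ j : r_ij > r_merge}
  adj <- r > r_merge
  diag(adj) <- TRUE
  comp <- seq_len(k)
  repeat {
    changed <- FALSE
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  groups <- split(seq_len(k), comp)
  out <- matrix(NA_real_, nrow = length(groups), ncol = ncol(profiles),
                dimnames = list(NULL, colnames(profiles)))
  members <- vector("list", length(groups))
  method <- character(length(groups))
  mixed <- logical(length(groups))
  nm <- character(length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    members[[gi]] <- rownames(profiles)[idx]
    nm[gi] <- paste(members[[gi]], collapse = "+")
    if (length(idx) == 1L) {
      out[gi, ] <- Z[idx, ]
      method[gi] <- "single"
    } else if (length(idx) == 2L) {
      out[gi, ] <- colMeans(Z[idx, , drop = FALSE])
      method[gi] <- "average"
    } else {
      out[gi, ] <- pc1_scores(profiles[idx, , drop = FALSE])$scores
      method[gi] <- "pc1"
    }
    if (length(idx) > 1L) {
      sub <- r[idx, idx]
      mixed[gi] <- any(sub[upper.tri(sub)] <= r_merge)
    }
  }
  rownames(out) <- nm
  list(profiles = out, groups = members, method = method, mixed = mixed)
}

#' Build a binned signed coexpression network
#'
#' Edges are the profile pairs with `|r| >= floor` (default 0.3), binned by
#' absolute correlation: `bold` for |r| in \[0.7, 1\], `normal` for
#' \[0.5, 0.7) and `dashed` for \[0.3, 0.5); the sign of r is kept on the
#' edge.
#'
#' @param correlations symmetric correlation matrix (from
#'   [correlation_matrix()]).
#' @param floor minimum |r| for an edge.
#' @param method correlation method recorded on the edges.
#' @return object of class `"coexpression_network"`: list with `nodes`
#'   (character vector) and `edges` (data frame `node_a`, `node_b`, `r`,
#'   `sign`, `bin`, `method`).
#' @export
build_network <- function(correlations, floor = 0.3, method = "pearson") {
  correlations <- as.matrix(correlations)
  nodes <- rownames(correlations) %||% paste0("n", seq_len(nrow(correlations)))
  ut <- which(upper.tri(correlations), arr.ind = TRUE)
  r <- correlations[ut]
  keep <- !is.na(r) & abs(r) >= floor
  ut <- ut[keep, , drop = FALSE]
  r <- r[keep]
  bin <- ifelse(abs(r) >= 0.7, "bold",
                ifelse(abs(r) >= 0.5, "normal", "dashed"))
  edges <- data.frame(node_a = nodes[ut[, 1L]], node_b = nodes[ut[, 2L]],
                      r = r, sign = ifelse(r >= 0, "positive", "negative"),
                      bin = bin, method = method, stringsAsFactors = FALSE,
                      row.names = NULL)
  structure(list(nodes = nodes, edges = edges, floor = floor),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression network:", length(x$nodes), "nodes,",
      nrow(x$edges), "edges (|r| >=", x$floor, ")\n")
  if (nrow(x$edges))
    print(table(bin = x$edges$bin, sign = x$edges$sign))
  invisible(x)
}

#' Module eigengene
#'
#' The first principal component of the standardized member profiles,
#' sign-oriented to correlate positively with the mean member profile. The
#' score vector is a per-strain composite trait directly usable in
#' [eqtl_scan()].
#'
#' @param profiles member genes x strains matrix (>= 2 members).
#' @return object of class `"module_eigengene"`: list with `scores` (named
#'   per-strain), `variance_fraction`, `members`.
#' @export
module_eigengene <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need >= 2 module members")
  pc <- pc1_scores(profiles)
  if (pc$degenerate) stop("degenerate module: all member profiles constant")
  scores <- pc$scores
  names(scores) <- colnames(profiles)
  structure(list(scores = scores, variance_fraction = pc$variance_fraction,
                 members = rownames(profiles) %||%
                   paste0("m", seq_len(nrow(profiles)))),
            class = "module_eigengene")
}

#' @export
print.module_eigengene <- function(x, ...) {
  cat(sprintf("module eigengene: %d members, PC1 explains %.1f%% of variance\n",
              length(x$members), 100 * x$variance_fraction))
  invisible(x)
}

#' Write a network as JSON
#' @param network a [build_network()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  jsonlite::write_json(list(nodes = network$nodes, floor = network$floor,
                            edges = network$edges),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
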