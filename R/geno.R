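#' Genotype matrix for a recombinant-inbred panel
#'
#' Constructs the panel genotype container used by every scan: an ordered
#' marker map plus a strains x markers matrix of allele calls drawn from
#' `B` (C57BL/6J-derived), `D` (DBA/2J-derived), `H` (residual heterozygote)
#' and `U` (unknown).
#'
#' @param strains character vector of unique strain names.
#' @param markers data frame with columns `marker`, `chr`, `pos_mb` and
#'   optionally `cm`; must be sorted by chromosome (order of first
#'   appearance) and non-decreasing position within chromosome.
#' @param calls character matrix, strains x markers, entries in
#'   `c("B","D","H","U")`.
#' @return An object of class `"ri_geno"`: a list with elements `strains`,
#'   `markers`, `calls` and `n` (number of strains).
#' @examples
#' mk <- data.frame(marker = c("m1", "m2"), chr = "1", pos_mb = c(10, 20))
#' g <- ri_geno(c("BXD1", "BXD2"), mk,
#'              matrix(c("B", "D", "D", "B"), 2, 2))
#' g$n
#' @export
ri_geno <- function(strains, markers, calls) {
  strains <- as.character(strains)
  if (anyDuplicated(strains)) stop("duplicate strain names")
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  need <- c("marker", "chr", "pos_mb")
  if (!all(need %in% names(markers)))
    stop("markers must have columns marker, chr, pos_mb")
  markers$marker <- as.character(markers$marker)
  markers$chr <- as.character(markers$chr)
  markers$pos_mb <- as.numeric(markers$pos_mb)
  if (anyDuplicated(markers$marker)) stop("duplicate marker ids")
  if (any(!is.finite(markers$pos_mb)) || any(markers$pos_mb < 0))
    stop("marker positions must be finite and >= 0")
  # sortedness: chromosomes contiguous in order of first appearance,
  # positions non-decreasing within each chromosome
  lev <- unique(markers$chr)
  r <- match(markers$chr, lev)
  if (is.unsorted(r)) stop("markers not grouped by chromosome")
  for (cc in lev) {
    p <- markers$pos_mb[markers$chr == cc]
    if (is.unsorted(p)) stop("marker positions not sorted on chromosome ", cc)
  }
  calls <- as.matrix(calls)
  if (nrow(calls) != length(strains) || ncol(calls) != nrow(markers))
    stop("calls must be strains x markers (",
         length(strains), " x ", nrow(markers), ")")
  bad <- !(calls %in% c("B", "D", "H", "U"))
  if (any(bad)) stop("invalid genotype call(s): ",
                     paste(unique(calls[bad]), collapse = ", "))
  dimnames(calls) <- list(strains, markers$marker)
  structure(list(strains = strains, markers = markers, calls = calls,
                 n = length(strains)),
            class = "ri_geno")
}

#' @export
print.ri_geno <- function(x, ...) {
  cat("RI panel genotypes: ", x$n, " strains, ", nrow(x$markers),
      " markers on ", length(unique(x$markers$chr)), " chromosome(s)\n",
      sep = "")
  tb <- table(factor(x$calls, levels = c("B", "D", "H", "U")))
  cat("calls: ", paste(names(tb), tb, sep = "=", collapse = "  "), "\n",
      sep = "")
  invisible(x)
}

#' Numeric genotype coding for regression
#'
#' Codes calls as B = -1, H = 0, D = +1 and U = NA (dropped pairwise by the
#' scan). RI strains are nearly fully homozygous, so no dominance term is
#' modelled.
#'
#' @param geno an [ri_geno()] object.
#' @return numeric strains x markers matrix.
#' @export
geno_codes <- function(geno) {
  stopifnot(inherits(geno, "ri_geno"))
  m <- matrix(NA_real_, nrow = geno$n, ncol = nrow(geno$markers),
              dimnames = dimnames(geno$calls))
  m[geno$calls == "B"] <- -1
  m[geno$calls == "H"] <- 0
  m[geno$calls == "D"] <- 1
  m
}

#' Read a GeneNetwork-style .geno file
#'
#' The dialect is tab-separated: optional `@`-prefixed metadata lines and
#' `#` comments, then a header row `Chr Locus [cM] [Mb] strain1 strain2 ...`
#' followed by one row per marker. Unknown calls (`U`) are preserved, never
#' imputed.
#'
#' @param path path to the file.
#' @return an [ri_geno()] object.
#' @export
read_genotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^\\s*(@|#|$)", lines)
  idx <- which(keep)
  if (length(idx) < 2L) stop("no marker rows in ", path)
  split_tab <- function(s) strsplit(s, "\t", fixed = TRUE)[[1L]]
  hdr <- split_tab(lines[idx[1L]])
  low <- tolower(hdr)
  c_chr <- match("chr", low)
  c_loc <- match("locus", low)
  c_cm <- match("cm", low)
  c_mb <- match("mb", low)
  if (is.na(c_chr) || is.na(c_loc))
    stop("header must contain Chr and Locus columns: ", path)
  if (is.na(c_mb) && is.na(c_cm))
    stop("header must contain an Mb or cM position column: ", path)
  meta_cols <- stats::na.omit(c(c_chr, c_loc, c_cm, c_mb))
  strain_cols <- setdiff(seq_along(hdr), meta_cols)
  if (length(strain_cols) < 1L) stop("no strain columns in ", path)
  strains <- hdr[strain_cols]

  n_mk <- length(idx) - 1L
  marker <- chr <- character(n_mk)
  pos_mb <- cm <- rep(NA_real_, n_mk)
  calls <- matrix(NA_character_, nrow = length(strains), ncol = n_mk)
  for (i in seq_len(n_mk)) {
    ln <- idx[i + 1L]
    f <- split_tab(lines[ln])
    if (length(f) != length(hdr))
      stop("line ", ln, ": expected ", length(hdr), " fields, got ", length(f))
    marker[i] <- f[c_loc]
    chr[i] <- f[c_chr]
    if (!is.na(c_mb)) {
      pos_mb[i] <- suppressWarnings(as.numeric(f[c_mb]))
      if (is.na(pos_mb[i])) stop("line ", ln, ": non-numeric Mb position")
    }
    if (!is.na(c_cm)) {
      cm[i] <- suppressWarnings(as.numeric(f[c_cm]))
      if (is.na(cm[i])) stop("line ", ln, ": non-numeric cM position")
    }
    cl <- f[strain_cols]
    bad <- !(cl %in% c("B", "D", "H", "U"))
    if (any(bad))
      stop("line ", ln, ": invalid call(s) ",
           paste(unique(cl[bad]), collapse = ", "), " for marker ", marker[i])
    calls[, i] <- cl
  }
  if (anyDuplicated(marker))
    stop("duplicate marker id(s): ",
         paste(unique(marker[duplicated(marker)]), collapse = ", "))
  if (all(is.na(pos_mb))) pos_mb <- cm  # cM-only maps: reuse cM as position
  mk <- data.frame(marker = marker, chr = chr, pos_mb = pos_mb,
                   stringsAsFactors = FALSE)
  if (!all(is.na(cm))) mk$cm <- cm
  ri_geno(strains, mk, calls)
}

#' Write a GeneNetwork-style .geno file
#'
#' @param geno an [ri_geno()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "ri_geno"))
  has_cm <- "cm" %in% names(geno$markers)
  hdr <- c("Chr", "Locus", if (has_cm) "cM", "Mb", geno$strains)
  rows <- vapply(seq_len(nrow(geno$markers)), function(i) {
    paste(c(geno$markers$chr[i], geno$markers$marker[i],
            if (has_cm) format(geno$markers$cm[i], digits = 15),
            format(geno$markers$pos_mb[i], digits = 15),
            geno$calls[, i]),
          collapse = "\t")
  }, character(1L))
  writeLines(c("@type:riset", paste(hdr, collapse = "\t"), rows), path)
  invisible(path)
}
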