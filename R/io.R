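#' Expression panel container
#'
#' Holds a probes-or-probe-sets x (strain, replicate) matrix of log2
#' intensities. Replicate columns are named `<strain>.r<k>` on disk; a bare
#' strain name means a single replicate.
#'
#' @param values numeric matrix with row ids as rownames; columns are
#'   (strain, replicate) pairs.
#' @param strains character vector, one entry per column: the strain each
#'   column belongs to.
#' @param reps integer vector, one entry per column: replicate index,
#'   contiguous from 1 within each strain.
#' @param scale expression scale tag, `"raw_log2"` or `"standardized_2z8"`.
#' @return an object of class `"expr_panel"`.
#' @export
expr_panel <- function(values, strains = colnames(values),
                       reps = rep(1L, ncol(values)),
                       scale = c("raw_log2", "standardized_2z8")) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  strains <- as.character(strains)
  reps <- as.integer(reps)
  if (length(strains) != ncol(values) || length(reps) != ncol(values))
    stop("strains/reps must have one entry per column")
  if (length(unique(strains)) < 2L) stop("need at least 2 strains")
  for (s in unique(strains)) {
    r <- sort(reps[strains == s])
    if (!identical(r, seq_along(r)))
      stop("replicate indices not contiguous from 1 for strain ", s)
  }
  if (is.null(rownames(values))) stop("values must have row ids as rownames")
  colnames(values) <- ifelse(ave(reps, strains, FUN = max)[seq_along(reps)] > 1L,
                             paste0(strains, ".r", reps), strains)
  structure(list(values = values, strains = strains, reps = reps,
                 scale = scale),
            class = "expr_panel")
}

#' @export
print.expr_panel <- function(x, ...) {
  cat("expression panel: ", nrow(x$values), " rows x ",
      length(unique(x$strains)), " strains (", ncol(x$values),
      " arrays), scale=", x$scale, "\n", sep = "")
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Column 1 holds row ids; remaining headers are strain names, optionally
#' suffixed `.r<k>` for replicates. Cells are log2 intensities; `.` denotes
#' missing. Any other non-numeric cell is rejected with its coordinates.
#'
#' @param path path to the TSV file.
#' @param scale expression scale tag recorded on the result; defaults to
#'   `"raw_log2"`.
#' @return an [expr_panel()].
#' @export
read_expression <- function(path, scale = "raw_log2") {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) < 3L) stop("expected row ids plus >=2 strain columns: ", path)
  ids <- tab[[1L]]
  hdr <- colnames(tab)[-1L]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(ifelse(raw == ".", NA, raw)),
                                dim = dim(raw)))
  bad <- is.na(num) & raw != "." & raw != ""
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1L, ]
    stop("non-numeric cell at row '", ids[w[1L]], "', column '",
         hdr[w[2L]], "': '", raw[w[1L], w[2L]], "'")
  }
  rownames(num) <- ids
  rep_match <- regmatches(hdr, regexec("^(.*)\\.r([0-9]+)$", hdr))
  strains <- vapply(seq_along(hdr), function(i) {
    if (length(rep_match[[i]])) rep_match[[i]][2L] else hdr[i]
  }, character(1L))
  reps <- vapply(seq_along(hdr), function(i) {
    if (length(rep_match[[i]])) as.integer(rep_match[[i]][3L]) else 1L
  }, integer(1L))
  expr_panel(num, strains = strains, reps = reps, scale = scale)
}

#' Write an expression panel as TSV
#'
#' @param panel an [expr_panel()].
#' @param path output path.
#' @param digits significant digits used when printing values.
#' @return `path`, invisibly.
#' @export
write_expression <- function(panel, path, digits = 10) {
  stopifnot(inherits(panel, "expr_panel"))
  v <- panel$values
  body <- cbind(rownames(v),
                matrix(ifelse(is.na(v), ".",
                              formatC(v, digits = digits, format = "g")),
                       nrow = nrow(v)))
  lines <- c(paste(c("id", colnames(v)), collapse = "\t"),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

.regions <- c("coding_exon", "proximal_3utr", "mid_3utr", "distal_3utr",
              "intron", "5utr")

#' Read a probe annotation table
#'
#' TSV with columns `probe_id`, `probeset_id`, `gene_symbol`, `region`,
#' `overlaps_variant` (0/1 or TRUE/FALSE), `chr`, `pos_mb`. The region label
#' must come from the closed vocabulary `coding_exon`, `proximal_3utr`,
#' `mid_3utr`, `distal_3utr`, `intron`, `5utr`.
#'
#' @param path path to the TSV file.
#' @return data frame of probe annotations, one row per probe.
#' @export
read_probe_annotation <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  an <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "probeset_id", "gene_symbol", "region",
            "overlaps_variant", "chr", "pos_mb")
  miss <- setdiff(need, names(an))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  validate_probe_annotation(an)
}

validate_probe_annotation <- function(an) {
  if (anyDuplicated(an$probe_id))
    stop("probe ids not unique: ",
         paste(unique(an$probe_id[duplicated(an$probe_id)]), collapse = ", "))
  bad <- !(an$region %in% .regions)
  if (any(bad))
    stop("unknown region label(s): ", paste(unique(an$region[bad]),
                                            collapse = ", "))
  an$overlaps_variant <- as.logical(an$overlaps_variant) |
    (an$overlaps_variant %in% c(1, "1"))
  an$pos_mb <- as.numeric(an$pos_mb)
  an
}

#' Write a probe annotation table
#' @param annot probe annotation data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_probe_annotation <- function(annot, path) {
  annot$overlaps_variant <- as.integer(annot$overlaps_variant)
  utils::write.table(annot, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene annotations from a BED file
#'
#' BED uses 0-based half-open base-pair coordinates; they are converted to
#' decimal megabases (`start_mb = start_bp/1e6`, `end_mb = end_bp/1e6`), the
#' unit used throughout the package. Strand is taken from column 6 when
#' present, otherwise `"unknown"`; a leading `chr` prefix on the chromosome
#' is stripped.
#'
#' @param path path to the BED file (3+ columns).
#' @return data frame with columns `symbol`, `chr`, `start_mb`, `end_mb`,
#'   `strand`.
#' @export
read_gene_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#|\\s*$)", lines)]
  if (!length(lines)) stop("no features in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) stop("BED line with fewer than 3 fields: line ",
                           which(ncol < 3L)[1L])
  get <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1L))
  chr <- sub("^chr", "", get(1L))
  start_bp <- suppressWarnings(as.numeric(get(2L)))
  end_bp <- suppressWarnings(as.numeric(get(3L)))
  if (any(is.na(start_bp) | is.na(end_bp)))
    stop("non-numeric BED coordinates at line ",
         which(is.na(start_bp) | is.na(end_bp))[1L])
  if (any(start_bp >= end_bp))
    stop("zero-length or inverted feature at line ",
         which(start_bp >= end_bp)[1L])
  symbol <- get(4L)
  symbol[is.na(symbol) | symbol == "." | symbol == ""] <-
    paste0("feature_", which(is.na(symbol) | symbol == "." | symbol == ""))
  strand <- get(6L)
  strand[!(strand %in% c("+", "-"))] <- "unknown"
  if (anyDuplicated(symbol))
    stop("duplicate gene symbol(s): ",
         paste(unique(symbol[duplicated(symbol)]), collapse = ", "))
  data.frame(symbol = symbol, chr = chr,
             start_mb = start_bp / 1e6, end_mb = end_bp / 1e6,
             strand = strand, stringsAsFactors = FALSE)
}

#' Write gene annotations as BED
#' @param genes data frame as returned by [read_gene_bed()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_bed <- function(genes, path) {
  strand <- ifelse(genes$strand %in% c("+", "-"), genes$strand, ".")
  lines <- paste(genes$chr,
                 format(round(genes$start_mb * 1e6), scientific = FALSE,
                        trim = TRUE),
                 format(round(genes$end_mb * 1e6), scientific = FALSE,
                        trim = TRUE),
                 genes$symbol, 0, strand, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
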