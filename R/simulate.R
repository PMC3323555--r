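#' Default marker map for a simulated RI panel
#'
#' A desk-scale stand-in for a dense RI genotype map: evenly spaced markers
#' on equally sized chromosomes, with both physical (Mb) and genetic (cM)
#' positions. The default (10 chromosomes x 20 markers at 5 Mb / 2.5 cM
#' spacing) gives genome-wide permutation-significant LRS thresholds in the
#' mid-teens, comparable to dense-map RI panels.
#'
#' @param n_chr number of chromosomes.
#' @param markers_per_chr markers per chromosome (>= 2).
#' @param spacing_mb physical gap between adjacent markers, megabases.
#' @param cm_per_mb genetic-to-physical ratio (cM per Mb; ~0.5 in mouse).
#' @return data frame with columns `marker`, `chr`, `pos_mb`, `cm`.
#' @export
default_marker_map <- function(n_chr = 10, markers_per_chr = 20,
                               spacing_mb = 5, cm_per_mb = 0.5) {
  stopifnot(n_chr >= 1, markers_per_chr >= 2, spacing_mb > 0)
  chr <- rep(as.character(seq_len(n_chr)), each = markers_per_chr)
  idx <- rep(seq_len(markers_per_chr), n_chr)
  pos <- (idx - 1) * spacing_mb
  data.frame(marker = sprintf("M%s_%02d", chr, idx), chr = chr,
             pos_mb = pos, cm = pos * cm_per_mb, stringsAsFactors = FALSE)
}

#' Default gene set for the simulator
#'
#' Eight genes spread over the first chromosomes of the default map, each
#' 0.06 Mb long: a miniature panel of co-regulated receptor-subunit-like
#' genes suitable for planting cis eQTLs, shared trans loci and a
#' coexpression module.
#'
#' @param map marker map, as from [default_marker_map()].
#' @param n_genes number of genes.
#' @return data frame with columns `symbol`, `chr`, `start_mb`, `end_mb`.
#' @export
default_gene_table <- function(map = default_marker_map(), n_genes = 8) {
  chrs <- unique(map$chr)
  chr <- chrs[((seq_len(n_genes) - 1L) %% length(chrs)) + 1L]
  pos <- vapply(seq_len(n_genes), function(i) {
    p <- map$pos_mb[map$chr == chr[i]]
    p[1L + ((3L * i) %% (length(p) - 2L))] + 1.2  # offset from the marker
  }, numeric(1L))
  data.frame(symbol = sprintf("gene%02d", seq_len(n_genes)), chr = chr,
             start_mb = pos, end_mb = pos + 0.06, stringsAsFactors = FALSE)
}

#' Architecture of a simulated expression panel
#'
#' Collects every knob of the generative model: panel size, marker map,
#' genes with planted cis effects, trans loci with per-region effects, a
#' latent coexpression module, variance components and the SNP-overlap
#' hybridization artifact. Defaults are the package's reference study
#' conditions (70 strains, 3 replicates, sigma_g = 0.2 and sigma_e = 0.3
#' log2 units, 11 probes per probe set with 3 variant-overlapping probes in
#' affected sets, artifact depth delta = 1 log2 unit).
#'
#' @param n_strains number of RI strains (>= 2).
#' @param n_replicates arrays per strain.
#' @param map marker map data frame (`marker`, `chr`, `pos_mb`, `cm`).
#' @param genes gene table (`symbol`, `chr`, `start_mb`, `end_mb`); optional
#'   columns `cis_effect` (additive effect a in log2 units, default 0),
#'   `h2_target` (planted broad-sense heritability, default NA = use
#'   `sigma_g` directly) and `module_loading` (default 0).
#' @param trans_loci list of trans effects, each
#'   `list(marker =, targets = data.frame(symbol, region, effect))`;
#'   `region = NA` applies the effect to every probe set of the gene.
#' @param module `NULL`, or `list(marker =, effect =, sd =)`: a latent
#'   factor `f = effect * g(marker) + N(0, sd)` entering each gene scaled by
#'   its `module_loading`.
#' @param sigma_g polygenic strain SD (log2 units), used when `h2_target`
#'   is NA.
#' @param sigma_e replicate (array) noise SD per probe (log2 units).
#' @param delta artifact depth: log2 signal lost by a variant-overlapping
#'   probe in strains carrying the D allele at the probe's locus (probes are
#'   designed against the B6 reference sequence).
#' @param probes_per_set probes per probe set.
#' @param regions transcript regions targeted per gene; each gene gets one
#'   probe set per region.
#' @param variant_genes symbols whose probe sets contain
#'   `n_variant_probes` variant-overlapping probes each.
#' @param n_variant_probes flagged probes per affected probe set.
#' @param seed base random seed recorded in all outputs.
#' @return object of class `"architecture_spec"`.
#' @export
architecture_spec <- function(n_strains = 70, n_replicates = 3,
                              map = default_marker_map(),
                              genes = default_gene_table(map),
                              trans_loci = list(), module = NULL,
                              sigma_g = 0.2, sigma_e = 0.3, delta = 1.0,
                              probes_per_set = 11,
                              regions = c("coding_exon", "proximal_3utr",
                                          "distal_3utr"),
                              variant_genes = character(),
                              n_variant_probes = 3, seed = 1L) {
  if (n_strains < 2) stop("n_strains must be >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (sigma_g < 0 || sigma_e < 0 || delta < 0)
    stop("sigma_g, sigma_e and delta must be >= 0")
  if (min(table(map$chr)) < 2) stop("need >= 2 markers per chromosome")
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!"cis_effect" %in% names(genes)) genes$cis_effect <- 0
  if (!"h2_target" %in% names(genes)) genes$h2_target <- NA_real_
  if (!"module_loading" %in% names(genes)) genes$module_loading <- 0
  if (any(!is.finite(genes$cis_effect))) stop("cis effects must be finite")
  for (tl in trans_loci) {
    if (!tl$marker %in% map$marker)
      stop("trans locus marker not in map: ", tl$marker)
    if (!all(tl$targets$symbol %in% genes$symbol))
      stop("trans target not in gene list: ",
           paste(setdiff(tl$targets$symbol, genes$symbol), collapse = ", "))
    if (any(!is.finite(tl$targets$effect)))
      stop("trans effects must be finite")
  }
  if (!is.null(module) && !module$marker %in% map$marker)
    stop("module marker not in map: ", module$marker)
  if (!all(variant_genes %in% genes$symbol))
    stop("variant_genes not in gene list")
  if (length(variant_genes) && n_variant_probes > probes_per_set)
    stop("n_variant_probes cannot exceed probes_per_set")
  structure(list(n_strains = as.integer(n_strains),
                 n_replicates = as.integer(n_replicates),
                 map = map, genes = genes, trans_loci = trans_loci,
                 module = module, sigma_g = sigma_g, sigma_e = sigma_e,
                 delta = delta, probes_per_set = as.integer(probes_per_set),
                 regions = regions, variant_genes = variant_genes,
                 n_variant_probes = as.integer(n_variant_probes),
                 seed = as.integer(seed)),
            class = "architecture_spec")
}

# Haldane map function: recombination fraction from a map distance in cM.
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

# Haldane-Waterman map expansion for sib-mated RI strains: the fixed
# recombinant fraction between adjacent markers is R = 4r/(1+6r).
ri_expansion <- function(r) 4 * r / (1 + 6 * r)

#' Simulate genotypes of a sib-mated RI panel
#'
#' Each strain is an independent first-order Markov mosaic of the two
#' parental alleles along every chromosome: the first marker is B or D with
#' probability 1/2, and adjacent markers recombine with probability
#' `R = 4r/(1+6r)` (the sib-mated RI map expansion), where `r` comes from
#' Haldane's map function on the cM gap. Strains are fully inbred, so no H
#' calls are produced.
#'
#' @param spec an [architecture_spec()].
#' @param seed random seed; defaults to `spec$seed`.
#' @return an [ri_geno()] object.
#' @export
simulate_ri_genotypes <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  n <- spec$n_strains
  map <- spec$map
  if (!"cm" %in% names(map)) stop("marker map needs a cM column")
  calls <- matrix(NA_character_, nrow = n, ncol = nrow(map))
  for (cc in unique(map$chr)) {
    j <- which(map$chr == cc)
    al <- matrix(NA_integer_, nrow = n, ncol = length(j))
    al[, 1L] <- stats::rbinom(n, 1L, 0.5)
    if (length(j) > 1L) {
      gaps <- diff(map$cm[j])
      R <- ri_expansion(haldane_r(gaps))
      for (k in seq_along(gaps)) {
        flip <- stats::rbinom(n, 1L, R[k])
        al[, k + 1L] <- bitwXor(al[, k], flip)
      }
    }
    calls[, j] <- ifelse(al == 1L, "D", "B")
  }
  ri_geno(sprintf("RI%03d", seq_len(n)), map, calls)
}

# Total genetic variance that makes the broad-sense estimator
# h2 = Var(strain means)/Var(all measurements) hit a target:
#   E Var(strain means) = G + sigma_e^2 / r    (r replicates)
#   E Var(all)          = G + sigma_e^2
# so  h2 = (G + se2/r)/(G + se2)  =>  G = se2 * (h2 - 1/r) / (1 - h2).
# Only attainable for h2 > 1/r (with one replicate the estimator is
# identically 1). The polygenic variance is G minus the planted fixed-effect
# variances.
solve_genetic_variance <- function(h2, sigma_e, n_replicates) {
  if (h2 <= 1 / n_replicates || h2 >= 1)
    stop("h2_target must lie in (1/n_replicates, 1); got ", h2,
         " with ", n_replicates, " replicate(s)")
  sigma_e^2 * (h2 - 1 / n_replicates) / (1 - h2)
}

#' Simulate a probe-level expression panel with planted architecture
#'
#' Generates log2 probe intensities under the additive model
#' `y = mu_p + a_cis g(cis) + sum a_trans g(trans) + lambda f + u + e -
#' delta 1[variant probe & D at probe locus]`, with genotypes coded
#' B = -1, D = +1, a per-gene polygenic strain term `u ~ N(0, sigma_g^2)`,
#' array noise `e ~ N(0, sigma_e^2)` per probe and replicate, and a
#' hybridization artifact that subtracts `delta` from variant-overlapping
#' probes in D-carrying strains. Each gene gets one probe set per region in
#' `spec$regions`; the cis locus is the marker nearest the gene midpoint.
#'
#' When a gene carries an `h2_target`, its polygenic SD is solved so that
#' the population value of the broad-sense estimator
#' Var(strain means)/Var(all measurements) equals the target (see
#' `solve_genetic_variance()` in the source for the algebra).
#'
#' @param geno an [ri_geno()] panel, typically from
#'   [simulate_ri_genotypes()].
#' @param spec the [architecture_spec()] used to generate `geno`.
#' @param seed random seed; defaults to `spec$seed + 1`.
#' @return list with elements `expr` (probe-level [expr_panel()]), `annot`
#'   (probe annotation data frame) and `truth` (planted-architecture list,
#'   JSON-serializable; see [write_truth()]).
#' @export
simulate_expression_panel <- function(geno, spec, seed = spec$seed + 1L) {
  stopifnot(inherits(geno, "ri_geno"), inherits(spec, "architecture_spec"))
  set.seed(seed)
  n <- geno$n
  r <- spec$n_replicates
  g <- geno_codes(geno)
  genes <- spec$genes
  var_g <- 1  # theoretical Var of +/-1 coding at allele frequency 1/2

  # cis marker: nearest map marker on the gene's chromosome
  cis_marker <- vapply(seq_len(nrow(genes)), function(i) {
    j <- which(spec$map$chr == genes$chr[i])
    if (!length(j)) stop("gene ", genes$symbol[i],
                         " lies on a chromosome with no markers")
    mid <- (genes$start_mb[i] + genes$end_mb[i]) / 2
    spec$map$marker[j[which.min(abs(spec$map$pos_mb[j] - mid))]]
  }, character(1L))

  # module latent factor (strain-level)
  f <- rep(0, n)
  var_f <- 0
  if (!is.null(spec$module)) {
    f <- spec$module$effect * g[, spec$module$marker] +
      stats::rnorm(n, 0, spec$module$sd)
    var_f <- spec$module$effect^2 * var_g + spec$module$sd^2
  }

  # per-gene trans effect bundles
  trans_for <- function(sym) {
    out <- list()
    for (tl in spec$trans_loci) {
      tt <- tl$targets[tl$targets$symbol == sym, , drop = FALSE]
      if (nrow(tt)) for (k in seq_len(nrow(tt)))
        out[[length(out) + 1L]] <- list(marker = tl$marker,
                                        region = tt$region[k],
                                        effect = tt$effect[k])
    }
    out
  }

  n_sets_per_gene <- length(spec$regions)
  p_per_set <- spec$probes_per_set
  n_probes <- nrow(genes) * n_sets_per_gene * p_per_set
  strain_level <- matrix(0, nrow = n_probes, ncol = n)
  probe_id <- probeset_id <- gene_symbol <- region <- character(n_probes)
  overlaps <- logical(n_probes)
  chr <- character(n_probes)
  pos_mb <- numeric(n_probes)
  truth_genes <- vector("list", nrow(genes))

  row <- 0L
  for (i in seq_len(nrow(genes))) {
    sym <- genes$symbol[i]
    tr <- trans_for(sym)
    # variance planted by fixed effects shared by all regions of the gene
    v_shared <- genes$cis_effect[i]^2 * var_g +
      genes$module_loading[i]^2 * var_f +
      sum(vapply(tr, function(t)
        if (is.na(t$region)) t$effect^2 * var_g else 0, numeric(1L)))
    if (!is.na(genes$h2_target[i])) {
      G <- solve_genetic_variance(genes$h2_target[i], spec$sigma_e, r)
      if (G < v_shared)
        stop("h2_target for ", sym,
             " is below the variance already planted by its effects")
      sg <- sqrt(G - v_shared)
    } else {
      sg <- spec$sigma_g
    }
    u <- stats::rnorm(n, 0, sg)
    base <- genes$cis_effect[i] * g[, cis_marker[i]] +
      genes$module_loading[i] * f + u
    for (tt in tr) if (is.na(tt$region))
      base <- base + tt$effect * g[, tt$marker]

    gene_mid <- (genes$start_mb[i] + genes$end_mb[i]) / 2
    d_at_locus <- geno$calls[, cis_marker[i]] == "D"
    affected <- sym %in% spec$variant_genes
    mu_set <- stats::runif(n_sets_per_gene, 8, 12)
    for (s in seq_len(n_sets_per_gene)) {
      rg <- spec$regions[s]
      set_prof <- base
      for (tt in tr) if (!is.na(tt$region) && tt$region == rg)
        set_prof <- set_prof + tt$effect * g[, tt$marker]
      ps <- paste0(sym, "_", rg)
      mu_p <- mu_set[s] + stats::rnorm(p_per_set, 0, 0.15)
      flag <- rep(FALSE, p_per_set)
      if (affected && spec$n_variant_probes > 0)
        flag[seq_len(spec$n_variant_probes)] <- TRUE
      for (p in seq_len(p_per_set)) {
        row <- row + 1L
        probe_id[row] <- sprintf("%s_p%02d", ps, p)
        probeset_id[row] <- ps
        gene_symbol[row] <- sym
        region[row] <- rg
        overlaps[row] <- flag[p]
        chr[row] <- genes$chr[i]
        pos_mb[row] <- gene_mid
        strain_level[row, ] <- mu_p[p] + set_prof -
          if (flag[p]) spec$delta * as.numeric(d_at_locus) else 0
      }
    }
    G_g <- v_shared + sg^2
    truth_genes[[i]] <- list(
      symbol = sym, chr = genes$chr[i],
      cis_marker = cis_marker[i], cis_effect = genes$cis_effect[i],
      trans = lapply(tr, function(t)
        list(marker = t$marker,
             region = if (is.na(t$region)) "all" else t$region,
             effect = t$effect)),
      module_loading = genes$module_loading[i],
      sigma_g_used = sg,
      h2 = if (r > 1) (G_g + spec$sigma_e^2 / r) / (G_g + spec$sigma_e^2)
           else 1.0)
  }

  # expand strains to replicate arrays and add per-array probe noise
  col_strain <- rep(seq_len(n), each = r)
  values <- strain_level[, col_strain, drop = FALSE] +
    matrix(stats::rnorm(n_probes * n * r, 0, spec$sigma_e),
           nrow = n_probes)
  rownames(values) <- probe_id
  expr <- expr_panel(values, strains = geno$strains[col_strain],
                     reps = rep(seq_len(r), n), scale = "raw_log2")

  annot <- data.frame(probe_id = probe_id, probeset_id = probeset_id,
                      gene_symbol = gene_symbol, region = region,
                      overlaps_variant = overlaps, chr = chr,
                      pos_mb = pos_mb, stringsAsFactors = FALSE)
  truth <- list(seed = seed, n_strains = n, n_replicates = r,
                sigma_e = spec$sigma_e, delta = spec$delta,
                genes = truth_genes,
                artifact_probes = probe_id[overlaps],
                module = if (is.null(spec$module)) NULL else
                  list(marker = spec$module$marker,
                       effect = spec$module$effect, sd = spec$module$sd,
                       genes = genes$symbol[genes$module_loading != 0]))
  list(expr = expr, annot = annot, truth = truth)
}

#' Write / read the planted-architecture truth table
#'
#' The truth table emitted by [simulate_expression_panel()] is plain nested
#' lists of scalars and therefore round-trips exactly through JSON.
#'
#' @param truth truth list.
#' @param path output path.
#' @return `path` (write) or the truth list (read).
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}
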