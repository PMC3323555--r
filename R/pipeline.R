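#' Demo architecture for the end-to-end pipeline
#'
#' A small but fully featured study design: three cis-regulated genes, one
#' shared trans locus with opposite-sign region-specific effects on the
#' distal 3' UTRs of two genes, a four-gene coexpression module driven by a
#' trans marker, and two genes whose probe sets carry variant-overlapping
#' probes.
#'
#' @param seed base seed recorded in the spec.
#' @return an [architecture_spec()].
#' @export
demo_architecture <- function(seed = 1L) {
  map <- default_marker_map()
  genes <- default_gene_table(map)
  # two cis-regulated genes inside the trans-QTL interval (M5_10 @ 45 Mb),
  # candidate regulators for the prioritization stage
  genes <- rbind(genes,
                 data.frame(symbol = c("gene09", "gene10"), chr = "5",
                            start_mb = c(45.3, 48.6),
                            end_mb = c(45.4, 48.7)))
  genes$cis_effect <- c(0.8, 0.6, 1.0, 0, 0, 0, 0, 0, 0.9, 0.7)
  genes$module_loading <- c(0, 0, 0, 0, 0.8, 0.9, 0.7, 0.8, 0, 0)
  trans <- list(list(
    marker = "M5_10",
    targets = data.frame(symbol = c("gene01", "gene02", "gene04"),
                         region = c("distal_3utr", "distal_3utr", NA),
                         effect = c(0.5, -0.5, 0.45),
                         stringsAsFactors = FALSE)))
  architecture_spec(map = map, genes = genes, trans_loci = trans,
                    module = list(marker = "M7_05", effect = 0.5, sd = 0.3),
                    variant_genes = c("gene02", "gene07"), seed = seed)
}

#' Read a flat key = value run configuration
#'
#' One `key = value` (or `key<TAB>value`) pair per line; `#` comments and
#' blank lines ignored; values that parse as numbers are numeric.
#'
#' @param path path to the config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(sub("=", "\t", ln), "\t")[[1L]]
    if (length(kv) < 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "\t"))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Per-probe-set replicate-level means
#'
#' Averages probes within each array so that heritability can be estimated
#' from probe-set values at the replicate level.
#'
#' @param expr probe-level [expr_panel()].
#' @param annot probe annotation covering the panel.
#' @return an [expr_panel()] with one row per probe set.
#' @export
probeset_replicate_means <- function(expr, annot) {
  an <- annot[match(rownames(expr$values), annot$probe_id), ]
  sets <- unique(an$probeset_id)
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr$values),
                dimnames = list(sets, colnames(expr$values)))
  for (s in sets)
    out[s, ] <- colMeans(expr$values[an$probeset_id == s, , drop = FALSE])
  expr_panel(out, strains = expr$strains, reps = expr$reps,
             scale = expr$scale)
}

#' Strongest cis LRS of a gene
#'
#' Maximum LRS among the markers within `window_mb` of the gene span on the
#' gene's own chromosome (0 when no marker falls in the window).
#'
#' @param profile named strain-mean trait vector.
#' @param geno an [ri_geno()] panel.
#' @param gene single-row gene annotation.
#' @param window_mb cis window, megabases.
#' @return numeric LRS.
#' @export
cis_lrs <- function(profile, geno, gene, window_mb = 10) {
  curve <- eqtl_scan(profile, geno)
  near <- curve$chr == gene$chr &
    curve$pos_mb >= gene$start_mb - window_mb &
    curve$pos_mb <= gene$end_mb + window_mb
  if (!any(near)) return(0)
  max(curve$lrs[near])
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — simulate, preprocess, heritability, map,
#' network, candidates — writing every artifact to `out_dir` together with
#' a provenance record sufficient to re-run the configuration exactly.
#' Outputs are written with a `.partial` suffix and renamed on stage
#' success, so a failed stage leaves its partial files visible. With a
#' fixed configuration and seed the output files are byte-identical across
#' runs.
#'
#' Recognized configuration keys (flat list or [read_run_config()] file):
#' `seed` (required), `out_dir` (required), `stages` (comma-separated,
#' default `"all"`), `n_perm` (default 1000), `expression_floor` (8),
#' `lrs_gate` (15), `r_floor` (0.3), `cis_window_mb` (10),
#' `half_width_mb` (5). The simulate stage uses [demo_architecture()]
#' unless an `architecture_spec` is passed as the `spec` element.
#'
#' @param config named list or path to a flat config file.
#' @return provenance list, invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (is.null(config$seed)) stop("config must set a seed")
  if (is.null(config$out_dir)) stop("config must set out_dir")
  seed <- as.integer(config$seed)
  out_dir <- config$out_dir
  stages <- config$stages %||% "all"
  if (identical(stages, "all"))
    stages <- c("simulate", "preprocess", "heritability", "map",
                "network", "candidates")
  else if (is.character(stages) && length(stages) == 1L)
    stages <- strsplit(stages, ",")[[1L]]
  n_perm <- as.integer(config$n_perm %||% 1000)
  floor_expr <- config$expression_floor %||% 8
  lrs_gate <- config$lrs_gate %||% 15
  r_floor <- config$r_floor %||% 0.3
  cis_window <- config$cis_window_mb %||% 10
  half_width <- config$half_width_mb %||% 5
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  path <- function(f) file.path(out_dir, f)
  finish <- function(files) for (f in files)
    stopifnot(file.rename(paste0(path(f), ".partial"), path(f)))

  # --- simulate -------------------------------------------------------
  if ("simulate" %in% stages) {
    spec <- config$spec %||% demo_architecture(seed)
    geno <- simulate_ri_genotypes(spec, seed = seed)
    panel <- simulate_expression_panel(geno, spec, seed = seed + 1L)
    genes <- spec$genes
    write_genotypes(geno, paste0(path("panel.geno"), ".partial"))
    write_expression(panel$expr, paste0(path("expression.tsv"), ".partial"))
    write_probe_annotation(panel$annot,
                           paste0(path("probe_annotation.tsv"), ".partial"))
    write_truth(panel$truth, paste0(path("truth.json"), ".partial"))
    write_gene_bed(genes, paste0(path("genes.bed"), ".partial"))
    finish(c("panel.geno", "expression.tsv", "probe_annotation.tsv",
             "truth.json", "genes.bed"))
    expr <- panel$expr; annot <- panel$annot
  } else {
    for (key in c("geno", "expression", "probe_annotation", "genes")) {
      p <- config[[key]]
      if (is.null(p)) stop("config must set input path '", key, "'")
      if (!file.exists(p)) stop("missing input path: ", p)
    }
    geno <- read_genotypes(config$geno)
    expr <- read_expression(config$expression)
    annot <- read_probe_annotation(config$probe_annotation)
    genes <- read_gene_bed(config$genes)
  }

  # --- preprocess -----------------------------------------------------
  filt <- filter_snp_probes(expr, annot)
  removed_counts <- table(annot$probeset_id[annot$probe_id %in% filt$removed])
  summ <- summarize_panel(filt$expr, annot, floor = floor_expr,
                          removed_counts = removed_counts)
  if ("preprocess" %in% stages) {
    tab <- cbind(summ$info,
                 as.data.frame(summ$profiles, check.names = FALSE))
    utils::write.table(format(tab, digits = 10),
                       paste0(path("summaries.tsv"), ".partial"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    finish("summaries.tsv")
  }

  # --- heritability ---------------------------------------------------
  if ("heritability" %in% stages) {
    h2 <- broad_sense_h2_panel(probeset_replicate_means(filt$expr, annot))
    utils::write.table(format(h2, digits = 6),
                       paste0(path("heritability.tsv"), ".partial"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    finish("heritability.tsv")
  }

  # --- map ------------------------------------------------------------
  peaks <- list()
  thresholds <- NULL
  usable <- summ$info$probeset_id[summ$info$expressed]
  if (any(c("map", "candidates") %in% stages)) {
    for (k in seq_along(usable)) {
      ps <- usable[k]
      prof <- summ$profiles[ps, ]
      gene_sym <- summ$info$gene_symbol[summ$info$probeset_id == ps]
      gene <- genes[genes$symbol == gene_sym, , drop = FALSE]
      thr <- permutation_thresholds(prof, geno, n_perm = n_perm,
                                    seed = seed + 1000L + k)
      if (is.null(thresholds)) thresholds <- thr
      pk <- peak_and_classify(eqtl_scan(prof, geno),
                              gene = if (nrow(gene)) gene[1L, ] else NULL,
                              thresholds = thr, cis_window_mb = cis_window)
      if (!is.null(pk)) {
        pk$probeset_id <- ps
        peaks[[length(peaks) + 1L]] <- pk
      }
    }
  }
  if ("map" %in% stages) {
    jsonlite::write_json(
      list(engine = "single_marker_regression",
           pc1_orientation = "positive_vs_mean_profile",
           n_perm = n_perm, lrs_gate = lrs_gate,
           cis_window_mb = cis_window,
           peaks = lapply(peaks, function(p)
             p[c("probeset_id", "gene", "marker", "chr", "pos_mb", "lrs",
                 "lod", "additive", "allele_direction", "classification",
                 "distance_mb", "significant", "thresholds")])),
      paste0(path("eqtl.json"), ".partial"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    finish("eqtl.json")
  }

  # --- network --------------------------------------------------------
  if ("network" %in% stages) {
    prof_ok <- summ$profiles[usable, , drop = FALSE]
    net <- build_network(correlation_matrix(prof_ok), floor = r_floor)
    write_network(net, paste0(path("network.json"), ".partial"))
    finish("network.json")
  }

  # --- candidates -----------------------------------------------------
  if ("candidates" %in% stages) {
    trans_sig <- Filter(function(p)
      identical(p$classification, "trans") && p$lrs > lrs_gate, peaks)
    if (length(trans_sig)) {
      best <- trans_sig[[which.max(vapply(trans_sig, `[[`, numeric(1L),
                                          "lrs"))]]
      target_prof <- summ$profiles[best$probeset_id, ]
      cand_genes <- interval_genes(best, genes, half_width_mb = half_width)
      cand_genes <- cand_genes[cand_genes$symbol !=
                                 sub("_.*$", "", best$probeset_id), ,
                               drop = FALSE]
      zc <- geno_codes(geno)[, best$marker]
      rows <- lapply(cand_genes$symbol, function(sym) {
        ps <- summ$info$probeset_id[summ$info$gene_symbol == sym]
        if (!length(ps)) return(data.frame(
          symbol = sym, cis_lrs = NA_real_, r = NA_real_,
          partial_r = NA_real_, polymorphic = TRUE, expression_ok = FALSE))
        ps <- ps[1L]
        prof <- summ$profiles[ps, ]
        gene <- cand_genes[cand_genes$symbol == sym, , drop = FALSE][1L, ]
        data.frame(
          symbol = sym,
          cis_lrs = cis_lrs(prof, geno, gene, window_mb = cis_window),
          r = stats::cor(prof, target_prof),
          partial_r = partial_correlation(prof, target_prof, zc),
          polymorphic = TRUE,
          expression_ok = summ$info$expressed[summ$info$probeset_id == ps])
      })
      tab <- do.call(rbind, rows)
      if (is.null(tab)) tab <- data.frame(
        symbol = character(), cis_lrs = numeric(), r = numeric(),
        partial_r = numeric(), polymorphic = logical(),
        expression_ok = logical())
      fl <- filter_candidates(tab, lrs_min = lrs_gate, r_min = r_floor)
      ranked <- rank_candidates(fl$retained)
      utils::write.table(format(as.data.frame(ranked), digits = 6),
                         paste0(path("candidates.tsv"), ".partial"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fl$excluded,
                         paste0(path("candidates_excluded.tsv"), ".partial"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      finish(c("candidates.tsv", "candidates_excluded.tsv"))
    } else {
      writeLines("symbol\treason", paste0(path("candidates.tsv"), ".partial"))
      finish("candidates.tsv")
    }
  }

  # --- provenance -----------------------------------------------------
  cfg_flat <- config[!vapply(config, is.object, logical(1L))]
  cfg_flat$out_dir <- NULL  # analysis-irrelevant: keeps outputs relocatable
  cfg_tmp <- tempfile()
  writeLines(paste(names(cfg_flat),
                   vapply(cfg_flat, function(v) paste(format(v), collapse = ","),
                          character(1L)), sep = "="), cfg_tmp)
  prov <- list(
    seed = seed, n_perm = n_perm,
    thresholds_example = if (!is.null(thresholds))
      list(significant = thresholds$significant,
           suggestive = thresholds$suggestive) else NULL,
    config = cfg_flat,
    config_md5 = unname(tools::md5sum(cfg_tmp)),
    package_version = as.character(utils::packageVersion("bxdeqtl")),
    decisions = list(pc1_orientation = "positive_vs_mean_profile",
                     sd_convention = "population",
                     suggestive_quantile = 0.37,
                     mapping_engine = "single_marker_regression"))
  unlink(cfg_tmp)
  jsonlite::write_json(prov, paste0(path("provenance.json"), ".partial"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  finish("provenance.json")
  invisible(prov)
}
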