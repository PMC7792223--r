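#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis, the region
#' parameters, and either input paths or a simulation block. Defaults are
#' the study's values: minimum coverage 10x, pairwise DMS at >= 15
#' percentage points and q <= 0.01, omnibus q <= 0.01, quadrant trimming
#' at 5 percentage points / 0.5 log2 units, DE adjusted p < 0.05.
#'
#' @param seed integer seed for the run.
#' @param inputs optional list of input paths (`samples`, per-tissue
#'   coverage directories under `coverage_dir`, `gff3`,
#'   `expression_counts`, `pools`, `candidates`); omitted when `simulate`
#'   is given.
#' @param simulate optional [sim_config()] generating the inputs in
#'   memory.
#' @param min_cov,dms_diff,dms_q,omnibus_q,trim_meth,trim_lfc,de_q
#'   analysis thresholds.
#' @param tss_up,tss_down,prom_up,prom_down,flank region parameters (bp).
#' @param standardize z-score scope (`"site"`, `"sample"`, `"grand"`).
#' @param fisher_alternative sidedness of the enrichment test.
#' @param out_dir output directory (`NULL` = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, inputs = NULL, simulate = NULL,
                            min_cov = 10, dms_diff = 15, dms_q = 0.01,
                            omnibus_q = 0.01, trim_meth = 5,
                            trim_lfc = 0.5, de_q = 0.05,
                            tss_up = 300, tss_down = 50,
                            prom_up = 2000, prom_down = 200,
                            flank = 10000,
                            standardize = "site",
                            fisher_alternative = "two.sided",
                            out_dir = NULL) {
  if (is.null(inputs) && is.null(simulate))
    stop("either input paths or a simulate block is required")
  cfg <- as.list(environment())
  if (any(c(min_cov, dms_diff, dms_q, omnibus_q, trim_meth, trim_lfc,
            de_q) <= 0))
    stop("all thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' The configuration round-trips unchanged (the `simulate` block is stored
#' as its parameter list).
#'
#' @param path YAML file.
#' @return for `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config a `pipeline_config`.
#' @return for `write_pipeline_config`, invisibly `path`.
#' @export
write_pipeline_config <- function(config, path) {
  y <- unclass(config)
  if (!is.null(y$simulate)) y$simulate <- unclass(y$simulate)
  yaml::write_yaml(y, path, precision = 12)
  invisible(path)
}

config_checksum <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # analysis parameters only, not the destination
  txt <- paste(deparse(cfg), collapse = "")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 1e9
}

write_stage_tsv <- function(d, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# methtempo %s | seed %d | config %d",
                     as.character(utils::packageVersion("methtempo")),
                     config$seed, config_checksum(config)), con)
  utils::write.table(as.data.frame(d), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes filter -> annotate -> differential methylation (pairwise and
#' omnibus) -> z-score / concordance -> differential expression ->
#' candidate-gene correlation -> quadrant association and enrichment, from
#' either simulated or on-disk inputs. With `out_dir` set, every stage
#' writes a TSV with a provenance header (package version, seed, config
#' checksum); identical config and seed give identical table bodies.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a named list of all stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log_stage <- function(...) message("[methtempo] ", sprintf(...))
  if (!is.null(config$simulate)) {
    log_stage("simulating inputs (seed %d)", config$simulate$seed)
    genome <- simulate_genome(config$simulate)
    sim <- simulate_methylation(config$simulate, genome)
    expr <- simulate_expression(config$simulate, genome, sim$truth)
    tables <- sim$tables
    genes <- genome$genes
    counts <- expr$counts
    candidates <- expr$candidates
  } else {
    inp <- config$inputs
    meta <- read_sample_meta(inp$samples)
    tables <- list()
    for (tis in unique(meta$tissue)) {
      m <- meta[meta$tissue == tis, , drop = FALSE]
      paths <- file.path(inp$coverage_dir, tis,
                         paste0(m$sample_id, ".cov"))
      tables[[tis]] <- read_coverage_files(paths, m)
    }
    genes <- load_gene_models(inp$gff3)
    pools <- utils::read.table(inp$pools, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    counts <- read_expr_counts(inp$expression_counts, pools)
    candidates <- if (!is.null(inp$candidates))
      utils::read.table(inp$candidates, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE) else NULL
  }
  res <- list(config = config)

  log_stage("filtering (min coverage %dx, invariant sites)", config$min_cov)
  filtered <- lapply(tables, filter_min_coverage, min_cov = config$min_cov)
  props <- lapply(filtered, function(x) {
    filter_invariant_sites(compute_proportions(x))
  })
  filtered <- lapply(names(filtered), function(tis) {
    keep <- site_key(filtered[[tis]]$sites) %in%
      site_key(props[[tis]]$sites)
    filtered[[tis]][keep, ]
  })
  names(filtered) <- names(props)
  res$filtered <- filtered
  res$qc <- lapply(props, qc_sample_stats)

  log_stage("annotating regions")
  intervals <- build_region_intervals(genes, config$tss_up,
                                      config$tss_down, config$prom_up,
                                      config$prom_down, config$flank)
  res$intervals <- intervals
  res$assignment <- lapply(props, function(p)
    assign_sites_to_regions(p$sites, intervals))

  two_tissue <- length(filtered) >= 2
  if (two_tissue) {
    pair <- intersect_tissues(filtered[[1]], filtered[[2]])
    names(pair) <- names(filtered)[1:2]
    log_stage("differential methylation on %d shared sites",
              nrow(pair[[1]]$sites))
    res$dms <- list()
    res$classification <- list()
    res$concordance <- list()
    for (lab in c("d12", "d23")) {
      ctr <- contrast_spec(lab)
      d1 <- test_pairwise_contrast(pair[[1]], ctr, config$dms_diff,
                                   config$dms_q)
      d2 <- test_pairwise_contrast(pair[[2]], ctr, config$dms_diff,
                                   config$dms_q)
      res$dms[[lab]] <- stats::setNames(list(d1, d2), names(pair))
      res$classification[[lab]] <- classify_tissue_generality(d1, d2)
      dms_union <- unique(rbind(d1[d1$is_dms, c("chrom", "pos", "strand")],
                                d2[d2$is_dms, c("chrom", "pos", "strand")]))
      z1 <- zscore_standardize(compute_proportions(pair[[1]]),
                               config$standardize)
      z2 <- zscore_standardize(compute_proportions(pair[[2]]),
                               config$standardize)
      c1 <- change_between_timepoints(z1, ctr)
      c2 <- change_between_timepoints(z2, ctr)
      res$concordance[[lab]] <- tryCatch(list(
        all_dms = correlate_tissue_changes(c1, c2, dms_union, "all_dms")),
        error = function(e) list(all_dms = NULL))
      for (reg in c("promoter", "tss")) {
        sub <- res$assignment[[1]]
        sub <- unique(sub[sub$region == reg, c("chrom", "pos", "strand")])
        sub <- sub[site_key(sub) %in% site_key(dms_union), , drop = FALSE]
        res$concordance[[lab]][[reg]] <- tryCatch(
          correlate_tissue_changes(c1, c2, sub, reg),
          error = function(e) NULL)
      }
    }
  }

  log_stage("omnibus time-effect tests")
  res$omnibus <- lapply(filtered, test_time_omnibus,
                        q_threshold = config$omnibus_q)

  log_stage("differential expression (%d genes)", length(counts$genes))
  sf <- normalize_size_factors(counts)
  de <- test_time_effect_nb(counts, sf)
  de <- filter_time_responsive_genes(de, de_q = config$de_q)
  res$size_factors <- sf
  res$de <- de

  if (!is.null(candidates)) {
    log_stage("candidate-gene correlations")
    res$candidates <- candidate_gene_analysis(
      candidates, props, res$assignment, config)
  }

  log_stage("quadrant associations and enrichment")
  expr_tis <- counts$pools$tissue[1]
  res$associations <- list()
  res$enrichment <- list()
  for (tis in names(filtered)) {
    pair_label <- paste0(tis, "->", expr_tis)
    for (lab in c("d12", "d23")) {
      key <- paste(pair_label, lab, sep = ":")
      assoc <- tryCatch(suppressWarnings(build_quadrant_associations(
        res$omnibus[[tis]], de, res$assignment[[tis]], props[[tis]],
        contrast_spec(lab), pair_label,
        config$trim_meth, config$trim_lfc)), error = function(e) NULL)
      res$associations[[key]] <- assoc
      res$enrichment[[key]] <- tryCatch(
        fisher_enrichment(assoc, alternative = config$fisher_alternative),
        error = function(e) NULL)
    }
  }

  if (!is.null(config$out_dir)) write_pipeline_outputs(res, config)
  invisible(res)
}

candidate_gene_analysis <- function(candidates, props, assignment,
                                    config) {
  out <- list()
  for (lab in c("d12", "d23")) {
    ctr <- contrast_spec(lab)
    rows <- list()
    for (g in unique(candidates$gene_id)) {
      cg <- candidates[candidates$gene_id == g, , drop = FALSE]
      e_earlier <- stats::setNames(
        cg$value[cg$time_point == ctr$time_a],
        cg$female_id[cg$time_point == ctr$time_a])
      e_later <- stats::setNames(
        cg$value[cg$time_point == ctr$time_b],
        cg$female_id[cg$time_point == ctr$time_b])
      if (!length(e_earlier) || !length(e_later)) next
      expr_pc <- pairwise_change(e_earlier, e_later)
      for (tis in names(props)) {
        p <- props[[tis]]
        asn <- assignment[[tis]]
        asn <- asn[asn$gene_id == g &
                     asn$region %in% c("tss", "promoter"), , drop = FALSE]
        if (!nrow(asn)) next
        for (k in seq_len(nrow(asn))) {
          si <- match(site_key(asn[k, ]), site_key(p$sites))
          if (is.na(si)) next
          vals <- p$proportion[si, ]
          ja <- p$samples$time_point == ctr$time_a
          jb <- p$samples$time_point == ctr$time_b
          meth_pc <- pairwise_change(
            stats::setNames(vals[ja], p$samples$female_id[ja]),
            stats::setNames(vals[jb], p$samples$female_id[jb]))
          cc <- correlate_candidate_gene(meth_pc, expr_pc)
          rows[[length(rows) + 1]] <- data.frame(
            gene_id = g, tissue = tis, region = asn$region[k],
            chrom = asn$chrom[k], pos = asn$pos[k],
            contrast = lab, cc, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows))
      out[[lab]] <- adjust_candidate_results(do.call(rbind, rows))
  }
  out
}

write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  for (tis in names(res$filtered)) {
    qc <- res$qc[[tis]]
    write_stage_tsv(data.frame(sample_id = qc$sample_id, mean = qc$mean,
                               variance = qc$variance,
                               p_location = qc$p_location,
                               p_scale = qc$p_scale),
                    file.path(od, paste0("qc_", tis, ".tsv")), config)
    write_stage_tsv(res$omnibus[[tis]],
                    file.path(od, paste0("omnibus_", tis, ".tsv")), config)
  }
  for (lab in names(res$dms)) {
    for (tis in names(res$dms[[lab]]))
      write_stage_tsv(res$dms[[lab]][[tis]],
                      file.path(od, sprintf("dms_%s_%s.tsv", lab, tis)),
                      config)
    write_stage_tsv(res$classification[[lab]],
                    file.path(od, paste0("classification_", lab, ".tsv")),
                    config)
    conc <- res$concordance[[lab]]
    conc <- conc[!vapply(conc, is.null, TRUE)]
    if (length(conc))
      write_stage_tsv(do.call(rbind, lapply(conc, function(x)
        data.frame(contrast = x$contrast, scope = x$scope, n = x$n,
                   r = x$r, df = x$df, p = x$p))),
        file.path(od, paste0("concordance_", lab, ".tsv")), config)
  }
  write_stage_tsv(res$de, file.path(od, "de_genes.tsv"), config)
  for (lab in names(res$candidates))
    write_stage_tsv(res$candidates[[lab]],
                    file.path(od, paste0("candidates_", lab, ".tsv")),
                    config)
  assoc <- res$associations[!vapply(res$associations, function(x)
    is.null(x) || !nrow(x), TRUE)]
  if (length(assoc))
    write_stage_tsv(do.call(rbind, assoc),
                    file.path(od, "quadrant_associations.tsv"), config)
  enr <- res$enrichment[!vapply(res$enrichment, is.null, TRUE)]
  if (length(enr)) {
    write_stage_tsv(do.call(rbind, lapply(names(enr), function(k)
      data.frame(analysis = k, n_test = sum(enr[[k]]$table[1, ]),
                 n_control = sum(enr[[k]]$table[2, ]),
                 odds_ratio = enr[[k]]$odds_ratio, p = enr[[k]]$p))),
      file.path(od, "enrichment.tsv"), config)
  }
  write_regions_bed(res$intervals, file.path(od, "regions.bed"))
  invisible(NULL)
}
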