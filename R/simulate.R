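#' Configuration for the synthetic cohort generator
#'
#' Emulates the study design: 18 females (6 per sampling time point, three
#' time points), two temperature environments, family structure, RRBS-style
#' methylation counts for red blood cells and liver, and pooled expression
#' counts (2 pools x 3 females per time point). Methylation counts are
#' beta-binomial (replicate overdispersion `rho`), coverage is negative
#' binomial. Temporal CpG sites shift their methylation by `effect_pp`
#' percentage points per contrast, realized in both tissues with
#' probability `fraction_general`, otherwise in one tissue. Temperature is
#' generated but carries no true effect by default, so the omnibus
#' covariate is exercised without confounding. Gene expression time
#' effects are independent by default; with `coupling_k` nonzero, genes
#' whose TSS contains a temporal CpG site receive a log2 shift of
#' `-coupling_k` times the site's true methylation change (in percentage
#' points) plus noise.
#'
#' @param seed integer seed (mandatory; all generator randomness derives
#'   from it).
#' @param n_genes,chrom_length,n_sites genome dimensions.
#' @param n_females_per_timepoint females sacrificed per time point.
#' @param baseline_logit_mean,baseline_logit_sd logit-normal distribution
#'   of per-site baseline methylation.
#' @param fraction_temporal fraction of sites with a temporal effect.
#' @param fraction_general probability a temporal effect is tissue-general.
#' @param effect_pp methylation shift per contrast, percentage points.
#' @param sample_shift_sd per-sample mean shift SD (logit scale).
#' @param family_sd family effect SD (logit scale), shared across tissues.
#' @param temperature_effect true warm-environment effect (logit; 0).
#' @param coverage_mean,coverage_size negative-binomial coverage model.
#' @param rho beta-binomial intra-site correlation (0 = pure binomial).
#' @param expr_baseline_log_mean,expr_baseline_log_sd log-normal per-gene
#'   baseline expression (natural log of the per-female mean count).
#' @param expr_dispersion negative-binomial dispersion of pooled counts.
#' @param fraction_temporal_genes fraction of (uncoupled) genes with an
#'   expression time effect.
#' @param expr_effect_sd SD of uncoupled per-contrast log2 shifts.
#' @param coupling_k TSS methylation-expression coupling slope (log2 units
#'   per percentage point; 0 disables coupling).
#' @param coupling_noise_sd SD of the coupling noise (log2 units).
#' @param pools_per_timepoint RNA pools per time point (default 2).
#' @param n_candidate_genes genes emitted in the per-female qPCR-style
#'   candidate table.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_genes = 150, chrom_length = 6e6, n_sites = 5000,
                       n_females_per_timepoint = 6,
                       baseline_logit_mean = 0, baseline_logit_sd = 1.5,
                       fraction_temporal = 0.1, fraction_general = 0.5,
                       effect_pp = 25,
                       sample_shift_sd = 0.1, family_sd = 0.1,
                       temperature_effect = 0,
                       coverage_mean = 30, coverage_size = 20,
                       rho = 0.02,
                       expr_baseline_log_mean = log(200),
                       expr_baseline_log_sd = 1,
                       expr_dispersion = 0.05,
                       fraction_temporal_genes = 0.3,
                       expr_effect_sd = 1,
                       coupling_k = 0, coupling_noise_sd = 0.3,
                       pools_per_timepoint = 2,
                       n_candidate_genes = 7) {
  if (missing(seed) || !is.numeric(seed) || is.na(seed))
    stop("a numeric seed is mandatory")
  if (seed >= 2^31 - 10) stop("seed too large")
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(fraction_temporal >= 0, fraction_temporal <= 1,
              fraction_general >= 0, fraction_general <= 1,
              fraction_temporal_genes >= 0, fraction_temporal_genes <= 1,
              rho >= 0, rho < 1, effect_pp >= 0, coverage_mean > 0,
              n_genes >= 1, n_sites >= 1, pools_per_timepoint >= 1)
  })
  structure(cfg, class = "sim_config")
}

#' Simulate a one-chromosome genome annotation and CpG site set
#'
#' Places non-overlapping genes on both strands along a single chromosome
#' and scatters CpG sites, guaranteeing at least one site inside every
#' gene's TSS, promoter, gene-body and both 10 kb flank regions (so every
#' region category is populated); remaining sites are uniform over the
#' chromosome. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene models, see [load_gene_models()]) and
#'   `sites` (data.frame `chrom`, `pos`, `strand`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1)
  slot <- floor((config$chrom_length - 20000) / config$n_genes)
  if (slot < 25000)
    stop("infeasible gene packing: increase chrom_length to at least ",
         config$n_genes * 25000 + 20000)
  len <- sample(1000:4000, config$n_genes, replace = TRUE)
  jitter <- vapply(seq_len(config$n_genes),
                   function(i) sample.int(slot - len[i] - 1000, 1), 0L)
  tx_start <- 10000 + (seq_len(config$n_genes) - 1) * slot + jitter
  tx_end <- tx_start + len
  strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  genes <- data.frame(gene_id = sprintf("g%03d", seq_len(config$n_genes)),
                      chrom = "chr1", strand = strand,
                      tx_start = tx_start, tx_end = tx_end,
                      stringsAsFactors = FALSE)
  genes$exons <- lapply(seq_len(nrow(genes)), function(i) {
    brk <- round(tx_start[i] + len[i] * c(0.4, 0.6))
    m <- rbind(c(tx_start[i], brk[1]), c(brk[2], tx_end[i]))
    m[order(m[, 1]), , drop = FALSE]
  })
  iv <- build_region_intervals(genes)
  quota_pos <- vapply(seq_len(nrow(iv)), function(k) {
    s <- iv$start[k]; e <- min(iv$end[k], config$chrom_length)
    s + sample.int(e - s + 1, 1) - 1
  }, 0)
  n_extra <- max(config$n_sites - length(quota_pos), 0)
  extra <- sample.int(config$chrom_length, n_extra, replace = TRUE)
  pos <- sort(unique(c(quota_pos, extra)))
  sites <- data.frame(chrom = "chr1", pos = pos, strand = "+",
                      stringsAsFactors = FALSE)
  list(genes = genes, sites = sites)
}

sample_metadata <- function(config, tissue) {
  npt <- config$n_females_per_timepoint
  nf <- 3 * npt
  fem <- sprintf("F%02d", seq_len(nf))
  tp <- rep(1:3, each = npt)
  # alternate temperature within each time point; families of two females
  temp <- rep(rep(c("warm", "cold"), length.out = npt), 3)
  fam <- sprintf("fam%02d", ((seq_len(nf) - 1) %% ceiling(nf / 2)) + 1)
  data.frame(sample_id = paste(tissue, fem, sep = "_"),
             female_id = fem, tissue = tissue, time_point = tp,
             temperature_env = temp, family_id = fam,
             pool_id = NA_character_, stringsAsFactors = FALSE)
}

#' Simulate two-tissue methylation count tables with ground truth
#'
#' Per site, a shared logit-normal baseline; temporal sites follow a
#' three-point trajectory shifting `effect_pp` percentage points per
#' contrast (direction chosen at random where feasible), realized in both
#' tissues (tissue-general) or a single tissue (tissue-specific).
#' Per-sample mean shifts, family effects and the (default-zero)
#' temperature effect add on the logit scale; coverage is negative
#' binomial and methylated counts beta-binomial with correlation `rho`.
#'
#' @param config a [sim_config()].
#' @param genome from [simulate_genome()].
#' @param tissues methylation tissues to emit (default RBC and liver).
#' @return list with `tables` (named list of `meth_counts`) and `truth`
#'   (per-site data.frame: `temporal`, `general`, `affected`,
#'   `true_d12_pp`, `true_d23_pp`).
#' @export
simulate_methylation <- function(config, genome,
                                 tissues = c("RBC", "liver")) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2)
  sites <- genome$sites
  ns <- nrow(sites)
  e <- config$effect_pp / 100
  p1 <- stats::plogis(stats::rnorm(ns, config$baseline_logit_mean,
                                   config$baseline_logit_sd))
  temporal <- stats::runif(ns) < config$fraction_temporal
  general <- ifelse(temporal, stats::runif(ns) < config$fraction_general, NA)
  pick <- sample(tissues, ns, replace = TRUE)
  affected <- ifelse(!temporal, NA_character_,
                     ifelse(general, "both", pick))
  feas_dir <- function(p) {
    up_ok <- p + e <= 0.97; dn_ok <- p - e >= 0.03
    d <- ifelse(up_ok & dn_ok, sample(c(-1, 1), length(p), replace = TRUE),
                ifelse(up_ok, 1, -1))
    d
  }
  d12 <- feas_dir(p1)
  p2 <- ifelse(temporal, pmin(pmax(p1 + d12 * e, 0.02), 0.98), p1)
  d23 <- feas_dir(p2)
  p3 <- ifelse(temporal, pmin(pmax(p2 + d23 * e, 0.02), 0.98), p2)
  truth <- data.frame(sites, temporal = temporal, general = general,
                      affected = affected,
                      true_d12_pp = 100 * (p2 - p1),
                      true_d23_pp = 100 * (p3 - p2),
                      stringsAsFactors = FALSE)
  fam_ids <- unique(sample_metadata(config, tissues[1])$family_id)
  fam_eff <- stats::setNames(stats::rnorm(length(fam_ids), 0,
                                          config$family_sd), fam_ids)
  traj <- cbind(p1, p2, p3)
  tables <- list()
  for (tis in tissues) {
    meta <- sample_metadata(config, tis)
    nsamp <- nrow(meta)
    active <- temporal & (affected == "both" | affected == tis)
    active[is.na(active)] <- FALSE
    shift <- stats::rnorm(nsamp, 0, config$sample_shift_sd)
    lt <- matrix(stats::qlogis(p1), ns, nsamp)
    for (j in seq_len(nsamp)) {
      t_j <- meta$time_point[j]
      lt[active, j] <- stats::qlogis(traj[active, t_j])
      lt[, j] <- lt[, j] + shift[j] + fam_eff[meta$family_id[j]] +
        config$temperature_effect * (meta$temperature_env[j] == "warm")
    }
    pcell <- stats::plogis(lt)
    pcell <- pmin(pmax(pcell, 1e-6), 1 - 1e-6)
    cov <- matrix(stats::rnbinom(ns * nsamp, mu = config$coverage_mean,
                                 size = config$coverage_size), ns, nsamp)
    if (config$rho > 0) {
      sc <- (1 - config$rho) / config$rho
      pdraw <- matrix(stats::rbeta(ns * nsamp, pcell * sc,
                                   (1 - pcell) * sc), ns, nsamp)
    } else pdraw <- pcell
    meth <- matrix(stats::rbinom(ns * nsamp, as.vector(cov),
                                 as.vector(pdraw)), ns, nsamp)
    colnames(cov) <- colnames(meth) <- meta$sample_id
    tables[[tis]] <- meth_counts(sites, meta, cov, meth)
  }
  list(tables = tables, truth = truth)
}

#' Simulate pooled expression counts and a per-female candidate table
#'
#' Gene log-means combine a log-normal baseline with per-contrast log2
#' time shifts. With `coupling_k` nonzero, a gene whose TSS region holds a
#' temporal CpG site (affected in `meth_tissue`) receives
#' `-coupling_k x true methylation change (pp) + noise` per contrast;
#' other genes draw independent time effects. Pools aggregate 3 females
#' (mean count x 3); pooled counts are negative binomial. A per-female
#' log-normal candidate-gene table (qPCR-like, continuous) is also
#' emitted for the pairwise-change correlation path.
#'
#' @param config a [sim_config()].
#' @param genome from [simulate_genome()].
#' @param truth methylation ground truth from [simulate_methylation()]
#'   (required when `coupling_k != 0`).
#' @param tissue expression tissue label.
#' @param meth_tissue methylation tissue whose TSS sites drive coupling.
#' @return list with `counts` (`expr_counts`), `gene_truth` (per-gene
#'   `coupled`, `temporal_expr`, `shift12_log2`, `shift23_log2`) and
#'   `candidates` (data.frame `gene_id`, `female_id`, `time_point`,
#'   `value`).
#' @export
simulate_expression <- function(config, genome, truth = NULL,
                                tissue = "liver", meth_tissue = "liver") {
  stopifnot(inherits(config, "sim_config"))
  if (config$coupling_k != 0 && is.null(truth))
    stop("methylation truth is required when coupling_k != 0")
  set.seed(config$seed + 3)
  genes <- genome$genes
  ng <- nrow(genes)
  base <- stats::rnorm(ng, config$expr_baseline_log_mean,
                       config$expr_baseline_log_sd)
  shift12 <- shift23 <- numeric(ng)
  coupled <- logical(ng)
  if (config$coupling_k != 0) {
    iv <- build_region_intervals(genes)
    tss_iv <- iv[iv$region == "tss", , drop = FALSE]
    active <- truth$temporal &
      (truth$affected == "both" | truth$affected == meth_tissue)
    active[is.na(active)] <- FALSE
    asn <- assign_sites_to_regions(truth[active, c("chrom", "pos", "strand")],
                                   tss_iv)
    if (nrow(asn)) {
      akey <- site_key(asn)
      tkey <- site_key(truth)
      asn$d12 <- truth$true_d12_pp[match(akey, tkey)]
      asn$d23 <- truth$true_d23_pp[match(akey, tkey)]
      agg12 <- tapply(asn$d12, asn$gene_id, mean)
      agg23 <- tapply(asn$d23, asn$gene_id, mean)
      gi <- match(names(agg12), genes$gene_id)
      coupled[gi] <- TRUE
      shift12[gi] <- -config$coupling_k * agg12 +
        stats::rnorm(length(gi), 0, config$coupling_noise_sd)
      shift23[gi] <- -config$coupling_k * agg23 +
        stats::rnorm(length(gi), 0, config$coupling_noise_sd)
    }
  }
  temporal_expr <- !coupled &
    stats::runif(ng) < config$fraction_temporal_genes
  shift12[temporal_expr] <- stats::rnorm(sum(temporal_expr), 0,
                                         config$expr_effect_sd)
  shift23[temporal_expr] <- stats::rnorm(sum(temporal_expr), 0,
                                         config$expr_effect_sd)
  cum <- cbind(0, shift12, shift12 + shift23)
  npp <- config$pools_per_timepoint
  pools <- data.frame(pool_id = sprintf("%s_P%d", tissue, seq_len(3 * npp)),
                      tissue = tissue,
                      time_point = rep(1:3, each = npp),
                      stringsAsFactors = FALSE)
  mu <- matrix(0, ng, nrow(pools))
  for (j in seq_len(nrow(pools)))
    mu[, j] <- 3 * exp(base) * 2^cum[, pools$time_point[j]]
  cts <- matrix(stats::rnbinom(length(mu), mu = as.vector(mu),
                               size = 1 / config$expr_dispersion),
                ng, nrow(pools))
  counts <- expr_counts(genes$gene_id, pools, cts)
  gene_truth <- data.frame(gene_id = genes$gene_id, coupled = coupled,
                           temporal_expr = temporal_expr,
                           shift12_log2 = shift12, shift23_log2 = shift23,
                           stringsAsFactors = FALSE)
  # candidate genes: prefer coupled genes, fill with temporal, then others
  ord <- order(!coupled, !temporal_expr)
  cand <- genes$gene_id[ord][seq_len(min(config$n_candidate_genes, ng))]
  meta <- sample_metadata(config, tissue)
  cand_rows <- lapply(cand, function(g) {
    gi <- match(g, genes$gene_id)
    data.frame(gene_id = g, female_id = meta$female_id,
               time_point = meta$time_point,
               value = 2^(cum[gi, meta$time_point] +
                            stats::rnorm(nrow(meta), 0, 0.3)),
               stringsAsFactors = FALSE)
  })
  list(counts = counts, gene_truth = gene_truth,
       candidates = do.call(rbind, cand_rows))
}

write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$tx_start, g$tx_end, g$strand, g$gene_id),
               con)
    ex <- genes$exons[[i]]
    for (k in seq_len(nrow(ex)))
      writeLines(sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$chrom, ex[k, 1], ex[k, 2], g$strand,
                         g$gene_id, k, g$gene_id), con)
  }
  invisible(path)
}

#' Write a complete synthetic input bundle to disk
#'
#' Emits the fixture files in the exact formats the pipeline reads:
#' per-sample Bismark-style coverage files under `<dir>/<tissue>/`, a
#' combined sample metadata TSV, a GFF3 gene annotation, pooled expression
#' counts and pool metadata TSVs, the per-female candidate-gene table, and
#' the ground-truth TSVs.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisibly, the directory path.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(config)
  sim <- simulate_methylation(config, genome)
  expr <- simulate_expression(config, genome, sim$truth)
  write_gff3(genome$genes, file.path(dir, "genes.gff3"))
  metas <- list()
  for (tis in names(sim$tables)) {
    write_coverage_files(sim$tables[[tis]], file.path(dir, tis))
    metas[[tis]] <- sim$tables[[tis]]$samples
  }
  utils::write.table(do.call(rbind, metas), file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cts <- data.frame(gene_id = expr$counts$genes, expr$counts$counts,
                    check.names = FALSE)
  utils::write.table(cts, file.path(dir, "expression_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$counts$pools, file.path(dir, "pools.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$candidates, file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$gene_truth, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
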