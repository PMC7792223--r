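test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- sim_config(seed = 202, n_genes = 20, chrom_length = 7e5,
                    n_sites = 300, coupling_k = 0.05)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  m1 <- simulate_methylation(cfg, g1); m2 <- simulate_methylation(cfg, g1)
  expect_identical(m1, m2)
  e1 <- simulate_expression(cfg, g1, m1$truth)
  e2 <- simulate_expression(cfg, g1, m1$truth)
  expect_identical(e1, e2)
})

test_that("genome packing guarantees region quotas and rejects tight chromosomes", {
  cfg <- sim_config(seed = 203, n_genes = 15, chrom_length = 6e5,
                    n_sites = 50)
  g <- simulate_genome(cfg)
  iv <- build_region_intervals(g$genes)
  asn <- assign_sites_to_regions(g$sites, iv)
  # every gene has at least one site in its TSS interval
  tss_genes <- unique(asn$gene_id[asn$region == "tss"])
  expect_setequal(tss_genes, g$genes$gene_id)
  # and every region category is populated
  expect_setequal(unique(asn$region),
                  c("tss", "promoter", "gene_body", "up10kb", "down10kb"))
  expect_error(simulate_genome(
    sim_config(seed = 1, n_genes = 100, chrom_length = 1e6)),
    "chrom_length")
})

test_that("methylated counts respect the binomial/beta-binomial variance", {
  # with rho = 0 and no sample/family effects all samples share one p per
  # site: the Pearson dispersion over cells should match the binomial
  cfg0 <- sim_config(seed = 205, n_genes = 10, chrom_length = 4e5,
                     n_sites = 150, fraction_temporal = 0, rho = 0,
                     sample_shift_sd = 0, family_sd = 0)
  g <- simulate_genome(cfg0)
  m <- simulate_methylation(cfg0, g, tissues = "RBC")$tables$RBC
  phat <- rowSums(m$methylated) / rowSums(m$coverage)
  use <- m$coverage > 0 & phat > 0 & phat < 1
  pe <- (m$methylated - m$coverage * phat)^2 /
    (m$coverage * phat * (1 - phat))
  stat <- sum(pe[use])                      # ~ chi-square, df ~ n cells
  n_cells <- sum(use)
  expect_gt(stat, qchisq(0.025, n_cells - nrow(m$sites)))
  expect_lt(stat, qchisq(0.975, n_cells + nrow(m$sites)))
  # with rho = 0.02 the same statistic is clearly inflated
  cfg1 <- sim_config(seed = 205, n_genes = 10, chrom_length = 4e5,
                     n_sites = 150, fraction_temporal = 0, rho = 0.02,
                     sample_shift_sd = 0, family_sd = 0)
  m1 <- simulate_methylation(cfg1, g, tissues = "RBC")$tables$RBC
  p1 <- rowSums(m1$methylated) / rowSums(m1$coverage)
  u1 <- m1$coverage > 0 & p1 > 0 & p1 < 1
  pe1 <- (m1$methylated - m1$coverage * p1)^2 /
    (m1$coverage * p1 * (1 - p1))
  expect_gt(sum(pe1[u1]) / sum(u1), 1.2)
})

test_that("marginal methylation matches the logit-normal baseline", {
  cfg <- sim_config(seed = 211, n_genes = 40, chrom_length = 1.5e6,
                    n_sites = 6000, fraction_temporal = 0)
  g <- simulate_genome(cfg)
  m <- simulate_methylation(cfg, g, tissues = "liver")$tables$liver
  obs <- mean(m$methylated[m$coverage > 0] / m$coverage[m$coverage > 0])
  want <- mean(plogis(rnorm(2e5, cfg$baseline_logit_mean,
                            cfg$baseline_logit_sd)))
  expect_equal(obs, want, tolerance = 0.02)
})

test_that("truth flags are consistent with the emitted effects", {
  cfg <- sim_config(seed = 213, n_genes = 20, chrom_length = 7e5,
                    n_sites = 2000, fraction_temporal = 0.3,
                    fraction_general = 0.5)
  g <- simulate_genome(cfg)
  tr <- simulate_methylation(cfg, g)$truth
  expect_true(all(abs(tr$true_d12_pp[!tr$temporal]) < 1e-9))
  expect_true(all(abs(tr$true_d12_pp[tr$temporal]) > 1))
  expect_true(all(is.na(tr$affected[!tr$temporal])))
  expect_true(all(tr$affected[which(tr$general)] == "both"))
  frac_gen <- mean(tr$general[tr$temporal])
  expect_gt(frac_gen, 0.35); expect_lt(frac_gen, 0.65)
})

test_that("expression coupling follows -k x delta and vanishes at k = 0", {
  cfg <- sim_config(seed = 217, n_genes = 120, chrom_length = 4.8e6,
                    n_sites = 1500, fraction_temporal = 0.8,
                    coupling_k = 0.05, coupling_noise_sd = 0.3,
                    fraction_temporal_genes = 0)
  g <- simulate_genome(cfg)
  sim <- simulate_methylation(cfg, g)
  e <- simulate_expression(cfg, g, sim$truth)
  gt <- e$gene_truth[e$gene_truth$coupled, ]
  expect_gt(nrow(gt), 30)
  # recover the slope: shift ~ -k * delta + noise
  iv <- build_region_intervals(g$genes)
  tss <- iv[iv$region == "tss", ]
  act <- sim$truth[sim$truth$temporal &
                     sim$truth$affected %in% c("both", "liver"), ]
  asn <- assign_sites_to_regions(act[, c("chrom", "pos", "strand")], tss)
  akey <- paste(asn$chrom, asn$pos, asn$strand)
  tkey <- paste(act$chrom, act$pos, act$strand)
  d12 <- tapply(act$true_d12_pp[match(akey, tkey)], asn$gene_id, mean)
  d12 <- d12[gt$gene_id]
  fit <- lm(gt$shift12_log2 ~ d12)
  expect_lt(abs(unname(coef(fit)[2]) + 0.05), 0.005)
})

test_that("without coupling, expression effects are independent of methylation", {
  cfg0 <- sim_config(seed = 218, n_genes = 400, chrom_length = 1.1e7,
                     n_sites = 2500, fraction_temporal = 0.9,
                     fraction_general = 1, coupling_k = 0,
                     fraction_temporal_genes = 1)
  g <- simulate_genome(cfg0)
  sim <- simulate_methylation(cfg0, g, tissues = "liver")
  e0 <- simulate_expression(cfg0, g, sim$truth)
  iv <- build_region_intervals(g$genes)
  tss <- iv[iv$region == "tss", ]
  act <- sim$truth[sim$truth$temporal, ]
  asn <- assign_sites_to_regions(act[, c("chrom", "pos", "strand")], tss)
  akey <- paste(asn$chrom, asn$pos, asn$strand)
  tkey <- paste(act$chrom, act$pos, act$strand)
  d12 <- tapply(act$true_d12_pp[match(akey, tkey)], asn$gene_id, mean)
  d12v <- d12[e0$gene_truth$gene_id]
  ok <- !is.na(d12v)
  expect_gt(sum(ok), 300)
  expect_lt(abs(cor(e0$gene_truth$shift12_log2[ok], d12v[ok])), 0.1)
})

test_that("the fixture bundle round-trips through the file readers", {
  cfg <- sim_config(seed = 219, n_genes = 12, chrom_length = 5e5,
                    n_sites = 200)
  dir <- withr::local_tempdir()
  write_fixture_bundle(cfg, dir)
  genome <- simulate_genome(cfg)
  sim <- simulate_methylation(cfg, genome)
  meta <- read_sample_meta(file.path(dir, "samples.tsv"))
  rbc_meta <- meta[meta$tissue == "RBC", ]
  x <- read_coverage_files(
    file.path(dir, "RBC", paste0(rbc_meta$sample_id, ".cov")), rbc_meta)
  orig <- sim$tables$RBC
  # cells with coverage 0 denote absence in the .cov dialect; compare
  # the covered cells and the site union
  covered <- orig[rowSums(orig$coverage > 0) > 0, ]
  expect_equal(x$sites, covered$sites, ignore_attr = TRUE)
  expect_equal(x$coverage, covered$coverage, ignore_attr = TRUE)
  expect_equal(x$methylated, covered$methylated, ignore_attr = TRUE)
  g2 <- load_gene_models(file.path(dir, "genes.gff3"))
  expect_equal(g2$gene_id, genome$genes$gene_id)
  expect_equal(g2$tx_start, genome$genes$tx_start)
  expect_equal(g2$strand, genome$genes$strand)
  pools <- read.table(file.path(dir, "pools.tsv"), header = TRUE, sep = "\t")
  cts <- read_expr_counts(file.path(dir, "expression_counts.tsv"), pools)
  e <- simulate_expression(cfg, genome, sim$truth)
  expect_equal(cts$counts, e$counts$counts, ignore_attr = TRUE)
})
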