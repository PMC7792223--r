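test_that("pairwise per-female change enumerates all cross differences", {
  pc <- pairwise_change(c(A = 1, B = 2), c(C = 3, D = 5))
  # earlier females first: mean(later - her); then later: mean(her - earlier)
  expect_equal(unclass(pc), c(A = 3, B = 2, C = 1.5, D = 3.5))
  # grand mean equals difference of time-point means
  expect_equal(mean(pc), mean(c(3, 5)) - mean(c(1, 2)))
  # identical values -> all zeros; single females collapse to one difference
  expect_equal(unname(unclass(pairwise_change(c(a = 2), c(b = 2)))), c(0, 0))
  expect_equal(unname(unclass(pairwise_change(c(a = 1), c(b = 4)))), c(3, 3))
  # reversing the contrast negates every entry
  rev <- pairwise_change(c(C = 3, D = 5), c(A = 1, B = 2))
  expect_equal(unclass(rev)[c("A", "B", "C", "D")],
               -unclass(pc)[c("A", "B", "C", "D")])
  expect_warning(pairwise_change(c(a = 1, b = NA), c(c = 2)), "omitted")
})

test_that("grand-mean identity holds on random cohorts", {
  set.seed(107)
  for (i in 1:20) {
    e <- rnorm(sample(2:8, 1)); l <- rnorm(sample(2:8, 1))
    names(e) <- paste0("e", seq_along(e)); names(l) <- paste0("l", seq_along(l))
    expect_equal(mean(pairwise_change(e, l)), mean(l) - mean(e),
                 tolerance = 1e-12)
  }
})

test_that("candidate-gene correlation handles exact and degenerate cases", {
  m <- structure(c(3, 2.5, 1.5, 3.5), class = "pairwise_change")
  e <- structure(-c(3, 2.5, 1.5, 3.5), class = "pairwise_change")
  cc <- correlate_candidate_gene(m, e)
  expect_equal(cc$r, -1)
  flat <- structure(rep(1, 4), class = "pairwise_change")
  cc2 <- correlate_candidate_gene(m, flat)
  expect_true(cc2$undefined)
  expect_true(is.na(cc2$r))
  expect_error(correlate_candidate_gene(
    structure(1:3, class = "pairwise_change"),
    structure(1:3, class = "pairwise_change")), "at least 4")
  # undefined rows are excluded from the BH adjustment
  res <- data.frame(p = c(0.01, NA, 0.04), undefined = c(FALSE, TRUE, FALSE))
  adj <- adjust_candidate_results(res)
  expect_equal(adj$p_adj, c(0.02, NA, 0.04))
})

test_that("correlation of independent changes is calibrated at the 5% level", {
  set.seed(1)
  cnt <- 0
  for (i in 1:1000) {
    r <- correlate_candidate_gene(
      structure(rnorm(12), class = "pairwise_change"),
      structure(rnorm(12), class = "pairwise_change"))
    if (abs(r$r) >= 0.576) cnt <- cnt + 1   # two-sided t critical, df = 10
  }
  expect_gte(cnt / 1000, 0.03)
  expect_lte(cnt / 1000, 0.07)
})

test_that("quadrants follow the sign convention", {
  expect_equal(assign_quadrant(-10, 0.8), "Q1")
  expect_equal(assign_quadrant(6, 0.6), "Q2")
  expect_equal(assign_quadrant(10, -0.8), "Q3")
  expect_equal(assign_quadrant(-6, -0.6), "Q4")
  expect_error(assign_quadrant(0, 1), "trim")
})

fake_omnibus <- function(sites, is_dms) {
  structure(data.frame(sites, meth_diff = NA_real_, lrt_stat = 10,
                       df = 2L, p = 0.001, q = 0.005, is_dms = is_dms),
            class = c("dms_result", "data.frame"),
            tissue = "liver", contrast = "omnibus")
}

fake_de <- function(gene_id, lfc12, passes) {
  structure(data.frame(gene_id = gene_id, dispersion = 0.05,
                       lrt_stat = 10, df = 2L, p_time = 0.001,
                       q_time = 0.01, log2fc_12 = lfc12, log2fc_23 = 0.1,
                       skipped = FALSE, passes_filter = passes),
            class = c("de_result", "data.frame"), tissue = "liver")
}

test_that("quadrant associations apply trimming and multi-region tallies", {
  sites <- make_sites(3)
  # per-female proportions: site 1 rises 20 pp, site 2 rises 4.9 pp,
  # site 3 falls 30 pp
  meta <- make_meta("liver", n_per_tp = 2, time_points = 1:2)
  p <- rbind(c(0.30, 0.30, 0.50, 0.50),
             c(0.300, 0.300, 0.349, 0.349),
             c(0.80, 0.80, 0.50, 0.50))
  props <- compute_proportions(make_counts(p, cov = 1000, meta = meta))
  asn <- data.frame(chrom = "chr1", pos = c(100, 100, 200, 300),
                    strand = "+",
                    gene_id = c("gX", "gX", "gX", "gY"),
                    region = c("tss", "promoter", "tss", "tss"))
  dms <- fake_omnibus(sites, c(TRUE, TRUE, TRUE))
  de <- fake_de(c("gX", "gY"), c(-1, 0.4), c(TRUE, TRUE))
  a <- build_quadrant_associations(dms, de, asn, props,
                                   contrast_spec("d12"), "liver->liver")
  # site 1 in both tss and promoter of gX (log2FC -1): two rows, Q3;
  # site 2 trimmed (4.9 pp); site 3 in gY trimmed (log2FC 0.4)
  expect_equal(nrow(a), 2)
  expect_setequal(a$region, c("tss", "promoter"))
  expect_true(all(a$quadrant == "Q3"))
  expect_equal(a$delta_meth, rep(20, 2), tolerance = 1e-9)
  # empty inputs warn and return an empty, well-formed table
  expect_warning(e1 <- build_quadrant_associations(
    fake_omnibus(sites, rep(FALSE, 3)), de, asn, props,
    contrast_spec("d12"), "liver->liver"), "empty")
  expect_equal(nrow(e1), 0)
  expect_true(all(c("quadrant", "delta_meth", "log2fc") %in% names(e1)))
})

test_that("Fisher enrichment matches enumeration and flags zero cells", {
  mk <- function(n_tss_conc, n_tss_disc, n_dn_conc, n_dn_disc) {
    data.frame(region = rep(c("tss", "down10kb"),
                            c(n_tss_conc + n_tss_disc,
                              n_dn_conc + n_dn_disc)),
               quadrant = c(rep(c("Q1", "Q2"), c(n_tss_conc, n_tss_disc)),
                            rep(c("Q3", "Q4"), c(n_dn_conc, n_dn_disc))))
  }
  flat <- fisher_enrichment(mk(5, 5, 5, 5))
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p, 1)
  skew <- fisher_enrichment(mk(8, 2, 2, 8))
  expect_equal(skew$p, 4252 / 184756, tolerance = 1e-9)
  corner <- fisher_enrichment(mk(3, 0, 0, 3))
  expect_equal(corner$p, 0.1, tolerance = 1e-12)
  expect_true(corner$continuity)
  expect_error(fisher_enrichment(mk(3, 3, 0, 0)), "down10kb")
  # agreement with stats::fisher.test over random small tables
  set.seed(109)
  for (i in 1:50) {
    t4 <- as.vector(stats::rmultinom(1, sample(8:40, 1), rep(0.25, 4)))
    if (sum(t4[1:2]) == 0 || sum(t4[3:4]) == 0) next
    mine <- fisher_enrichment(mk(t4[1], t4[2], t4[3], t4[4]))
    ref <- stats::fisher.test(matrix(t4, 2, byrow = TRUE))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("one-sided enrichment options use the hypergeometric tails", {
  a <- data.frame(region = rep(c("tss", "down10kb"), each = 10),
                  quadrant = c(rep("Q1", 8), rep("Q2", 2),
                               rep("Q1", 3), rep("Q2", 7)))
  g <- fisher_enrichment(a, alternative = "greater")
  l <- fisher_enrichment(a, alternative = "less")
  ref_g <- stats::fisher.test(matrix(c(8, 2, 3, 7), 2, byrow = TRUE),
                              alternative = "greater")
  expect_equal(g$p, ref_g$p.value, tolerance = 1e-9)
  expect_gt(l$p, g$p)
})
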