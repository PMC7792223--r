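test_that("coverage files parse, union sites, and round-trip", {
  dir <- withr::local_tempdir()
  meta <- make_meta(n_per_tp = 1, time_points = 1:2)
  writeLines("chr1\t100\t100\t50.0\t5\t5", file.path(dir, "a.cov"))
  writeLines("chr1\t200\t200\t25.0\t2\t6", file.path(dir, "b.cov"))
  x <- read_coverage_files(file.path(dir, c("a.cov", "b.cov")), meta)
  expect_equal(nrow(x$sites), 2)
  # file line "chr1 100 100 50.0 5 5" -> coverage 10, methylated 5
  i <- which(x$sites$pos == 100)
  expect_equal(unname(x$coverage[i, 1]), 10)
  expect_equal(unname(x$methylated[i, 1]), 5)
  # disjoint sites: one zero-coverage cell each
  expect_equal(unname(x$coverage[i, 2]), 0)
  expect_equal(unname(x$coverage[which(x$sites$pos == 200), 1]), 0)

  # write-then-read is a fixed point
  out <- file.path(dir, "rt")
  write_coverage_files(x, out)
  y <- read_coverage_files(file.path(out, paste0(meta$sample_id, ".cov")),
                           meta)
  expect_equal(y$coverage, x$coverage)
  expect_equal(y$methylated, x$methylated)
  expect_equal(y$sites, x$sites)
})

test_that("coverage parser flags malformed input and empty files", {
  dir <- withr::local_tempdir()
  meta <- make_meta(n_per_tp = 1, time_points = 1)
  bad <- file.path(dir, "bad.cov")
  writeLines(c("chr1\t100\t100\t50.0\t5\t5", "chr1\t200\t200"), bad)
  expect_error(read_coverage_files(bad, meta), "line 2")
  writeLines("chr1\t100\t100\t50.0\t-5\t5", bad)
  expect_error(read_coverage_files(bad, meta), "line 1")
  empty <- file.path(dir, "empty.cov")
  file.create(empty)
  expect_warning(x <- read_coverage_files(empty, meta), "empty")
  expect_equal(nrow(x$sites), 0)
})

test_that("count-table invariants are enforced", {
  meta <- make_meta(n_per_tp = 1, time_points = 1:2)
  sites <- make_sites(1)
  expect_error(meth_counts(sites, meta, matrix(c(5, 5), 1),
                           matrix(c(6, 5), 1)), "exceeds coverage")
  meta2 <- meta; meta2$tissue <- c("RBC", "liver")
  expect_error(meth_counts(sites, meta2, matrix(c(5, 5), 1),
                           matrix(c(5, 5), 1)), "share a tissue")
  expect_error(meth_counts(rbind(sites, sites), make_meta(n_per_tp = 1),
                           matrix(5, 2, 3), matrix(5, 2, 3)), "duplicate")
})

test_that("wide TSV dialect round-trips with strand", {
  meta <- make_meta(n_per_tp = 2)
  sites <- make_sites(4); sites$strand <- c("+", "-", "+", "-")
  cov <- matrix(10:33, 4, 6)
  x <- meth_counts(sites, meta, cov, cov %/% 2)
  path <- withr::local_tempfile()
  write_wide_counts(x, path)
  y <- read_wide_counts(path, meta)
  expect_equal(y$sites, x$sites)
  expect_equal(y$coverage, x$coverage, ignore_attr = TRUE)
  expect_equal(y$methylated, x$methylated, ignore_attr = TRUE)
})

test_that("coverage filter keeps exactly the fully covered sites", {
  meta <- make_meta(n_per_tp = 1)
  sites <- make_sites(2)
  cov <- rbind(c(10, 12, 30), c(9, 50, 50))
  x <- meth_counts(sites, meta, cov, cov %/% 2)
  f <- filter_min_coverage(x, 10)
  expect_equal(nrow(f$sites), 1)
  expect_equal(f$sites$pos, sites$pos[1])
  expect_equal(nrow(f$samples), 3)          # sample set unchanged
  # all cells >= 10 -> identity; vacuous min_cov = 1 -> identity
  allhi <- meth_counts(sites, meta, cov + 10, cov %/% 2)
  expect_equal(filter_min_coverage(allhi, 10)$coverage, allhi$coverage)
  expect_equal(filter_min_coverage(x, 1)$coverage, x$coverage)
  expect_error(filter_min_coverage(x, 0), "min_cov")
})

test_that("proportions are counts ratios and invariant-site filter drops 0/1 rows", {
  meta <- make_meta(n_per_tp = 1)
  props_in <- rbind(c(1, 1, 1), c(0, 0, 1), c(0.5, 0.5, 0.5), c(0, 0, 0))
  x <- make_counts(props_in, cov = 10, meta = meta)
  p <- compute_proportions(x)
  expect_true(all(p$proportion >= 0 & p$proportion <= 1))
  expect_equal(round(p$proportion * x$coverage), x$methylated,
               ignore_attr = TRUE)
  f <- filter_invariant_sites(p)
  # all-1 and all-0 removed; {0,0,1} and constant 0.5 kept
  expect_equal(nrow(f$sites), 2)
  expect_equal(f$proportion[1, ], c(0, 0, 1), ignore_attr = TRUE)
  expect_equal(f$proportion[2, ], c(0.5, 0.5, 0.5), ignore_attr = TRUE)
})

test_that("coverage + invariance filtering is idempotent", {
  set.seed(11)
  meta <- make_meta(n_per_tp = 2)
  cov <- matrix(rpois(50 * 6, 15), 50, 6)
  meth <- matrix(rbinom(50 * 6, as.vector(cov), 0.3), 50, 6)
  x <- meth_counts(make_sites(50), meta, cov, meth)
  once <- filter_invariant_sites(compute_proportions(
    filter_min_coverage(x, 10)))
  keep <- site_keys(x$sites) %in% site_keys(once$sites)
  twice <- filter_invariant_sites(compute_proportions(
    filter_min_coverage(x[keep, ], 10)))
  expect_equal(twice$proportion, once$proportion)
  expect_equal(twice$sites, once$sites)
})

test_that("tissue intersection preserves order and warns when empty", {
  meta_r <- make_meta("RBC", n_per_tp = 1)
  meta_l <- make_meta("liver", n_per_tp = 1)
  xy <- meth_counts(make_sites(2), meta_r, matrix(10, 2, 3),
                    matrix(5, 2, 3))
  yz <- meth_counts(data.frame(chrom = "chr1", pos = c(200, 300),
                               strand = "+"),
                    meta_l, matrix(10, 2, 3), matrix(5, 2, 3))
  both <- intersect_tissues(xy, yz)
  expect_equal(both$a$sites$pos, 200)
  expect_equal(both$b$sites$pos, 200)
  ident <- intersect_tissues(xy, xy)
  expect_equal(ident$a$sites, xy$sites)
  far <- meth_counts(data.frame(chrom = "chr2", pos = 1:2 * 100,
                                strand = "+"),
                     meta_l, matrix(10, 2, 3), matrix(5, 2, 3))
  expect_warning(empty <- intersect_tissues(xy, far), "no CpG sites")
  expect_equal(nrow(empty$a$sites), 0)
})

test_that("sample QC computes population variances and homogeneity tests", {
  set.seed(21)
  base <- runif(200, 0.2, 0.8)
  p <- cbind(base, base, base)
  meta <- make_meta(n_per_tp = 1)
  props <- compute_proportions(make_counts(p, cov = 100, meta = meta))
  # identical samples: no between-sample variation
  qc <- qc_sample_stats(props)
  expect_equal(qc$p_location, 1, tolerance = 1e-6)
  expect_equal(qc$variance,
               unname(apply(props$proportion, 2,
                            function(v) mean((v - mean(v))^2))),
               tolerance = 1e-12)
  # one sample shifted by +0.3 at every site -> detected
  p2 <- p; p2[, 3] <- pmin(p2[, 3] + 0.3, 1)
  props2 <- compute_proportions(make_counts(p2, cov = 100, meta = meta))
  expect_lt(qc_sample_stats(props2)$p_location, 0.05)
})

test_that("BH adjustment matches hand-computed step-up values", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_bh(0.04), 0.04)
  expect_equal(adjust_bh(c(1, 1)), c(1, 1))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:25) {
    p <- runif(sample(2:50, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})
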