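#' Keep sites covered in every sample
#'
#' Retains exactly the sites whose coverage is at least `min_cov` in every
#' sample of the table, emulating the "at least 10x in all samples within a
#' tissue" rule.
#'
#' @param x a `meth_counts` object.
#' @param min_cov minimum per-cell coverage (default 10).
#' @return a `meth_counts` object with the surviving sites.
#' @export
filter_min_coverage <- function(x, min_cov = 10) {
  stopifnot(inherits(x, "meth_counts"))
  if (!is.numeric(min_cov) || length(min_cov) != 1 || min_cov < 1)
    stop("min_cov must be a single number >= 1")
  if (nrow(x$sites) == 0) return(x)
  keep <- rowSums(x$coverage >= min_cov) == ncol(x$coverage)
  x[keep, ]
}

#' Methylation proportions from counts
#'
#' Per cell, methylated / coverage; `NA` where coverage is 0.
#'
#' @param x a `meth_counts` object.
#' @return an object of class `meth_props`: list with `sites`, `samples`
#'   and a `proportion` matrix in `[0, 1]`.
#' @export
compute_proportions <- function(x) {
  stopifnot(inherits(x, "meth_counts"))
  p <- x$methylated / x$coverage
  p[x$coverage == 0] <- NA_real_
  structure(list(sites = x$sites, samples = x$samples, proportion = p),
            class = "meth_props")
}

#' @export
print.meth_props <- function(x, ...) {
  cat(sprintf("meth_props: %d sites x %d samples (tissue: %s)\n",
              nrow(x$sites), nrow(x$samples),
              if (nrow(x$samples)) x$samples$tissue[1] else "?"))
  invisible(x)
}

#' Drop sites with methylation 0 or 1 in every sample
#'
#' Sites whose proportion is exactly zero across all samples, or exactly one
#' across all samples, carry no temporal signal and are removed. Constant
#' but intermediate sites (e.g. 0.5 everywhere) are kept; the rule applies
#' only to the two extremes.
#'
#' @param props a `meth_props` object without missing cells (apply after
#'   the coverage filter).
#' @return a `meth_props` object.
#' @export
filter_invariant_sites <- function(props) {
  stopifnot(inherits(props, "meth_props"))
  if (anyNA(props$proportion))
    stop("proportions contain missing cells; apply filter_min_coverage first")
  if (nrow(props$sites) == 0) return(props)
  all0 <- rowSums(props$proportion == 0) == ncol(props$proportion)
  all1 <- rowSums(props$proportion == 1) == ncol(props$proportion)
  keep <- !(all0 | all1)
  structure(list(sites = props$sites[keep, , drop = FALSE],
                 samples = props$samples,
                 proportion = props$proportion[keep, , drop = FALSE]),
            class = "meth_props")
}

#' Restrict two tissues to their shared CpG sites
#'
#' @param a,b `meth_counts` tables for two different tissues of the same
#'   cohort (apply after filtering).
#' @return list of the two tables restricted to the common sites, in
#'   identical site order.
#' @export
intersect_tissues <- function(a, b) {
  stopifnot(inherits(a, "meth_counts"), inherits(b, "meth_counts"))
  ka <- site_key(a$sites); kb <- site_key(b$sites)
  common <- intersect(ka, kb)
  if (!length(common))
    warning("no CpG sites shared between the two tissues")
  list(a = a[match(common, ka), ], b = b[match(common, kb), ])
}

#' Per-sample QC statistics and homogeneity tests
#'
#' Computes each sample's mean and (population) variance of methylation
#' proportion across sites, then tests homogeneity of location across
#' samples with the Kruskal-Wallis rank-sum test and homogeneity of scale
#' with the Fligner-Killeen test. Significant heterogeneity motivates
#' z-score standardization before cross-tissue comparison.
#'
#' @param props a `meth_props` object with at least 2 samples and 2 sites.
#' @return an object of class `meth_qc`: per-sample `mean` and `variance`,
#'   and `p_location` / `p_scale` homogeneity p-values.
#' @export
qc_sample_stats <- function(props) {
  stopifnot(inherits(props, "meth_props"))
  p <- props$proportion
  if (ncol(p) < 2) stop("need at least 2 samples")
  n_per <- colSums(!is.na(p))
  if (any(n_per < 2))
    stop("sample(s) with fewer than 2 covered sites: ",
         paste(props$samples$sample_id[n_per < 2], collapse = ", "))
  mu <- colMeans(p, na.rm = TRUE)
  v <- apply(p, 2, function(col) {
    col <- col[!is.na(col)]
    mean((col - mean(col))^2)  # population variance, divide by n
  })
  vals <- as.vector(p)
  grp <- factor(rep(props$samples$sample_id, each = nrow(p)))
  ok <- !is.na(vals)
  kw <- stats::kruskal.test(vals[ok], grp[ok])
  fk <- stats::fligner.test(vals[ok], grp[ok])
  structure(list(sample_id = props$samples$sample_id,
                 mean = unname(mu), variance = unname(v),
                 p_location = unname(kw$p.value),
                 p_scale = unname(fk$p.value)),
            class = "meth_qc")
}

#' @export
print.meth_qc <- function(x, ...) {
  cat("Sample QC over methylation proportions\n")
  cat(sprintf("  samples: %d; mean range %.4f-%.4f; variance range %.5f-%.5f\n",
              length(x$sample_id), min(x$mean), max(x$mean),
              min(x$variance), max(x$variance)))
  cat(sprintf("  location homogeneity (Kruskal-Wallis) p = %.3g\n",
              x$p_location))
  cat(sprintf("  scale homogeneity (Fligner-Killeen)  p = %.3g\n",
              x$p_scale))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment; used wherever a q-value is
#' reported in this package.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` passed through).
#' @return adjusted p-values, same length and order as `p`.
#' @export
adjust_bh <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  pv <- p[!is.na(p)]
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
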