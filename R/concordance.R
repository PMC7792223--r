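#' Z-score standardization of methylation proportions
#'
#' Standardizes methylation so that samples with shifted mean or inflated
#' variance become comparable before differencing between time points. The
#' default scope standardizes each site across the tissue's samples
#' (site-wise mean and sample standard deviation, n - 1 convention); sites
#' with zero standard deviation are dropped with a warning. Alternative
#' scopes: `"sample"` standardizes each sample's vector across sites,
#' `"grand"` centers and scales by the tissue-wide grand mean and SD.
#'
#' @param props a complete `meth_props` (at least 3 samples).
#' @param scope `"site"`, `"sample"` or `"grand"`.
#' @return object of class `zscore_matrix`: `sites`, `samples`, matrix `z`.
#' @export
zscore_standardize <- function(props, scope = c("site", "sample", "grand")) {
  stopifnot(inherits(props, "meth_props"))
  scope <- match.arg(scope)
  p <- props$proportion
  if (ncol(p) < 3) stop("need at least 3 samples to standardize")
  sites <- props$sites
  if (scope == "site") {
    mu <- rowMeans(p)
    sdv <- apply(p, 1, stats::sd)
    keep <- sdv > 0
    if (!any(keep)) {
      warning("all sites have zero standard deviation; empty result")
    } else if (any(!keep)) {
      warning(sum(!keep), " zero-SD site(s) dropped before z-scoring")
    }
    z <- (p[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    sites <- sites[keep, , drop = FALSE]
  } else if (scope == "sample") {
    z <- apply(p, 2, function(col) (col - mean(col)) / stats::sd(col))
  } else {
    z <- (p - mean(p)) / stats::sd(as.vector(p))
  }
  structure(list(sites = sites, samples = props$samples, z = z),
            class = "zscore_matrix")
}

#' Per-site methylation change between time points, in z units
#'
#' Mean z-score over samples at the later time point minus the mean at the
#' earlier one (unweighted by coverage; z-scores are proportion-scale-free).
#'
#' @param zs a `zscore_matrix`.
#' @param contrast a pairwise [contrast_spec()].
#' @return data.frame of class `change_vector`: site columns plus `change`;
#'   attributes `tissue` and `contrast`.
#' @export
change_between_timepoints <- function(zs, contrast) {
  stopifnot(inherits(zs, "zscore_matrix"),
            inherits(contrast, "contrast_spec"))
  if (is.null(contrast$time_a)) stop("need a pairwise contrast")
  ja <- zs$samples$time_point == contrast$time_a
  jb <- zs$samples$time_point == contrast$time_b
  if (!any(ja) || !any(jb))
    stop("a time point of the contrast has no samples")
  change <- rowMeans(zs$z[, jb, drop = FALSE]) -
    rowMeans(zs$z[, ja, drop = FALSE])
  out <- data.frame(zs$sites, change = change, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("change_vector", "data.frame"),
            tissue = if (nrow(zs$samples)) zs$samples$tissue[1] else NA,
            contrast = contrast$label)
}

#' Cross-tissue concordance of methylation change
#'
#' Pearson correlation between the two tissues' per-site z-scored changes,
#' over a chosen site subset (typically the sites called differentially
#' methylated in at least one tissue, optionally restricted to promoter or
#' TSS memberships). Two-sided p from the t-distribution with n - 2
#' degrees of freedom.
#'
#' @param a,b `change_vector` tables for the two tissues, same contrast.
#' @param sites optional data.frame (`chrom`, `pos`, `strand`) restricting
#'   the paired sites; default uses all sites shared by `a` and `b`.
#' @param scope label stored on the result (e.g. `"all_dms"`,
#'   `"promoter"`, `"tss"`).
#' @return object of class `concordance_result`: `contrast`, `scope`, `n`,
#'   `r`, `df` (= n - 2), `p`.
#' @export
correlate_tissue_changes <- function(a, b, sites = NULL, scope = "all_dms") {
  ka <- site_key(a); kb <- site_key(b)
  common <- intersect(ka, kb)
  if (!is.null(sites)) common <- intersect(common, site_key(sites))
  n <- length(common)
  if (n < 3) stop("need at least 3 paired sites, got ", n)
  va <- a$change[match(common, ka)]
  vb <- b$change[match(common, kb)]
  ct <- stats::cor.test(va, vb, method = "pearson")
  structure(list(contrast = attr(a, "contrast"), scope = scope, n = n,
                 r = unname(ct$estimate), df = n - 2L,
                 p = ct$p.value),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "Cross-tissue concordance (%s, %s): r = %.3f, df = %d, p = %.3g\n",
    x$contrast, x$scope, x$r, x$df, x$p))
  invisible(x)
}
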