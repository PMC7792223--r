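#' Per-female average change between two time points
#'
#' The cohort is cross-sectional (different females at each time point), so
#' a per-female change is built from all pairwise differences: for each
#' later-time female, the mean of (her value minus each earlier-time
#' female's value); for each earlier-time female, the mean of (each
#' later-time value minus her value). All entries are oriented
#' later-minus-earlier, and their grand mean equals
#' `mean(later) - mean(earlier)` exactly.
#'
#' @param earlier,later named numeric vectors of one scalar per female
#'   (methylation proportion at a site, or an expression level) at the
#'   earlier / later time point. `NA` females are omitted with a warning.
#' @return named numeric vector of class `pairwise_change`, earlier-time
#'   females first, then later-time females.
#' @export
pairwise_change <- function(earlier, later) {
  drop_na <- function(v, when) {
    if (anyNA(v)) {
      warning(sum(is.na(v)), " ", when,
              "-time female(s) with missing value omitted")
      v <- v[!is.na(v)]
    }
    v
  }
  earlier <- drop_na(earlier, "earlier")
  later <- drop_na(later, "later")
  if (!length(earlier) || !length(later))
    stop("need at least one female at each time point")
  avg_earlier <- vapply(earlier, function(v) mean(later - v), 0)
  avg_later <- vapply(later, function(v) mean(v - earlier), 0)
  structure(c(avg_earlier, avg_later), class = "pairwise_change")
}

#' Correlate per-female methylation and expression change
#'
#' Pearson correlation across the per-female average changes of one CpG
#' site's methylation and one candidate gene's expression (the qPCR-style
#' path). Zero variance in either vector makes the correlation undefined;
#' the result is flagged and should be excluded from multiplicity
#' adjustment (see [adjust_candidate_results()]).
#'
#' @param meth,expr `pairwise_change` vectors of equal length (same female
#'   ordering), n >= 4.
#' @return one-row data.frame: `n`, `r`, `p`, `undefined`.
#' @export
correlate_candidate_gene <- function(meth, expr) {
  m <- unclass(meth); e <- unclass(expr)
  if (length(m) != length(e))
    stop("methylation and expression change vectors differ in length")
  if (length(m) < 4) stop("need at least 4 per-female averages")
  if (stats::sd(m) == 0 || stats::sd(e) == 0)
    return(data.frame(n = length(m), r = NA_real_, p = NA_real_,
                      undefined = TRUE))
  ct <- stats::cor.test(m, e, method = "pearson")
  data.frame(n = length(m), r = unname(ct$estimate), p = ct$p.value,
             undefined = FALSE)
}

#' BH-adjust candidate-gene correlations within a contrast
#'
#' @param results data.frame of stacked [correlate_candidate_gene()] rows
#'   (plus identifying columns) for one contrast.
#' @return `results` with a `p_adj` column; undefined rows keep `NA`.
#' @export
adjust_candidate_results <- function(results) {
  results$p_adj <- NA_real_
  ok <- !results$undefined
  results$p_adj[ok] <- adjust_bh(results$p[ok])
  results
}

#' Quadrant of a methylation-change / expression-change pair
#'
#' Q1 = hypo-methylation with increased expression, Q2 = hyper-methylation
#' with increased expression, Q3 = hyper-methylation with decreased
#' expression, Q4 = hypo-methylation with decreased expression. Q1 and Q3
#' are the concordant quadrants under the expected negative
#' methylation-expression relationship.
#'
#' @param delta_meth methylation change in percentage points (nonzero).
#' @param log2fc expression log2 fold change (nonzero).
#' @return character vector of `"Q1"`..`"Q4"`.
#' @export
assign_quadrant <- function(delta_meth, log2fc) {
  if (any(delta_meth == 0) || any(log2fc == 0))
    stop("zero change reached quadrant assignment; trim inputs first")
  ifelse(log2fc > 0,
         ifelse(delta_meth < 0, "Q1", "Q2"),
         ifelse(delta_meth > 0, "Q3", "Q4"))
}

#' Methylation change in percentage points for quadrant analysis
#'
#' Raw-scale change (not z-scored): mean methylation percentage across
#' females at the later time minus the mean at the earlier time, per site.
#'
#' @param props a complete `meth_props`.
#' @param contrast a pairwise [contrast_spec()].
#' @return numeric vector (percentage points), one value per site.
#' @export
delta_meth_percent <- function(props, contrast) {
  stopifnot(inherits(props, "meth_props"),
            inherits(contrast, "contrast_spec"))
  ja <- props$samples$time_point == contrast$time_a
  jb <- props$samples$time_point == contrast$time_b
  100 * (rowMeans(props$proportion[, jb, drop = FALSE]) -
           rowMeans(props$proportion[, ja, drop = FALSE]))
}

#' Build site-gene-region quadrant associations
#'
#' Pairs every omnibus-significant CpG site with every time-responsive gene
#' whose annotated region contains it, computes the raw methylation change
#' and the gene's log2 fold change for the contrast, trims weak changes
#' (|delta| < `trim_meth` percentage points or |log2FC| < `trim_lfc`), and
#' assigns the quadrant. A site contributes once per region category it
#' belongs to.
#'
#' @param dms an omnibus `dms_result` for the methylation tissue.
#' @param de a `de_result` with `passes_filter` (see
#'   [filter_time_responsive_genes()]).
#' @param assignment site-region memberships from
#'   [assign_sites_to_regions()].
#' @param props the methylation tissue's complete `meth_props` (source of
#'   the raw change).
#' @param contrast a pairwise [contrast_spec()].
#' @param tissue_pair label such as `"liver->liver"` or `"RBC->ovary"`.
#' @param trim_meth,trim_lfc trimming thresholds (defaults 5 pp, 0.5).
#' @return data.frame of class `quadrant_assoc`: `chrom`, `pos`, `strand`,
#'   `gene_id`, `region`, `tissue_pair`, `contrast`, `delta_meth`,
#'   `log2fc`, `quadrant`.
#' @export
build_quadrant_associations <- function(dms, de, assignment, props,
                                        contrast, tissue_pair,
                                        trim_meth = 5, trim_lfc = 0.5) {
  stopifnot(inherits(contrast, "contrast_spec"))
  empty <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      region = character(), tissue_pair = character(),
                      contrast = character(), delta_meth = numeric(),
                      log2fc = numeric(), quadrant = character())
  class(empty) <- c("quadrant_assoc", "data.frame")
  sig_sites <- dms[dms$is_dms, , drop = FALSE]
  sig_genes <- de[de$passes_filter, , drop = FALSE]
  if (!nrow(sig_sites) || !nrow(sig_genes)) {
    warning("no significant ",
            if (nrow(sig_sites)) "genes" else "sites",
            "; empty association table")
    return(empty)
  }
  lfc_col <- if (contrast$label == "d12") "log2fc_12" else "log2fc_23"
  dmv <- delta_meth_percent(props, contrast)
  names(dmv) <- site_key(props$sites)
  skey <- site_key(sig_sites)
  akey <- site_key(assignment)
  hit <- assignment[akey %in% skey &
                      assignment$gene_id %in% sig_genes$gene_id, ,
                    drop = FALSE]
  if (!nrow(hit)) {
    warning("no significant site falls in a region of a significant gene")
    return(empty)
  }
  hit$delta_meth <- dmv[site_key(hit)]
  hit$log2fc <- sig_genes[[lfc_col]][match(hit$gene_id, sig_genes$gene_id)]
  keep <- !is.na(hit$delta_meth) & abs(hit$delta_meth) >= trim_meth &
    abs(hit$log2fc) >= trim_lfc
  hit <- hit[keep, , drop = FALSE]
  if (!nrow(hit)) return(empty)
  hit$tissue_pair <- tissue_pair
  hit$contrast <- contrast$label
  hit$quadrant <- assign_quadrant(hit$delta_meth, hit$log2fc)
  out <- hit[, c("chrom", "pos", "strand", "gene_id", "region",
                 "tissue_pair", "contrast", "delta_meth", "log2fc",
                 "quadrant")]
  rownames(out) <- NULL
  class(out) <- c("quadrant_assoc", "data.frame")
  out
}

# two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables with the observed margins whose
# probability does not exceed the observed table's (with the usual
# relative tolerance for ties).
fisher_p_enum <- function(a, b, c_, d, alternative = "two.sided") {
  N <- a + b + c_ + d
  K <- a + b       # row 1 total
  n1 <- a + c_     # column 1 total
  lo <- max(0, n1 - (N - K)); hi <- min(K, n1)
  xs <- lo:hi
  probs <- stats::dhyper(xs, n1, N - n1, K)
  obs <- stats::dhyper(a, n1, N - n1, K)
  switch(alternative,
         two.sided = sum(probs[probs <= obs * (1 + 1e-7)]),
         greater = stats::phyper(a - 1, n1, N - n1, K, lower.tail = FALSE),
         less = stats::phyper(a, n1, N - n1, K))
}

#' Fisher enrichment of concordant quadrants, TSS vs downstream flank
#'
#' Tests whether associations in the TSS region fall into the concordant
#' quadrants (Q1 or Q3) more often than associations in the 10 kb
#' downstream control region, where methylation and expression are not
#' expected to be related. The 2x2 table is region (test vs control) by
#' quadrant class (Q1+Q3 vs Q2+Q4); the p-value is the exact
#' hypergeometric enumeration (two-sided by default), and the odds ratio
#' is the sample odds ratio, with a 0.5 continuity correction applied (and
#' flagged) only when a cell is zero.
#'
#' @param assocs a `quadrant_assoc` table.
#' @param test_region,control_region region labels (defaults `"tss"`,
#'   `"down10kb"`).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return object of class `enrichment_result`: `table` (2x2 counts),
#'   `odds_ratio`, `p`, `continuity`.
#' @export
fisher_enrichment <- function(assocs, test_region = "tss",
                              control_region = "down10kb",
                              alternative = c("two.sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  conc <- assocs$quadrant %in% c("Q1", "Q3")
  in_test <- assocs$region == test_region
  in_ctrl <- assocs$region == control_region
  if (!any(in_test))
    stop("no associations in test region '", test_region, "'")
  if (!any(in_ctrl))
    stop("no associations in control region '", control_region, "'")
  a <- sum(in_test & conc); b <- sum(in_test & !conc)
  c_ <- sum(in_ctrl & conc); d <- sum(in_ctrl & !conc)
  tab <- matrix(c(a, b, c_, d), 2, byrow = TRUE,
                dimnames = list(c(test_region, control_region),
                                c("Q1+Q3", "Q2+Q4")))
  continuity <- any(tab == 0)
  or <- if (continuity) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else (a * d) / (b * c_)
  structure(list(table = tab, odds_ratio = or,
                 p = fisher_p_enum(a, b, c_, d, alternative),
                 alternative = alternative, continuity = continuity),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("Quadrant enrichment (Fisher exact, ", x$alternative, ")\n", sep = "")
  print(x$table)
  cat(sprintf("  odds ratio = %.3f%s, p = %.4g\n", x$odds_ratio,
              if (x$continuity) " (0.5 continuity correction)" else "",
              x$p))
  invisible(x)
}
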