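#' Construct a pooled expression count matrix
#'
#' @param genes character vector of gene ids.
#' @param pools data.frame of pool metadata with `pool_id`, `tissue` and
#'   `time_point` (2 pools x 3 time points per tissue in the study design,
#'   each pool aggregating 3 females).
#' @param counts genes x pools matrix of non-negative integer counts.
#' @return object of class `expr_counts`.
#' @export
expr_counts <- function(genes, pools, counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (nrow(counts) != length(genes) || ncol(counts) != nrow(pools))
    stop("count matrix dimensions do not match genes/pools")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(is.na(pools$time_point))) stop("every pool needs a time_point")
  rownames(counts) <- genes
  colnames(counts) <- pools$pool_id
  structure(list(genes = genes, pools = pools, counts = counts),
            class = "expr_counts")
}

#' @export
print.expr_counts <- function(x, ...) {
  cat(sprintf("expr_counts: %d genes x %d pools (tissue: %s)\n",
              length(x$genes), nrow(x$pools),
              if (nrow(x$pools)) x$pools$tissue[1] else "?"))
  invisible(x)
}

#' Read a pooled gene count table
#'
#' TSV with header: `gene_id` then one column per pool_id.
#'
#' @param path file path.
#' @param pools pool metadata data.frame.
#' @return an `expr_counts` object.
#' @export
read_expr_counts <- function(path, pools) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(pools$pool_id, names(d))
  if (length(miss))
    stop("count table lacks pool column(s): ", paste(miss, collapse = ", "))
  expr_counts(d$gene_id, pools, as.matrix(d[, pools$pool_id, drop = FALSE]))
}

#' Median-of-ratios size factors
#'
#' Each pool's factor is the median ratio of its counts to the per-gene
#' geometric-mean pseudo-reference (computed over genes positive in every
#' pool), then the factors are centered to geometric mean 1.
#'
#' @param x an `expr_counts` object.
#' @return named numeric vector of positive size factors.
#' @export
normalize_size_factors <- function(x) {
  stopifnot(inherits(x, "expr_counts"))
  cts <- x$counts
  if (any(colSums(cts) == 0))
    stop("pool(s) with all-zero counts: ",
         paste(x$pools$pool_id[colSums(cts) == 0], collapse = ", "))
  pos <- rowSums(cts > 0) == ncol(cts)
  if (!any(pos))
    stop("no gene has nonzero counts in every pool")
  logref <- rowMeans(log(cts[pos, , drop = FALSE]))
  sf <- apply(cts[pos, , drop = FALSE], 2,
              function(col) exp(stats::median(log(col) - logref)))
  sf <- sf / exp(mean(log(sf)))  # geometric-mean centering
  stats::setNames(sf, x$pools$pool_id)
}

nb_loglik <- function(y, mu, size) {
  sum(stats::dnbinom(y, size = size, mu = mu, log = TRUE))
}

# MLE of a common mean m (on the normalized scale, fitted means m * sf)
# for NB counts with fixed size r, by Newton iteration on log(m).
nb_fit_mean <- function(y, sf, size) {
  m <- sum(y) / sum(sf)
  if (m <= 0) return(0)
  lm_ <- log(m)
  for (it in 1:50) {
    mu <- exp(lm_) * sf
    # d loglik / d log m
    g <- sum(y - (y + size) * mu / (mu + size))
    h <- -sum((y + size) * mu * size / (mu + size)^2)
    if (abs(h) < 1e-12) break
    step <- g / h
    step <- max(min(step, 5), -5)
    lm_ <- lm_ - step
    if (abs(step) < 1e-10) break
  }
  exp(lm_)
}

#' Negative-binomial time-effect test for pooled expression
#'
#' Simplified stand-in for a full differential-expression analysis: per
#' gene, the counts are modelled as negative binomial with a gene-wise
#' dispersion estimated by the method of moments on normalized counts
#' (residual variance about the time-point means, so a true time effect
#' does not inflate the estimate; floored at 1e-8), and the mean model
#' with a time-point factor is
#' compared to an intercept-only model by likelihood ratio on 2 degrees of
#' freedom. Size factors enter as multiplicative offsets. The same
#' dispersion is shared by both models of a gene, so the statistic is
#' non-negative. All-zero genes are skipped (`NA` statistics,
#' `skipped = TRUE`). Per-contrast log2 fold changes are attached via
#' [log2fc_contrast()].
#'
#' @param x an `expr_counts` object with 3 time points, >= 2 pools each.
#' @param sf size factors from [normalize_size_factors()].
#' @param dispersion_floor lower bound on the moment dispersion estimate.
#' @return data.frame of class `de_result`: `gene_id`, `dispersion`,
#'   `lrt_stat`, `df`, `p_time`, `q_time`, `log2fc_12`, `log2fc_23`,
#'   `skipped`.
#' @export
test_time_effect_nb <- function(x, sf, dispersion_floor = 1e-8) {
  stopifnot(inherits(x, "expr_counts"))
  tp <- x$pools$time_point
  if (!all(1:3 %in% tp)) stop("all three time points must be present")
  if (any(table(tp) < 2)) stop("need >= 2 pools per time point")
  ng <- length(x$genes)
  lrt <- disp <- rep(NA_real_, ng)
  skipped <- logical(ng)
  for (i in seq_len(ng)) {
    y <- x$counts[i, ]
    if (all(y == 0)) { skipped[i] <- TRUE; next }
    norm <- y / sf
    mbar <- mean(norm)
    # residual (within time-point) variance so true time effects do not
    # inflate the dispersion estimate
    resid <- norm - stats::ave(norm, tp)
    vbar <- sum(resid^2) / (length(y) - 3L)
    phi <- max((vbar - mbar) / mbar^2, dispersion_floor)
    size <- 1 / phi
    ll_null <- nb_loglik(y, nb_fit_mean(y, sf, size) * sf, size)
    ll_full <- 0
    for (t in 1:3) {
      jt <- tp == t
      ll_full <- ll_full +
        nb_loglik(y[jt], nb_fit_mean(y[jt], sf[jt], size) * sf[jt], size)
    }
    lrt[i] <- max(2 * (ll_full - ll_null), 0)
    disp[i] <- phi
  }
  p <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  out <- data.frame(gene_id = x$genes, dispersion = disp, lrt_stat = lrt,
                    df = 2L, p_time = p, stringsAsFactors = FALSE)
  out$q_time <- NA_real_
  out$q_time[!skipped] <- adjust_bh(out$p_time[!skipped])
  out$log2fc_12 <- log2fc_contrast(x, sf, contrast_spec("d12"))
  out$log2fc_23 <- log2fc_contrast(x, sf, contrast_spec("d23"))
  out$skipped <- skipped
  structure(out, class = c("de_result", "data.frame"),
            tissue = if (nrow(x$pools)) x$pools$tissue[1] else NA)
}

#' Per-gene log2 fold change between two time points
#'
#' `log2((mean normalized count at the later time + 0.5) / (mean at the
#' earlier time + 0.5))`; positive means up-regulation at the later time.
#' The 0.5 pseudo-count keeps zero-count groups finite.
#'
#' @param x an `expr_counts` object.
#' @param sf size factors.
#' @param contrast a pairwise [contrast_spec()].
#' @return numeric vector, one value per gene.
#' @export
log2fc_contrast <- function(x, sf, contrast) {
  stopifnot(inherits(x, "expr_counts"), inherits(contrast, "contrast_spec"))
  if (is.null(contrast$time_a)) stop("need a pairwise contrast")
  norm <- sweep(x$counts, 2, sf, "/")
  ja <- x$pools$time_point == contrast$time_a
  jb <- x$pools$time_point == contrast$time_b
  ma <- rowMeans(norm[, ja, drop = FALSE])
  mb <- rowMeans(norm[, jb, drop = FALSE])
  log2((mb + 0.5) / (ma + 0.5))
}

#' Select genes responding to time but not to selection line
#'
#' A gene passes when its time-effect adjusted p is below `de_q` and, if a
#' selection-line p-value is supplied, its BH-adjusted line p is above
#' 0.05 (line-responsive genes are excluded). Cohorts without a line
#' factor omit `line_p`.
#'
#' @param de a `de_result`.
#' @param line_p optional per-gene raw p-values for a selection-line
#'   effect, same order as `de`.
#' @param de_q time-effect threshold on the adjusted p (default 0.05).
#' @return the `de_result` with a logical `passes_filter` column.
#' @export
filter_time_responsive_genes <- function(de, line_p = NULL, de_q = 0.05) {
  passes <- !de$skipped & !is.na(de$q_time) & de$q_time < de_q
  if (!is.null(line_p)) {
    if (length(line_p) != nrow(de))
      stop("line_p must have one value per gene")
    passes <- passes & adjust_bh(line_p) > 0.05
  }
  de$passes_filter <- passes
  de
}
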