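#' Specify a time-point contrast
#'
#' @param label one of `"d12"` (time point 1 vs 2), `"d23"` (2 vs 3) or
#'   `"omnibus"` (joint test over all three time points).
#' @return list of class `contrast_spec` with `label` and, for pairwise
#'   contrasts, `time_a` (earlier) and `time_b` (later).
#' @export
contrast_spec <- function(label = c("d12", "d23", "omnibus")) {
  label <- match.arg(label)
  out <- switch(label,
                d12 = list(label = "d12", time_a = 1L, time_b = 2L),
                d23 = list(label = "d23", time_a = 2L, time_b = 3L),
                omnibus = list(label = "omnibus"))
  structure(out, class = "contrast_spec")
}

# binomial log-likelihood term with 0*log(0) = 0
xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

binom_ll <- function(m, n, p) xlogy(m, p) + xlogy(n - m, 1 - p)

#' Pairwise differential methylation test
#'
#' Per CpG site, a two-group binomial likelihood-ratio test on
#' coverage-pooled counts. Reads within each time-point group are pooled
#' (sum of methylated over sum of coverage); the alternative evaluates the
#' binomial log-likelihood at the two group proportions, the null at the
#' overall pooled proportion, statistic = 2 x difference on 1 degree of
#' freedom. The methylation difference is the later-minus-earlier pooled
#' proportion in percentage points. A site is called differentially
#' methylated when both `|meth_diff| >= diff_threshold` and
#' `q <= q_threshold` (defaults 15 percentage points, 0.01). The pairwise
#' test uses only the two groups' samples and no covariate.
#'
#' The plain binomial likelihood assumes no replicate overdispersion
#' (the default, matching the common logistic-regression test for RRBS);
#' `overdispersion = "scale"` divides the statistic by a per-site Pearson
#' dispersion factor (floored at 1) estimated from the per-sample counts
#' under the fitted group proportions.
#'
#' @param x a filtered `meth_counts` table.
#' @param contrast a pairwise [contrast_spec()].
#' @param diff_threshold minimum absolute difference in percentage points.
#' @param q_threshold maximum BH-adjusted p-value.
#' @param overdispersion `"none"` (default) or `"scale"`.
#' @return data.frame of class `dms_result`: site columns, `meth_diff`,
#'   `lrt_stat`, `df`, `p`, `q`, `is_dms`; attributes `tissue`, `contrast`
#'   and the thresholds. Sites with zero pooled coverage in a group are
#'   skipped with a warning.
#' @export
test_pairwise_contrast <- function(x, contrast, diff_threshold = 15,
                                   q_threshold = 0.01,
                                   overdispersion = c("none", "scale")) {
  stopifnot(inherits(x, "meth_counts"), inherits(contrast, "contrast_spec"))
  overdispersion <- match.arg(overdispersion)
  if (is.null(contrast$time_a))
    stop("test_pairwise_contrast needs a pairwise contrast")
  ja <- x$samples$time_point == contrast$time_a
  jb <- x$samples$time_point == contrast$time_b
  if (!any(ja) || !any(jb))
    stop("both time points of the contrast need at least one sample")
  m1 <- rowSums(x$methylated[, ja, drop = FALSE])
  c1 <- rowSums(x$coverage[, ja, drop = FALSE])
  m2 <- rowSums(x$methylated[, jb, drop = FALSE])
  c2 <- rowSums(x$coverage[, jb, drop = FALSE])
  ok <- c1 > 0 & c2 > 0
  if (any(!ok))
    warning(sum(!ok), " site(s) skipped: zero pooled coverage in a group")
  p1 <- m1 / c1; p2 <- m2 / c2; p0 <- (m1 + m2) / (c1 + c2)
  lrt <- 2 * (binom_ll(m1, c1, p1) + binom_ll(m2, c2, p2) -
                binom_ll(m1 + m2, c1 + c2, p0))
  lrt <- pmax(lrt, 0)
  if (overdispersion == "scale") {
    # Pearson dispersion of per-sample counts about the fitted group
    # proportions; statistic deflated when replicates are overdispersed
    phat <- matrix(NA_real_, nrow(x$sites), ncol(x$coverage))
    phat[, ja] <- p1; phat[, jb] <- p2
    use <- !is.na(phat) & x$coverage > 0 & phat > 0 & phat < 1
    resid2 <- (x$methylated - x$coverage * phat)^2 /
      (x$coverage * phat * (1 - phat))
    resid2[!use] <- 0
    scale_hat <- pmax(rowSums(resid2) / pmax(rowSums(use) - 2, 1), 1)
    lrt <- lrt / scale_hat
  }
  pval <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  out <- data.frame(x$sites,
                    meth_diff = 100 * (p2 - p1),
                    lrt_stat = lrt, df = 1L, p = pval,
                    stringsAsFactors = FALSE)
  out <- out[ok, , drop = FALSE]
  out$q <- adjust_bh(out$p)
  out$is_dms <- abs(out$meth_diff) >= diff_threshold & out$q <= q_threshold
  rownames(out) <- NULL
  structure(out, class = c("dms_result", "data.frame"),
            tissue = if (nrow(x$samples)) x$samples$tissue[1] else NA,
            contrast = contrast$label,
            diff_threshold = diff_threshold, q_threshold = q_threshold)
}

#' @export
print.dms_result <- function(x, ...) {
  cat(sprintf(
    "Differential methylation (%s, %s): %d sites tested, %d DMS\n",
    attr(x, "tissue"), attr(x, "contrast"), nrow(x), sum(x$is_dms)))
  NextMethod()
}

# IRLS fit of a binomial-logit model; returns deviance and convergence flag.
# y = successes, n = trials, X = design. Step halving on deviance increase,
# linear predictor clamped to +-30 (bounds the step under separation).
irls_binom <- function(y, n, X, max_iter = 50, tol = 1e-8) {
  use <- n > 0
  yv <- y[use]; nv <- n[use]; Xv <- X[use, , drop = FALSE]
  dev_at <- function(mu) {
    2 * sum(xlogy(yv, yv / (nv * mu)) + xlogy(nv - yv, (nv - yv) / (nv - nv * mu)))
  }
  beta <- numeric(ncol(Xv))
  eta <- drop(Xv %*% beta)
  mu <- stats::plogis(eta)
  dev <- dev_at(mu)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    var_mu <- mu * (1 - mu)
    w <- nv * var_mu
    z <- eta + (yv / nv - mu) / pmax(var_mu, 1e-10)
    fit <- stats::lm.wfit(Xv, z, pmax(w, 1e-10))
    beta_new <- fit$coefficients
    beta_new[is.na(beta_new)] <- 0
    step <- beta_new - beta
    dev_new <- NA
    for (h in 0:10) {  # step halving
      bh <- beta + step / 2^h
      eta_h <- pmin(pmax(drop(Xv %*% bh), -30), 30)
      mu_h <- stats::plogis(eta_h)
      dev_new <- dev_at(mu_h)
      if (is.finite(dev_new) && dev_new <= dev + 1e-12) {
        beta <- bh; eta <- eta_h; mu <- mu_h
        break
      }
    }
    if (!is.finite(dev_new)) break
    if (abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      converged <- TRUE
      break
    }
    dev <- dev_new
  }
  list(deviance = dev, converged = converged)
}

#' Omnibus time-effect test for methylation
#'
#' Per CpG site, a binomial regression on the logit scale fitted by
#' iteratively reweighted least squares. The full model has an intercept,
#' two time-point indicators and a temperature-environment indicator; the
#' null model drops the time indicators (keeping temperature). The
#' likelihood-ratio statistic is the deviance difference on 2 degrees of
#' freedom. A time effect is significant at `q <= q_threshold`
#' (default 0.01).
#'
#' @param x a filtered `meth_counts` table with all three time points and
#'   `temperature_env` recorded for every sample.
#' @param include_temperature logical; drop the covariate to obtain the
#'   pure three-group comparison (default `TRUE`).
#' @param q_threshold significance threshold on the adjusted p-value.
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance.
#' @return `dms_result` data.frame with `lrt_stat`, `df = 2`, `p`, `q`,
#'   `is_dms` and a `converged` flag (non-converged sites keep the deviance
#'   at the last iterate).
#' @export
test_time_omnibus <- function(x, include_temperature = TRUE,
                              q_threshold = 0.01, max_iter = 50,
                              tol = 1e-8) {
  stopifnot(inherits(x, "meth_counts"))
  tp <- x$samples$time_point
  if (!all(1:3 %in% tp)) stop("all three time points must be present")
  if (include_temperature && any(is.na(x$samples$temperature_env)))
    stop("temperature_env missing for some samples")
  t2 <- as.numeric(tp == 2); t3 <- as.numeric(tp == 3)
  Xn <- matrix(1, length(tp), 1, dimnames = list(NULL, "intercept"))
  if (include_temperature) {
    temp <- as.numeric(x$samples$temperature_env == "warm")
    Xn <- cbind(Xn, temp = temp)
  }
  Xf <- cbind(intercept = 1, t2 = t2, t3 = t3,
              Xn[, -1, drop = FALSE])
  ns <- nrow(x$sites)
  lrt <- numeric(ns); conv <- logical(ns)
  for (i in seq_len(ns)) {
    y <- x$methylated[i, ]; n <- x$coverage[i, ]
    ff <- irls_binom(y, n, Xf, max_iter, tol)
    fn <- irls_binom(y, n, Xn, max_iter, tol)
    lrt[i] <- max(fn$deviance - ff$deviance, 0)
    conv[i] <- ff$converged && fn$converged
  }
  pval <- stats::pchisq(lrt, df = 2, lower.tail = FALSE)
  out <- data.frame(x$sites, meth_diff = NA_real_, lrt_stat = lrt,
                    df = 2L, p = pval, stringsAsFactors = FALSE)
  out$q <- adjust_bh(out$p)
  out$is_dms <- out$q <= q_threshold
  out$converged <- conv
  rownames(out) <- NULL
  structure(out, class = c("dms_result", "data.frame"),
            tissue = if (nrow(x$samples)) x$samples$tissue[1] else NA,
            contrast = "omnibus", q_threshold = q_threshold)
}

#' Classify shared DMS as tissue-general or tissue-specific
#'
#' A site significant in both tissues changes in a tissue-general manner;
#' significant in exactly one, in a tissue-specific manner; significant in
#' neither, it is omitted.
#'
#' @param rbc,liv `dms_result` tables for the two tissues over the same
#'   contrast, restricted to shared sites (see [intersect_tissues()]).
#' @return data.frame: site columns, `contrast`, `klass` in
#'   `{general, rbc_specific, liver_specific}`.
#' @export
classify_tissue_generality <- function(rbc, liv) {
  if (!identical(attr(rbc, "contrast"), attr(liv, "contrast")))
    stop("contrast mismatch: ", attr(rbc, "contrast"), " vs ",
         attr(liv, "contrast"))
  ka <- site_key(rbc); kb <- site_key(liv)
  common <- intersect(ka, kb)
  a <- rbc[match(common, ka), ]; b <- liv[match(common, kb), ]
  klass <- ifelse(a$is_dms & b$is_dms, "general",
                  ifelse(a$is_dms, "rbc_specific",
                         ifelse(b$is_dms, "liver_specific", NA)))
  out <- data.frame(chrom = a$chrom, pos = a$pos, strand = a$strand,
                    contrast = attr(rbc, "contrast"), klass = klass,
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$klass), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a DMS table as TSV
#'
#' @param dms a `dms_result`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dms_tsv <- function(dms, path) {
  d <- as.data.frame(dms)
  d$tissue <- attr(dms, "tissue")
  d$contrast <- attr(dms, "contrast")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
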