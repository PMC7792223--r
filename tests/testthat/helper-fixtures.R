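# small in-code fixtures shared across test files

make_meta <- function(tissue = "RBC", n_per_tp = 2, time_points = 1:3) {
  n <- length(time_points) * n_per_tp
  data.frame(
    sample_id = paste0(tissue, "_s", seq_len(n)),
    female_id = sprintf("F%02d", seq_len(n)),
    tissue = tissue,
    time_point = rep(time_points, each = n_per_tp),
    temperature_env = rep(c("warm", "cold"), length.out = n),
    family_id = paste0("fam", rep(seq_len(ceiling(n / 2)), 2)[seq_len(n)]),
    stringsAsFactors = FALSE)
}

make_sites <- function(n, chrom = "chr1") {
  data.frame(chrom = chrom, pos = seq(100, by = 100, length.out = n),
             strand = "+", stringsAsFactors = FALSE)
}

# counts with per-cell proportions given as a sites x samples matrix
make_counts <- function(props, cov = 30, meta = NULL, tissue = "RBC") {
  props <- as.matrix(props)
  if (is.null(meta)) {
    npt <- ncol(props) / 3
    meta <- make_meta(tissue, n_per_tp = npt)
  }
  covm <- matrix(cov, nrow(props), ncol(props))
  meth_counts(make_sites(nrow(props)), meta, covm, round(covm * props))
}

site_keys <- function(d) paste(d$chrom, d$pos, d$strand, sep = ":")

# independent binomial-LRT oracle: maximize each likelihood over a grid
# (boundary values included so degenerate group proportions are exact)
grid_lrt_oracle <- function(m1, c1, m2, c2,
                            grid = c(0, seq(1e-4, 0.9999, by = 1e-4), 1)) {
  ll <- function(m, cc) {
    out <- rep(0, length(grid))
    if (m > 0) out <- out + m * log(grid)
    if (cc - m > 0) out <- out + (cc - m) * log(1 - grid)
    max(out, na.rm = TRUE)
  }
  2 * (ll(m1, c1) + ll(m2, c2) - ll(m1 + m2, c1 + c2))
}

# explicit BH step-up oracle: sort, scale by n/rank, cummin from largest
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# closed-form k-group pooled binomial LRT (df = k - 1)
pooled_group_lrt <- function(m_list, c_list) {
  ll <- function(m, cc, p) {
    ifelse(m == 0, 0, m * log(p)) + ifelse(cc - m == 0, 0,
                                           (cc - m) * log(1 - p))
  }
  m_tot <- sum(unlist(m_list)); c_tot <- sum(unlist(c_list))
  alt <- sum(mapply(function(m, cc) ll(m, cc, m / cc), m_list, c_list))
  2 * (alt - ll(m_tot, c_tot, m_tot / c_tot))
}
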