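#' methtempo: temporal methylation dynamics across tissues
#'
#' Tools for RRBS time-course analysis: per-CpG count handling, coverage and
#' invariance filtering, strand-aware region annotation, binomial
#' likelihood-ratio differential methylation, cross-tissue concordance of
#' z-scored change, simplified negative-binomial differential expression,
#' methylation--expression quadrant integration, and a seeded synthetic-data
#' generator.
#'
#' @name methtempo-package
#' @keywords internal
"_PACKAGE"

VALID_TISSUES <- c("RBC", "liver", "hypothalamus", "ovary")

site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$strand, sep = ":")
}

#' Construct a per-tissue methylation count table
#'
#' Container for a sites x samples matrix pair of sequencing coverage and
#' methylated-read counts, all samples from a single tissue.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position of the cytosine) and `strand` (`"+"`/`"-"`).
#' @param samples data.frame of sample metadata with at least `sample_id`,
#'   `female_id`, `tissue`, `time_point` (1, 2 or 3) and `temperature_env`
#'   (`"warm"`/`"cold"`); optionally `family_id` and `pool_id`.
#' @param coverage,methylated integer matrices, rows = sites, columns =
#'   samples; `methylated <= coverage` cellwise.
#' @return An object of class `meth_counts`.
#' @export
meth_counts <- function(sites, samples, coverage, methylated) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  coverage <- as.matrix(coverage)
  methylated <- as.matrix(methylated)
  storage.mode(coverage) <- "double"
  storage.mode(methylated) <- "double"
  obj <- structure(
    list(sites = sites, samples = samples,
         coverage = coverage, methylated = methylated),
    class = "meth_counts")
  validate_meth_counts(obj)
  obj
}

validate_meth_counts <- function(x) {
  stopifnot(is.data.frame(x$sites), is.data.frame(x$samples))
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(x$sites)))
    stop("sites must have columns chrom, pos, strand")
  if (any(x$sites$pos < 1)) stop("site positions must be >= 1")
  if (!all(x$sites$strand %in% c("+", "-")))
    stop("site strand must be '+' or '-'")
  if (anyDuplicated(site_key(x$sites)))
    stop("duplicate (chrom, pos, strand) site")
  if (!"sample_id" %in% names(x$samples)) stop("samples need sample_id")
  if (nrow(x$coverage) != nrow(x$sites) ||
      nrow(x$methylated) != nrow(x$sites) ||
      ncol(x$coverage) != nrow(x$samples) ||
      ncol(x$methylated) != nrow(x$samples))
    stop("count matrix dimensions do not match sites/samples")
  if (any(x$coverage < 0) || any(x$methylated < 0))
    stop("counts must be non-negative")
  if (any(x$methylated > x$coverage))
    stop("methylated count exceeds coverage")
  tis <- unique(x$samples$tissue)
  if (length(tis) > 1)
    stop("all samples in one table must share a tissue; got: ",
         paste(tis, collapse = ", "))
  if ("female_id" %in% names(x$samples) &&
      anyDuplicated(paste(x$samples$female_id, x$samples$tissue)))
    stop("each (female_id, tissue) may appear at most once")
  invisible(x)
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("meth_counts: %d CpG sites x %d samples (tissue: %s)\n",
              nrow(x$sites), nrow(x$samples),
              if (nrow(x$samples)) x$samples$tissue[1] else "?"))
  if (nrow(x$sites)) {
    cat(sprintf("  coverage: median %.0f (range %.0f-%.0f)\n",
                stats::median(x$coverage), min(x$coverage), max(x$coverage)))
  }
  invisible(x)
}

#' @export
dim.meth_counts <- function(x) c(nrow(x$sites), nrow(x$samples))

#' Subset a methylation count table by site and/or sample index
#'
#' @param x a `meth_counts` object.
#' @param i site indices (logical or integer).
#' @param j sample indices.
#' @param ... ignored.
#' @return a `meth_counts` object.
#' @export
`[.meth_counts` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$sites))
  if (missing(j)) j <- seq_len(nrow(x$samples))
  meth_counts(x$sites[i, , drop = FALSE],
              x$samples[j, , drop = FALSE],
              x$coverage[i, j, drop = FALSE],
              x$methylated[i, j, drop = FALSE])
}

#' Read a sample metadata table
#'
#' Tab-separated with header: sample_id, female_id, tissue, time_point,
#' temperature_env, family_id and optionally pool_id.
#'
#' @param path file path.
#' @return data.frame of sample metadata.
#' @export
read_sample_meta <- function(path) {
  meta <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  need <- c("sample_id", "female_id", "tissue", "time_point",
            "temperature_env")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(is.na(meta$time_point)) || !all(meta$time_point %in% 1:3))
    stop("every sample needs a time_point in 1..3")
  if (any(is.na(meta$temperature_env)))
    stop("every sample needs a temperature_env")
  meta
}

parse_coverage_file <- function(path) {
  if (!file.exists(path)) stop("coverage file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("coverage file is empty: ", path)
    return(data.frame(chrom = character(), pos = integer(),
                      meth = integer(), unmeth = integer()))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 6L)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected 6 fields, got %d",
                 bad[1], path, nf[bad[1]]))
  m <- matrix(unlist(fields), ncol = 6L, byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  meth <- suppressWarnings(as.numeric(m[, 5]))
  unmeth <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos) | is.na(meth) | is.na(unmeth) |
                 meth < 0 | unmeth < 0)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: non-numeric or negative count",
                 bad[1], path))
  data.frame(chrom = m[, 1], pos = pos, meth = meth, unmeth = unmeth,
             stringsAsFactors = FALSE)
}

#' Read Bismark-style coverage files into a count table
#'
#' One file per sample, six whitespace-separated columns: chromosome, start,
#' end (1-based, start == end for a CpG), percent methylation, count
#' methylated, count unmethylated. Coverage is the sum of the two counts.
#' The coverage dialect carries no strand column, so sites are recorded on
#' the "+" strand; use [read_wide_counts()] for strand-resolved input.
#' The site set of the returned table is the union over files; a site absent
#' from a sample gets coverage 0 there (removed later by the coverage
#' filter; no imputation).
#'
#' @param paths character vector of file paths, one per sample, in the same
#'   order as the rows of `meta`.
#' @param meta sample metadata data.frame (see [read_sample_meta()]).
#' @return a `meth_counts` object.
#' @export
read_coverage_files <- function(paths, meta) {
  if (length(paths) != nrow(meta))
    stop("need exactly one coverage file per metadata row")
  per <- lapply(paths, parse_coverage_file)
  keys <- unique(unlist(lapply(per, function(d) paste(d$chrom, d$pos))))
  if (!length(keys)) {
    sites <- data.frame(chrom = character(), pos = integer(),
                        strand = character())
    z <- matrix(0, 0, nrow(meta))
    return(meth_counts(sites, meta, z, z))
  }
  parts <- do.call(rbind, strsplit(keys, " ", fixed = TRUE))
  sites <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                      strand = "+", stringsAsFactors = FALSE)
  ord <- order(sites$chrom, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  keys <- keys[ord]
  cov <- meth <- matrix(0, nrow(sites), nrow(meta))
  for (j in seq_along(per)) {
    d <- per[[j]]
    if (!nrow(d)) next
    idx <- match(paste(d$chrom, d$pos), keys)
    cov[idx, j] <- d$meth + d$unmeth
    meth[idx, j] <- d$meth
  }
  colnames(cov) <- colnames(meth) <- meta$sample_id
  meth_counts(sites, meta, cov, meth)
}

#' Write a count table as Bismark-style coverage files
#'
#' Writes one `<sample_id>.cov` file per sample into `dir`, containing only
#' the cells with coverage > 0 (zero-coverage cells denote absence in this
#' dialect). Inverse of [read_coverage_files()] for "+"-strand tables.
#'
#' @param x a `meth_counts` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_coverage_files <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(x$samples$sample_id, ".cov"))
  for (j in seq_len(nrow(x$samples))) {
    keep <- x$coverage[, j] > 0
    d <- data.frame(chrom = x$sites$chrom[keep], start = x$sites$pos[keep],
                    end = x$sites$pos[keep],
                    pct = round(100 * x$methylated[keep, j] /
                                  x$coverage[keep, j], 6),
                    meth = x$methylated[keep, j],
                    unmeth = x$coverage[keep, j] - x$methylated[keep, j])
    utils::write.table(d, paths[j], sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(paths)
}

#' Read a wide TSV count table
#'
#' Alternative dialect: header row, columns `chrom`, `pos`, `strand`, then
#' for each sample a `<sample_id>.cov` and `<sample_id>.meth` column pair.
#'
#' @param path file path.
#' @param meta sample metadata data.frame.
#' @return a `meth_counts` object.
#' @export
read_wide_counts <- function(path, meta) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "strand")
  if (!all(need %in% names(d)))
    stop("wide count table ", path, " must start with chrom, pos, strand")
  covc <- paste0(meta$sample_id, ".cov")
  metc <- paste0(meta$sample_id, ".meth")
  miss <- setdiff(c(covc, metc), names(d))
  if (length(miss))
    stop("wide count table lacks column(s): ", paste(miss, collapse = ", "))
  sites <- d[, need]
  cov <- as.matrix(d[, covc, drop = FALSE])
  meth <- as.matrix(d[, metc, drop = FALSE])
  colnames(cov) <- colnames(meth) <- meta$sample_id
  meth_counts(sites, meta, cov, meth)
}

#' Write a wide TSV count table
#'
#' @param x a `meth_counts` object.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_wide_counts <- function(x, path) {
  d <- x$sites
  for (j in seq_len(nrow(x$samples))) {
    d[[paste0(x$samples$sample_id[j], ".cov")]] <- x$coverage[, j]
    d[[paste0(x$samples$sample_id[j], ".meth")]] <- x$methylated[, j]
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
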