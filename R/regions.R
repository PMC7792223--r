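REGION_LEVELS <- c("tss", "promoter", "gene_body", "up10kb", "down10kb")

#' Load gene models from GFF3/GTF
#'
#' Reads gene-level records (type `gene`) and attaches exon records by
#' resolving each exon's `Parent` chain (exon -> transcript -> gene, or
#' exon -> gene directly). Coordinates are 1-based inclusive as in GFF3.
#'
#' @param path a GFF3 or GTF file.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end` and a list-column `exons` of two-column
#'   (start, end) matrices sorted by start.
#' @export
load_gene_models <- function(path) {
  gr <- rtracklayer::import(path)
  md <- S4Vectors::mcols(gr)
  types <- as.character(md$type)
  gi <- which(types == "gene")
  if (!length(gi)) stop("no gene records in ", path)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else
    as.character(md$gene_id)
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands[gi] == "*"))
    stop("gene record(s) without strand in ", path)
  gene_id <- ids[gi]
  if ("gene_id" %in% names(md) && anyNA(gene_id))
    gene_id <- ifelse(is.na(gene_id), as.character(md$gene_id)[gi], gene_id)
  # map any feature id to its gene by climbing Parent links
  parent_of <- list()
  if ("Parent" %in% names(md)) {
    pl <- md$Parent
    for (k in seq_along(gr)) {
      pk <- as.character(unlist(pl[k]))
      if (length(pk) && !is.na(ids[k])) parent_of[[ids[k]]] <- pk[1]
    }
  }
  gene_set <- stats::setNames(rep(TRUE, length(gene_id)), gene_id)
  resolve_gene <- function(id) {
    seen <- character()
    while (!is.na(id) && !isTRUE(gene_set[id])) {
      if (id %in% seen) return(NA_character_)
      seen <- c(seen, id)
      id <- if (!is.null(parent_of[[id]])) parent_of[[id]] else NA_character_
    }
    id
  }
  st <- GenomicRanges::start(gr); en <- GenomicRanges::end(gr)
  exon_map <- stats::setNames(vector("list", length(gene_id)), gene_id)
  ei <- which(types == "exon")
  for (k in ei) {
    parent <- if ("Parent" %in% names(md)) {
      pk <- as.character(unlist(md$Parent[k])); if (length(pk)) pk[1] else NA
    } else if ("gene_id" %in% names(md)) as.character(md$gene_id)[k] else NA
    g <- resolve_gene(parent)
    if (!is.na(g) && g %in% gene_id)
      exon_map[[g]] <- rbind(exon_map[[g]], c(st[k], en[k]))
  }
  exons <- lapply(seq_along(gi), function(j) {
    ex <- exon_map[[gene_id[j]]]
    if (is.null(ex)) ex <- matrix(c(st[gi[j]], en[gi[j]]), 1)
    ex[order(ex[, 1]), , drop = FALSE]
  })
  out <- data.frame(gene_id = gene_id,
                    chrom = as.character(GenomicRanges::seqnames(gr))[gi],
                    strand = strands[gi],
                    tx_start = st[gi], tx_end = en[gi],
                    stringsAsFactors = FALSE)
  out$exons <- exons
  out
}

#' Build strand-aware TSS, promoter, gene-body and flank intervals
#'
#' For a plus-strand gene the TSS is `tx_start` and "upstream" means smaller
#' coordinates; for a minus-strand gene the TSS is `tx_end` and upstream
#' means larger coordinates. Defaults follow the study's definitions: TSS
#' region 300 bp upstream to 50 bp downstream of the TSS, promoter 2000 bp
#' upstream to 200 bp downstream, gene body the full transcript span (exons
#' and introns), and 10 kb flanks adjacent to the gene body. Intervals are
#' 1-based inclusive and truncated at coordinate 1; an interval that would
#' fall entirely below 1 is dropped.
#'
#' @param genes gene models from [load_gene_models()] (or any data.frame
#'   with gene_id, chrom, strand, tx_start, tx_end).
#' @param tss_up,tss_down TSS region extent (bp up/downstream of the TSS).
#' @param prom_up,prom_down promoter extent.
#' @param flank flank width in bp.
#' @return data.frame: `gene_id`, `region`, `chrom`, `start`, `end`,
#'   `strand`.
#' @export
build_region_intervals <- function(genes, tss_up = 300, tss_down = 50,
                                   prom_up = 2000, prom_down = 200,
                                   flank = 10000) {
  stopifnot(tss_up > 0, tss_down > 0, prom_up > 0, prom_down > 0, flank > 0)
  rows <- vector("list", nrow(genes) * 5L)
  k <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    plus <- g$strand == "+"
    tss <- if (plus) g$tx_start else g$tx_end
    iv <- if (plus) list(
      tss      = c(tss - tss_up,  tss + tss_down),
      promoter = c(tss - prom_up, tss + prom_down),
      gene_body = c(g$tx_start, g$tx_end),
      up10kb   = c(g$tx_start - flank, g$tx_start - 1),
      down10kb = c(g$tx_end + 1, g$tx_end + flank)
    ) else list(
      tss      = c(tss - tss_down, tss + tss_up),
      promoter = c(tss - prom_down, tss + prom_up),
      gene_body = c(g$tx_start, g$tx_end),
      up10kb   = c(g$tx_end + 1, g$tx_end + flank),
      down10kb = c(g$tx_start - flank, g$tx_start - 1)
    )
    for (r in names(iv)) {
      s <- max(1L, iv[[r]][1]); e <- iv[[r]][2]
      if (e < 1) next  # interval entirely off-chromosome
      k <- k + 1L
      rows[[k]] <- data.frame(gene_id = g$gene_id, region = r,
                              chrom = g$chrom, start = s, end = e,
                              strand = g$strand, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows[seq_len(k)])
}

#' Assign CpG sites to gene regions
#'
#' Interval containment (both endpoints inclusive) via
#' `GenomicRanges::findOverlaps`. By default a site receives every
#' membership: it may belong to several genes and several region
#' categories (the categories overlap by construction). With
#' `priority_assignment = TRUE` each site keeps only its highest-priority
#' category (tss > promoter > gene_body > up10kb > down10kb), one row per
#' gene at that category.
#'
#' @param sites data.frame with `chrom`, `pos`, `strand`.
#' @param intervals region intervals from [build_region_intervals()].
#' @param priority_assignment logical; default `FALSE` (multi-assignment).
#' @return data.frame: `chrom`, `pos`, `strand`, `gene_id`, `region`.
#'   Sites with no membership are absent.
#' @export
assign_sites_to_regions <- function(sites, intervals,
                                    priority_assignment = FALSE) {
  if (!nrow(sites) || is.null(intervals) || !nrow(intervals))
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), gene_id = character(),
                      region = character()))
  sgr <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos, sites$pos))
  igr <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start,
                                                 intervals$end))
  hits <- GenomicRanges::findOverlaps(sgr, igr, ignore.strand = TRUE)
  si <- S4Vectors::queryHits(hits); ii <- S4Vectors::subjectHits(hits)
  out <- data.frame(chrom = sites$chrom[si], pos = sites$pos[si],
                    strand = sites$strand[si],
                    gene_id = intervals$gene_id[ii],
                    region = intervals$region[ii],
                    stringsAsFactors = FALSE)
  if (priority_assignment && nrow(out)) {
    pr <- match(out$region, REGION_LEVELS)
    key <- paste(out$chrom, out$pos, out$strand)
    best <- stats::ave(pr, key, FUN = min)
    out <- out[pr == best, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write region intervals as BED6
#'
#' Converts the internal 1-based inclusive coordinates to BED's 0-based
#' half-open convention; the name field is `gene_id|region`.
#'
#' @param intervals from [build_region_intervals()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_regions_bed <- function(intervals, path) {
  d <- data.frame(chrom = intervals$chrom,
                  start = intervals$start - 1L,
                  end = intervals$end,
                  name = paste(intervals$gene_id, intervals$region,
                               sep = "|"),
                  score = 0L, strand = intervals$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
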