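#' Intersect DMRs with chromatin-loop anchors
#'
#' A DMR is "anchored" iff it overlaps anchor1 or anchor2 of any loop
#' by at least 1 bp.
#'
#' @param dmrs region set (`GRanges` or chrom/start/end data.frame).
#' @param loops a [loop_set()].
#' @return list with `fraction` (anchored DMRs over all DMRs) and
#'   `hits` (data.frame: dmr index, loop index, anchor 1 or 2).
#' @export
intersect_dmr_anchors <- function(dmrs, loops) {
  dg <- as_gr(dmrs)
  h1 <- find_hits(dg, loops$anchor1)
  h2 <- find_hits(dg, loops$anchor2)
  hits <- rbind(
    data.frame(dmr = S4Vectors::queryHits(h1),
               loop = S4Vectors::subjectHits(h1),
               anchor = rep(1L, length(h1))),
    data.frame(dmr = S4Vectors::queryHits(h2),
               loop = S4Vectors::subjectHits(h2),
               anchor = rep(2L, length(h2))))
  hits <- hits[order(hits$dmr, hits$loop, hits$anchor), , drop = FALSE]
  anchored <- unique(hits$dmr)
  list(fraction = if (length(dg)) length(anchored) / length(dg) else NA_real_,
       hits = hits)
}

#' Map enhancer DMRs to target genes through loop anchors
#'
#' For every (eDMR, loop) pair where the eDMR overlaps one anchor, a
#' link is emitted for each gene whose promoter overlaps the partner
#' anchor (>= 1 bp each side). An eDMR hitting both anchors of one loop
#' yields links for the partner genes of each side. Links are
#' deduplicated per (dmr, gene).
#'
#' @param edmrs enhancer-classified DMRs (region set).
#' @param loops a [loop_set()].
#' @param promoters `GRanges` with a `label` column of gene ids (e.g.
#'   from [promoters_from_genes()]).
#' @return data.frame of links: `dmr` (index into `edmrs`), `chrom`,
#'   `start`, `end` of the DMR, `anchor` hit (1/2), `gene`.
#' @export
map_edmr_targets <- function(edmrs, loops, promoters) {
  dg <- as_gr(edmrs)
  promoters <- as_gr(promoters)
  gene_ids <- S4Vectors::mcols(promoters)$label
  if (is.null(gene_ids)) stop_validation("promoters need gene ids in `label`")
  links <- list()
  for (side in 1:2) {
    own <- if (side == 1) loops$anchor1 else loops$anchor2
    partner <- if (side == 1) loops$anchor2 else loops$anchor1
    hd <- find_hits(dg, own)
    if (!length(hd)) next
    hp <- find_hits(partner, promoters)
    if (!length(hp)) next
    dt_d <- data.table::data.table(dmr = S4Vectors::queryHits(hd),
                                   loop = S4Vectors::subjectHits(hd))
    dt_p <- data.table::data.table(loop = S4Vectors::queryHits(hp),
                                   gene = gene_ids[S4Vectors::subjectHits(hp)])
    j <- merge(dt_d, dt_p, by = "loop", allow.cartesian = TRUE)
    if (nrow(j)) {
      j[, anchor := side]
      links[[length(links) + 1]] <- j
    }
  }
  if (!length(links))
    return(data.frame(dmr = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      anchor = integer(0), gene = character(0)))
  out <- data.table::rbindlist(links)
  data.table::setorder(out, dmr, gene, anchor)
  out <- out[!duplicated(out[, list(dmr, gene)]), ]
  df <- as_region_df(edmrs)
  data.frame(dmr = out$dmr, chrom = df$chrom[out$dmr],
             start = df$start[out$dmr], end = df$end[out$dmr],
             anchor = out$anchor, gene = out$gene,
             stringsAsFactors = FALSE)
}

#' Derive promoter intervals from gene locations
#'
#' Promoter = TSS +/- `pad` bp, where the TSS is the gene-interval start
#' (all synthetic genes are forward-strand). Coordinates are clipped at
#' zero.
#'
#' @param genes `GRanges` of gene bodies with a `label` column of gene
#'   ids.
#' @param pad half-width of the promoter window in bp.
#' @return `GRanges` of promoters carrying the gene ids.
#' @export
promoters_from_genes <- function(genes, pad = 2000) {
  genes <- as_gr(genes)
  tss <- GenomicRanges::start(genes)   # 1-based start
  st <- pmax(tss - pad, 1L)
  en <- tss + pad - 1L
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                IRanges::IRanges(st, en))
  S4Vectors::mcols(out)$label <- S4Vectors::mcols(genes)$label
  out
}

#' Expression percentiles of target genes
#'
#' Each gene's expression summary is its mean TPM over `sample_set`;
#' "expressed" genes have mean TPM > 0. Percentiles are mid-rank over
#' all expressed genes: `100 * (rank - 0.5) / N` with average ranks for
#' ties. The top-quartile fraction is the share of target genes with
#' percentile >= 75. Target genes missing from the table or not
#' expressed are dropped and reported.
#'
#' @param expr an `ExpressionTable`.
#' @param sample_set sample (column) names to average over.
#' @param target_genes character vector of gene ids.
#' @return list with `percentiles` (named, per retained target gene),
#'   `top_quartile_fraction`, `n_expressed` (all expressed genes) and
#'   `dropped` (target ids not usable).
#' @export
expression_percentiles <- function(expr, sample_set, target_genes) {
  if (!length(sample_set)) stop_validation("sample_set empty")
  miss <- setdiff(sample_set, colnames(expr$tpm))
  if (length(miss))
    stop_validation("unknown sample(s): ", paste(miss, collapse = ", "))
  means <- rowMeans(expr$tpm[, sample_set, drop = FALSE])
  expressed <- means > 0
  if (!any(expressed)) stop_validation("no expressed genes")
  e_means <- means[expressed]
  n <- length(e_means)
  pct <- 100 * (rank(e_means, ties.method = "average") - 0.5) / n
  names(pct) <- names(e_means)
  keep <- target_genes[target_genes %in% names(pct)]
  dropped <- setdiff(target_genes, keep)
  tq <- if (length(keep)) mean(pct[keep] >= 75) else NA_real_
  list(percentiles = pct[keep], top_quartile_fraction = tq,
       n_expressed = n, dropped = dropped)
}
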