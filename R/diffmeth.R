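#' Analysis thresholds
#'
#' Bundles every tunable cutoff of the differential-methylation pipeline
#' with its default: a minimum group methylation difference of 0.2 and
#' FDR 0.05 for both stages, regions requiring more than 10 CpGs,
#' a 10x coverage cutoff where coverage filters apply (strict `>`),
#' a 0.3 cutoff for "low methylation in the reference group", 1 kb bins
#' for genome-wide summaries, 5 kb flanks for meta-region profiles, a
#' 1 kb maximum gap when chaining DMCs into regions, and a minimum DMC
#' share of 0.5 within a chained span.
#'
#' @param min_diff minimum absolute methylation difference.
#' @param fdr Benjamini-Hochberg false-discovery-rate cutoff.
#' @param min_cpgs_per_dmr minimum CpGs per region (11 encodes "> 10").
#' @param min_cov coverage cutoff used by coverage filters (strict `>`).
#' @param low_meth_cutoff reference-group mean below which a region
#'   counts as lowly methylated.
#' @param bin_size genome bin width in bp.
#' @param flank meta-region flank in bp.
#' @param max_gap maximum bp between consecutive DMCs in one region.
#' @param min_dmc_share minimum fraction of DMCs among covered CpGs in a
#'   chained span.
#' @param phi_prior_weight prior weight of the dispersion shrinkage.
#' @return A list of class `Thresholds`.
#' @export
thresholds <- function(min_diff = 0.2, fdr = 0.05, min_cpgs_per_dmr = 11,
                       min_cov = 10, low_meth_cutoff = 0.3, bin_size = 1000,
                       flank = 5000, max_gap = 1000, min_dmc_share = 0.5,
                       phi_prior_weight = 20) {
  th <- list(min_diff = min_diff, fdr = fdr,
             min_cpgs_per_dmr = as.integer(min_cpgs_per_dmr),
             min_cov = as.integer(min_cov),
             low_meth_cutoff = low_meth_cutoff,
             bin_size = as.integer(bin_size), flank = as.integer(flank),
             max_gap = as.integer(max_gap), min_dmc_share = min_dmc_share,
             phi_prior_weight = phi_prior_weight)
  stopifnot(min_diff > 0, min_diff < 1, fdr > 0, fdr < 1,
            low_meth_cutoff >= 0, low_meth_cutoff < 1,
            th$min_cpgs_per_dmr > 0, th$min_cov > 0, th$bin_size > 0,
            th$flank >= 0, th$max_gap > 0,
            min_dmc_share >= 0, min_dmc_share <= 1)
  structure(th, class = "Thresholds")
}

resolve_samples <- function(matrix, who) {
  if (is.null(who)) return(character(0))
  who <- as.character(who)
  if (all(who %in% matrix$metadata$group) && !any(who %in% matrix$samples))
    return(group_samples(matrix, who))
  miss <- setdiff(who, matrix$samples)
  if (length(miss))
    stop_validation("unknown sample(s)/group(s): ", paste(miss, collapse = ", "))
  who
}

#' Pooled per-CpG group methylation means
#'
#' The pooled mean at a CpG is `sum(n_meth) / sum(n_total)` over the
#' group's samples with `n_total >= 1`; zero-coverage cells are ignored.
#' CpGs whose pooled total does not exceed `min_cov` are flagged
#' low-coverage. An alternative mean-of-per-sample-betas is available.
#'
#' @param matrix a `CpGCountMatrix`.
#' @param group sample ids or a metadata group label.
#' @param min_cov pooled-coverage flag cutoff (strict `>` to pass).
#' @param per_sample if `TRUE`, average per-sample betas instead of
#'   pooling counts.
#' @return data.table with `chrom`, `pos`, `mean`, `total`, `low_cov`.
#' @export
pooled_group_means <- function(matrix, group, min_cov = 10,
                               per_sample = FALSE) {
  ids <- resolve_samples(matrix, group)
  if (!length(ids)) stop_validation("empty group")
  j <- match(ids, matrix$samples)
  meth <- matrix$meth[, j, drop = FALSE]
  tot <- matrix$total[, j, drop = FALSE]
  T <- rowSums(tot)
  if (per_sample) {
    b <- ifelse(tot > 0, meth / tot, NA_real_)
    m <- rowMeans(b, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
  } else {
    m <- ifelse(T > 0, rowSums(meth) / T, NA_real_)
  }
  data.table::data.table(chrom = matrix$chrom, pos = matrix$pos,
                         mean = m, total = T, low_cov = !(T > min_cov))
}

#' Call differentially methylated CpGs between two groups
#'
#' Runs the beta-binomial Wald test ([bb_wald()]) at every CpG where
#' both groups have at least two covered samples, with the dispersion
#' median taken per chromosome, then applies Benjamini-Hochberg across
#' all tested CpGs. A CpG is a DMC iff `q < fdr` and
#' `|diff| >= min_diff`.
#'
#' @param matrix a `CpGCountMatrix`.
#' @param group_a,group_b disjoint sample id sets (or metadata group
#'   labels); `diff` is `mu_b - mu_a`, so `group_a` is the reference.
#' @param th a [thresholds()] object.
#' @return data.table of per-CpG records (`chrom`, `pos`, means, `diff`,
#'   `phi`, `wald`, `p`, `q`, `is_dmc`, pooled sums); attribute
#'   `n_skipped` counts CpGs failing the testability rule.
#' @export
dmc_test <- function(matrix, group_a, group_b, th = thresholds()) {
  ids_a <- resolve_samples(matrix, group_a)
  ids_b <- resolve_samples(matrix, group_b)
  if (!length(ids_a) || !length(ids_b)) stop_validation("empty group")
  if (length(intersect(ids_a, ids_b)))
    stop_validation("groups share sample(s): ",
                    paste(intersect(ids_a, ids_b), collapse = ", "))
  ja <- match(ids_a, matrix$samples); jb <- match(ids_b, matrix$samples)
  res <- bb_wald(matrix$meth[, ja, drop = FALSE],
                 matrix$total[, ja, drop = FALSE],
                 matrix$meth[, jb, drop = FALSE],
                 matrix$total[, jb, drop = FALSE],
                 stratum = matrix$chrom,
                 prior_weight = th$phi_prior_weight)
  res[, `:=`(chrom = matrix$chrom, pos = matrix$pos)]
  n_skipped <- sum(!res$testable)
  out <- res[res$testable, ]
  if (nrow(out) == 0) stop_validation("no testable CpGs")
  out[, q := p.adjust(p, method = "BH")]
  out[, is_dmc := q < th$fdr & abs(diff) >= th$min_diff]
  data.table::setcolorder(out, c("chrom", "pos"))
  data.table::setattr(out, "n_skipped", n_skipped)
  data.table::setattr(out, "groups", list(a = ids_a, b = ids_b))
  out[]
}

#' Segment DMCs into differentially methylated regions
#'
#' Same-direction DMCs within `max_gap` bp of each other are chained;
#' a chain becomes a DMR iff the chained span (first to last DMC)
#' contains more than 10 covered CpGs (`min_cpgs_per_dmr`), its pooled
#' group-mean difference over *all* CpGs in the span is at least
#' `min_diff` in absolute value with the chain's direction, and DMCs
#' make up at least `min_dmc_share` of the span's CpGs. Region
#' boundaries are CpG-anchored and half-open:
#' `[first CpG pos, last CpG pos + 2)`.
#'
#' @param dmcs the full tested-CpG table from [dmc_test()] (the
#'   non-DMC rows supply the covered-CpG universe of each span).
#' @param th a [thresholds()] object.
#' @return data.frame of DMR records with per-group pooled means,
#'   difference, direction (`hyper`/`hypo` relative to group a) and
#'   `stage = "vs_reference"`.
#' @export
segment_dmrs <- function(dmcs, th = thresholds()) {
  empty <- data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    n_cpgs = integer(0), n_dmcs = integer(0), dmc_share = numeric(0),
    mean_a = numeric(0), mean_b = numeric(0), diff = numeric(0),
    direction = character(0), stage = character(0))
  if (is.null(dmcs) || nrow(dmcs) == 0) return(as.data.frame(empty))
  dmcs <- data.table::as.data.table(dmcs)
  data.table::setorder(dmcs, chrom, pos)
  out <- list()
  for (ch in unique(dmcs$chrom)) {
    d <- dmcs[dmcs$chrom == ch, ]
    hits <- which(d$is_dmc)
    if (!length(hits)) next
    dirs <- sign(d$diff[hits])
    pos <- d$pos[hits]
    newchain <- c(TRUE, diff(pos) > th$max_gap | dirs[-1] != dirs[-length(dirs)])
    chain_id <- cumsum(newchain)
    for (k in unique(chain_id)) {
      idx <- hits[chain_id == k]
      span <- seq.int(min(idx), max(idx))   # covered CpGs in span
      n_cpgs <- length(span)
      n_dmcs <- length(idx)
      share <- n_dmcs / n_cpgs
      mean_a <- sum(d$m_a[span]) / sum(d$t_a[span])
      mean_b <- sum(d$m_b[span]) / sum(d$t_b[span])
      diff_r <- mean_b - mean_a
      dir_chain <- sign(d$diff[idx[1]])
      if (n_cpgs >= th$min_cpgs_per_dmr &&
          abs(diff_r) >= th$min_diff &&
          sign(diff_r) == dir_chain &&
          share >= th$min_dmc_share) {
        out[[length(out) + 1]] <- data.table::data.table(
          chrom = ch, start = d$pos[span[1]], end = d$pos[span[n_cpgs]] + 2L,
          n_cpgs = n_cpgs, n_dmcs = n_dmcs, dmc_share = share,
          mean_a = mean_a, mean_b = mean_b, diff = diff_r,
          direction = if (diff_r > 0) "hyper" else "hypo",
          stage = "vs_reference")
      }
    }
  }
  res <- if (length(out)) data.table::rbindlist(out) else empty
  as.data.frame(res)
}

# per-sample counts aggregated over each region span; regions as a
# data.frame with chrom/start/end, matrix a CpGCountMatrix
aggregate_region_counts <- function(matrix, regions, sample_ids) {
  j <- match(sample_ids, matrix$samples)
  cg <- cpg_gr(matrix$chrom, matrix$pos)
  rg <- gr_from_bed0(regions$chrom, regions$start, regions$end)
  ov <- find_hits(cg, rg)
  ridx <- S4Vectors::subjectHits(ov)
  cidx <- S4Vectors::queryHits(ov)
  n <- nrow(regions)
  meth <- matrix(0, n, length(j))
  tot <- matrix(0, n, length(j))
  if (length(ridx)) {
    rs_m <- rowsum(matrix$meth[cidx, j, drop = FALSE], ridx)
    rs_t <- rowsum(matrix$total[cidx, j, drop = FALSE], ridx)
    hit <- as.integer(rownames(rs_m))
    meth[hit, ] <- rs_m
    tot[hit, ] <- rs_t
  }
  list(meth = meth, tot = tot,
       n_cpgs = tabulate(ridx, nbins = n))
}

#' Second-stage test: group-specific DMRs
#'
#' Re-tests stage-1 DMRs for specificity to the target group: counts
#' are aggregated per sample over each region span and one beta-binomial
#' Wald test of target versus the pooled comparison samples is run per
#' region, with BH across regions. A region is group-specific iff its
#' adjusted p is below `fdr`, the aggregated difference is at least
#' `min_diff` in absolute value, and its direction matches stage 1.
#' Samples of `excluded_groups` take part in neither side.
#'
#' @param dmrs stage-1 regions from [segment_dmrs()].
#' @param matrix a `CpGCountMatrix`.
#' @param target_group group label(s) or sample ids under test.
#' @param comparison_groups group label(s) or sample ids of the other
#'   tumor samples ("all other AML").
#' @param excluded_groups group label(s)/samples dropped entirely.
#' @param th a [thresholds()] object.
#' @return data.frame of the specific regions
#'   (`stage = "group_specific"`, with `stage2_p`, `stage2_q`); the
#'   full re-tested table is in attribute `all`.
#' @export
call_group_specific <- function(dmrs, matrix, target_group,
                                comparison_groups,
                                excluded_groups = character(0),
                                th = thresholds()) {
  tgt <- resolve_samples(matrix, target_group)
  cmp <- resolve_samples(matrix, comparison_groups)
  exc <- resolve_samples(matrix, excluded_groups)
  if (length(intersect(tgt, exc)) || length(intersect(cmp, exc)))
    stop_validation("excluded samples must be disjoint from both sides")
  cmp <- setdiff(cmp, exc)
  if (length(intersect(tgt, cmp)))
    stop_validation("target and comparison groups overlap")
  if (!length(cmp))
    stop_validation("comparison set empty after exclusions")
  dmrs <- as.data.frame(dmrs)
  if (nrow(dmrs) == 0) {
    dmrs$stage2_p <- numeric(0); dmrs$stage2_q <- numeric(0)
    attr(dmrs, "all") <- dmrs
    return(dmrs)
  }
  agg_t <- aggregate_region_counts(matrix, dmrs, tgt)
  agg_c <- aggregate_region_counts(matrix, dmrs, cmp)
  res <- bb_wald(agg_c$meth, agg_c$tot, agg_t$meth, agg_t$tot,
                 stratum = rep("all", nrow(dmrs)),
                 prior_weight = th$phi_prior_weight)
  all_tab <- cbind(data.table::as.data.table(dmrs),
                   data.table::data.table(
                     stage2_diff = res$diff, stage2_p = res$p))
  all_tab[, stage2_q := NA_real_]
  ok <- res$testable
  all_tab$stage2_q[ok] <- p.adjust(res$p[ok], method = "BH")
  dir_sign <- ifelse(dmrs$direction == "hyper", 1, -1)
  specific <- ok & !is.na(all_tab$stage2_q) &
    all_tab$stage2_q < th$fdr &
    abs(res$diff) >= th$min_diff &
    sign(res$diff) == dir_sign
  out <- all_tab[specific, ]
  out[, stage := "group_specific"]
  out <- as.data.frame(out)
  attr(out, "all") <- as.data.frame(all_tab)
  out
}

#' Aggregated beta-binomial re-test of fixed regions between two groups
#'
#' The region-level test of [call_group_specific()] exposed directly:
#' per region, per-sample counts are aggregated over the span and the
#' two named groups compared by one beta-binomial Wald test, BH across
#' regions. Used for cross-genotype re-testing of a fixed DMR set.
#'
#' @param matrix a `CpGCountMatrix`.
#' @param regions data.frame with `chrom`, `start`, `end` (or a
#'   `GRanges`).
#' @param group_a,group_b disjoint sample sets or group labels;
#'   `diff = mu_b - mu_a`.
#' @param th a [thresholds()] object.
#' @return data.frame with per-region means, `diff`, `p`, `q`.
#' @export
region_group_test <- function(matrix, regions, group_a, group_b,
                              th = thresholds()) {
  regions <- as_region_df(regions)
  ids_a <- resolve_samples(matrix, group_a)
  ids_b <- resolve_samples(matrix, group_b)
  if (length(intersect(ids_a, ids_b)))
    stop_validation("groups overlap")
  agg_a <- aggregate_region_counts(matrix, regions, ids_a)
  agg_b <- aggregate_region_counts(matrix, regions, ids_b)
  res <- bb_wald(agg_a$meth, agg_a$tot, agg_b$meth, agg_b$tot,
                 stratum = rep("all", nrow(regions)),
                 prior_weight = th$phi_prior_weight)
  out <- cbind(regions[, c("chrom", "start", "end")],
               as.data.frame(res[, list(mu_a, mu_b, diff, p, testable)]))
  out$q <- NA_real_
  out$q[res$testable] <- p.adjust(res$p[res$testable], method = "BH")
  out
}

as_region_df <- function(regions) {
  if (inherits(regions, "GRanges")) {
    df <- bed0_from_gr(regions)
    as.data.frame(df)
  } else {
    as.data.frame(regions)
  }
}

#' Overlap report between two region sets
#'
#' Symmetric summary: for each set, the count and fraction of members
#' overlapping (>= 1 bp) the other set, plus total intersection and
#' union widths.
#'
#' @param set_a,set_b region sets (`GRanges` or chrom/start/end
#'   data.frames).
#' @return A list with `n_a`, `n_b`, `a_hits`, `frac_a`, `b_hits`,
#'   `frac_b`, `intersection_bp`, `union_bp`.
#' @export
dmr_set_operations <- function(set_a, set_b) {
  ga <- if (inherits(set_a, "GRanges")) set_a else {
    df <- as.data.frame(set_a); gr_from_bed0(df$chrom, df$start, df$end) }
  gb <- if (inherits(set_b, "GRanges")) set_b else {
    df <- as.data.frame(set_b); gr_from_bed0(df$chrom, df$start, df$end) }
  a_hits <- sum(count_hits(ga, gb) > 0)
  b_hits <- sum(count_hits(gb, ga) > 0)
  inter <- sum(GenomicRanges::width(GenomicRanges::intersect(
    GenomicRanges::reduce(ga), GenomicRanges::reduce(gb))))
  uni <- sum(GenomicRanges::width(GenomicRanges::union(ga, gb)))
  list(n_a = length(ga), n_b = length(gb),
       a_hits = a_hits, frac_a = if (length(ga)) a_hits / length(ga) else NA_real_,
       b_hits = b_hits, frac_b = if (length(gb)) b_hits / length(gb) else NA_real_,
       intersection_bp = inter, union_bp = uni)
}

#' Mean methylation in fixed-width genome bins
#'
#' Per sample and bin, the pooled mean over the bin's CpGs. Bins with no
#' covered CpG in *any* sample are dropped (complete-case table for
#' downstream clustering/PCA); the dropped count is in attribute
#' `n_dropped`.
#'
#' @param matrix a `CpGCountMatrix`.
#' @param bin_size bin width in bp.
#' @return data.table with `chrom`, `start`, `end` and one mean column
#'   per sample.
#' @export
bin_mean_methylation <- function(matrix, bin_size = 1000) {
  stopifnot(bin_size > 0)
  bin <- matrix$pos %/% as.integer(bin_size)
  key <- paste(matrix$chrom, bin)
  f <- factor(key, levels = unique(key))
  meth <- rowsum(matrix$meth, f, reorder = FALSE)
  tot <- rowsum(matrix$total, f, reorder = FALSE)
  mean_mat <- ifelse(tot > 0, meth / tot, NA_real_)
  first <- !duplicated(key)
  out <- data.table::data.table(
    chrom = matrix$chrom[first],
    start = bin[first] * as.integer(bin_size),
    end = (bin[first] + 1L) * as.integer(bin_size))
  out <- cbind(out, data.table::as.data.table(mean_mat))
  keep <- stats::complete.cases(mean_mat)
  res <- out[keep, ]
  data.table::setorder(res, chrom, start)
  data.table::setattr(res, "n_dropped", sum(!keep))
  res[]
}

#' Per-region pooled methylation means by group
#'
#' @param matrix a `CpGCountMatrix`.
#' @param regions `GRanges` or chrom/start/end data.frame.
#' @param groups named list of sample sets (or group labels).
#' @return data.frame: regions with one pooled-mean column per group;
#'   regions with zero covered CpGs in a group get `NA`.
#' @export
region_group_methylation <- function(matrix, regions, groups) {
  regions <- as_region_df(regions)
  cols <- lapply(groups, function(g) {
    ids <- resolve_samples(matrix, g)
    agg <- aggregate_region_counts(matrix, regions, ids)
    T <- rowSums(agg$tot)
    ifelse(T > 0, rowSums(agg$meth) / T, NA_real_)
  })
  out <- cbind(regions[, c("chrom", "start", "end")],
               as.data.frame(cols, optional = TRUE))
  names(out) <- c("chrom", "start", "end", names(groups))
  out
}

#' Fraction of regions lowly methylated in a reference group
#'
#' Regions whose reference-group pooled mean is undefined (no covered
#' CpG) are excluded from the denominator; their count is reported in
#' attribute `n_undefined`.
#'
#' @param region_means output of [region_group_methylation()].
#' @param reference name of the reference-group column.
#' @param cutoff methylation cutoff (strict `<`).
#' @return The fraction (scalar).
#' @export
low_meth_fraction <- function(region_means, reference, cutoff = 0.3) {
  v <- region_means[[reference]]
  ok <- !is.na(v)
  frac <- if (any(ok)) mean(v[ok] < cutoff) else NA_real_
  attr(frac, "n_undefined") <- sum(!ok)
  frac
}

#' Aggregate meta-region methylation profile
#'
#' For each region, methylation is sampled in fixed-width sub-bins over
#' a window centered on the region midpoint extending `flank` bp up- and
#' downstream; the aggregate profile is the per-sub-bin mean over regions
#' with coverage. Windows truncated at chromosome edges simply lack
#' those CpGs.
#'
#' @param matrix a `CpGCountMatrix`.
#' @param regions `GRanges` or chrom/start/end data.frame.
#' @param group sample ids or a group label.
#' @param flank half-window in bp.
#' @param bin_width sub-bin width in bp.
#' @return list with `offsets` (bp of sub-bin starts relative to the
#'   center), `profile` (aggregate means) and `matrix` (regions x
#'   sub-bins of pooled means, `NA` where uncovered).
#' @export
profile_matrix <- function(matrix, regions, group, flank = 5000,
                           bin_width = 100) {
  stopifnot(flank >= 0, bin_width > 0)
  regions <- as_region_df(regions)
  ids <- resolve_samples(matrix, group)
  j <- match(ids, matrix$samples)
  n_bins <- max(1L, as.integer(2 * flank / bin_width))
  offsets <- (seq_len(n_bins) - 1L) * bin_width - as.integer(flank)
  centers <- (regions$start + regions$end) %/% 2L
  prof <- matrix(NA_real_, nrow(regions), n_bins)
  dt_pos <- data.table::data.table(chrom = matrix$chrom, pos = matrix$pos,
                                   idx = seq_along(matrix$pos))
  data.table::setkey(dt_pos, chrom, pos)
  for (i in seq_len(nrow(regions))) {
    lo <- centers[i] - flank
    sel <- dt_pos[chrom == regions$chrom[i] & pos >= lo &
                    pos < centers[i] + flank]
    if (!nrow(sel)) next
    b <- pmin(((sel$pos - lo) %/% bin_width) + 1L, n_bins)
    m <- rowsum(rowSums(matrix$meth[sel$idx, j, drop = FALSE]), b)
    t <- rowsum(rowSums(matrix$total[sel$idx, j, drop = FALSE]), b)
    vals <- ifelse(t > 0, m / t, NA_real_)
    prof[i, as.integer(rownames(m))] <- vals
  }
  aggregate <- colMeans(prof, na.rm = TRUE)
  aggregate[is.nan(aggregate)] <- NA_real_
  list(offsets = offsets, profile = aggregate, matrix = prof)
}
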