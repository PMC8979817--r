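as_gr <- function(x) {
  if (inherits(x, "GRanges")) return(x)
  df <- as.data.frame(x)
  gr <- gr_from_bed0(df$chrom, df$start, df$end)
  if ("label" %in% names(df)) S4Vectors::mcols(gr)$label <- df$label
  if ("score" %in% names(df)) S4Vectors::mcols(gr)$score <- df$score
  gr
}

# order of state labels: numeric prefix ("7_Enh") when present, else
# order of first appearance in the sorted map
state_levels <- function(labels) {
  u <- unique(labels)
  num <- suppressWarnings(as.integer(sub("_.*$", "", u)))
  if (!anyNA(num)) u[order(num)] else u
}

#' Assign regions to chromatin states and tabulate fractions
#'
#' Each region is assigned the state with maximal base-pair overlap
#' (ties broken toward the lowest state index); fractions are over
#' assigned regions and sum to 1. The state map must be a
#' non-overlapping tiling.
#'
#' @param regions `GRanges` or chrom/start/end data.frame.
#' @param state_map `GRanges` with a `label` metadata column.
#' @return list with `assignment` (per-region state, `NA` when a region
#'   overlaps no state interval) and `fractions` (named vector over all
#'   states of the map).
#' @export
state_overlap_distribution <- function(regions, state_map) {
  state_map <- as_gr(state_map)
  if (length(state_map) > 1 &&
      any(GenomicRanges::countOverlaps(state_map, state_map) > 1))
    stop_validation("state map intervals must not overlap")
  regions <- as_gr(regions)
  lv <- state_levels(S4Vectors::mcols(state_map)$label)
  ov <- find_hits(regions, state_map)
  assignment <- rep(NA_character_, length(regions))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(regions)[qh],
      GenomicRanges::ranges(state_map)[sh]))
    lab <- as.character(S4Vectors::mcols(state_map)$label[sh])
    idx <- match(lab, lv)
    dt <- data.table::data.table(q = qh, w = w, idx = idx, lab = lab)
    # total bp per (region, state); winner is max bp, ties to lowest index
    agg <- dt[, list(w = sum(w)), by = list(q, lab, idx)]
    data.table::setorder(agg, q, -w, idx)
    best <- agg[!duplicated(agg$q), ]
    assignment[best$q] <- best$lab
  }
  counts <- table(factor(assignment, levels = lv))
  n_assigned <- sum(counts)
  fractions <- if (n_assigned > 0) as.numeric(counts) / n_assigned
    else rep(NA_real_, length(lv))
  names(fractions) <- lv
  list(assignment = assignment, fractions = fractions)
}

#' Chromatin-state enrichment of a region set over a background
#'
#' Fold enrichment per state: fraction of `regions` assigned to the
#' state divided by the fraction of `background` assigned to it; `0/0`
#' is reported as `NA`.
#'
#' @param regions,background region sets.
#' @param state_map non-overlapping labelled `GRanges` tiling.
#' @return Named numeric vector of fold enrichments.
#' @export
state_enrichment <- function(regions, background, state_map) {
  if (length(as_gr(background)) == 0) stop_validation("background empty")
  fg <- state_overlap_distribution(regions, state_map)$fractions
  bg <- state_overlap_distribution(background, state_map)$fractions
  enr <- ifelse(fg == 0 & bg == 0, NA_real_, fg / bg)
  enr[is.infinite(enr)] <- Inf
  enr
}

#' Fraction of regions overlapping a feature set
#'
#' @param regions region set.
#' @param features feature set.
#' @param min_overlap_bp minimum overlap width to count a hit.
#' @return The fraction; per-region logical flags in attribute `hits`.
#' @export
overlap_fraction <- function(regions, features, min_overlap_bp = 1) {
  regions <- as_gr(regions); features <- as_gr(features)
  hits <- count_hits(regions, features, minoverlap = min_overlap_bp) > 0
  frac <- if (length(regions)) mean(hits) else NA_real_
  attr(frac, "hits") <- hits
  frac
}

#' CpG density of regions
#'
#' Density is CpGs per 100 bp: `100 * count / width`, counting CpGs
#' whose cytosine position lies in `[start, end)`.
#'
#' @param regions region set.
#' @param cpg_positions data.frame with `chrom`, `pos` (or a
#'   `CpGCountMatrix`).
#' @return list with `density` (per region) and `mean` (set mean).
#' @export
cpg_density <- function(regions, cpg_positions) {
  regions <- as_region_df(regions)
  if (inherits(cpg_positions, "CpGCountMatrix"))
    cpg_positions <- data.frame(chrom = cpg_positions$chrom,
                                pos = cpg_positions$pos)
  pg <- gr_from_bed0(cpg_positions$chrom, cpg_positions$pos,
                     cpg_positions$pos + 1L)   # count by cytosine position
  rg <- gr_from_bed0(regions$chrom, regions$start, regions$end)
  counts <- count_hits(rg, pg)
  density <- 100 * counts / (regions$end - regions$start)
  list(density = density,
       mean = if (length(density)) mean(density) else NA_real_)
}

#' Classify regions into enhancer classes from histone-mark peaks
#'
#' Overlap (>= 1 bp) with H3K27ac, H3K4me1 and H3K27me3 peaks yields
#' booleans (a, m1, m3); the class rule is: poised if `a & m3`; else
#' active if `a`; else weak if `m1 & !m3`; else none. The full truth
#' table (a, m1, m3 -> class):
#' `000 -> none`, `100 -> active`, `010 -> weak`, `001 -> none`,
#' `110 -> active`, `101 -> poised`, `011 -> none`, `111 -> poised`.
#'
#' @param regions region set.
#' @param k27ac,k4me1,k27me3 peak sets (`GRanges` or data.frames).
#' @return data.frame with per-region booleans and `class` in
#'   `{active, poised, weak, none}`.
#' @export
classify_enhancers <- function(regions, k27ac, k4me1, k27me3) {
  rg <- as_gr(regions)
  a <- count_hits(rg, as_gr(k27ac)) > 0
  m1 <- count_hits(rg, as_gr(k4me1)) > 0
  m3 <- count_hits(rg, as_gr(k27me3)) > 0
  class <- ifelse(a & m3, "poised",
           ifelse(a, "active",
           ifelse(m1 & !m3, "weak", "none")))
  df <- as_region_df(regions)
  data.frame(df[, c("chrom", "start", "end")],
             k27ac = a, k4me1 = m1, k27me3 = m3, class = class,
             stringsAsFactors = FALSE)
}

#' Permutation test for region-set overlap
#'
#' Observed statistic: the number of query regions overlapping the
#' reference set (>= 1 bp). Null: draw `|query|` regions from the
#' finite universe without replacement and recount, `n_perm` times.
#' The empirical p-value uses add-one smoothing:
#' `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' Query membership in the universe is by interval identity
#' (chrom, start, end).
#'
#' @param query region set, a subset of `universe`.
#' @param reference region set overlapped against.
#' @param universe finite region universe the null draws from.
#' @param n_perm number of permutations (>= 100; ignored when `exact`).
#' @param seed integer seed; the test is deterministic given it.
#' @param exact if `TRUE`, enumerate all `choose(|universe|, |query|)`
#'   subsets instead of sampling (feasible for toy instances only);
#'   the p-value is then the exact tail probability without smoothing.
#' @return list with `observed`, `p`, `n_perm` and the `null` counts.
#' @export
permutation_overlap_test <- function(query, reference, universe,
                                     n_perm = 10000, seed = 1,
                                     exact = FALSE) {
  stopifnot(exact || n_perm >= 100)
  query <- as_gr(query); universe <- as_gr(universe)
  if (length(universe) < length(query))
    stop_validation("universe smaller than query")
  key_u <- paste(GenomicRanges::seqnames(universe),
                 GenomicRanges::start(universe),
                 GenomicRanges::end(universe))
  key_q <- paste(GenomicRanges::seqnames(query),
                 GenomicRanges::start(query), GenomicRanges::end(query))
  if (!all(key_q %in% key_u))
    stop_validation("query contains regions outside the universe")
  flags <- count_hits(universe, as_gr(reference)) > 0
  observed <- sum(flags[match(key_q, key_u)])
  m <- length(query)
  n <- length(universe)
  if (exact) {
    if (choose(n, m) > 1e6)
      stop_validation("exact enumeration infeasible for this size")
    subsets <- utils::combn(n, m)
    null <- colSums(matrix(flags[subsets], nrow = m))
    p <- mean(null >= observed)
    return(list(observed = observed, p = p, n_perm = ncol(subsets),
                null = null))
  }
  set.seed(as.integer(seed))
  null <- vapply(seq_len(n_perm),
                 function(i) sum(flags[sample.int(n, m)]), numeric(1))
  p <- (1 + sum(null >= observed)) / (1 + n_perm)
  list(observed = observed, p = p, n_perm = n_perm, null = null)
}

#' Call superenhancers from ranked stitched peak signal
#'
#' Peaks within `stitch_distance` bp of each other are merged and their
#' signals summed. Stitched regions are sorted by ascending signal and
#' both axes scaled to the unit square; the cutoff is the point where a
#' slope-1 line is tangent to the rank-signal curve, located as the
#' minimizer of (scaled signal - scaled rank), ties toward the highest
#' rank. Regions with signal strictly above the cutoff signal are
#' superenhancers; an all-equal signal profile (degenerate flat curve)
#' therefore yields none.
#'
#' @param peaks `GRanges` with a numeric `score` column (signal >= 0),
#'   or a data.frame with chrom/start/end/score.
#' @param stitch_distance maximum gap merged across (12500 bp, the
#'   field-standard stitching default).
#' @return A `GRanges` of stitched regions with `signal`, `rank`
#'   (ascending by signal) and `is_superenhancer`; the cutoff signal is
#'   in `metadata(...)$cutoff_signal` attribute `cutoff_signal`.
#' @export
call_superenhancers <- function(peaks, stitch_distance = 12500) {
  peaks <- as_gr(peaks)
  if (length(peaks) == 0) {
    out <- GenomicRanges::GRanges()
    attr(out, "cutoff_signal") <- NA_real_
    return(out)
  }
  sig <- S4Vectors::mcols(peaks)$score
  if (is.null(sig)) stop_validation("peaks need a numeric score column")
  if (any(sig < 0)) stop_validation("peak signal must be >= 0")
  stitched <- GenomicRanges::reduce(peaks,
                                    min.gapwidth = stitch_distance + 1L)
  ov <- find_hits(peaks, stitched)
  signal <- as.numeric(rowsum(sig[S4Vectors::queryHits(ov)],
                              S4Vectors::subjectHits(ov)))
  ord <- order(signal)
  n <- length(signal)
  x <- seq_len(n) / n
  y <- signal[ord] / max(signal)
  dmin <- y - x
  cut_rank <- max(which(dmin == min(dmin)))
  cutoff_signal <- signal[ord][cut_rank]
  rank_vec <- integer(n)
  rank_vec[ord] <- seq_len(n)
  out <- stitched
  S4Vectors::mcols(out)$signal <- signal
  S4Vectors::mcols(out)$rank <- rank_vec
  S4Vectors::mcols(out)$is_superenhancer <- signal > cutoff_signal
  attr(out, "cutoff_signal") <- cutoff_signal
  out
}

#' Distribution of DMR counts per superenhancer
#'
#' @param ses output of [call_superenhancers()] (only rows with
#'   `is_superenhancer` are counted, unless none are flagged, in which
#'   case all stitched regions are used).
#' @param dmrs region set.
#' @return list with `counts` (per superenhancer), `distribution`
#'   (table over counts) and `frac_with_dmr`.
#' @export
count_dmrs_per_superenhancer <- function(ses, dmrs) {
  if (length(ses) == 0)
    return(list(counts = integer(0), distribution = table(integer(0)),
                frac_with_dmr = NA_real_))
  flag <- S4Vectors::mcols(ses)$is_superenhancer
  sel <- if (!is.null(flag) && any(flag)) ses[flag] else ses
  counts <- count_hits(sel, as_gr(dmrs))
  list(counts = counts, distribution = table(counts),
       frac_with_dmr = mean(counts > 0))
}
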