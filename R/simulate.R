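CHROMHMM_STATES <- c("1_TssA", "2_TssAFlnk", "3_TxFlnk", "4_Tx", "5_TxWk",
                     "6_EnhG", "7_Enh", "8_ZNF_Rpts", "9_Het", "10_TssBiv",
                     "11_BivFlnk", "12_EnhBiv", "13_ReprPC", "14_ReprPCWk",
                     "15_Quies")
STATE_WEIGHTS <- c(0.03, 0.03, 0.02, 0.08, 0.10, 0.04, 0.08, 0.02, 0.15,
                   0.03, 0.02, 0.03, 0.04, 0.08, 0.25)

#' Synthetic cohort configuration
#'
#' Defines the generative model behind the synthetic methylome cohort:
#' a clustered CpG map (dense islands over a sparse background, so CpG
#' density statistics are non-degenerate), a bimodal baseline
#' methylome (islands mostly low, background mostly high), beta-binomial
#' per-sample methylation with overdispersion `dispersion`, negative
#' binomial coverage, focal hypermethylated regions planted for chosen
#' target groups (specific) or all tumor groups (shared), planted 5hmC
#' regions with a configurable oxidation efficiency, and annotation
#' tracks (chromatin states, peaks, CGIs, loops, expression) arranged so
#' enhancer-placed planted regions fall in enhancer states and, for a
#' configurable fraction, inside loop anchors whose partner anchor
#' holds the promoter of a highly expressed gene.
#'
#' The seed fully determines every output.
#'
#' @param seed integer seed (mandatory).
#' @param n_chroms,chrom_length genome shape.
#' @param islands_per_mb,island_length,island_spacing,background_spacing
#'   clustered CpG placement: dense islands (mean CpG gap
#'   `island_spacing`) over sparse background (mean gap
#'   `background_spacing`).
#' @param meth_low,meth_high baseline bimodal mixture modes.
#' @param island_low_prob,bg_low_prob probability that an island /
#'   background block sits at the low mode.
#' @param baseline_jitter_sd per-CpG jitter around the block mode.
#' @param dispersion beta-binomial overdispersion phi in (0, 1).
#' @param coverage_mean,coverage_size negative binomial coverage model.
#' @param groups named integer vector of per-group sample counts.
#' @param reference_group the normal-cell group name.
#' @param planted_dmrs list of planting specs, each a list with
#'   `target_groups`, `n_regions`, `cpg_range` (length-2), `delta`,
#'   `placement` (`"enhancer_state"` or `"random"`).
#' @param planted_shared like `planted_dmrs` but planted in every
#'   non-reference group (pan-tumor hypermethylation).
#' @param hmc_regions,hmc_level,hmc_cpg_range planted 5hmC regions.
#' @param oxbs_efficiency oxidation efficiency in (0, 1]; scalar or a
#'   named per-group vector.
#' @param n_genes,frac_regions_in_anchors,n_background_loops,link_top_quartile
#'   annotation layer: gene count, fraction of enhancer-placed planted
#'   regions put inside a loop anchor, background loop count, and
#'   whether linked partner genes are drawn from the top expression
#'   quartile.
#' @return A validated list of class `SimConfig`.
#' @export
sim_config <- function(seed,
                       n_chroms = 2, chrom_length = 5e6,
                       islands_per_mb = 40, island_length = 2000,
                       island_spacing = 30, background_spacing = 350,
                       meth_low = 0.15, meth_high = 0.85,
                       island_low_prob = 0.9, bg_low_prob = 0.05,
                       baseline_jitter_sd = 0.03,
                       dispersion = 0.05,
                       coverage_mean = 30, coverage_size = 10,
                       groups = c(CD34 = 6, IDHmut = 7, otherAML = 20),
                       reference_group = "CD34",
                       planted_dmrs = list(),
                       planted_shared = list(),
                       hmc_regions = 0, hmc_level = 0.2,
                       hmc_cpg_range = c(20, 60),
                       oxbs_efficiency = 1.0,
                       n_genes = 400,
                       frac_regions_in_anchors = 0.8,
                       n_background_loops = 100,
                       link_top_quartile = TRUE) {
  if (missing(seed)) stop_validation("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(dispersion > 0, dispersion < 1,
            meth_low >= 0, meth_low <= 1, meth_high >= 0, meth_high <= 1,
            island_low_prob >= 0, island_low_prob <= 1,
            bg_low_prob >= 0, bg_low_prob <= 1,
            frac_regions_in_anchors >= 0, frac_regions_in_anchors <= 1,
            hmc_level >= 0, hmc_level <= 1,
            all(oxbs_efficiency > 0), all(oxbs_efficiency <= 1),
            coverage_mean > 0, coverage_size > 0,
            length(groups) >= 2, !is.null(names(groups)),
            reference_group %in% names(groups))
  for (spec in c(planted_dmrs, planted_shared)) {
    stopifnot(spec$delta > 0, spec$delta <= 1,
              length(spec$cpg_range) == 2, spec$n_regions >= 0)
    if (spec$delta + meth_low > 1)
      stop_validation("delta + low baseline mode exceeds 1")
  }
  structure(cfg, class = "SimConfig")
}

# clustered CpG placement for one chromosome; returns sorted positions
# plus island intervals and per-CpG island id (0 = background)
place_cpgs_chrom <- function(cfg) {
  n_islands <- as.integer(cfg$islands_per_mb * cfg$chrom_length / 1e6)
  slot <- cfg$chrom_length / n_islands
  isl_start <- as.integer(floor((seq_len(n_islands) - 1) * slot +
    runif(n_islands, 0.1 * slot, 0.9 * slot - cfg$island_length)))
  isl_end <- isl_start + as.integer(cfg$island_length)
  isl_cpgs <- lapply(seq_len(n_islands), function(i) {
    n_draw <- ceiling(cfg$island_length / cfg$island_spacing * 2)
    gaps <- pmax(2, round(rexp(n_draw, 1 / cfg$island_spacing)))
    p <- isl_start[i] + cumsum(gaps)
    p[p < isl_end[i]]
  })
  n_bg <- ceiling(cfg$chrom_length / cfg$background_spacing * 1.5)
  bg_gaps <- pmax(2, round(rexp(n_bg, 1 / cfg$background_spacing)))
  bg <- cumsum(bg_gaps)
  bg <- bg[bg < cfg$chrom_length - 2]
  in_island <- rep(FALSE, length(bg))
  for (i in seq_len(n_islands))
    in_island <- in_island | (bg >= isl_start[i] & bg < isl_end[i])
  bg <- bg[!in_island]
  pos <- c(unlist(isl_cpgs), bg)
  isl_id <- c(rep(seq_len(n_islands), lengths(isl_cpgs)),
              rep(0L, length(bg)))
  ord <- order(pos)
  keep <- !duplicated(pos[ord])
  list(pos = as.integer(pos[ord][keep]), island = isl_id[ord][keep],
       island_start = isl_start, island_end = isl_end)
}

plant_regions <- function(spec_list, type, cpg_dt, baseline, used_islands,
                          cfg, all_groups) {
  regions <- list()
  for (spec in spec_list) {
    tg <- if (type == "shared")
      setdiff(all_groups, cfg$reference_group) else spec$target_groups
    if (!all(tg %in% all_groups))
      stop_validation("unknown target group in planting spec")
    placement <- if (is.null(spec$placement)) "enhancer_state" else
      spec$placement
    kmin <- spec$cpg_range[1]; kmax <- spec$cpg_range[2]
    # candidate islands: large enough, unused, headroom for delta
    key <- ifelse(cpg_dt$island > 0,
                  paste(cpg_dt$chrom, cpg_dt$island), NA_character_)
    idx_by_key <- split(seq_len(nrow(cpg_dt))[!is.na(key)],
                        key[!is.na(key)])
    cand_keys <- names(idx_by_key)[lengths(idx_by_key) >= kmin]
    cand_keys <- setdiff(cand_keys, used_islands)
    ok <- vapply(cand_keys, function(k)
      all(baseline[idx_by_key[[k]]] + spec$delta <= 1), logical(1))
    cand_keys <- cand_keys[ok]
    if (length(cand_keys) < spec$n_regions)
      stop_validation("not enough low-baseline islands to plant ",
                      spec$n_regions, " regions")
    chosen <- sample(cand_keys, spec$n_regions)
    used_islands <- c(used_islands, chosen)
    for (k in chosen) {
      idx <- idx_by_key[[k]]
      n_avail <- length(idx)
      ksize <- min(sample(seq.int(kmin, kmax), 1), n_avail)
      off <- if (n_avail > ksize) sample.int(n_avail - ksize + 1, 1) else 1L
      sel <- idx[seq.int(off, off + ksize - 1)]
      regions[[length(regions) + 1]] <- list(
        chrom = cpg_dt$chrom[sel[1]],
        start = cpg_dt$pos[sel[1]],
        end = cpg_dt$pos[sel[ksize]] + 2L,
        type = type, target_groups = paste(tg, collapse = ","),
        delta = spec$delta, placement = placement,
        n_cpgs = ksize, idx = sel)
    }
  }
  list(regions = regions, used_islands = used_islands)
}

#' Simulate a methylome cohort with planted differential regions
#'
#' Generates the clustered CpG map, the bimodal baseline, plants the
#' configured specific and shared hypermethylated regions (adding
#' `delta` to the target groups' mean track), and draws per-sample
#' counts: `p_s ~ Beta(mean, phi)`, `n_total ~ NegBin`,
#' `n_meth ~ Binomial(n_total, p_s)`.
#'
#' @param cfg a [sim_config()].
#' @return list with `matrix` (a `CpGCountMatrix`) and `truth`
#'   (class `SimTruth`: planted regions with coordinates and CpG
#'   indices, per-group true mean tracks, the baseline, 5hmC levels,
#'   island intervals, and the configuration).
#' @export
simulate_methylomes <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(child_seed(cfg$seed, "methylomes"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  placed <- lapply(chroms, function(ch) place_cpgs_chrom(cfg))
  cpg_dt <- data.table::data.table(
    chrom = rep(chroms, vapply(placed, function(p) length(p$pos), 1L)),
    pos = unlist(lapply(placed, `[[`, "pos")),
    island = unlist(lapply(placed, `[[`, "island")))
  islands <- data.table::rbindlist(lapply(seq_along(chroms), function(i)
    data.table::data.table(chrom = chroms[i],
                           start = placed[[i]]$island_start,
                           end = placed[[i]]$island_end,
                           island = seq_along(placed[[i]]$island_start))))
  n_cpg <- nrow(cpg_dt)

  # block-level bimodal baseline: islands and 2 kb background tiles
  blk <- paste(cpg_dt$chrom,
               ifelse(cpg_dt$island > 0,
                      paste0("isl", cpg_dt$island),
                      paste0("bg", cpg_dt$pos %/% 2000L)))
  ublk <- unique(blk)
  is_isl_blk <- grepl("isl", ublk)
  low_blk <- ifelse(is_isl_blk,
                    runif(length(ublk)) < cfg$island_low_prob,
                    runif(length(ublk)) < cfg$bg_low_prob)
  mode_blk <- ifelse(low_blk, cfg$meth_low, cfg$meth_high)
  baseline <- mode_blk[match(blk, ublk)] +
    rnorm(n_cpg, 0, cfg$baseline_jitter_sd)
  baseline <- pmin(pmax(baseline, 0.01), 0.99)

  group_names <- names(cfg$groups)
  used <- character(0)
  ps <- plant_regions(cfg$planted_dmrs, "specific", cpg_dt, baseline,
                      used, cfg, group_names)
  used <- ps$used_islands
  sh <- plant_regions(cfg$planted_shared, "shared", cpg_dt, baseline,
                      used, cfg, group_names)
  used <- sh$used_islands
  regions <- c(ps$regions, sh$regions)

  m <- matrix(baseline, n_cpg, length(group_names),
              dimnames = list(NULL, group_names))
  for (r in regions) {
    tg <- strsplit(r$target_groups, ",")[[1]]
    m[r$idx, tg] <- m[r$idx, tg] + r$delta
  }
  if (any(m > 1))
    stop_validation("configuration implies a group mean above 1")

  # planted 5hmC regions in unused low-baseline islands
  hmc <- numeric(n_cpg)
  hmc_regions <- list()
  if (cfg$hmc_regions > 0) {
    hs <- plant_regions(list(list(target_groups = group_names[1],
                                  n_regions = cfg$hmc_regions,
                                  cpg_range = cfg$hmc_cpg_range,
                                  delta = cfg$hmc_level,
                                  placement = "random")),
                        "hmc", cpg_dt, baseline, used, cfg, group_names)
    used <- hs$used_islands
    for (r in hs$regions) {
      if (any(apply(m[r$idx, , drop = FALSE], 1, max) + cfg$hmc_level > 1))
        stop_validation("5mC + 5hmC would exceed 1 at a planted CpG")
      hmc[r$idx] <- cfg$hmc_level
      r$delta <- cfg$hmc_level
      hmc_regions[[length(hmc_regions) + 1]] <- r
    }
  }

  draw_counts <- function(mean_track) {
    total <- rnbinom(n_cpg, size = cfg$coverage_size, mu = cfg$coverage_mean)
    p <- mean_track
    interior <- p > 0 & p < 1
    if (any(interior)) {
      phi <- cfg$dispersion
      a <- p[interior] * (1 - phi) / phi
      b <- (1 - p[interior]) * (1 - phi) / phi
      p[interior] <- rbeta(sum(interior), a, b)
    }
    meth <- rbinom(n_cpg, total, p)
    list(meth = meth, total = total)
  }

  n_samples <- sum(cfg$groups)
  meth <- matrix(0L, n_cpg, n_samples)
  total <- matrix(0L, n_cpg, n_samples)
  ids <- character(n_samples); grp <- character(n_samples)
  j <- 0
  for (g in group_names) {
    for (i in seq_len(cfg$groups[[g]])) {
      j <- j + 1
      d <- draw_counts(m[, g])
      meth[, j] <- d$meth; total[, j] <- d$total
      ids[j] <- sprintf("%s_%02d", g, i); grp[j] <- g
    }
  }
  md <- data.frame(sample_id = ids, assay = "WGBS", group = grp,
                   stringsAsFactors = FALSE)
  mat <- cpg_count_matrix(cpg_dt$chrom, cpg_dt$pos, meth, total, md)

  region_df <- if (length(regions))
    data.table::rbindlist(lapply(regions, function(r)
      data.table::data.table(chrom = r$chrom, start = r$start, end = r$end,
                             type = r$type, target_groups = r$target_groups,
                             delta = r$delta, placement = r$placement,
                             n_cpgs = r$n_cpgs)))
  else data.table::data.table(chrom = character(0), start = integer(0),
                              end = integer(0), type = character(0),
                              target_groups = character(0),
                              delta = numeric(0), placement = character(0),
                              n_cpgs = integer(0))
  hmc_df <- if (length(hmc_regions))
    data.table::rbindlist(lapply(hmc_regions, function(r)
      data.table::data.table(chrom = r$chrom, start = r$start, end = r$end,
                             level = cfg$hmc_level, n_cpgs = r$n_cpgs)))
  else data.table::data.table(chrom = character(0), start = integer(0),
                              end = integer(0), level = numeric(0),
                              n_cpgs = integer(0))

  truth <- structure(list(
    regions = as.data.frame(region_df),
    region_idx = lapply(regions, `[[`, "idx"),
    hmc_regions = as.data.frame(hmc_df),
    chrom = cpg_dt$chrom, pos = cpg_dt$pos, island = cpg_dt$island,
    baseline = baseline, m = m, hmc = hmc,
    islands = as.data.frame(islands), config = cfg),
    class = "SimTruth")
  list(matrix = mat, truth = truth)
}

#' Simulate paired standard and oxidative bisulfite tracks
#'
#' WGBS success probability per CpG is `5mC + 5hmC`; oxWGBS success
#' probability is `5mC + (1 - efficiency) * 5hmC` (incomplete oxidation
#' leaks 5hmC into the oxWGBS signal). At perfect efficiency the
#' expected WGBS-minus-oxWGBS subtraction equals the planted 5hmC.
#' Counts are drawn exactly as in [simulate_methylomes()]; the two
#' assays of one sample are independent library draws.
#'
#' @param truth a `SimTruth` from [simulate_methylomes()].
#' @param cfg the same [sim_config()]; `coverage_mean` may be
#'   overridden via `coverage` for high-coverage checks.
#' @param coverage optional coverage mean override.
#' @return list with `wgbs` and `oxwgbs` (`CpGCountMatrix`, same sample
#'   ids, assay labels set accordingly).
#' @export
simulate_paired_oxbs <- function(truth, cfg = truth$config, coverage = NULL) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(child_seed(cfg$seed, "oxbs"))
  cov_mean <- if (is.null(coverage)) cfg$coverage_mean else coverage
  m5 <- truth$m
  h <- truth$hmc
  if (any(m5 + h > 1))
    stop_validation("5mC + 5hmC exceeds 1 at some CpG")
  group_names <- colnames(m5)
  eff <- cfg$oxbs_efficiency
  eff_g <- if (length(eff) == 1) setNames(rep(eff, length(group_names)),
                                          group_names) else eff
  if (!all(group_names %in% names(eff_g)))
    stop_validation("per-group oxbs_efficiency must name every group")
  n_cpg <- nrow(m5)
  phi <- cfg$dispersion
  draw <- function(p_true) {
    total <- rnbinom(n_cpg, size = cfg$coverage_size, mu = cov_mean)
    p <- p_true
    interior <- p > 0 & p < 1
    if (any(interior)) {
      a <- p[interior] * (1 - phi) / phi
      b <- (1 - p[interior]) * (1 - phi) / phi
      p[interior] <- rbeta(sum(interior), a, b)
    }
    list(meth = rbinom(n_cpg, total, p), total = total)
  }
  n_samples <- sum(cfg$groups)
  mw <- tw <- mo <- to <- matrix(0L, n_cpg, n_samples)
  ids <- character(n_samples); grp <- character(n_samples)
  j <- 0
  for (g in group_names) {
    p_w <- m5[, g] + h
    p_o <- m5[, g] + (1 - eff_g[[g]]) * h
    for (i in seq_len(cfg$groups[[g]])) {
      j <- j + 1
      dw <- draw(p_w); do_ <- draw(p_o)
      mw[, j] <- dw$meth; tw[, j] <- dw$total
      mo[, j] <- do_$meth; to[, j] <- do_$total
      ids[j] <- sprintf("%s_%02d", g, i); grp[j] <- g
    }
  }
  md_w <- data.frame(sample_id = ids, assay = "WGBS", group = grp,
                     stringsAsFactors = FALSE)
  md_o <- data.frame(sample_id = ids, assay = "oxWGBS", group = grp,
                     stringsAsFactors = FALSE)
  list(wgbs = cpg_count_matrix(truth$chrom, truth$pos, mw, tw, md_w),
       oxwgbs = cpg_count_matrix(truth$chrom, truth$pos, mo, to, md_o))
}

#' Simulate annotation tracks consistent with the planted regions
#'
#' Emits a 15-label chromatin-state tiling in which every
#' enhancer-placed planted region lies inside an enhancer-state
#' interval; histone-mark peak sets consistent with the states
#' (H3K27ac over active-enhancer and TSS states, H3K4me1 over enhancer
#' states, H3K27me3 over bivalent/Polycomb states; planted
#' enhancer-placed regions get H3K27ac + H3K4me1, i.e. active); the CGI
#' set (the simulated islands); gene models with promoters and a TPM
#' expression table; and a loop set in which a configurable fraction of
#' enhancer-placed planted regions sit inside an anchor whose partner
#' anchor overlaps the promoter of a top-expression-quartile gene.
#'
#' @param truth a `SimTruth`.
#' @param cfg the matching [sim_config()].
#' @return list with `states`, `cgis`, `promoters`, `genes`
#'   (labelled `GRanges`), `k27ac`, `k4me1`, `k27me3` (scored
#'   `GRanges`), `loops` (a `LoopSet`), `expression`
#'   (`ExpressionTable`) and `truth` (the input truth augmented with a
#'   `links` data.frame of planted region-to-gene links).
#' @export
simulate_annotations <- function(truth, cfg = truth$config) {
  stopifnot(inherits(truth, "SimTruth"))
  set.seed(child_seed(cfg$seed, "annotations"))
  chroms <- sprintf("chr%d", seq_len(cfg$n_chroms))
  enh_regions <- truth$regions[truth$regions$placement == "enhancer_state", ,
                               drop = FALSE]

  seg_list <- list()
  for (ch in chroms) {
    lens <- pmax(500, round(rexp(ceiling(cfg$chrom_length / 2000), 1 / 3000)))
    brk <- cumsum(lens)
    brk <- brk[brk < cfg$chrom_length]
    er <- enh_regions[enh_regions$chrom == ch, , drop = FALSE]
    brk <- sort(unique(c(brk, er$start, er$end, cfg$chrom_length)))
    st <- c(0L, brk[-length(brk)]); en <- brk
    lab <- sample(CHROMHMM_STATES, length(st), replace = TRUE,
                  prob = STATE_WEIGHTS)
    if (nrow(er)) {
      inside <- rep(FALSE, length(st))
      for (i in seq_len(nrow(er)))
        inside <- inside | (st >= er$start[i] & en <= er$end[i])
      lab[inside] <- "7_Enh"
    }
    # merge runs of consecutive same-label segments so each planted
    # region lies inside a single enhancer-state interval
    r <- rle(lab)
    seg_end <- en[cumsum(r$lengths)]
    seg_start <- c(0L, seg_end[-length(seg_end)])
    seg_list[[ch]] <- data.table::data.table(chrom = ch, start = seg_start,
                                             end = seg_end,
                                             label = r$values)
  }
  segs <- data.table::rbindlist(seg_list)
  states <- gr_from_bed0(segs$chrom, segs$start, segs$end)
  S4Vectors::mcols(states)$label <- segs$label

  cgis <- gr_from_bed0(truth$islands$chrom, truth$islands$start,
                       truth$islands$end)
  S4Vectors::mcols(cgis)$label <- "CGI"

  # peaks driven by states, plus forced active marks at planted regions
  mk_peaks <- function(seg_sel, prob, pad = 0) {
    take <- runif(nrow(seg_sel)) < prob
    s <- seg_sel[take, ]
    if (!nrow(s)) return(GenomicRanges::GRanges())
    g <- gr_from_bed0(s$chrom, pmax(s$start - pad, 0), s$end + pad)
    S4Vectors::mcols(g)$score <- round(rlnorm(length(g), log(15), 0.8), 3)
    g
  }
  enh_states <- segs[segs$label %in% c("6_EnhG", "7_Enh"), ]
  tss_states <- segs[segs$label == "1_TssA", ]
  biv_states <- segs[segs$label %in% c("10_TssBiv", "12_EnhBiv",
                                       "13_ReprPC"), ]
  k27ac <- c(mk_peaks(enh_states, 0.7), mk_peaks(tss_states, 0.8))
  k4me1 <- mk_peaks(enh_states, 0.7, pad = 500)
  k27me3 <- mk_peaks(biv_states, 0.8, pad = 500)
  if (nrow(enh_regions)) {
    forced <- gr_from_bed0(enh_regions$chrom,
                           pmax(enh_regions$start - 200L, 0),
                           enh_regions$end + 200L)
    S4Vectors::mcols(forced)$score <- round(rlnorm(length(forced),
                                                   log(25), 0.5), 3)
    k27ac <- c(k27ac, forced)
    k4me1 <- c(k4me1, forced)
  }
  k27ac <- GenomicRanges::sort(k27ac)
  k4me1 <- GenomicRanges::sort(k4me1)
  k27me3 <- GenomicRanges::sort(k27me3)

  # gene models and expression
  gene_ids <- sprintf("gene_%04d", seq_len(cfg$n_genes))
  g_chrom <- sample(chroms, cfg$n_genes, replace = TRUE)
  g_start <- as.integer(runif(cfg$n_genes, 10000, cfg$chrom_length - 20000))
  genes <- gr_from_bed0(g_chrom, g_start, g_start + 5000L)
  S4Vectors::mcols(genes)$label <- gene_ids
  promoters <- promoters_from_genes(genes, pad = 2000)

  sample_ids <- unlist(lapply(names(cfg$groups), function(g)
    sprintf("%s_%02d", g, seq_len(cfg$groups[[g]]))))
  base_expr <- rlnorm(cfg$n_genes, meanlog = 2, sdlog = 1.5)
  base_expr[runif(cfg$n_genes) < 0.1] <- 0
  tpm <- matrix(base_expr, cfg$n_genes, length(sample_ids)) *
    matrix(rlnorm(cfg$n_genes * length(sample_ids), 0, 0.3),
           cfg$n_genes, length(sample_ids))
  colnames(tpm) <- sample_ids
  expr <- expression_table(gene_ids, tpm, gene_locations = genes)

  # loops: planted enhancer regions -> promoters of highly expressed genes
  gene_means <- rowMeans(tpm)
  expressed <- which(gene_means > 0)
  top_q <- expressed[gene_means[expressed] >=
                       quantile(gene_means[expressed], 0.75)]
  pool <- if (cfg$link_top_quartile) top_q else expressed
  a1 <- list(); a2 <- list(); links <- list()
  if (nrow(enh_regions) && length(pool)) {
    linked <- which(runif(nrow(enh_regions)) < cfg$frac_regions_in_anchors)
    for (i in linked) {
      gi <- if (length(pool) == 1) pool else sample(pool, 1)
      reg_mid <- (enh_regions$start[i] + enh_regions$end[i]) %/% 2
      a1[[length(a1) + 1]] <- data.frame(
        chrom = enh_regions$chrom[i],
        start = max(enh_regions$start[i] - 1000L, 0),
        end = enh_regions$end[i] + 1000L)
      pr_start <- max(g_start[gi] - 2500L, 0)
      a2[[length(a2) + 1]] <- data.frame(
        chrom = g_chrom[gi], start = pr_start, end = g_start[gi] + 2500L)
      links[[length(links) + 1]] <- data.frame(
        chrom = enh_regions$chrom[i], start = enh_regions$start[i],
        end = enh_regions$end[i], gene = gene_ids[gi],
        stringsAsFactors = FALSE)
    }
  }
  n_bg <- cfg$n_background_loops
  if (n_bg > 0) {
    bg_chrom <- sample(chroms, n_bg, replace = TRUE)
    max_gap_bp <- min(1e6, cfg$chrom_length * 0.3)
    s1 <- as.integer(runif(n_bg, 5000,
                           cfg$chrom_length - max_gap_bp - 10000))
    gap <- as.integer(runif(n_bg, max_gap_bp / 10, max_gap_bp))
    a1[[length(a1) + 1]] <- data.frame(chrom = bg_chrom, start = s1,
                                       end = s1 + 5000L)
    a2[[length(a2) + 1]] <- data.frame(chrom = bg_chrom, start = s1 + gap,
                                       end = s1 + gap + 5000L)
  }
  a1 <- data.table::rbindlist(a1); a2 <- data.table::rbindlist(a2)
  loops <- if (nrow(a1))
    loop_set(gr_from_bed0(a1$chrom, a1$start, a1$end),
             gr_from_bed0(a2$chrom, a2$start, a2$end),
             provenance = "synthetic")
  else loop_set(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                provenance = "synthetic")
  truth$links <- if (length(links)) do.call(rbind, links) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               gene = character(0))

  list(states = states, cgis = cgis, promoters = promoters, genes = genes,
       k27ac = k27ac, k4me1 = k4me1, k27me3 = k27me3, loops = loops,
       expression = expr, truth = truth)
}

#' Write a complete synthetic bundle to disk
#'
#' Runs the three simulation stages and writes everything the pipeline
#' reads: per-sample WGBS bedGraphs (plus paired WGBS/oxWGBS tracks
#' when 5hmC regions are configured), a sample sheet, the annotation
#' BED/BEDPE/TSV files, and a JSON ground-truth file.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created).
#' @param write_oxbs whether to also write the paired oxBS tracks.
#' @return Invisibly, a list with the in-memory objects and the paths.
#' @export
simulate_cohort <- function(cfg, dir, write_oxbs = cfg$hmc_regions > 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_methylomes(cfg)
  ann <- simulate_annotations(sim$truth, cfg)
  truth <- ann$truth
  bg_dir <- file.path(dir, "bedgraph")
  dir.create(bg_dir, showWarnings = FALSE)
  sheet <- sim$matrix$metadata
  sheet$path <- file.path("bedgraph", paste0(sheet$sample_id, ".bedgraph"))
  for (s in sim$matrix$samples)
    write_cpg_bedgraph(sim$matrix, s,
                       file.path(bg_dir, paste0(s, ".bedgraph")))
  pair <- NULL
  if (write_oxbs) {
    pair <- simulate_paired_oxbs(truth, cfg)
    for (s in pair$wgbs$samples) {
      write_cpg_bedgraph(pair$wgbs, s,
                         file.path(bg_dir, paste0(s, ".wgbs_paired.bedgraph")))
      write_cpg_bedgraph(pair$oxwgbs, s,
                         file.path(bg_dir, paste0(s, ".oxwgbs.bedgraph")))
    }
  }
  data.table::fwrite(sheet, file.path(dir, "samples.tsv"), sep = "\t")
  write_bed(ann$states, file.path(dir, "states.bed"))
  write_bed(ann$cgis, file.path(dir, "cgis.bed"))
  write_bed(ann$promoters, file.path(dir, "promoters.bed"))
  write_bed(ann$genes, file.path(dir, "genes.bed"))
  write_bed(ann$k27ac, file.path(dir, "k27ac.bed"))
  write_bed(ann$k4me1, file.path(dir, "k4me1.bed"))
  write_bed(ann$k27me3, file.path(dir, "k27me3.bed"))
  write_bedpe(ann$loops, file.path(dir, "loops.bedpe"))
  write_expression(ann$expression, file.path(dir, "expression.tsv"))
  jsonlite::write_json(
    list(seed = cfg$seed,
         regions = truth$regions,
         hmc_regions = truth$hmc_regions,
         links = truth$links),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(matrix = sim$matrix, truth = truth, annotations = ann,
                 paired = pair, dir = dir))
}
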