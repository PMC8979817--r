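#' Estimate 5hmC from paired standard and oxidative bisulfite tracks
#'
#' Standard bisulfite (WGBS) betas report 5mC + 5hmC; oxidative
#' bisulfite (oxWGBS) betas report 5mC only, so the per-CpG difference
#' `beta_WGBS - beta_oxWGBS` estimates 5hmC. The estimate is kept only
#' at CpGs where *both* assays have coverage strictly above `min_cov`
#' (the "> 10x" rule); negative values are retained, since flooring
#' would bias region means upward.
#'
#' Samples are paired by sample id: both matrices must contain the same
#' sample ids (assay labels may differ). Positions are intersected.
#'
#' @param wgbs,oxwgbs `CpGCountMatrix` objects for the two assays with
#'   identical sample id sets.
#' @param min_cov coverage cutoff; a CpG/sample cell is covered iff
#'   `n_total > min_cov` in both assays.
#' @return An object of class `HmcTrack`: `chrom`, `pos`, `hmc`
#'   (CpGs x samples, `NA` where uncovered), `covered` (logical
#'   matrix), `samples`, `metadata` (from the WGBS matrix).
#' @export
compute_hmc <- function(wgbs, oxwgbs, min_cov = 10) {
  if (!setequal(wgbs$samples, oxwgbs$samples))
    stop_validation("unpaired sample(s): ",
                    paste(union(setdiff(wgbs$samples, oxwgbs$samples),
                                setdiff(oxwgbs$samples, wgbs$samples)),
                          collapse = ", "))
  key_w <- paste(wgbs$chrom, wgbs$pos)
  key_o <- paste(oxwgbs$chrom, oxwgbs$pos)
  common <- intersect(key_w, key_o)
  if (!length(common)) stop_validation("no shared CpG positions")
  iw <- match(common, key_w)
  io <- match(common, key_o)
  jo <- match(wgbs$samples, oxwgbs$samples)
  mw <- wgbs$meth[iw, , drop = FALSE]
  tw <- wgbs$total[iw, , drop = FALSE]
  mo <- oxwgbs$meth[io, jo, drop = FALSE]
  to <- oxwgbs$total[io, jo, drop = FALSE]
  covered <- tw > min_cov & to > min_cov
  hmc <- matrix(NA_real_, nrow(mw), ncol(mw))
  hmc[covered] <- mw[covered] / tw[covered] - mo[covered] / to[covered]
  colnames(hmc) <- wgbs$samples
  colnames(covered) <- wgbs$samples
  structure(list(chrom = wgbs$chrom[iw], pos = wgbs$pos[iw],
                 hmc = hmc, covered = covered,
                 samples = wgbs$samples, metadata = wgbs$metadata),
            class = "HmcTrack")
}

#' @export
print.HmcTrack <- function(x, ...) {
  cat(sprintf("HmcTrack: %d CpGs x %d samples (%.1f%% covered)\n",
              nrow(x$hmc), ncol(x$hmc), 100 * mean(x$covered)))
  invisible(x)
}

#' Per-region, per-sample mean 5hmC
#'
#' Unweighted mean of the per-CpG 5hmC estimates over each region's
#' covered CpGs; regions with no covered CpG for a sample are `NA`.
#'
#' @param track an `HmcTrack` from [compute_hmc()].
#' @param regions `GRanges` or chrom/start/end data.frame.
#' @return data.frame: regions x samples of mean 5hmC.
#' @export
region_hmc <- function(track, regions) {
  regions <- as_region_df(regions)
  cg <- cpg_gr(track$chrom, track$pos)
  rg <- gr_from_bed0(regions$chrom, regions$start, regions$end)
  ov <- find_hits(cg, rg)
  ridx <- S4Vectors::subjectHits(ov)
  cidx <- S4Vectors::queryHits(ov)
  n <- nrow(regions)
  means <- matrix(NA_real_, n, length(track$samples))
  colnames(means) <- track$samples
  if (length(ridx)) {
    vals <- track$hmc[cidx, , drop = FALSE]
    cov <- !is.na(vals)
    vals0 <- ifelse(cov, vals, 0)
    s <- rowsum(vals0, ridx)
    k <- rowsum(cov + 0, ridx)
    hit <- as.integer(rownames(s))
    m <- s / k
    m[k == 0] <- NA_real_
    means[hit, ] <- m
  }
  cbind(regions[, c("chrom", "start", "end")], as.data.frame(means))
}

#' Compare mean 5hmC across region sets and sample groups
#'
#' For each named region set, each sample's mean 5hmC over the set's
#' regions (mean of per-region means, regions without coverage
#' excluded) is computed; group contrasts use two-sided Welch tests on
#' these per-sample means, with Benjamini-Hochberg adjustment across all
#' reported contrasts. Degenerate contrasts (zero variance on both
#' sides, e.g. identical groups) are reported with p = 1; groups with
#' fewer than two samples are skipped with a warning.
#'
#' @param region_sets named list of `GRanges`/data.frame region sets.
#' @param groups named list of sample id sets (or group labels present
#'   in the track metadata).
#' @param track an `HmcTrack`.
#' @return list with `sample_means` (data.frame: set, sample, group,
#'   mean) and `contrasts` (data.frame: set, group pair, means, p, q).
#' @export
compare_region_hmc <- function(region_sets, groups, track) {
  resolve <- function(g) {
    g <- as.character(g)
    if (all(g %in% track$metadata$group) && !any(g %in% track$samples))
      return(track$samples[track$metadata$group %in% g])
    miss <- setdiff(g, track$samples)
    if (length(miss)) stop_validation("unknown sample(s): ",
                                      paste(miss, collapse = ", "))
    g
  }
  groups <- lapply(groups, resolve)
  sm <- list()
  for (set_name in names(region_sets)) {
    rm_ <- region_hmc(track, region_sets[[set_name]])
    vals <- as.matrix(rm_[, track$samples, drop = FALSE])
    per_sample <- colMeans(vals, na.rm = TRUE)
    per_sample[is.nan(per_sample)] <- NA_real_
    for (g in names(groups)) {
      ids <- groups[[g]]
      sm[[length(sm) + 1]] <- data.frame(
        set = set_name, sample = ids, group = g,
        mean = unname(per_sample[ids]), stringsAsFactors = FALSE)
    }
  }
  sample_means <- do.call(rbind, sm)
  gn <- names(groups)
  contrasts <- list()
  for (set_name in names(region_sets)) {
    if (length(gn) < 2) break
    for (i in seq_len(length(gn) - 1)) for (k in seq.int(i + 1, length(gn))) {
      xi <- sample_means$mean[sample_means$set == set_name &
                                sample_means$group == gn[i]]
      xk <- sample_means$mean[sample_means$set == set_name &
                                sample_means$group == gn[k]]
      xi <- xi[!is.na(xi)]; xk <- xk[!is.na(xk)]
      if (length(xi) < 2 || length(xk) < 2) {
        warning("contrast skipped (fewer than 2 samples): ", set_name,
                " ", gn[i], " vs ", gn[k])
        next
      }
      p <- if (var(xi) == 0 && var(xk) == 0) {
        if (mean(xi) == mean(xk)) 1 else 0
      } else t.test(xi, xk)$p.value
      contrasts[[length(contrasts) + 1]] <- data.frame(
        set = set_name, group_a = gn[i], group_b = gn[k],
        mean_a = mean(xi), mean_b = mean(xk),
        diff = mean(xk) - mean(xi), p = p, stringsAsFactors = FALSE)
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame(set = character(0), group_a = character(0),
               group_b = character(0), mean_a = numeric(0),
               mean_b = numeric(0), diff = numeric(0), p = numeric(0))
  contrasts$q <- p.adjust(contrasts$p, method = "BH")
  list(sample_means = sample_means, contrasts = contrasts)
}

#' Write a 5hmC track as per-sample bedGraphs
#'
#' One five-column bedGraph per sample (chrom, start, end, hmc,
#' covered-flag); uncovered CpGs are omitted.
#'
#' @param track an `HmcTrack`.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
write_hmc_bedgraphs <- function(track, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (s in track$samples) {
    keep <- track$covered[, s]
    dt <- data.table::data.table(
      chrom = track$chrom[keep], start = track$pos[keep],
      end = track$pos[keep] + 2L,
      hmc = sprintf("%.6f", track$hmc[keep, s]))
    p <- file.path(dir, paste0(s, ".hmc.bedgraph"))
    data.table::fwrite(dt, p, sep = "\t", col.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
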