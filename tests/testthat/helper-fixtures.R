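# tiny in-code fixtures shared across test files

# matrix from explicit beta "m/t" strings, one row per CpG, columns are
# samples; positions 0, 100, 200, ... on chr1
tiny_matrix <- function(counts, groups,
                        chrom = rep("chr1", nrow(counts$meth)),
                        pos = seq(0, by = 100,
                                  length.out = nrow(counts$meth))) {
  ids <- sprintf("s%02d", seq_along(groups))
  md <- data.frame(sample_id = ids, assay = "WGBS", group = groups,
                   stringsAsFactors = FALSE)
  cpg_count_matrix(chrom, pos, counts$meth, counts$total, md)
}

# counts helper: meth and total matrices from vectors of pairs
cpairs <- function(...) {
  rows <- list(...)
  meth <- do.call(rbind, lapply(rows, function(r) r[c(TRUE, FALSE)]))
  total <- do.call(rbind, lapply(rows, function(r) r[c(FALSE, TRUE)]))
  list(meth = meth, total = total)
}

# random count matrices for oracle comparisons
random_counts <- function(n_units, n_a, n_b, seed) {
  set.seed(seed)
  tot_a <- matrix(rpois(n_units * n_a, 12), n_units, n_a)
  tot_b <- matrix(rpois(n_units * n_b, 12), n_units, n_b)
  # sprinkle zero and single-read cells to hit the edge rules
  tot_a[runif(length(tot_a)) < 0.05] <- 0
  tot_b[runif(length(tot_b)) < 0.05] <- 0
  tot_a[runif(length(tot_a)) < 0.05] <- 1
  tot_b[runif(length(tot_b)) < 0.05] <- 1
  pa <- runif(n_units); pb <- runif(n_units)
  meth_a <- matrix(rbinom(length(tot_a), tot_a, pa), n_units, n_a)
  meth_b <- matrix(rbinom(length(tot_b), tot_b, pb), n_units, n_b)
  list(meth_a = meth_a, tot_a = tot_a, meth_b = meth_b, tot_b = tot_b)
}

sim_cfg_planted <- function(seed, n_regions = 100, delta = 0.4,
                            groups = c(CD34 = 6, IDHmut = 7,
                                       otherAML = 20), ...) {
  sim_config(seed = seed, groups = groups, reference_group = "CD34",
             planted_dmrs = list(list(target_groups = "IDHmut",
                                      n_regions = n_regions,
                                      cpg_range = c(20, 60),
                                      delta = delta,
                                      placement = "enhancer_state")),
             ...)
}

regions_gr <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1, df$end))
}
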