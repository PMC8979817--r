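test_that("pooled group means pool counts and skip zero-coverage cells", {
  m <- tiny_matrix(cpairs(c(5L, 10L), c(0L, 10L), c(3L, 4L)),
                   groups = "g1")
  expect_equal(pooled_group_means(m, "g1")$mean, c(0.5, 0, 0.75))

  m2 <- tiny_matrix(cpairs(c(0L, 10L, 10L, 10L), c(3L, 4L, 0L, 0L)),
                    groups = c("g1", "g1"))
  pm <- pooled_group_means(m2, "g1")
  expect_equal(pm$mean, c(0.5, 0.75))    # 0/10 + 10/10 pooled; 0/0 ignored
  expect_equal(pm$low_cov, c(FALSE, TRUE))
  expect_error(pooled_group_means(m, character(0)), "empty group")
})

test_that("Wald statistic and p agree with the direct-formula oracle", {
  # 1000 random count configurations, mixed group sizes, zero cells
  for (case in list(c(400, 3, 3, 101), c(300, 2, 5, 202),
                    c(300, 6, 4, 303))) {
    rc <- random_counts(case[1], case[2], case[3], case[4])
    strat <- rep(c("chrA", "chrB"), length.out = case[1])
    got <- bb_wald(rc$meth_a, rc$tot_a, rc$meth_b, rc$tot_b,
                   stratum = strat)
    want <- oracle_bb_wald(rc$meth_a, rc$tot_a, rc$meth_b, rc$tot_b,
                           stratum = strat)
    expect_equal(got$wald, want$wald, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$phi, want$phi, tolerance = 1e-10)
    expect_equal(got$testable, want$testable)
  }
})

test_that("dmc_test is symmetric, gated on both q and diff, and guarded", {
  set.seed(9)
  n <- 200
  tot <- matrix(rpois(n * 8, 20), n, 8)
  meth <- matrix(rbinom(n * 8, tot, rep(runif(n), 8)), n, 8)
  # plant a strong difference at 20 CpGs
  meth[1:20, 5:8] <- tot[1:20, 5:8]
  meth[1:20, 1:4] <- 0
  md <- data.frame(sample_id = sprintf("s%d", 1:8), assay = "WGBS",
                   group = rep(c("A", "B"), each = 4))
  m <- cpg_count_matrix(rep("chr1", n), seq(0, by = 50, length.out = n),
                        meth, tot, md)
  ab <- dmc_test(m, "A", "B")
  ba <- dmc_test(m, "B", "A")
  expect_equal(ab$diff, -ba$diff)
  expect_equal(ab$p, ba$p)
  expect_true(all(ab$is_dmc == (ab$q < 0.05 & abs(ab$diff) >= 0.2)))
  expect_true(all(ab$q >= ab$p))
  expect_true(all(ab$is_dmc[1:20]))

  # identical columns in both groups -> diff 0, wald 0, p 1
  mm <- tiny_matrix(cpairs(c(5L, 10L, 5L, 10L, 5L, 10L, 5L, 10L)),
                    groups = c("A", "A", "B", "B"))
  r <- dmc_test(mm, "A", "B")
  expect_equal(r$diff, 0)
  expect_equal(r$wald, 0)
  expect_equal(r$p, 1)

  # q below fdr but diff below 0.2 is not a DMC
  expect_error(dmc_test(m, "A", "A"), "share sample")
  one_cov <- tiny_matrix(cpairs(c(1L, 1L, 0L, 0L, 1L, 1L, 0L, 0L)),
                         groups = c("A", "A", "B", "B"))
  expect_error(dmc_test(one_cov, "A", "B"), "no testable CpGs")
})

test_that("strong group difference yields a significant negative diff", {
  m <- tiny_matrix(cpairs(c(9L, 10L, 8L, 10L, 10L, 10L,
                            1L, 10L, 2L, 10L, 0L, 10L)),
                   groups = c(rep("A", 3), rep("B", 3)))
  r <- dmc_test(m, "A", "B")
  expect_equal(r$diff, -0.8)
  expect_lt(r$p, 0.01)
  ora <- oracle_bb_wald(matrix(c(9, 8, 10), 1), matrix(10, 1, 3),
                        matrix(c(1, 2, 0), 1), matrix(10, 1, 3))
  expect_equal(r$wald, ora$wald, tolerance = 1e-10)
})

test_that("DMR segmentation applies the >10 CpG rule and chaining", {
  mk_dmc <- function(pos, diff, is_dmc, chrom = "chr1") {
    n <- length(pos)
    diff <- rep_len(diff, n); is_dmc <- rep_len(is_dmc, n)
    data.frame(chrom = rep_len(chrom, n), pos = pos,
               mu_a = rep_len(0.2, n), mu_b = 0.2 + diff, diff = diff,
               m_a = rep_len(20, n), t_a = rep_len(100, n),
               m_b = (0.2 + diff) * 100, t_b = rep_len(100, n),
               p = ifelse(is_dmc, 1e-8, 0.5),
               q = ifelse(is_dmc, 1e-6, 0.6), is_dmc = is_dmc)
  }
  expect_equal(nrow(segment_dmrs(mk_dmc(integer(0), numeric(0),
                                        logical(0)))), 0)

  # exactly 10 CpGs, all DMCs: rejected by the "> 10" rule
  d10 <- mk_dmc(seq(0, by = 50, length.out = 10), 0.4, TRUE)
  expect_equal(nrow(segment_dmrs(d10)), 0)

  # 11 CpGs, all DMCs: accepted, boundaries CpG-anchored half-open
  d11 <- mk_dmc(seq(0, by = 50, length.out = 11), 0.4, TRUE)
  r <- segment_dmrs(d11)
  expect_equal(nrow(r), 1)
  expect_equal(r$start, 0L)
  expect_equal(r$end, 500L + 2L)
  expect_equal(r$n_cpgs, 11L)
  expect_equal(r$direction, "hyper")

  # a gap over max_gap splits the chain; each half is too small
  pos <- c(seq(0, by = 50, length.out = 6),
           seq(5000, by = 50, length.out = 6))
  expect_equal(nrow(segment_dmrs(mk_dmc(pos, 0.4, TRUE))), 0)

  # opposite-direction DMCs never chain together
  d <- rbind(mk_dmc(seq(0, by = 50, length.out = 6), 0.4, TRUE),
             mk_dmc(seq(300, by = 50, length.out = 6), -0.4, TRUE))
  expect_equal(nrow(segment_dmrs(d)), 0)

  # low DMC share within the span blocks the call
  sparse <- mk_dmc(seq(0, by = 50, length.out = 30), 0.4,
                   rep(c(TRUE, FALSE, FALSE), 10))
  expect_equal(nrow(segment_dmrs(sparse)), 0)
})

test_that("raising thresholds never increases DMC or DMR counts", {
  set.seed(21)
  cfg <- sim_cfg_planted(seed = 77, n_regions = 20,
                         groups = c(CD34 = 4, IDHmut = 4, otherAML = 4))
  sim <- simulate_methylomes(cfg)
  base <- thresholds()
  d1 <- dmc_test(sim$matrix, "CD34", "IDHmut", base)
  d2 <- dmc_test(sim$matrix, "CD34", "IDHmut",
                 thresholds(min_diff = 0.3))
  d3 <- dmc_test(sim$matrix, "CD34", "IDHmut", thresholds(fdr = 0.01))
  expect_lte(sum(d2$is_dmc), sum(d1$is_dmc))
  expect_lte(sum(d3$is_dmc), sum(d1$is_dmc))
  r1 <- segment_dmrs(d1, base)
  r2 <- segment_dmrs(d1, thresholds(min_cpgs_per_dmr = 40))
  expect_lte(nrow(r2), nrow(r1))
})

test_that("stage 2 separates group-specific from shared regions", {
  cfg <- sim_config(seed = 31,
    groups = c(CD34 = 5, IDHmut = 5, otherAML = 8),
    reference_group = "CD34",
    planted_dmrs = list(list(target_groups = "IDHmut", n_regions = 15,
                             cpg_range = c(20, 40), delta = 0.4,
                             placement = "random")),
    planted_shared = list(list(n_regions = 15, cpg_range = c(20, 40),
                               delta = 0.4, placement = "random")))
  sim <- simulate_methylomes(cfg)
  dmcs <- dmc_test(sim$matrix, "CD34", "IDHmut")
  dmrs <- segment_dmrs(dmcs)
  spec <- call_group_specific(dmrs, sim$matrix, "IDHmut", "otherAML")
  truth <- sim$truth$regions
  shared_gr <- regions_gr(truth[truth$type == "shared", ])
  spec_gr <- regions_gr(truth[truth$type == "specific", ])
  called <- regions_gr(spec)
  # no shared region survives stage 2; specific regions do
  expect_equal(sum(GenomicRanges::countOverlaps(shared_gr, called) > 0), 0)
  expect_gte(sum(GenomicRanges::countOverlaps(spec_gr, called) > 0), 13)
  # direction conserved from stage 1
  expect_true(all(spec$direction == "hyper"))
  expect_true(all(sign(spec$stage2_diff) > 0))

  expect_error(call_group_specific(dmrs, sim$matrix, "IDHmut", "IDHmut"),
               "overlap")
  expect_error(call_group_specific(dmrs, sim$matrix, "IDHmut", "otherAML",
                                   excluded_groups = "otherAML"),
               "comparison set empty|disjoint")
})

test_that("dmr_set_operations matches a brute-force all-pairs check", {
  set.seed(5)
  for (i in 1:20) {
    a <- random_regions(sample(3:25, 1))
    b <- random_regions(sample(3:25, 1))
    rep <- dmr_set_operations(a, b)
    expect_equal(rep$a_hits, sum(brute_overlap_flags(a, b)))
    expect_equal(rep$b_hits, sum(brute_overlap_flags(b, a)))
  }
  a <- random_regions(10)
  self <- dmr_set_operations(a, a)
  expect_equal(self$frac_a, 1)
  disj <- dmr_set_operations(
    data.frame(chrom = "chr1", start = 0, end = 10),
    data.frame(chrom = "chr1", start = 100, end = 110))
  expect_equal(disj$frac_a, 0)
})

test_that("binned methylation pools per bin and drops uncovered bins", {
  m <- tiny_matrix(cpairs(c(5L, 10L, 2L, 10L), c(0L, 0L, 8L, 10L)),
                   groups = c("g1", "g1"),
                   pos = c(100L, 1500L))
  b <- bin_mean_methylation(m, 1000)
  # second bin: sample 1 has no coverage -> dropped (complete case)
  expect_equal(nrow(b), 1)
  expect_equal(b$start, 0L)
  expect_equal(unname(unlist(b[, 4:5])), c(0.5, 0.2))
  expect_equal(attr(b, "n_dropped"), 1)

  # two CpGs pooled within one bin
  m2 <- tiny_matrix(cpairs(c(5L, 10L), c(1L, 10L)), groups = "g1",
                    pos = c(100L, 200L))
  b2 <- bin_mean_methylation(m2, 1000)
  expect_equal(unname(unlist(b2[, 4])), 6 / 20)
})

test_that("region means, low-methylation fraction and re-testing work", {
  cfg <- sim_cfg_planted(seed = 51, n_regions = 10,
                         groups = c(CD34 = 4, IDHmut = 4, otherAML = 4))
  sim <- simulate_methylomes(cfg)
  tr <- sim$truth$regions
  rm_ <- region_group_methylation(sim$matrix, tr,
                                  list(CD34 = "CD34", IDHmut = "IDHmut"))
  # planted regions sit on the low baseline mode; target is shifted by delta
  expect_true(all(rm_$IDHmut - rm_$CD34 > 0.25))
  expect_equal(low_meth_fraction(rm_, "CD34", 0.3),
               mean(rm_$CD34 < 0.3), ignore_attr = TRUE)
  expect_equal(as.numeric(low_meth_fraction(rm_, "CD34", 0)), 0)

  rt <- region_group_test(sim$matrix, tr, "CD34", "IDHmut")
  expect_true(all(rt$q < 0.05))
  expect_true(all(rt$diff > 0.25))
})

test_that("meta-region profiles peak at planted centers", {
  cfg <- sim_cfg_planted(seed = 61, n_regions = 15,
                         groups = c(CD34 = 4, IDHmut = 4, otherAML = 2))
  sim <- simulate_methylomes(cfg)
  tr <- sim$truth$regions
  pr_t <- profile_matrix(sim$matrix, tr, "IDHmut", flank = 5000)
  pr_r <- profile_matrix(sim$matrix, tr, "CD34", flank = 5000)
  nb <- length(pr_t$profile)
  # the group contrast peaks at the region center and vanishes at the
  # edges (the baseline itself is shared between groups)
  contrast <- pr_t$profile - pr_r$profile
  center <- mean(contrast[(nb %/% 2):(nb %/% 2 + 1)], na.rm = TRUE)
  edge <- mean(c(contrast[1:3], contrast[(nb - 2):nb]), na.rm = TRUE)
  expect_gte(center - edge, 0.5 * 0.4)
  expect_lt(abs(edge), 0.05)
  # uniform methylation -> flat profile
  flat <- tiny_matrix(cpairs(c(5L, 10L), c(5L, 10L), c(5L, 10L)),
                      groups = "g1", pos = c(100L, 200L, 300L))
  pf <- profile_matrix(flat, data.frame(chrom = "chr1", start = 150L,
                                        end = 250L), "g1",
                       flank = 200, bin_width = 100)
  expect_true(all(abs(pf$profile[!is.na(pf$profile)] - 0.5) < 1e-12))
})
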