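test_that("enhancer classification matches the full truth table", {
  # eight regions, one per (K27ac, K4me1, K27me3) combination
  regions <- data.frame(chrom = "chr1",
                        start = seq(0, by = 1000, length.out = 8),
                        end = seq(0, by = 1000, length.out = 8) + 500)
  combos <- expand.grid(a = c(FALSE, TRUE), m1 = c(FALSE, TRUE),
                        m3 = c(FALSE, TRUE))
  combos <- combos[order(combos$a, combos$m1, combos$m3), ]
  mk <- function(flag) {
    hit <- regions[flag, , drop = FALSE]
    if (!nrow(hit)) return(GenomicRanges::GRanges())
    regions_gr(hit)
  }
  calls <- classify_enhancers(regions, mk(combos$a), mk(combos$m1),
                              mk(combos$m3))
  want <- ifelse(combos$a & combos$m3, "poised",
          ifelse(combos$a, "active",
          ifelse(combos$m1 & !combos$m3, "weak", "none")))
  expect_equal(calls$class, want)
  # spot-check the documented rows
  key <- paste0(combos$a + 0, combos$m1 + 0, combos$m3 + 0)
  expect_equal(calls$class[key == "100"], "active")
  expect_equal(calls$class[key == "110"], "active")
  expect_equal(calls$class[key == "101"], "poised")
  expect_equal(calls$class[key == "111"], "poised")
  expect_equal(calls$class[key == "010"], "weak")
  expect_equal(calls$class[key == "011"], "none")
  expect_equal(calls$class[key == "001"], "none")
  expect_equal(calls$class[key == "000"], "none")
})

test_that("state assignment equals the per-bp brute-force oracle", {
  set.seed(17)
  labels <- c("1_TssA", "7_Enh", "9_Het", "15_Quies")
  for (rep_i in 1:25) {
    # random tiling of [0, 4000) per chromosome
    states <- do.call(rbind, lapply(c("chrA", "chrB"), function(ch) {
      brk <- sort(sample(seq(100, 3900, by = 100),
                         sample(3:8, 1)))
      data.frame(chrom = ch, start = c(0, brk), end = c(brk, 4000),
                 label = sample(labels, length(brk) + 1, replace = TRUE))
    }))
    regions <- random_regions(sample(4:12, 1), span = 3800)
    sgr <- regions_gr(states)
    S4Vectors::mcols(sgr)$label <- states$label
    got <- state_overlap_distribution(regions, sgr)
    want <- brute_state_assignment(regions, states, labels)
    expect_equal(got$assignment, want)
  }
})

test_that("state fractions and enrichment behave at the fixed points", {
  states <- data.frame(chrom = "chr1", start = c(0, 1000, 2000),
                       end = c(1000, 2000, 3000),
                       label = c("1_TssA", "7_Enh", "9_Het"))
  sgr <- regions_gr(states)
  S4Vectors::mcols(sgr)$label <- states$label
  inside <- data.frame(chrom = "chr1", start = c(1100, 1500),
                       end = c(1300, 1900))
  d <- state_overlap_distribution(inside, sgr)
  expect_equal(unname(d$fractions["7_Enh"]), 1)
  expect_equal(sum(d$fractions), 1)
  # background == regions -> enrichment 1 where defined
  e <- state_enrichment(inside, inside, sgr)
  expect_equal(unname(e["7_Enh"]), 1)
  expect_true(all(is.na(e[c("1_TssA", "9_Het")])))
  # overlapping state map is rejected
  bad <- regions_gr(data.frame(chrom = "chr1", start = c(0, 500),
                               end = c(1000, 1500)))
  S4Vectors::mcols(bad)$label <- c("1_TssA", "7_Enh")
  expect_error(state_overlap_distribution(inside, bad), "overlap")
})

test_that("overlap_fraction matches brute force on random instances", {
  set.seed(23)
  for (rep_i in 1:30) {
    regions <- random_regions(sample(3:30, 1))
    features <- random_regions(sample(3:30, 1))
    got <- overlap_fraction(regions, features)
    flags <- brute_overlap_flags(regions, features)
    expect_equal(as.numeric(got), mean(flags))
    expect_equal(unname(attr(got, "hits")), flags)
    # higher min-overlap requirement with brute force
    got40 <- overlap_fraction(regions, features, min_overlap_bp = 40)
    expect_equal(as.numeric(got40),
                 mean(brute_overlap_flags(regions, features, 40)))
  }
  # fixed points
  g <- data.frame(chrom = "chr1", start = 0, end = 100)
  expect_equal(as.numeric(overlap_fraction(g,
    data.frame(chrom = "chr1", start = 0, end = 1e6))), 1)
  expect_equal(as.numeric(overlap_fraction(g,
    data.frame(chrom = "chr2", start = 0, end = 1e6))), 0)
})

test_that("cpg_density counts CpGs per 100 bp", {
  cpgs <- data.frame(chrom = "chr1",
                     pos = as.integer(seq(0, 990, by = 100)))
  d <- cpg_density(data.frame(chrom = "chr1", start = 0L, end = 1000L),
                   cpgs)
  expect_equal(d$density, 1.0)   # 10 CpGs in 1000 bp
  d0 <- cpg_density(data.frame(chrom = "chr2", start = 0L, end = 500L),
                    cpgs)
  expect_equal(d0$density, 0.0)
})

test_that("permutation test matches exhaustive enumeration on toys", {
  universe <- data.frame(chrom = "chr1",
                         start = seq(0, by = 1000, length.out = 6),
                         end = seq(0, by = 1000, length.out = 6) + 500)
  reference <- universe[c(2, 5), ]
  flags <- brute_overlap_flags(universe, reference)
  for (qi in list(c(2, 5), c(1, 2), c(1, 3), c(1, 2, 5))) {
    query <- universe[qi, ]
    got <- permutation_overlap_test(query, reference, universe,
                                    exact = TRUE)
    subsets <- combn(6, length(qi))
    obs <- sum(flags[qi])
    want <- mean(colSums(matrix(flags[subsets],
                                nrow = length(qi))) >= obs)
    expect_equal(got$observed, obs)
    expect_equal(got$p, want)
  }
  # degenerate fixed points
  all_q <- permutation_overlap_test(universe, reference, universe,
                                    n_perm = 200, seed = 4)
  expect_equal(all_q$p, 1)
  cover_all <- permutation_overlap_test(universe[1:2, ], universe,
                                        universe, n_perm = 200, seed = 4)
  expect_equal(cover_all$p, 1)
  expect_error(permutation_overlap_test(universe, reference,
                                        universe[1:3, ], n_perm = 200),
               "smaller than query")
  expect_error(permutation_overlap_test(
    data.frame(chrom = "chr9", start = 1, end = 10), reference,
    universe, n_perm = 200), "outside the universe")
})

test_that("permutation p-values are calibrated under a uniform null", {
  # universe of 2000 regions, ~30% overlapping the reference; query is
  # itself a uniform draw, so rejection at alpha = 0.05 must sit near
  # the nominal rate
  n_u <- 2000
  universe <- data.frame(chrom = "chr1",
                         start = seq(0, by = 1000, length.out = n_u))
  universe$end <- universe$start + 500
  reference <- universe[seq(1, n_u, by = 3), ]
  set.seed(2024)
  rej <- 0
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    qi <- sample.int(n_u, 200)
    res <- permutation_overlap_test(universe[qi, ], reference, universe,
                                    n_perm = 200, seed = r)
    if (res$p <= 0.05) rej <- rej + 1
  }
  expect_gte(rej / n_rep, 0.03)
  expect_lte(rej / n_rep, 0.07)
})

test_that("superenhancer tangent cutoff isolates dominant peaks", {
  # one dominant peak among 99 unit peaks: exactly one superenhancer
  peaks <- data.frame(chrom = "chr1",
                      start = seq(0, by = 50000, length.out = 100))
  peaks$end <- peaks$start + 1000
  peaks$score <- c(rep(1, 99), 100)
  ses <- call_superenhancers(peaks)
  expect_equal(length(ses), 100)   # 50 kb spacing beats 12.5 kb stitch
  expect_equal(sum(S4Vectors::mcols(ses)$is_superenhancer), 1)
  top <- ses[S4Vectors::mcols(ses)$is_superenhancer]
  expect_equal(S4Vectors::mcols(top)$signal, 100)
  # all-equal signals: zero superenhancers
  peaks$score <- rep(5, 100)
  expect_equal(sum(S4Vectors::mcols(
    call_superenhancers(peaks))$is_superenhancer), 0)
  # ranks are unique
  expect_equal(sort(S4Vectors::mcols(ses)$rank), 1:100)
})

test_that("stitching merges within distance and is idempotent", {
  peaks <- data.frame(chrom = "chr1",
                      start = c(0, 5000, 40000), end = c(1000, 6000, 41000),
                      score = c(2, 3, 4))
  ses <- call_superenhancers(peaks, stitch_distance = 12500)
  expect_equal(length(ses), 2)     # first two merge (4 kb gap), third apart
  expect_equal(sort(S4Vectors::mcols(ses)$signal), c(4, 5))
  # stitching an already-stitched set changes nothing
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(ses)),
                   start = GenomicRanges::start(ses) - 1,
                   end = GenomicRanges::end(ses),
                   score = S4Vectors::mcols(ses)$signal)
  ses2 <- call_superenhancers(df, stitch_distance = 12500)
  expect_equal(GenomicRanges::ranges(ses2), GenomicRanges::ranges(ses))
  expect_equal(S4Vectors::mcols(ses2)$signal, S4Vectors::mcols(ses)$signal)

  # DMR-per-SE distribution: disjoint DMRs give all-zero counts
  dmrs <- data.frame(chrom = "chr2", start = 0, end = 100)
  dist <- count_dmrs_per_superenhancer(ses, dmrs)
  expect_true(all(dist$counts == 0))
})

test_that("uniform draws from a background show no state enrichment", {
  # regions drawn uniformly from the background have fold enrichment
  # near 1 in every well-populated state
  set.seed(31)
  cfg <- sim_cfg_planted(seed = 73, n_regions = 10,
                         groups = c(CD34 = 2, IDHmut = 2, otherAML = 2))
  sim <- simulate_methylomes(cfg)
  ann <- simulate_annotations(sim$truth, cfg)
  n_bg <- 2000
  start <- sample.int(4.9e6, n_bg)
  background <- data.frame(chrom = sample(c("chr1", "chr2"), n_bg,
                                          replace = TRUE),
                           start = start, end = start + 500)
  draw <- background[sample.int(n_bg, 1000), ]
  enr <- state_enrichment(draw, background, ann$states)
  common <- names(enr)[!is.na(enr)]
  frac_bg <- state_overlap_distribution(background, ann$states)$fractions
  common <- common[frac_bg[common] > 0.03]
  expect_true(all(enr[common] > 0.8 & enr[common] < 1.25))
})
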