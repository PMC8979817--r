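# shared end-to-end fixtures: a small synthetic bundle and its run config
make_bundle <- function(dir, seed = 101) {
  cfg <- sim_config(seed = seed,
    n_chroms = 1, chrom_length = 2e6,
    groups = c(CD34 = 3, IDHmut = 3, otherAML = 4),
    reference_group = "CD34",
    planted_dmrs = list(list(target_groups = "IDHmut", n_regions = 12,
                             cpg_range = c(20, 40), delta = 0.4,
                             placement = "enhancer_state")),
    planted_shared = list(list(n_regions = 6, cpg_range = c(20, 40),
                               delta = 0.4, placement = "random")),
    hmc_regions = 5, n_genes = 80, n_background_loops = 20)
  simulate_cohort(cfg, dir)
}

bundle_config <- function(dir, out, with_oxbs = TRUE, ...) {
  ox <- NULL
  if (with_oxbs) {
    sheet <- read_sample_sheet(file.path(dir, "samples.tsv"))
    sheet <- sheet[sheet$group != "CD34", ][1:4, ]
    oxs <- data.frame(
      sample_id = sheet$sample_id,
      wgbs_path = file.path("bedgraph",
                            paste0(sheet$sample_id,
                                   ".wgbs_paired.bedgraph")),
      oxwgbs_path = file.path("bedgraph",
                              paste0(sheet$sample_id, ".oxwgbs.bedgraph")),
      group = sheet$group)
    ox <- file.path(dir, "oxbs.tsv")
    write.table(oxs, ox, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  run_config(
    sample_sheet = file.path(dir, "samples.tsv"),
    target_group = "IDHmut", reference_group = "CD34",
    comparison_groups = "otherAML",
    states = file.path(dir, "states.bed"),
    cgis = file.path(dir, "cgis.bed"),
    promoters = file.path(dir, "promoters.bed"),
    genes = file.path(dir, "genes.bed"),
    k27ac = file.path(dir, "k27ac.bed"),
    k4me1 = file.path(dir, "k4me1.bed"),
    k27me3 = file.path(dir, "k27me3.bed"),
    loops = file.path(dir, "loops.bedpe"),
    expression = file.path(dir, "expression.tsv"),
    oxbs_sheet = ox,
    seed = 99, out_dir = out, n_perm = 200, ...)
}

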