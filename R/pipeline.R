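#' Build a validated run configuration
#'
#' Collects everything one end-to-end run needs: the sample sheet (with
#' per-sample bedGraph paths), the group roles, optional annotation
#' inputs, thresholds, a seed and the output directory. Stages whose
#' inputs are `NULL` are skipped by [run_all()] and recorded in the
#' manifest. All referenced files must exist at validation time.
#'
#' @param sample_sheet path to a TSV with columns `sample_id`, `assay`,
#'   `group`, `path` (bedGraph per sample, relative to the sheet's
#'   directory or absolute).
#' @param target_group,reference_group,comparison_groups,excluded_groups
#'   group labels: stage 1 tests target vs reference, stage 2 target vs
#'   the pooled comparison groups minus exclusions.
#' @param states,cgis,promoters,genes,k27ac,k4me1,k27me3 optional BED
#'   paths.
#' @param loops optional BEDPE path.
#' @param expression optional expression TSV path.
#' @param oxbs_sheet optional TSV (`sample_id`, `wgbs_path`,
#'   `oxwgbs_path`, `group`) for the 5hmC stage.
#' @param th a [thresholds()] object.
#' @param seed integer seed for the permutation stage.
#' @param out_dir output directory.
#' @param n_perm permutations for the overlap test.
#' @return A list of class `RunConfig`.
#' @export
run_config <- function(sample_sheet, target_group, reference_group,
                       comparison_groups, excluded_groups = character(0),
                       states = NULL, cgis = NULL, promoters = NULL,
                       genes = NULL, k27ac = NULL, k4me1 = NULL,
                       k27me3 = NULL, loops = NULL, expression = NULL,
                       oxbs_sheet = NULL, th = thresholds(), seed = 1,
                       out_dir = "methylphase_out", n_perm = 1000) {
  cfg <- as.list(environment())
  paths <- c(sample_sheet, states, cgis, promoters, genes, k27ac, k4me1,
             k27me3, loops, expression, oxbs_sheet)
  miss <- paths[!file.exists(paths)]
  if (length(miss))
    stop_validation("missing input file(s): ", paste(miss, collapse = ", "))
  if (target_group %in% c(reference_group, comparison_groups))
    stop_validation("target group must be disjoint from reference and comparison")
  structure(cfg, class = "RunConfig")
}

read_cohort <- function(cfg) {
  sheet <- read_sample_sheet(cfg$sample_sheet)
  if (!"path" %in% names(sheet))
    stop_validation("sample sheet needs a `path` column")
  base <- dirname(cfg$sample_sheet)
  tracks <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$path[i]
    if (!file.exists(p)) p <- file.path(base, sheet$path[i])
    read_cpg_bedgraph(p, sheet$sample_id[i], sheet$assay[i],
                      sheet$group[i])
  })
  merge_samples(tracks, sheet)
}

#' Run the full analysis end-to-end
#'
#' Stage order: DMC calling (target vs reference), DMR segmentation,
#' group-specificity testing (target vs pooled comparison), 5hmC (when
#' paired oxBS tracks are configured), chromatin-state annotation and
#' enrichment, permutation overlap test, superenhancer calling,
#' enhancer classification, loop-anchor linking and expression
#' percentiles. Stages with absent inputs are skipped and recorded.
#' A failing stage halts the run with the stage named; outputs written
#' so far are retained. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param cfg a [run_config()].
#' @return Invisibly, a list of stage results; all tables and the JSON
#'   manifest are written under `cfg$out_dir`.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "RunConfig"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(thresholds = unclass(cfg$th), seed = cfg$seed,
                   groups = list(target = cfg$target_group,
                                 reference = cfg$reference_group,
                                 comparison = cfg$comparison_groups,
                                 excluded = cfg$excluded_groups),
                   stages = list())
  res <- list()
  stage <- function(name, enabled, fun) {
    if (!enabled) {
      manifest$stages[[name]] <<- "skipped (inputs absent)"
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) {
      write_manifest(manifest, file.path(cfg$out_dir, "manifest.json"))
      stop("stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- "ok"
    out
  }

  res$matrix <- stage("load", TRUE, function() read_cohort(cfg))
  mat <- res$matrix

  res$dmcs <- stage("dmc", TRUE, function()
    dmc_test(mat, cfg$reference_group, cfg$target_group, cfg$th))
  data.table::fwrite(res$dmcs, file.path(cfg$out_dir, "dmcs.tsv"),
                     sep = "\t")

  res$dmrs <- stage("dmr", TRUE, function()
    segment_dmrs(res$dmcs, cfg$th))
  write_results_tables(res$dmrs, cfg$out_dir, "dmrs")

  res$specific <- stage("specific", TRUE, function()
    call_group_specific(res$dmrs, mat, cfg$target_group,
                        cfg$comparison_groups, cfg$excluded_groups,
                        cfg$th))
  write_results_tables(res$specific, cfg$out_dir, "dmrs_specific")

  res$hmc <- stage("hmc", !is.null(cfg$oxbs_sheet), function() {
    ox <- data.table::fread(cfg$oxbs_sheet, colClasses = "character")
    base <- dirname(cfg$oxbs_sheet)
    fix <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    w <- merge_samples(lapply(seq_len(nrow(ox)), function(i)
      read_cpg_bedgraph(fix(ox$wgbs_path[i]), ox$sample_id[i], "WGBS",
                        ox$group[i])),
      data.frame(sample_id = ox$sample_id, assay = "WGBS",
                 group = ox$group))
    o <- merge_samples(lapply(seq_len(nrow(ox)), function(i)
      read_cpg_bedgraph(fix(ox$oxwgbs_path[i]), ox$sample_id[i], "oxWGBS",
                        ox$group[i])),
      data.frame(sample_id = ox$sample_id, assay = "oxWGBS",
                 group = ox$group))
    track <- compute_hmc(w, o, min_cov = cfg$th$min_cov)
    if (nrow(res$specific)) {
      rh <- region_hmc(track, res$specific)
      data.table::fwrite(data.table::as.data.table(rh),
                         file.path(cfg$out_dir, "hmc_regions.tsv"),
                         sep = "\t")
    }
    track
  })

  have_states <- !is.null(cfg$states)
  res$annotation <- stage("annotate", have_states, function() {
    states <- read_bed(cfg$states)
    out <- list(
      state_fractions =
        state_overlap_distribution(res$specific, states)$fractions)
    if (!is.null(cfg$cgis)) {
      cgis <- read_bed(cfg$cgis)
      out$cgi_overlap <- as.numeric(overlap_fraction(res$specific, cgis))
      out$enrichment_vs_dmrs <-
        state_enrichment(res$specific, res$dmrs, states)
    }
    out$cpg_density <- cpg_density(res$specific, mat)$mean
    data.table::fwrite(data.table::data.table(
      state = names(out$state_fractions),
      fraction = out$state_fractions),
      file.path(cfg$out_dir, "state_fractions.tsv"), sep = "\t")
    out
  })

  res$permtest <- stage("permtest",
                        !is.null(cfg$cgis) && nrow(res$specific) > 0 &&
                          nrow(res$dmrs) > nrow(res$specific),
                        function() {
    permutation_overlap_test(res$specific, read_bed(cfg$cgis), res$dmrs,
                             n_perm = cfg$n_perm,
                             seed = child_seed(cfg$seed, "permtest"))[
                               c("observed", "p", "n_perm")]
  })

  res$enhancers <- stage("enhancers",
                         !is.null(cfg$k27ac) && !is.null(cfg$k4me1) &&
                           !is.null(cfg$k27me3), function() {
    calls <- classify_enhancers(res$specific, read_bed(cfg$k27ac),
                                read_bed(cfg$k4me1), read_bed(cfg$k27me3))
    data.table::fwrite(data.table::as.data.table(calls),
                       file.path(cfg$out_dir, "enhancer_calls.tsv"),
                       sep = "\t")
    calls
  })

  res$superenhancers <- stage("superenhancers", !is.null(cfg$k27ac),
                              function() {
    ses <- call_superenhancers(read_bed(cfg$k27ac))
    dist <- count_dmrs_per_superenhancer(ses, res$specific)
    out <- bed0_from_gr(ses)
    out$signal <- S4Vectors::mcols(ses)$signal
    out$is_superenhancer <- S4Vectors::mcols(ses)$is_superenhancer
    data.table::fwrite(out, file.path(cfg$out_dir, "superenhancers.tsv"),
                       sep = "\t")
    list(ses = ses, dmr_distribution = dist)
  })

  res$loops <- stage("loops",
                     !is.null(cfg$loops) && !is.null(cfg$promoters) &&
                       !is.null(res$enhancers), function() {
    loops <- read_bedpe(cfg$loops)
    promoters <- read_bed(cfg$promoters)
    edmrs <- res$specific[res$enhancers$class != "none", , drop = FALSE]
    anchored <- intersect_dmr_anchors(res$specific, loops)
    links <- map_edmr_targets(edmrs, loops, promoters)
    data.table::fwrite(data.table::as.data.table(links),
                       file.path(cfg$out_dir, "edmr_links.tsv"), sep = "\t")
    out <- list(anchored_fraction = anchored$fraction, links = links)
    if (!is.null(cfg$expression) && nrow(links)) {
      expr <- read_expression(cfg$expression)
      tgt_samples <- intersect(colnames(expr$tpm),
                               group_samples(mat, cfg$target_group))
      if (!length(tgt_samples)) tgt_samples <- colnames(expr$tpm)
      pct <- expression_percentiles(expr, tgt_samples, unique(links$gene))
      out$top_quartile_fraction <- pct$top_quartile_fraction
      out$n_target_genes <- length(pct$percentiles)
    }
    out
  })

  summary <- list(
    n_cpgs_tested = nrow(res$dmcs),
    n_dmcs = sum(res$dmcs$is_dmc),
    n_dmrs = nrow(res$dmrs),
    n_specific = nrow(res$specific),
    frac_hyper = if (nrow(res$specific))
      mean(res$specific$direction == "hyper") else NA)
  if (!is.null(res$permtest)) summary$permtest_p <- res$permtest$p
  if (!is.null(res$loops)) {
    summary$anchored_fraction <- res$loops$anchored_fraction
    summary$top_quartile_fraction <- res$loops$top_quartile_fraction
  }
  manifest$summary <- summary
  write_manifest(manifest, file.path(cfg$out_dir, "manifest.json"))
  invisible(res)
}
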