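# tolerate empty files: fread() refuses zero-byte input
fread_or_empty <- function(path) {
  if (file.size(path) == 0) return(data.table::data.table())
  tryCatch(
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = "character"),
    error = function(e) stop_parse("cannot read ", path, ": ",
                                   conditionMessage(e)))
}

#' Read a biscuit-style CpG bedGraph into a single-sample count matrix
#'
#' Expects five tab-separated columns: chrom, start, end, beta, coverage.
#' Both CpG dialects are accepted (`end == start + 1` or `start + 2`) and
#' normalized to the cytosine start. Methylated counts are reconstructed
#' as `round(beta * coverage)`, rounding half away from zero.
#'
#' @param path path to the bedGraph file.
#' @param sample_id sample identifier to attach.
#' @param assay `"WGBS"` or `"oxWGBS"`.
#' @param group optional group label recorded in the metadata.
#' @return A single-sample [cpg_count_matrix()].
#' @export
read_cpg_bedgraph <- function(path, sample_id, assay = "WGBS", group = NA_character_) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  dt <- fread_or_empty(path)
  if (nrow(dt) == 0) {
    return(cpg_count_matrix(character(0), integer(0),
                            matrix(0L, 0, 1), matrix(0L, 0, 1),
                            data.frame(sample_id = sample_id, assay = assay,
                                       group = group)))
  }
  if (ncol(dt) != 5)
    stop_parse(path, ": expected 5 tab-separated columns, found ", ncol(dt))
  suppressWarnings({
    start <- as.integer(dt[[2]]); end <- as.integer(dt[[3]])
    beta <- as.numeric(dt[[4]]); cov <- as.numeric(dt[[5]])
  })
  bad <- which(is.na(start) | is.na(end) | is.na(beta) | is.na(cov) |
                 cov != floor(cov))
  if (length(bad))
    stop_parse(path, ": malformed row at line ", bad[1])
  if (any(beta < 0 | beta > 1))
    stop_validation(path, ": beta outside [0,1] at line ",
                    which(beta < 0 | beta > 1)[1])
  if (any(cov < 0))
    stop_validation(path, ": negative coverage at line ", which(cov < 0)[1])
  if (!all(end == start + 1L | end == start + 2L))
    stop_validation(path, ": CpG rows must have end = start+1 or start+2 (line ",
                    which(!(end == start + 1L | end == start + 2L))[1], ")")
  if (anyDuplicated(paste(dt[[1]], start)))
    stop_validation(path, ": duplicate CpG position at line ",
                    which(duplicated(paste(dt[[1]], start)))[1])
  ord <- order(dt[[1]], start)
  meth <- as.integer(round_half_away(beta * cov))
  cpg_count_matrix(dt[[1]][ord], start[ord],
                   matrix(meth[ord], ncol = 1),
                   matrix(as.integer(cov)[ord], ncol = 1),
                   data.frame(sample_id = sample_id, assay = assay,
                              group = group, stringsAsFactors = FALSE))
}

#' Write one sample of a count matrix as a CpG bedGraph
#'
#' Emits the 2-bp dialect (`end = start + 2`) with beta to 6 decimals;
#' zero-coverage CpGs are written with beta 0.
#'
#' @param x a `CpGCountMatrix`.
#' @param sample_id which sample column to write.
#' @param path output path.
#' @export
write_cpg_bedgraph <- function(x, sample_id, path) {
  j <- match(sample_id, x$samples)
  if (is.na(j)) stop_validation("unknown sample id: ", sample_id)
  tot <- x$total[, j]
  beta <- ifelse(tot > 0, x$meth[, j] / tot, 0)
  dt <- data.table::data.table(x$chrom, x$pos, x$pos + 2L,
                               sprintf("%.6f", beta), tot)
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file into a labelled GRanges
#'
#' Accepts BED3/BED4/BED5+ (name in column 4, score in column 5).
#' Coordinates are 0-based half-open on disk.
#'
#' @param path path to a BED file.
#' @return A `GRanges` with metadata columns `label` and `score` (when
#'   present), sorted by (chrom, start).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  dt <- fread_or_empty(path)
  if (nrow(dt) == 0)
    return(GenomicRanges::GRanges())
  suppressWarnings({
    start <- as.numeric(dt[[2]]); end <- as.numeric(dt[[3]])
  })
  if (anyNA(start) || anyNA(end) || any(start != floor(start)) ||
      any(end != floor(end)))
    stop_parse(path, ": non-integer coordinates")
  if (any(start >= end))
    stop_validation(path, ": start >= end at line ", which(start >= end)[1])
  gr <- gr_from_bed0(dt[[1]], as.integer(start), as.integer(end))
  if (ncol(dt) >= 4) S4Vectors::mcols(gr)$label <- dt[[4]]
  if (ncol(dt) >= 5) {
    suppressWarnings(sc <- as.numeric(dt[[5]]))
    S4Vectors::mcols(gr)$score <- sc
  }
  GenomicRanges::sort(gr)
}

#' Write a GRanges as BED
#'
#' Writes BED3, BED4 (with `label`) or BED5 (with `label` and `score`)
#' depending on which metadata columns are present.
#'
#' @param gr a `GRanges`.
#' @param path output path.
#' @export
write_bed <- function(gr, path) {
  dt <- bed0_from_gr(gr)
  mc <- S4Vectors::mcols(gr)
  if ("label" %in% names(mc)) dt$label <- as.character(mc$label)
  if ("score" %in% names(mc)) {
    if (!"label" %in% names(dt)) dt$label <- "."
    dt$score <- mc$score
  }
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Chromatin loop set
#'
#' Paired genomic anchors with BEDPE semantics. Anchors are stored as two
#' parallel `GRanges`; within each loop the anchors are in canonical
#' order (anchor1 before anchor2 by chrom then start).
#'
#' @param anchor1,anchor2 parallel `GRanges` of equal length.
#' @param provenance free-text origin tag.
#' @return An object of class `LoopSet`.
#' @export
loop_set <- function(anchor1, anchor2, provenance = "") {
  if (length(anchor1) != length(anchor2))
    stop_validation("anchor1 and anchor2 must be parallel")
  if (length(anchor1)) {
    c1 <- as.character(GenomicRanges::seqnames(anchor1))
    c2 <- as.character(GenomicRanges::seqnames(anchor2))
    s1 <- GenomicRanges::start(anchor1); s2 <- GenomicRanges::start(anchor2)
    swap <- c2 < c1 | (c1 == c2 & s2 < s1)
    if (any(swap)) {
      tmp <- anchor1[swap]
      anchor1[swap] <- anchor2[swap]
      anchor2[swap] <- tmp
    }
  }
  structure(list(anchor1 = anchor1, anchor2 = anchor2,
                 provenance = provenance),
            class = "LoopSet")
}

#' @export
print.LoopSet <- function(x, ...) {
  cat(sprintf("LoopSet: %d loops\n", length(x$anchor1)))
  invisible(x)
}

#' @export
length.LoopSet <- function(x) length(x$anchor1)

#' Read loop calls from a BEDPE file
#'
#' First six columns: chrom1, start1, end1, chrom2, start2, end2.
#' Anchors are normalized to canonical order.
#'
#' @param path path to a BEDPE file.
#' @return A [loop_set()].
#' @export
read_bedpe <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  dt <- fread_or_empty(path)
  if (nrow(dt) == 0)
    return(loop_set(GenomicRanges::GRanges(), GenomicRanges::GRanges(),
                    provenance = path))
  if (ncol(dt) < 6)
    stop_parse(path, ": BEDPE needs at least 6 columns")
  co <- lapply(dt[, c(2, 3, 5, 6)], function(v) suppressWarnings(as.numeric(v)))
  if (anyNA(unlist(co)) || any(vapply(co, function(v) any(v != floor(v)), TRUE)))
    stop_parse(path, ": non-integer coordinates")
  if (any(co[[1]] >= co[[2]]) || any(co[[3]] >= co[[4]]))
    stop_validation(path, ": anchor with start >= end")
  loop_set(gr_from_bed0(dt[[1]], as.integer(co[[1]]), as.integer(co[[2]])),
           gr_from_bed0(dt[[4]], as.integer(co[[3]]), as.integer(co[[4]])),
           provenance = path)
}

#' Write a loop set as BEDPE
#' @param loops a `LoopSet`.
#' @param path output path.
#' @export
write_bedpe <- function(loops, path) {
  a1 <- bed0_from_gr(loops$anchor1); a2 <- bed0_from_gr(loops$anchor2)
  data.table::fwrite(cbind(a1, a2), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated, header row, first column `gene_id`, remaining columns
#' one per sample holding TPM values.
#'
#' @param path path to the TSV.
#' @param gene_locations optional `GRanges` named by (or labelled with)
#'   gene id, used later for promoter derivation.
#' @return A list of class `ExpressionTable` with elements `genes`,
#'   `tpm` (genes x samples matrix) and `gene_locations`.
#' @export
read_expression <- function(path, gene_locations = NULL) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (ncol(dt) < 2) stop_parse(path, ": expected gene_id plus sample columns")
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes)) stop_validation(path, ": duplicate gene ids")
  tpm <- as.matrix(dt[, -1])
  mode(tpm) <- "numeric"
  if (anyNA(tpm) || any(tpm < 0))
    stop_validation(path, ": TPM values must be non-negative")
  rownames(tpm) <- genes
  expression_table(genes, tpm, gene_locations)
}

#' Construct an expression table
#' @param genes character vector of unique gene ids.
#' @param tpm numeric matrix (genes x samples), non-negative.
#' @param gene_locations optional `GRanges` with a `label` column of gene ids.
#' @return An `ExpressionTable`.
#' @export
expression_table <- function(genes, tpm, gene_locations = NULL) {
  tpm <- as.matrix(tpm)
  if (anyDuplicated(genes)) stop_validation("duplicate gene ids")
  if (any(tpm < 0)) stop_validation("TPM values must be non-negative")
  if (nrow(tpm) != length(genes)) stop_validation("tpm rows must match genes")
  rownames(tpm) <- genes
  structure(list(genes = as.character(genes), tpm = tpm,
                 gene_locations = gene_locations),
            class = "ExpressionTable")
}

#' Write an expression table as TSV
#' @param expr an `ExpressionTable`.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  dt <- data.table::data.table(gene_id = expr$genes)
  dt <- cbind(dt, data.table::as.data.table(expr$tpm))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' Tab-separated with header columns `sample_id`, `assay`, `group`.
#'
#' @param path path to the TSV.
#' @return A data.frame.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_parse("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  req <- c("sample_id", "assay", "group")
  if (!all(req %in% names(dt)))
    stop_parse(path, ": sample sheet needs columns ",
               paste(req, collapse = ", "))
  as.data.frame(dt, stringsAsFactors = FALSE)
}

#' Write DMR records as a BED6+ file plus a TSV summary
#'
#' The BED carries chrom, start, end, a generated name, the methylation
#' difference as score, and `.` strand; every remaining statistic follows
#' as extra columns after column 6.
#'
#' @param dmrs data.frame of DMR records (as returned by
#'   [segment_dmrs()] or [call_group_specific()]).
#' @param dir output directory (created if needed).
#' @param prefix file name stem.
#' @return Invisibly, the paths written.
#' @export
write_results_tables <- function(dmrs, dir, prefix = "dmrs") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed_path <- file.path(dir, paste0(prefix, ".bed"))
  tsv_path <- file.path(dir, paste0(prefix, ".tsv"))
  dt <- data.table::as.data.table(dmrs)
  if (nrow(dt)) {
    extra <- setdiff(names(dt), c("chrom", "start", "end"))
    bed <- data.table::data.table(
      chrom = dt$chrom, start = dt$start, end = dt$end,
      name = sprintf("%s_%d", prefix, seq_len(nrow(dt))),
      score = dt$diff, strand = ".")
    bed <- cbind(bed, dt[, extra, with = FALSE])
    data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  } else {
    file.create(bed_path)
  }
  data.table::fwrite(dt, tsv_path, sep = "\t")
  invisible(c(bed = bed_path, tsv = tsv_path))
}

#' Write a JSON run manifest
#'
#' Records parameters, seeds and thresholds of a run so outputs are
#' reproducible from the manifest alone.
#'
#' @param manifest named list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
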