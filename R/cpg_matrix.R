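#' CpG count matrix
#'
#' The pipeline's primary container: per-CpG methylated and total read
#' counts across samples, plus per-sample metadata (assay, group). CpG
#' positions are 0-based forward-strand cytosine coordinates; a CpG
#' occupies `[pos, pos + 2)` for overlap purposes.
#'
#' @param chrom character vector, one entry per CpG.
#' @param pos integer vector, 0-based cytosine positions, strictly
#'   increasing within each chromosome.
#' @param meth,total integer matrices (CpGs x samples) of methylated and
#'   total read counts; `0 <= meth <= total` cellwise.
#' @param metadata data.frame with columns `sample_id`, `assay`
#'   (`"WGBS"` or `"oxWGBS"`), `group`; one row per sample, in column
#'   order of `meth`/`total`.
#' @return An object of class `CpGCountMatrix`.
#' @export
cpg_count_matrix <- function(chrom, pos, meth, total, metadata) {
  meth <- as.matrix(meth)
  total <- as.matrix(total)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  obj <- structure(
    list(chrom = chrom, pos = pos, meth = meth, total = total,
         samples = as.character(metadata$sample_id), metadata = metadata),
    class = "CpGCountMatrix")
  colnames(obj$meth) <- obj$samples
  colnames(obj$total) <- obj$samples
  validate_cpg_matrix(obj)
  obj
}

validate_cpg_matrix <- function(x) {
  if (!is.matrix(x$meth) || !is.matrix(x$total) ||
      !all(dim(x$meth) == dim(x$total)))
    stop_validation("meth and total must be matrices of identical dimension")
  if (length(x$chrom) != nrow(x$meth) || length(x$pos) != nrow(x$meth))
    stop_validation("positions and count rows disagree in length")
  if (anyNA(x$meth) || anyNA(x$total))
    stop_validation("counts must not contain NA")
  if (any(x$meth < 0) || any(x$total < 0) || any(x$meth > x$total))
    stop_validation("counts must satisfy 0 <= n_meth <= n_total")
  req <- c("sample_id", "assay", "group")
  if (!all(req %in% names(x$metadata)))
    stop_validation("metadata must have columns sample_id, assay, group")
  if (anyDuplicated(x$metadata$sample_id))
    stop_validation("duplicate sample ids in metadata")
  if (!identical(as.character(x$metadata$sample_id), x$samples) ||
      ncol(x$meth) != length(x$samples))
    stop_validation("metadata rows must match count columns one-to-one")
  ord <- order(x$chrom, x$pos)
  if (!identical(ord, seq_along(ord)))
    stop_validation("positions must be sorted by (chrom, pos)")
  if (any(duplicated(paste(x$chrom, x$pos))))
    stop_validation("duplicate (chrom, pos) entries")
  d <- diff(x$pos)
  same <- x$chrom[-1] == x$chrom[-length(x$chrom)]
  if (length(d) && any(same & d <= 0))
    stop_validation("positions must be strictly increasing within chromosomes")
  invisible(x)
}

#' @export
print.CpGCountMatrix <- function(x, ...) {
  cat(sprintf("CpGCountMatrix: %d CpGs x %d samples (%s)\n",
              nrow(x$meth), ncol(x$meth),
              paste(unique(x$metadata$group), collapse = ", ")))
  invisible(x)
}

#' @export
dim.CpGCountMatrix <- function(x) dim(x$meth)

#' Subset samples of a CpG count matrix
#'
#' @param x a `CpGCountMatrix`.
#' @param sample_ids character vector of sample ids to keep, in order.
#' @return A `CpGCountMatrix` restricted to the requested samples.
#' @export
subset_samples <- function(x, sample_ids) {
  miss <- setdiff(sample_ids, x$samples)
  if (length(miss))
    stop_validation("unknown sample id(s): ", paste(miss, collapse = ", "))
  idx <- match(sample_ids, x$samples)
  cpg_count_matrix(x$chrom, x$pos, x$meth[, idx, drop = FALSE],
                   x$total[, idx, drop = FALSE],
                   x$metadata[idx, , drop = FALSE])
}

#' Sample ids belonging to a metadata group
#'
#' @param x a `CpGCountMatrix`.
#' @param group group label (or vector of labels) to look up.
#' @return Character vector of sample ids.
#' @export
group_samples <- function(x, group) {
  x$samples[x$metadata$group %in% group]
}

#' Merge single-sample count tracks into a cohort matrix
#'
#' Takes the union of CpG positions across tracks; cells absent from a
#' track are filled with `n_total = 0` (retained but treated as uncovered
#' by every statistical operation). Metadata is joined from the sample
#' sheet, which must cover every track.
#'
#' @param tracks list of single-sample `CpGCountMatrix` objects (as
#'   returned by [read_cpg_bedgraph()]).
#' @param sample_sheet data.frame with columns `sample_id`, `assay`,
#'   `group`.
#' @return A multi-sample `CpGCountMatrix`.
#' @export
merge_samples <- function(tracks, sample_sheet) {
  sample_sheet <- as.data.frame(sample_sheet, stringsAsFactors = FALSE)
  ids <- vapply(tracks, function(t) t$samples, character(1))
  if (anyDuplicated(ids))
    stop_validation("duplicate sample ids among tracks")
  miss <- setdiff(ids, sample_sheet$sample_id)
  if (length(miss))
    stop_validation("sample id(s) absent from sample sheet: ",
                    paste(miss, collapse = ", "))
  for (t in tracks) {
    sheet_assay <- sample_sheet$assay[sample_sheet$sample_id == t$samples]
    if (!is.na(t$metadata$assay[1]) && nzchar(t$metadata$assay[1]) &&
        t$metadata$assay[1] != sheet_assay)
      stop_validation("conflicting assay label for sample ", t$samples)
  }
  key <- unique(data.table::rbindlist(lapply(tracks, function(t)
    data.table::data.table(chrom = t$chrom, pos = t$pos))))
  data.table::setorder(key, chrom, pos)
  n <- nrow(key)
  meth <- matrix(0L, n, length(tracks))
  total <- matrix(0L, n, length(tracks))
  ref <- paste(key$chrom, key$pos)
  for (j in seq_along(tracks)) {
    t <- tracks[[j]]
    i <- match(paste(t$chrom, t$pos), ref)
    meth[i, j] <- t$meth[, 1]
    total[i, j] <- t$total[, 1]
  }
  md <- sample_sheet[match(ids, sample_sheet$sample_id),
                     c("sample_id", "assay", "group"), drop = FALSE]
  cpg_count_matrix(key$chrom, key$pos, meth, total, md)
}
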