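#' @importFrom stats median p.adjust pnorm rbeta rbinom rlnorm rnbinom
#'   rnorm runif t.test setNames rexp quantile var complete.cases
#' @importFrom utils head tail
NULL

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Convert an interval table to GRanges
#'
#' Internal convenience: the package stores interval sets as `GRanges`
#' (0-based half-open on disk, converted to the 1-based closed convention
#' GRanges uses in memory).
#'
#' @param chrom,start,end vectors describing 0-based half-open intervals.
#' @return A `GRanges` object.
#' @keywords internal
gr_from_bed0 <- function(chrom, start, end) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1L, end = end))
}

# back to 0-based half-open columns
bed0_from_gr <- function(gr) {
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr)
  )
}

# CpG dinucleotide footprint [pos, pos+2) as GRanges for overlap arithmetic
cpg_gr <- function(chrom, pos) {
  gr_from_bed0(chrom, pos, pos + 2L)
}

# overlap counting across arbitrary user sets: sets sharing no
# chromosome are a legitimate zero-overlap case, not a warning
count_hits <- function(a, b, minoverlap = 1L) {
  suppressWarnings(GenomicRanges::countOverlaps(a, b,
                                                minoverlap = minoverlap))
}

find_hits <- function(a, b) {
  suppressWarnings(GenomicRanges::findOverlaps(a, b))
}

stop_validation <- function(...) {
  stop(structure(class = c("methylphase_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_parse <- function(...) {
  stop(structure(class = c("methylphase_parse_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# derive a reproducible 32-bit child seed from a parent seed and a stage tag
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
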