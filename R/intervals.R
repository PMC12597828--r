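#' Build a validated GRanges from BED-style coordinates
#'
#' All genomic intervals in taclr are `GRanges` (1-based, closed).  This
#' constructor takes BED-style 0-based half-open coordinates, validates them,
#' and converts.  Use it at every file or simulation boundary so that
#' coordinate conventions are fixed in exactly one place.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start,end numeric vectors, 0-based half-open (`end > start >= 0`).
#' @param strand optional strand vector in `+`, `-`, `*`.
#' @return a `GRanges` of the same length as the inputs.
#' @export
as_granges_bed <- function(chrom, start, end, strand = NULL) {
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric interval coordinates")
  if (any(!nzchar(chrom)) || any(is.na(chrom)))
    stop("empty chromosome name")
  if (any(start < 0))
    stop("negative start coordinate")
  bad <- which(end <= start)
  if (length(bad))
    stop(sprintf("interval end <= start at record %d", bad[1]))
  if (is.null(strand)) strand <- "*"
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                         strand = strand)
}

#' Canonical chromosome set
#'
#' The human autosomes plus chrX and chrY.  Peak-level filters restrict to
#' this set by default; pass any other character vector to override.
#'
#' @return character vector of chromosome names.
#' @export
canonical_chromosomes <- function() {
  c(paste0("chr", 1:22), "chrX", "chrY")
}

# midpoint of each range, as 1-based positions
.centers <- function(gr) {
  floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
}

# genomic gap between consecutive sorted ranges on one chromosome:
# bp between end of one and start of the next (adjacent ranges -> 0)
.gaps_bp <- function(starts, ends) {
  if (length(starts) < 2) return(numeric(0))
  pmax(starts[-1] - ends[-length(ends)] - 1, 0)
}
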