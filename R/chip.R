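# Reference-peak scaling and peak-level utilities for ChIP-seq signal
# tracks.  Tracks are step-function GRanges with a `score` column (bedGraph
# semantics); uncovered bp count as zero signal.

# mean signal of a step track over each region (denominator = full width)
.track_region_means <- function(track, regions) {
  stopifnot(!is.null(track$score))
  out <- numeric(length(regions))
  hits <- GenomicRanges::findOverlaps(regions, track)
  if (length(hits)) {
    q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(GenomicRanges::ranges(regions)[q],
                              GenomicRanges::ranges(track)[s])
    acc <- tapply(IRanges::width(ov) * track$score[s],
                  factor(q, levels = seq_along(regions)), sum)
    acc[is.na(acc)] <- 0
    out <- as.numeric(acc) / GenomicRanges::width(regions)
  }
  out
}

# anchor points: summit when present, else interval midpoint
.anchor_points <- function(peaks) {
  ctr <- .centers(peaks)
  if (!is.null(peaks$summit)) {
    s <- peaks$summit
    ctr[!is.na(s)] <- s[!is.na(s)]
  }
  ctr
}

#' Filter peaks by signal value and resolve overlaps
#'
#' Drops peaks whose `signalValue` falls below `min_signal` (the cut is
#' inclusive: a peak exactly at the threshold is kept), then reduces every
#' chain of mutually overlapping peaks to the single peak with the highest
#' signal (ties broken by leftmost start).
#'
#' @param peaks `GRanges` with a `signalValue` column.
#' @param min_signal inclusive signal threshold (35 for CTCF and FLAG-MAU2).
#' @return filtered `GRanges`, sorted.
#' @export
filter_peaks <- function(peaks, min_signal = 35) {
  stopifnot(!is.null(peaks$signalValue))
  peaks <- peaks[peaks$signalValue >= min_signal]
  if (!length(peaks)) return(peaks)
  peaks <- GenomicRanges::sort(peaks, ignore.strand = TRUE)
  cluster <- GenomicRanges::findOverlaps(
    peaks, GenomicRanges::reduce(peaks, ignore.strand = TRUE),
    ignore.strand = TRUE)
  grp <- S4Vectors::subjectHits(cluster)
  best <- vapply(split(seq_along(peaks), grp), function(i) {
    i[order(-peaks$signalValue[i], GenomicRanges::start(peaks)[i])[1]]
  }, 0L)
  peaks[sort(best)]
}

#' Reference-peak scaling factor for a signal track
#'
#' Two modes, matching the two normalization schemes used for wild-type and
#' degron ChIP-seq respectively.  `center_resize`: reference peaks are
#' resized to `resize_width` (10 bp) around their summit (midpoint when no
#' summit), and the factor is the mean over peaks of the mean signal in that
#' window.  `flank_background`: peaks are resized to 5 kb around their
#' center and the factor is the average signal over the two outer 1 kb
#' flanks (2.5-1.5 kb away from the center on each side), i.e. local
#' background rather than peak height.
#'
#' @param track step `GRanges` with `score`.
#' @param reference_peaks `GRanges` of filtered reference peaks.
#' @param mode `"center_resize"` or `"flank_background"`.
#' @param resize_width center window width in bp (`center_resize` mode).
#' @return positive scalar scaling factor.
#' @export
scaling_factor <- function(track, reference_peaks,
                           mode = c("center_resize", "flank_background"),
                           resize_width = 10) {
  mode <- match.arg(mode)
  if (!length(reference_peaks)) stop("reference peak set is empty")
  chrom <- as.character(GenomicRanges::seqnames(reference_peaks))
  if (mode == "center_resize") {
    ctr <- .anchor_points(reference_peaks)
    win <- GenomicRanges::GRanges(chrom,
             IRanges::IRanges(start = pmax(ctr - floor(resize_width / 2), 1),
                              width = resize_width))
    factor <- mean(.track_region_means(track, win))
  } else {
    ctr <- .centers(reference_peaks)
    flank <- GenomicRanges::GRanges(
      rep(chrom, 2),
      IRanges::IRanges(pmax(c(ctr - 2500, ctr + 1501), 1),
                       c(ctr - 1501, ctr + 2500)))
    factor <- mean(.track_region_means(track, flank))
  }
  if (factor <= 0) stop("scaling factor is zero; reference peaks carry no signal")
  factor
}

#' Divide a signal track by a scaling factor
#'
#' @param track step `GRanges` with `score`.
#' @param factor positive scalar, typically from [scaling_factor()].
#' @return the track with `score` divided by `factor`.
#' @export
scale_track <- function(track, factor) {
  if (factor <= 0) stop("scaling factor must be positive")
  track$score <- track$score / factor
  track
}

#' Anchor-centered binned signal matrix (tornado rows + mean curve)
#'
#' Bins the track into `bin`-bp bins over `half_window` bp on each side of
#' each anchor point (summit when present, midpoint otherwise).  Anchors
#' whose window sticks out of the track extent are dropped with a warning.
#' Rows are ordered by decreasing row sum, the display convention for
#' tornado heatmaps.
#'
#' @param track step `GRanges` with `score`.
#' @param anchors `GRanges` of anchor peaks.
#' @param half_window bp on each side of the anchor point.
#' @param bin bin width in bp (`2 * half_window` must be a multiple).
#' @return list with `matrix` (anchors x bins, tornado-ordered),
#'   `mean_curve` (column means over all kept anchors), `bin_size`,
#'   `half_window` and `anchors` (kept, in tornado order).
#' @export
profile_matrix <- function(track, anchors, half_window = 2500, bin = 10) {
  if ((2 * half_window) %% bin != 0)
    stop("2 * half_window must be divisible by bin")
  n_bins <- 2 * half_window / bin
  ctr <- .anchor_points(anchors)
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  tchrom <- as.character(GenomicRanges::seqnames(track))
  lo <- tapply(GenomicRanges::start(track), tchrom, min)
  hi <- tapply(GenomicRanges::end(track), tchrom, max)
  keep <- chrom %in% names(lo) &
    ctr - half_window >= lo[chrom] & ctr + half_window - 1 <= hi[chrom]
  if (!any(keep)) stop("all anchors fall outside the track extent")
  if (any(!keep))
    warning(sprintf("%d anchors dropped at the track extent edge", sum(!keep)))
  anchors <- anchors[keep]; ctr <- ctr[keep]; chrom <- chrom[keep]
  bins <- GenomicRanges::GRanges(
    rep(chrom, each = n_bins),
    IRanges::IRanges(
      start = as.vector(vapply(ctr, function(c)
        c - half_window + bin * (0:(n_bins - 1)), numeric(n_bins))),
      width = bin))
  vals <- .track_region_means(track, bins)
  mat <- matrix(vals, ncol = n_bins, byrow = TRUE)
  rownames(mat) <- if (!is.null(anchors$name)) anchors$name
                   else sprintf("anchor_%d", seq_along(anchors))
  ord <- order(-rowSums(mat))
  list(matrix = mat[ord, , drop = FALSE], mean_curve = colMeans(mat),
       bin_size = bin, half_window = half_window, anchors = anchors[ord])
}

#' Label differential FLAG peaks
#'
#' The ON signal is the mean of the normalized ON replicates; with a
#' pseudocount added to both sides, peaks are differential when
#' `log2((on + pc) / (off + pc)) > min_lfc` and the ON average also exceeds
#' `min_on_signal` (2^4.5), which suppresses high fold changes on barely
#' covered peaks.
#'
#' @param counts peaks x samples count matrix.
#' @param on_samples,off_samples column names or indices of the ON
#'   replicates and the OFF sample(s).
#' @param size_factors per-sample normalization factors (see
#'   [median_of_ratios()]); counts are divided by them first.
#' @param pseudocount added to both averages before the ratio.
#' @param min_lfc log2 fold-change threshold (strict).
#' @param min_on_signal normalized ON-average floor (strict).
#' @return data.frame with `on_avg`, `off_avg`, `lfc`, `differential`.
#' @export
differential_flag_peaks <- function(counts, on_samples, off_samples,
                                    size_factors = NULL, pseudocount = 1,
                                    min_lfc = 1, min_on_signal = 2^4.5) {
  counts <- as.matrix(counts)
  if (is.null(size_factors)) size_factors <- rep(1, ncol(counts))
  if (length(size_factors) != ncol(counts))
    stop("one size factor per sample required")
  norm <- sweep(counts, 2, size_factors, "/")
  on_avg <- rowMeans(norm[, on_samples, drop = FALSE])
  off_avg <- rowMeans(norm[, off_samples, drop = FALSE])
  lfc <- log2((on_avg + pseudocount) / (off_avg + pseudocount))
  data.frame(on_avg = on_avg, off_avg = off_avg, lfc = lfc,
             differential = lfc > min_lfc & on_avg > min_on_signal,
             row.names = rownames(counts))
}

#' TetO reference-sequence enrichment
#'
#' Coverage over the TetO reference divided by the mean input coverage,
#' optionally normalized to a control condition's ratio.
#'
#' @param sample_cov read coverage of the sample over the TetO reference.
#' @param input_covs coverages of the input control experiments.
#' @param control_ratio optional ratio of the control condition to divide by.
#' @return enrichment ratio.
#' @export
teto_enrichment <- function(sample_cov, input_covs, control_ratio = NULL) {
  if (!length(input_covs) || mean(input_covs) <= 0)
    stop("input coverages must be non-empty with positive mean")
  ratio <- sample_cov / mean(input_covs)
  if (!is.null(control_ratio)) ratio <- ratio / control_ratio
  ratio
}

#' Consensus peaks from pooled and replicate calls
#'
#' A pooled peak is retained when it lies on a canonical chromosome, does
#' not touch the blacklist, and at least half of its length is covered by
#' peaks of each replicate.
#'
#' @param pooled,rep1,rep2 `GRanges` peak sets.
#' @param blacklist `GRanges` of excluded regions (may be empty).
#' @param canonical chromosome names considered canonical.
#' @param min_overlap minimal covered fraction of the pooled peak.
#' @return subset of `pooled`.
#' @export
consensus_peaks <- function(pooled, rep1, rep2,
                            blacklist = GenomicRanges::GRanges(),
                            canonical = canonical_chromosomes(),
                            min_overlap = 0.5) {
  keep <- as.character(GenomicRanges::seqnames(pooled)) %in% canonical
  if (length(blacklist))
    keep <- keep & !IRanges::overlapsAny(pooled, blacklist,
                                         ignore.strand = TRUE)
  frac <- function(reps) {
    cov <- numeric(length(pooled))
    hits <- GenomicRanges::findOverlaps(pooled,
              GenomicRanges::reduce(reps, ignore.strand = TRUE),
              ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      ov <- IRanges::pintersect(
        GenomicRanges::ranges(pooled)[q],
        GenomicRanges::ranges(GenomicRanges::reduce(reps,
          ignore.strand = TRUE))[S4Vectors::subjectHits(hits)])
      acc <- tapply(IRanges::width(ov),
                    factor(q, levels = seq_along(pooled)), sum)
      acc[is.na(acc)] <- 0
      cov <- as.numeric(acc)
    }
    cov / GenomicRanges::width(pooled)
  }
  pooled[keep & frac(rep1) >= min_overlap & frac(rep2) >= min_overlap]
}
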