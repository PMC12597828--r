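#' Per-viewpoint 4C fragment profile
#'
#' Bundles a fragment map, the TetO viewpoint it was measured from, and one
#' value per fragment.  `stage` tracks what the values are: raw counts,
#' per-million normalized signal, or smoothed normalized signal.  Missing
#' values (`NA`) mark fragments without usable signal (blind fragments, or
#' fragments outside the normalization region).
#'
#' @param map fragment `GRanges` with a logical `blind` column.
#' @param values numeric vector, one value per fragment.
#' @param teto_pos,teto_id viewpoint position (bp) and label.
#' @param stage one of `"raw"`, `"normalized"`, `"smoothed"`.
#' @return a `fragment_profile` object.
#' @export
fragment_profile <- function(map, values, teto_pos, teto_id = "TetO_1",
                             stage = "raw") {
  stopifnot(is(map, "GRanges"), !is.null(map$blind))
  if (length(values) != length(map))
    stop("values must have one entry per fragment")
  stage <- match.arg(stage, c("raw", "normalized", "smoothed"))
  if (any(values < 0, na.rm = TRUE)) stop("negative 4C signal")
  structure(list(map = map, values = as.numeric(values),
                 teto_pos = teto_pos, teto_id = teto_id, stage = stage),
            class = "fragment_profile")
}

#' @export
print.fragment_profile <- function(x, ...) {
  cat(sprintf("<fragment_profile> %s @ %s:%s | %d fragments (%d observed) | stage: %s\n",
              x$teto_id, as.character(GenomicRanges::seqnames(x$map))[1],
              format(x$teto_pos, big.mark = ","), length(x$map),
              sum(!is.na(x$values)), x$stage))
  invisible(x)
}

#' Normalize a 4C viewpoint profile to reads per million
#'
#' Counts at non-blind fragments within `region_half_width` of the viewpoint
#' are rescaled so that their total — after excluding the `n_top_excluded`
#' highest-count fragments from the denominator — equals `target_total`.
#' The excluded top fragments themselves are still rescaled and kept.  Blind
#' and out-of-region fragments become `NA`.
#'
#' @param raw a `fragment_profile` with `stage == "raw"`.
#' @param region_half_width bp kept on each side of the viewpoint.
#' @param target_total normalization target (reads).
#' @param n_top_excluded number of highest-count fragments excluded from the
#'   scaling denominator (ties broken by leftmost coordinate).
#' @return a `fragment_profile` with `stage == "normalized"`.
#' @export
normalize_viewpoint <- function(raw, region_half_width = 1e7,
                                target_total = 1e6, n_top_excluded = 2) {
  stopifnot(inherits(raw, "fragment_profile"))
  if (raw$stage != "raw") stop("normalize_viewpoint expects a raw profile")
  centers <- .centers(raw$map)
  ext <- range(c(GenomicRanges::start(raw$map), GenomicRanges::end(raw$map)))
  if (raw$teto_pos < ext[1] || raw$teto_pos > ext[2])
    stop("viewpoint outside the fragment map extent")
  keep <- !raw$map$blind &
    abs(centers - raw$teto_pos) <= region_half_width &
    !is.na(raw$values)
  counts <- raw$values[keep]
  if (length(counts) < n_top_excluded + 1)
    stop("fewer retained fragments than n_top_excluded + 1")
  top <- order(-counts, GenomicRanges::start(raw$map)[keep])[
    seq_len(n_top_excluded)]
  denom <- sum(counts[-top])
  if (denom <= 0)
    stop("normalization denominator is zero: no counts outside the top fragments")
  out <- rep(NA_real_, length(raw$values))
  out[keep] <- counts * (target_total / denom)
  fragment_profile(raw$map, out, raw$teto_pos, raw$teto_id, "normalized")
}

#' Smooth a normalized profile with a running mean in fragment space
#'
#' A centered running mean over `window` fragments, computed on the observed
#' (non-`NA`) fragments as a contiguous series; at the profile edges the
#' window truncates to the available fragments.  Missing fragments stay
#' missing.
#'
#' @param profile a normalized `fragment_profile`.
#' @param window odd window size in fragments (21 by default; `1` is the
#'   identity).
#' @return a `fragment_profile` with `stage == "smoothed"`.
#' @export
smooth_profile <- function(profile, window = 21) {
  stopifnot(inherits(profile, "fragment_profile"))
  if (profile$stage != "normalized")
    stop("smooth_profile expects a normalized profile")
  if (window %% 2 == 0) stop("window must be odd")
  idx <- which(!is.na(profile$values))
  out <- profile$values
  out[idx] <- running_mean(profile$values[idx], window)
  fragment_profile(profile$map, out, profile$teto_pos, profile$teto_id,
                   "smoothed")
}

#' Truncated centered running mean
#'
#' @param x numeric vector without `NA`.
#' @param window odd window size.
#' @return numeric vector of the same length.
#' @export
running_mean <- function(x, window) {
  if (window %% 2 == 0) stop("window must be odd")
  n <- length(x)
  if (n == 0) return(x)
  k <- (window - 1) / 2
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - k, 1)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Per-fragment differential 4C signal (ON minus control)
#'
#' @param a,b smoothed `fragment_profile`s on the same map and viewpoint.
#' @return numeric vector `a - b`, `NA` where either profile is missing.
#' @export
differential_profile <- function(a, b) {
  stopifnot(inherits(a, "fragment_profile"), inherits(b, "fragment_profile"))
  if (a$stage != "smoothed" || b$stage != "smoothed")
    stop("differential_profile expects smoothed profiles")
  if (length(a$map) != length(b$map) ||
      !all(GenomicRanges::start(a$map) == GenomicRanges::start(b$map)) ||
      !all(GenomicRanges::end(a$map) == GenomicRanges::end(b$map)) ||
      a$teto_pos != b$teto_pos)
    stop("profiles must share the same fragment map and viewpoint")
  a$values - b$values
}

#' Anchor-centered aggregate 4C
#'
#' Averages normalized 4C signal around a set of anchor peaks.  Anchors
#' within `min_anchor_distance` of any TetO integration are dropped (ligation
#' background near the viewpoint would dominate); survivors are re-centered
#' and expanded to `window_span`, divided into `bin_size` bins, and each bin
#' takes the bp-weighted mean of the fragment values it overlaps.
#'
#' @param profiles list of smoothed or normalized `fragment_profile`s; each
#'   anchor is scored against every profile whose chromosome it shares.
#' @param anchors `GRanges` of peaks to aggregate around.
#' @param tetos numeric vector of TetO positions (bp) used for the distance
#'   filter (the profiles' own viewpoints are always included).
#' @param min_anchor_distance minimum anchor-to-TetO center distance in bp.
#' @param window_span total window width in bp (must be a multiple of
#'   `bin_size`).
#' @param bin_size bin width in bp.
#' @return list with `matrix` (one row per surviving profile/anchor pair),
#'   `mean_curve` (column means) and `anchors` (the survivors).
#' @export
aggregate_4c <- function(profiles, anchors, tetos = numeric(0),
                         min_anchor_distance = 1e5, window_span = 1e5,
                         bin_size = 2000) {
  if (inherits(profiles, "fragment_profile")) profiles <- list(profiles)
  if (window_span %% bin_size != 0)
    stop("window_span must be divisible by bin_size")
  n_bins <- window_span / bin_size
  rows <- list(); used <- integer(0)
  for (p in profiles) {
    chrom <- as.character(GenomicRanges::seqnames(p$map))[1]
    on_chrom <- which(as.character(GenomicRanges::seqnames(anchors)) == chrom)
    if (!length(on_chrom)) next
    cen <- .centers(anchors[on_chrom])
    all_tetos <- unique(c(tetos, p$teto_pos))
    min_d <- vapply(cen, function(x) min(abs(x - all_tetos)), 0)
    ok <- on_chrom[min_d >= min_anchor_distance]
    if (!length(ok)) next
    for (j in ok) {
      ctr <- .centers(anchors[j])
      lo <- ctr - window_span / 2
      brk <- lo + bin_size * (0:n_bins)
      rows[[length(rows) + 1]] <-
        .binned_fragment_means(p$map, p$values, brk)
      used <- c(used, j)
    }
  }
  if (!length(rows))
    stop("no anchors survive the min_anchor_distance filter")
  mat <- do.call(rbind, rows)
  rownames(mat) <- sprintf("anchor_%d", used)
  list(matrix = mat, mean_curve = colMeans(mat, na.rm = TRUE),
       anchors = anchors[used])
}

# bp-weighted mean of fragment values within [brk[i], brk[i+1]) bins
.binned_fragment_means <- function(map, values, brk) {
  n_bins <- length(brk) - 1
  bins <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(map))[1],
    IRanges::IRanges(start = pmax(brk[-length(brk)], 1), end = brk[-1] - 1))
  hits <- GenomicRanges::findOverlaps(bins, map)
  out <- rep(NA_real_, n_bins)
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- IRanges::pintersect(GenomicRanges::ranges(bins)[q],
                            GenomicRanges::ranges(map)[s])
  w <- IRanges::width(ov)
  v <- values[s]
  keep <- !is.na(v)
  if (!any(keep)) return(out)
  num <- tapply(w[keep] * v[keep], q[keep], sum)
  den <- tapply(w[keep], q[keep], sum)
  out[as.integer(names(num))] <- num / den
  out
}
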