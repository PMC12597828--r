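#' Dense contact matrix container
#'
#' A square symmetric matrix of contact frequencies for one chromosome
#' region, with bin resolution and genomic offset, tagged by `kind`
#' (`observed`, `expected`, or `obs_over_exp`).
#'
#' @param matrix square numeric matrix (dimension >= 3, symmetric to within
#'   1e-9 relative tolerance).
#' @param resolution bp per bin.
#' @param chrom chromosome name.
#' @param start genomic start (bp) of bin 1.
#' @param kind matrix kind.
#' @return a `contact_matrix` object.
#' @export
contact_matrix <- function(matrix, resolution = 10000L, chrom = "chrS",
                           start = 0L,
                           kind = c("observed", "expected", "obs_over_exp")) {
  kind <- match.arg(kind)
  if (nrow(matrix) != ncol(matrix)) stop("contact matrix must be square")
  if (nrow(matrix) < 3) stop("contact matrix must be at least 3 x 3")
  if (any(matrix < 0, na.rm = TRUE)) stop("negative contact frequencies")
  sym_err <- max(abs(matrix - t(matrix)), na.rm = TRUE)
  scale <- max(abs(matrix), na.rm = TRUE)
  if (scale > 0 && sym_err / scale > 1e-9)
    stop("contact matrix is not symmetric")
  structure(list(matrix = matrix, resolution = as.integer(resolution),
                 chrom = chrom, start = as.integer(start), kind = kind),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s, %d bins @ %d bp (%s)\n", x$chrom,
              nrow(x$matrix), x$resolution, x$kind))
  invisible(x)
}

#' Observed-over-expected transformation by diagonal averaging
#'
#' The expected value at bin distance `k` is the mean of the observed matrix
#' over all pixels with `|i - j| == k`; dividing observed by expected gives
#' an obs/exp matrix whose every diagonal has mean 1.  Diagonals with zero
#' mean produce `NA` ratios.
#'
#' @param obs a `contact_matrix` of kind `"observed"`.
#' @return list with `expected` and `obs_over_exp` contact matrices.
#' @export
expected_by_diagonal <- function(obs) {
  stopifnot(inherits(obs, "contact_matrix"))
  if (obs$kind != "observed")
    stop("expected_by_diagonal needs an observed matrix")
  m <- obs$matrix
  n <- nrow(m)
  d <- abs(row(m) - col(m))
  diag_mean <- tapply(m, d, mean)
  exp_m <- matrix(diag_mean[as.character(d)], n, n)
  ratio <- ifelse(exp_m > 0, m / exp_m, NA_real_)
  list(expected = contact_matrix(exp_m, obs$resolution, obs$chrom,
                                 obs$start, "expected"),
       obs_over_exp = contact_matrix(ratio, obs$resolution, obs$chrom,
                                     obs$start, "obs_over_exp"))
}

#' Aggregate pileup of obs/exp windows around anchors
#'
#' For each anchor the `(2f + 1)`-bin square sub-matrix centered on the
#' anchor's diagonal bin is extracted (`f = flank / resolution`); anchors
#' whose window exceeds the matrix bounds are skipped and counted.  The
#' pileup is the elementwise mean over the used anchors.
#'
#' @param ooe a `contact_matrix` of kind `"obs_over_exp"`.
#' @param anchors `GRanges` of anchor intervals (snapped to the bin holding
#'   their midpoint) or a numeric vector of bp positions.
#' @param flank flank size in bp (a multiple of the resolution).
#' @return a `pileup_window` list: `matrix`, `flank_bins`,
#'   `n_anchors_used`, `n_anchors_skipped`.
#' @export
pileup <- function(ooe, anchors, flank = 5e5) {
  stopifnot(inherits(ooe, "contact_matrix"))
  if (ooe$kind != "obs_over_exp")
    stop("pileup needs an obs_over_exp matrix")
  if (flank %% ooe$resolution != 0)
    stop("flank must be a multiple of the matrix resolution")
  f <- flank / ooe$resolution
  pos <- if (is(anchors, "GRanges")) .centers(anchors) else as.numeric(anchors)
  bins <- floor((pos - ooe$start) / ooe$resolution) + 1
  n <- nrow(ooe$matrix)
  ok <- bins - f >= 1 & bins + f <= n
  if (!any(ok)) stop("every anchor window exceeds the matrix bounds")
  acc <- matrix(0, 2 * f + 1, 2 * f + 1)
  cnt <- matrix(0, 2 * f + 1, 2 * f + 1)
  for (b in bins[ok]) {
    w <- ooe$matrix[(b - f):(b + f), (b - f):(b + f)]
    hit <- !is.na(w)
    w[!hit] <- 0
    acc <- acc + w
    cnt <- cnt + hit
  }
  structure(list(matrix = ifelse(cnt > 0, acc / cnt, NA_real_),
                 flank_bins = f, n_anchors_used = sum(ok),
                 n_anchors_skipped = sum(!ok)),
            class = "pileup_window")
}

#' @export
print.pileup_window <- function(x, ...) {
  cat(sprintf("<pileup_window> %dx%d (flank %d bins), %d anchors used, %d skipped\n",
              nrow(x$matrix), ncol(x$matrix), x$flank_bins,
              x$n_anchors_used, x$n_anchors_skipped))
  invisible(x)
}

.window_matrix <- function(window) {
  if (inherits(window, "pileup_window")) window$matrix
  else as.matrix(window)
}

#' Average loop strength of a pileup window
#'
#' Mean of the central 3 x 3 pixels.
#'
#' @param window a `pileup_window` (or plain odd-dimension matrix).
#' @return scalar loop strength.
#' @export
loop_strength <- function(window) {
  m <- .window_matrix(window)
  if (nrow(m) < 3) stop("window must be at least 3 x 3")
  c0 <- (nrow(m) + 1) / 2
  mean(m[(c0 - 1):(c0 + 1), (c0 - 1):(c0 + 1)], na.rm = TRUE)
}

#' Average boundary strength of a pileup window
#'
#' Mean of the intra-TAD quarters (upper-left and bottom-right) divided by
#' the mean of the inter-TAD quarters (upper-right and bottom-left).  The
#' central row and column are excluded from the quarter decomposition.
#'
#' @param window a `pileup_window` (or plain odd-dimension matrix).
#' @return scalar boundary strength.
#' @export
boundary_strength <- function(window) {
  m <- .window_matrix(window)
  n <- nrow(m)
  if (n < 3 || n %% 2 == 0) stop("window must be odd-dimensioned, >= 3")
  c0 <- (n + 1) / 2
  a <- 1:(c0 - 1); b <- (c0 + 1):n
  intra <- mean(c(m[a, a], m[b, b]), na.rm = TRUE)
  inter <- mean(c(m[a, b], m[b, a]), na.rm = TRUE)
  if (!is.finite(inter) || inter == 0)
    stop("inter-TAD mean is zero; boundary strength undefined")
  intra / inter
}

#' Average TAD density of a pileup window
#'
#' Mean of the central 33 x 33 pixels.
#'
#' @param window a `pileup_window` (or plain odd-dimension matrix).
#' @param core_bins side length of the central block (default 33).
#' @return scalar TAD density.
#' @export
tad_density <- function(window, core_bins = 33) {
  m <- .window_matrix(window)
  if (nrow(m) < core_bins)
    stop(sprintf("window smaller than the %d-bin core", core_bins))
  c0 <- (nrow(m) + 1) / 2
  h <- (core_bins - 1) / 2
  mean(m[(c0 - h):(c0 + h), (c0 - h):(c0 + h)], na.rm = TRUE)
}
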