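# Count normalization, a simplified negative-binomial Wald test, and the
# distance-grouped expression comparison around TetO integrations.

#' Median-of-ratios size factors
#'
#' The DESeq-style estimator: the reference level of each feature is its
#' geometric mean across samples (features with any zero count are
#' excluded), and a sample's size factor is the median over features of the
#' ratio of its count to the reference.
#'
#' @param counts features x samples matrix of nonnegative counts.
#' @return positive numeric vector of per-sample size factors.
#' @export
median_of_ratios <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  ok <- rowSums(counts == 0) == 0
  if (!any(ok))
    stop("no feature with nonzero counts in all samples")
  logc <- log(counts[ok, , drop = FALSE])
  ref <- rowMeans(logc)
  factors <- apply(logc, 2, function(x) exp(stats::median(x - ref)))
  if (any(!is.finite(factors) | factors <= 0))
    stop("degenerate size factors")
  factors
}

#' Prefilter low-count features
#'
#' Keeps features whose counts exceed `min_count` in every sample, the
#' filter applied before differential testing of nascent transcription.
#'
#' @param counts features x samples count matrix.
#' @param min_count strict lower bound (default 10: "greater than ten").
#' @return logical vector of kept features.
#' @export
filter_low_counts <- function(counts, min_count = 10) {
  counts <- as.matrix(counts)
  rowSums(counts > min_count) == ncol(counts)
}

#' Simplified negative-binomial Wald test
#'
#' Per feature, condition means are fitted on size-factor-normalized counts,
#' the common dispersion of the two conditions is estimated by the method of
#' moments (floored at 1e-8), and the Wald statistic is the log2 fold change
#' over its delta-method standard error, referred to the standard normal.
#' No dispersion shrinkage or fold-change moderation is applied: this is a
#' deliberately plain NB test whose calibration on synthetic data is
#' verified in the test suite, not a reimplementation of DESeq2's
#' empirical-Bayes machinery.
#'
#' @param counts features x samples matrix of raw counts.
#' @param conditions per-sample condition labels (two levels).
#' @param size_factors per-sample size factors; estimated by
#'   [median_of_ratios()] when omitted.
#' @param contrast character pair `c(numerator, denominator)`; defaults to
#'   the two levels in order of appearance.
#' @return data.frame with `base_mean`, `lfc`, `se`, `stat`, `pvalue`
#'   (all-`NA` rows for all-zero features).
#' @export
nb_wald_test <- function(counts, conditions, size_factors = NULL,
                         contrast = NULL) {
  counts <- as.matrix(counts)
  conditions <- as.character(conditions)
  if (length(conditions) != ncol(counts))
    stop("one condition label per sample required")
  lev <- unique(conditions)
  if (length(lev) != 2) stop("exactly two conditions required")
  if (is.null(contrast)) contrast <- lev
  if (!all(contrast %in% lev)) stop("contrast levels not found")
  ia <- conditions == contrast[1]; ib <- conditions == contrast[2]
  if (sum(ia) < 2 || sum(ib) < 2)
    stop("at least two samples per condition required for dispersion estimation")
  if (is.null(size_factors)) size_factors <- median_of_ratios(counts)
  norm <- sweep(counts, 2, size_factors, "/")
  mu_a <- rowMeans(norm[, ia, drop = FALSE])
  mu_b <- rowMeans(norm[, ib, drop = FALSE])
  var_a <- apply(norm[, ia, drop = FALSE], 1, stats::var)
  var_b <- apply(norm[, ib, drop = FALSE], 1, stats::var)
  # pooled method-of-moments dispersion: Var = mu + phi * mu^2
  num <- (sum(ia) - 1) * (var_a - mu_a) + (sum(ib) - 1) * (var_b - mu_b)
  den <- (sum(ia) - 1) * mu_a^2 + (sum(ib) - 1) * mu_b^2
  phi <- pmax(ifelse(den > 0, num / den, 0), 1e-8)
  lfc <- log2(mu_a / mu_b)
  v_lfc <- ((mu_a + phi * mu_a^2) / (sum(ia) * mu_a^2) +
            (mu_b + phi * mu_b^2) / (sum(ib) * mu_b^2)) / log(2)^2
  se <- sqrt(v_lfc)
  stat <- lfc / se
  p <- 2 * stats::pnorm(-abs(stat))
  zero <- rowSums(counts) == 0
  out <- data.frame(base_mean = rowMeans(norm), lfc = lfc, se = se,
                    stat = stat, pvalue = p, row.names = rownames(counts))
  out[zero, c("lfc", "se", "stat", "pvalue")] <- NA_real_
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR control via [stats::p.adjust()], with input validation.
#'
#' @param pvalues numeric p-values in `[0, 1]` (`NA` allowed, propagated).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Significance labels at the published thresholds
#'
#' A feature is significant when `q < max_q` and `|lfc| > min_abs_lfc`.
#' The `gene` preset uses (0.05, 1); the `peak` preset, used for ATAC and
#' H3K27ac differential occupancy, uses (0.05, 0.5).
#'
#' @param lfc,q aligned vectors of log2 fold changes and q-values.
#' @param preset `"gene"` or `"peak"`, or `NULL` to use the explicit
#'   thresholds.
#' @param min_abs_lfc,max_q explicit thresholds.
#' @return logical vector (`NA` where inputs are `NA`).
#' @export
significant_features <- function(lfc, q, preset = c("gene", "peak"),
                                 min_abs_lfc = NULL, max_q = 0.05) {
  if (is.null(min_abs_lfc)) {
    preset <- match.arg(preset)
    min_abs_lfc <- if (preset == "gene") 1 else 0.5
  }
  stopifnot(length(lfc) == length(q))
  q < max_q & abs(lfc) > min_abs_lfc
}

#' Group genes by distance to their TetO integration
#'
#' Genes whose body overlaps a TetO interval are `overlapping_TetO`.  Other
#' genes inside a called domain are binned by the distance from their
#' nearest edge to the TetO position: `0-100kb`, `100-250kb`, `250-500kb`,
#' `>500kb`.  Genes outside every domain form the `outside_domain` control
#' group.  A gene overlapping two domains is assigned to the nearer TetO
#' with a warning.
#'
#' @param genes `GRanges` of gene bodies.
#' @param tetos `GRanges` of TetO integrations.
#' @param domains `GRanges` of called domains carrying a numeric `teto_pos`
#'   metadata column.
#' @return factor with levels `overlapping_TetO`, `0-100kb`, `100-250kb`,
#'   `250-500kb`, `>500kb`, `outside_domain`.
#' @export
gene_distance_groups <- function(genes, tetos, domains) {
  stopifnot(!is.null(domains$teto_pos))
  lev <- c("overlapping_TetO", "0-100kb", "100-250kb", "250-500kb",
           ">500kb", "outside_domain")
  out <- rep("outside_domain", length(genes))
  ov <- GenomicRanges::findOverlaps(genes, domains, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
    multi <- unique(q[duplicated(q)])
    if (length(multi))
      warning(sprintf("%d genes span several domains; assigned to the nearer TetO",
                      length(multi)))
    gs <- GenomicRanges::start(genes)[q]; ge <- GenomicRanges::end(genes)[q]
    tp <- domains$teto_pos[s]
    # edge-to-TetO distance; 0 when the TetO position falls inside the gene
    d <- pmax(pmax(gs - tp, 0), pmax(tp - ge, 0))
    pick <- tapply(seq_along(q), factor(q, levels = unique(q)),
                   function(i) i[which.min(d[i])])
    q1 <- q[pick]; d1 <- d[pick]
    out[q1] <- as.character(cut(d1, c(-1, 1e5, 2.5e5, 5e5, Inf),
                                labels = lev[2:5]))
  }
  if (length(tetos))
    out[IRanges::overlapsAny(genes, tetos, ignore.strand = TRUE)] <-
      "overlapping_TetO"
  factor(out, levels = lev)
}

#' Compare expression shifts of distance groups against the outside control
#'
#' Per non-control group, a two-sided Mann-Whitney U test of the per-gene
#' log2 fold changes against the `outside_domain` control group, with BH
#' correction across groups.
#'
#' @param lfc per-gene log2 fold changes.
#' @param groups factor from [gene_distance_groups()].
#' @param control control level name.
#' @return data.frame with one row per non-control group: `group`, `n`,
#'   `U`, `pvalue`, `qvalue` (rows with `n == 0` carry `NA`).
#' @export
group_shift_test <- function(lfc, groups, control = "outside_domain") {
  stopifnot(length(lfc) == length(groups))
  groups <- as.factor(groups)
  ctrl <- lfc[groups == control & !is.na(lfc)]
  if (!length(ctrl)) stop("control group is empty")
  test_levels <- setdiff(levels(groups), control)
  res <- lapply(test_levels, function(g) {
    x <- lfc[groups == g & !is.na(lfc)]
    if (!length(x))
      return(data.frame(group = g, n = 0L, U = NA_real_, pvalue = NA_real_))
    w <- stats::wilcox.test(x, ctrl, alternative = "two.sided", exact = FALSE)
    data.frame(group = g, n = length(x), U = unname(w$statistic),
               pvalue = w$p.value)
  })
  out <- do.call(rbind, res)
  out$qvalue <- bh_adjust(out$pvalue)
  out
}
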