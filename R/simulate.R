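# Seeded synthetic inputs with planted ground truth.  Every generator is a
# pure function of its arguments including `seed`: the global RNG state is
# saved and restored around each call.

.with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

#' Simulate a restriction-fragment map of one pseudo-chromosome
#'
#' Emulates digestion by a 4-bp cutter: fragment lengths are i.i.d.
#' geometric with the stated mean (a 4-cutter such as MboI cuts on average
#' every 4^4 = 256 bp), tiling the chromosome contiguously.  A random subset
#' of fragments is flagged blind (unobservable in 4C); blind fragments are
#' excluded from normalization downstream.
#'
#' @param chrom_length chromosome length in bp (>= 10 * `mean_fragment`).
#' @param mean_fragment mean fragment length in bp (>= 50).
#' @param blind_fraction proportion of fragments flagged blind, in `[0, 1)`.
#' @param seed RNG seed.
#' @param chrom chromosome name for the pseudo-chromosome.
#' @return `GRanges` of contiguous fragments with a logical `blind` column.
#' @export
simulate_fragment_map <- function(chrom_length, mean_fragment = 256,
                                  blind_fraction = 0.05, seed,
                                  chrom = "chrS") {
  if (mean_fragment < 50)
    stop("mean_fragment < 50 bp is unrealistically dense for a 4-cutter")
  if (chrom_length < 10 * mean_fragment)
    stop("chrom_length must be at least 10 * mean_fragment")
  if (blind_fraction < 0 || blind_fraction >= 1)
    stop("blind_fraction must be in [0, 1)")
  .with_seed(seed, {
    n_guess <- ceiling(1.3 * chrom_length / mean_fragment) + 50L
    lens <- 1 + stats::rgeom(n_guess, 1 / mean_fragment)
    while (sum(lens) < chrom_length)
      lens <- c(lens, 1 + stats::rgeom(n_guess, 1 / mean_fragment))
    ends <- cumsum(lens)
    n <- which(ends >= chrom_length)[1]
    ends <- pmin(ends[seq_len(n)], chrom_length)
    starts <- c(1, head(ends, -1) + 1)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
    gr$blind <- stats::runif(n) < blind_fraction
    gr
  })
}

#' Describe a planted induced-looping domain
#'
#' Ground truth for parameter-recovery tests: the TetO integration, the
#' interval over which its long-range 4C contacts are elevated, and the
#' enrichment multiplier applied there in the ON condition.
#'
#' @param teto_pos TetO integration position (bp, inside `domain`).
#' @param domain_start,domain_end planted domain interval in bp (1-based,
#'   closed, on the simulated pseudo-chromosome).
#' @param enrichment multiplicative signal gain inside the domain, >= 1
#'   (`1` gives a null simulation with no planted domain).
#' @param teto_id label for the integration.
#' @param chrom chromosome name; must match the fragment map used later.
#' @return a `domain_spec` list.
#' @export
domain_spec <- function(teto_pos, domain_start, domain_end, enrichment,
                        teto_id = "TetO_1", chrom = "chrS") {
  if (enrichment < 1) stop("enrichment must be >= 1")
  if (domain_end <= domain_start) stop("empty domain interval")
  if (teto_pos < domain_start || teto_pos > domain_end)
    stop("teto_pos must lie inside the domain interval")
  structure(list(teto_pos = teto_pos, teto_id = teto_id, chrom = chrom,
                 domain_start = domain_start, domain_end = domain_end,
                 enrichment = enrichment),
            class = "domain_spec")
}

#' Simulate a matched ON/control 4C fragment-count pair
#'
#' Both conditions share a power-law distance decay from the viewpoint,
#' `mu(d) = c * max(d, floor)^alpha`, with the decay floored below
#' `distance_floor` (ligation frequencies plateau near the viewpoint).  In
#' the ON condition, fragments inside the planted domain and more than
#' `distance_floor` from the TetO are multiplied by `spec$enrichment` before
#' the total is rescaled to `depth` reads.  Counts are drawn
#' negative-binomially around these expectations; blind fragments yield no
#' counts.
#'
#' @param map fragment map from [simulate_fragment_map()].
#' @param spec a [domain_spec()].
#' @param depth total expected read count per condition.
#' @param decay_exponent power-law exponent, < 0.
#' @param noise_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); `0` gives Poisson noise.
#' @param distance_floor bp below which the decay (and the enrichment
#'   exclusion zone around TetO) is flat.
#' @param seed RNG seed.
#' @return list with `on` and `control` integer count vectors (one entry per
#'   map fragment), plus the expected values `mu_on`, `mu_control`.
#' @export
simulate_4c_pair <- function(map, spec, depth = 1e6, decay_exponent = -0.3,
                             noise_dispersion = 0.01, distance_floor = 1e5,
                             seed = 1) {
  stopifnot(is(map, "GRanges"), inherits(spec, "domain_spec"))
  if (decay_exponent >= 0) stop("decay_exponent must be negative")
  if (depth <= 0) stop("depth must be positive")
  ext <- range(c(GenomicRanges::start(map), GenomicRanges::end(map)))
  if (spec$teto_pos < ext[1] || spec$teto_pos > ext[2])
    stop("TetO position outside the fragment map extent")
  centers <- .centers(map)
  d <- pmax(abs(centers - spec$teto_pos), distance_floor)
  w <- d^decay_exponent
  in_dom <- centers >= spec$domain_start & centers <= spec$domain_end &
    abs(centers - spec$teto_pos) > distance_floor
  w_on <- w * ifelse(in_dom, spec$enrichment, 1)
  mu_ctrl <- depth * w / sum(w)
  mu_on <- depth * w_on / sum(w_on)
  .with_seed(seed, {
    draw <- function(mu) {
      y <- if (noise_dispersion > 0)
        stats::rnbinom(length(mu), mu = mu, size = 1 / noise_dispersion)
      else stats::rpois(length(mu), mu)
      y[map$blind] <- 0L
      y
    }
    list(on = draw(mu_on), control = draw(mu_ctrl),
         mu_on = mu_on, mu_control = mu_ctrl)
  })
}

#' Simulate a replicate peak-count table with planted differential peaks
#'
#' Null peaks share their expected level across conditions; the first
#' `n_diff` peaks are shifted up by `2^lfc` in the first condition.  Counts
#' are negative binomial and column totals scale with `depth_factors`, so
#' size-factor estimation is exercised realistically.
#'
#' @param n_peaks,n_diff number of peaks, and of truly differential peaks.
#' @param lfc planted log2 fold change for differential peaks.
#' @param dispersion negative-binomial dispersion.
#' @param depth_factors per-sample sequencing-depth multipliers (positive).
#' @param conditions per-sample condition labels (two levels); defaults to
#'   the first half vs the second half of the samples.
#' @param base_mean mean of the log-normal distribution of baseline levels.
#' @param seed RNG seed.
#' @return list with `counts` (peaks x samples), logical `truth`, and
#'   `conditions`.
#' @export
simulate_replicate_peak_counts <- function(n_peaks, n_diff, lfc = 2,
                                           dispersion = 0.05,
                                           depth_factors = c(1, 1, 1, 1),
                                           conditions = NULL,
                                           base_mean = 100, seed = 1) {
  if (n_diff > n_peaks) stop("n_diff cannot exceed n_peaks")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (any(depth_factors <= 0)) stop("depth factors must be positive")
  n_s <- length(depth_factors)
  if (is.null(conditions))
    conditions <- rep(c("A", "B"), c(ceiling(n_s / 2), floor(n_s / 2)))
  if (length(conditions) != n_s) stop("one condition label per sample")
  .with_seed(seed, {
    base <- base_mean * exp(stats::rnorm(n_peaks, 0, 0.5))
    truth <- seq_len(n_peaks) <= n_diff
    shift <- ifelse(truth, 2^lfc, 1)
    first <- conditions == conditions[1]
    mu <- outer(base, depth_factors)
    mu[, first] <- mu[, first] * shift
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                     nrow = n_peaks,
                     dimnames = list(sprintf("peak_%d", seq_len(n_peaks)),
                                     sprintf("s%d_%s", seq_len(n_s), conditions)))
    list(counts = counts, truth = truth, conditions = conditions)
  })
}

#' Simulate a block/loop-structured contact matrix
#'
#' Builds a symmetric matrix with background `inter_level`, TAD blocks at
#' `intra_level`, loop pixels multiplied by their strength, and optional
#' Poisson noise.
#'
#' @param n_bins matrix dimension.
#' @param tads list of integer pairs `c(first_bin, last_bin)` (1-based,
#'   inclusive, non-overlapping).
#' @param intra_level,inter_level expected contact level inside / outside
#'   TADs (positive).
#' @param loops list of triples `c(i, j, strength)`.
#' @param resolution bp per bin (metadata for the resulting matrix).
#' @param noise add Poisson noise around the expectation.
#' @param seed RNG seed (used only when `noise = TRUE`).
#' @return a `contact_matrix` of kind `"observed"`.
#' @export
simulate_contact_matrix <- function(n_bins, tads = list(),
                                    intra_level = 2, inter_level = 1,
                                    loops = list(), resolution = 10000L,
                                    noise = FALSE, seed = 1) {
  if (intra_level <= 0 || inter_level <= 0) stop("levels must be positive")
  if (length(tads) > 1) {
    b <- do.call(rbind, tads)
    b <- b[order(b[, 1]), , drop = FALSE]
    if (any(b[-1, 1] <= b[-nrow(b), 2]))
      stop("overlapping TAD intervals")
  }
  m <- matrix(inter_level, n_bins, n_bins)
  for (t in tads) {
    if (t[1] < 1 || t[2] > n_bins || t[2] < t[1]) stop("TAD outside matrix")
    idx <- t[1]:t[2]
    m[idx, idx] <- intra_level
  }
  for (lp in loops) {
    i <- lp[1]; j <- lp[2]
    if (i < 1 || j < 1 || i > n_bins || j > n_bins)
      stop("loop pixel outside matrix")
    m[i, j] <- m[i, j] * lp[3]
    m[j, i] <- m[i, j]
  }
  if (noise) {
    m <- .with_seed(seed, {
      r <- matrix(stats::rpois(n_bins^2, m), n_bins)
      (r + t(r)) / 2   # keep symmetry
    })
  }
  contact_matrix(m, resolution = resolution, kind = "observed")
}
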