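#' Filter-cascade parameters for domain drafting
#'
#' The decoded state path is turned into domains by a cascade: keep runs of
#' more than `min_run - 1` consecutive domain states, merge runs closer than
#' `merge_gap`, keep merged regions with at least `min_fragments` positive
#' fragments, then merge survivors closer than `draft_merge_gap` into draft
#' domains.  The `main` preset holds the distances used for the standard
#' ON-vs-control comparison; the `degron` preset widens them (200 kb /
#' 2.5 Mb) for the acute-depletion comparisons, where domains fragment more.
#'
#' @param preset `"main"` or `"degron"`.
#' @param min_run minimal run length in fragments (21 = "more than 20").
#' @param merge_gap bp gap below which runs are merged.
#' @param min_fragments minimal positive-fragment count per merged region.
#' @param draft_merge_gap bp gap below which retained regions are merged
#'   into draft domains.
#' @return a `filter_params` list.
#' @export
filter_params <- function(preset = c("main", "degron"), min_run = 21,
                          merge_gap = NULL, min_fragments = 40,
                          draft_merge_gap = NULL) {
  preset <- match.arg(preset)
  if (is.null(merge_gap))
    merge_gap <- if (preset == "degron") 2e5 else 1e5
  if (is.null(draft_merge_gap))
    draft_merge_gap <- if (preset == "degron") 2.5e6 else 1.5e6
  if (min_run <= 0 || merge_gap <= 0 || min_fragments <= 0 ||
      draft_merge_gap <= 0)
    stop("all filter parameters must be positive")
  if (merge_gap > draft_merge_gap)
    stop("merge_gap cannot exceed draft_merge_gap")
  structure(list(preset = preset, min_run = min_run, merge_gap = merge_gap,
                 min_fragments = min_fragments,
                 draft_merge_gap = draft_merge_gap),
            class = "filter_params")
}

#' Retain sufficiently long domain-state runs
#'
#' @param states character state path from [decode_states()].
#' @param min_run minimal run length (a run of exactly `min_run` is kept).
#' @return data.frame with one row per retained run: `first`, `last`
#'   (observation indices) and `n_fragments`.
#' @export
filter_runs <- function(states, min_run = 21) {
  r <- rle(states == "domain")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run
  data.frame(first = starts[keep], last = ends[keep],
             n_fragments = r$lengths[keep])
}

#' Merge runs and draft domains
#'
#' Stage 1 merges retained runs whose genomic gap is at most `merge_gap`
#' (transitively, left to right); stage 2 drops merged regions carrying
#' fewer than `min_fragments` positive-state fragments; stage 3 merges
#' survivors whose gap is at most `draft_merge_gap` into draft domains.
#' Gaps are measured end-to-start in bp.
#'
#' @param runs data.frame from [filter_runs()].
#' @param starts,ends genomic start/end (bp) of each run, parallel to
#'   `runs` (derived from the fragment map of the observed fragments).
#' @param params a [filter_params()] object.
#' @return data.frame of draft domains: `start`, `end`, `n_positive`
#'   (positive fragments), and `provenance` (list column of contributing
#'   run intervals).
#' @export
merge_and_draft <- function(runs, starts, ends, params = filter_params()) {
  stopifnot(inherits(params, "filter_params"))
  n <- nrow(runs)
  if (n == 0)
    return(data.frame(start = numeric(0), end = numeric(0),
                      n_positive = integer(0)))
  ord <- order(starts)
  starts <- starts[ord]; ends <- ends[ord]
  n_frag <- runs$n_fragments[ord]
  merged <- .merge_by_gap(starts, ends, n_frag, params$merge_gap)
  merged <- merged[merged$n_positive >= params$min_fragments, , drop = FALSE]
  if (!nrow(merged)) {
    merged$provenance <- list()
    return(merged)
  }
  drafted <- .merge_by_gap(merged$start, merged$end, merged$n_positive,
                           params$draft_merge_gap)
  prov <- split(merged[, c("start", "end")],
                .gap_groups(merged$start, merged$end, params$draft_merge_gap))
  drafted$provenance <- unname(prov)
  drafted
}

.gap_groups <- function(starts, ends, gap) {
  if (!length(starts)) return(factor(integer(0)))
  gaps <- .gaps_bp(starts, ends)
  g <- cumsum(c(1L, as.integer(gaps > gap)))
  factor(g, levels = unique(g))   # keep genomic order, even past 9 groups
}

.merge_by_gap <- function(starts, ends, n_frag, gap) {
  g <- .gap_groups(starts, ends, gap)
  data.frame(start = as.numeric(tapply(starts, g, min)),
             end = as.numeric(tapply(ends, g, max)),
             n_positive = as.integer(tapply(n_frag, g, sum)),
             row.names = NULL)
}

#' Ensure the final domain contains its TetO integration
#'
#' If the TetO lies inside a draft domain that domain is returned unchanged.
#' Otherwise the draft segment nearest to the TetO is joined with the
#' nearest segment on the opposite side of the TetO, and the final domain
#' spans from the leftmost to the rightmost included segment (so the TetO
#' ends up inside).  With no segment on the opposite side, the nearest
#' domain is extended to the TetO position and a warning is raised.
#'
#' @param drafted data.frame of draft domains (`start`, `end`, ...).
#' @param teto_pos TetO position in bp.
#' @return one-row data.frame: `start`, `end`, `n_positive`, `rescued`.
#' @export
rescue_teto <- function(drafted, teto_pos) {
  if (!nrow(drafted)) stop("no draft domains to rescue")
  inside <- which(drafted$start <= teto_pos & drafted$end >= teto_pos)
  if (length(inside)) {
    d <- drafted[inside[1], c("start", "end", "n_positive"), drop = FALSE]
    d$rescued <- FALSE
    rownames(d) <- NULL
    return(d)
  }
  dist <- pmin(abs(drafted$start - teto_pos), abs(drafted$end - teto_pos))
  nearest <- which.min(dist)
  near_left <- drafted$end[nearest] < teto_pos
  opposite <- if (near_left) which(drafted$start > teto_pos)
              else which(drafted$end < teto_pos)
  if (!length(opposite)) {
    warning("no draft segment on the opposite side of TetO; ",
            "extending the nearest domain to the TetO position")
    d <- data.frame(start = min(drafted$start[nearest], teto_pos),
                    end = max(drafted$end[nearest], teto_pos),
                    n_positive = drafted$n_positive[nearest],
                    rescued = TRUE)
    return(d)
  }
  opp_dist <- pmin(abs(drafted$start[opposite] - teto_pos),
                   abs(drafted$end[opposite] - teto_pos))
  partner <- opposite[which.min(opp_dist)]
  picked <- c(nearest, partner)
  data.frame(start = min(drafted$start[picked]),
             end = max(drafted$end[picked]),
             n_positive = sum(drafted$n_positive[picked]),
             rescued = TRUE)
}

#' Call the induced looping domain of one TetO viewpoint
#'
#' End-to-end domain caller: normalize both conditions to reads per million,
#' smooth with a 21-fragment running mean, difference (ON minus control),
#' binarize at the threshold, decode the two-state HMM, apply the
#' run/merge/draft filter cascade, and rescue the TetO if it falls outside
#' the draft.  Raw profiles are normalized and smoothed on the way in;
#' already-smoothed profiles are used as given.
#'
#' @param on,control `fragment_profile`s (raw counts, or both smoothed) for
#'   the ON and control conditions on the same map and viewpoint.
#' @param preset filter preset, `"main"` or `"degron"` (see
#'   [filter_params()]).
#' @param hmm [hmm_params()] overrides.
#' @param filters [filter_params()] overrides; defaults follow `preset`.
#' @param region_half_width,target_total,smooth_window normalization and
#'   smoothing settings applied to raw input profiles.
#' @return a `tacl_domains` object: the final domain (zero rows when the
#'   null cascade retains nothing), draft segments, retained runs, and the
#'   parameters used.
#' @export
call_domains <- function(on, control, preset = c("main", "degron"),
                         hmm = hmm_params(), filters = NULL,
                         region_half_width = 1e7, target_total = 1e6,
                         smooth_window = 21) {
  preset <- match.arg(preset)
  if (is.null(filters)) filters <- filter_params(preset)
  if (on$stage == "raw") {
    on <- smooth_profile(normalize_viewpoint(on, region_half_width,
                                             target_total), smooth_window)
  }
  if (control$stage == "raw") {
    control <- smooth_profile(normalize_viewpoint(control, region_half_width,
                                                  target_total), smooth_window)
  }
  diff <- differential_profile(on, control)
  b <- binarize(diff, hmm$binarize_threshold)
  states <- decode_states(b$obs, hmm)
  runs <- filter_runs(states, filters$min_run)
  map_obs <- on$map[b$index]
  run_start <- GenomicRanges::start(map_obs)[runs$first]
  run_end <- GenomicRanges::end(map_obs)[runs$last]
  drafted <- merge_and_draft(runs, run_start, run_end, filters)
  domain <- if (nrow(drafted)) rescue_teto(drafted, on$teto_pos)
            else data.frame(start = numeric(0), end = numeric(0),
                            n_positive = integer(0), rescued = logical(0))
  structure(list(domain = domain, drafted = drafted,
                 runs = data.frame(start = run_start, end = run_end,
                                   n_fragments = runs$n_fragments),
                 chrom = as.character(GenomicRanges::seqnames(on$map))[1],
                 teto_pos = on$teto_pos, teto_id = on$teto_id,
                 preset = preset, hmm = hmm, filters = filters,
                 n_observed = length(b$obs),
                 n_positive_obs = sum(b$obs)),
            class = "tacl_domains")
}

#' @export
print.tacl_domains <- function(x, ...) {
  cat(sprintf("<tacl_domains> %s (%s preset)\n", x$teto_id, x$preset))
  if (nrow(x$domain)) {
    cat(sprintf("  domain: %s:%s-%s (%.2f Mb, %d positive fragments%s)\n",
                x$chrom, format(x$domain$start, big.mark = ","),
                format(x$domain$end, big.mark = ","),
                (x$domain$end - x$domain$start + 1) / 1e6,
                x$domain$n_positive,
                if (x$domain$rescued) ", TetO rescued" else ""))
  } else {
    cat("  no domain called\n")
  }
  cat(sprintf("  %d retained runs, %d draft segments, %d/%d positive observations\n",
              nrow(x$runs), nrow(x$drafted), x$n_positive_obs, x$n_observed))
  invisible(x)
}

#' @export
summary.tacl_domains <- function(object, ...) {
  d <- object$domain
  out <- list(teto_id = object$teto_id, preset = object$preset,
              called = nrow(d) > 0,
              size_mb = if (nrow(d)) (d$end - d$start + 1) / 1e6 else NA_real_,
              n_positive = if (nrow(d)) d$n_positive else 0L,
              rescued = if (nrow(d)) d$rescued else NA,
              n_draft_segments = nrow(object$drafted),
              n_runs = nrow(object$runs))
  class(out) <- "summary.tacl_domains"
  out
}

#' @export
print.summary.tacl_domains <- function(x, ...) {
  cat(sprintf("TACL domain call for %s (%s preset): %s\n", x$teto_id,
              x$preset,
              if (x$called) sprintf("%.2f Mb, %d positive fragments",
                                    x$size_mb, x$n_positive)
              else "no domain"))
  cat(sprintf("  draft segments: %d, retained runs: %d\n",
              x$n_draft_segments, x$n_runs))
  invisible(x)
}

#' Final domain as a GRanges
#'
#' @param x a `tacl_domains` object.
#' @return `GRanges` of length 0 or 1 with `teto_id`, `n_positive`,
#'   `rescued` metadata.
#' @export
domain_granges <- function(x) {
  stopifnot(inherits(x, "tacl_domains"))
  if (!nrow(x$domain)) return(GenomicRanges::GRanges())
  gr <- GenomicRanges::GRanges(x$chrom,
          IRanges::IRanges(x$domain$start, x$domain$end))
  gr$teto_id <- x$teto_id
  gr$n_positive <- x$domain$n_positive
  gr$rescued <- x$domain$rescued
  gr
}
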