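# Stratification of CTCF peaks: binding strength, motif orientation, and
# orientation relative to the TetO anchor (a convergent site faces the
# approaching extruding cohesin and can stall it; a divergent site points
# away).

#' Genome-wide CTCF reference set
#'
#' CTCF peaks suitable as a TACL-independent reference: outside every called
#' domain and at least `exclusion` bp (center-to-center) from every TetO
#' integration.
#'
#' @param peaks `GRanges` of CTCF peaks.
#' @param domains `GRanges` of called domains (may be empty).
#' @param tetos `GRanges` of TetO integration sites.
#' @param exclusion minimal distance from any TetO, in bp.
#' @return subset of `peaks`.
#' @export
genomewide_reference_set <- function(peaks, domains, tetos, exclusion = 3e6) {
  keep <- rep(TRUE, length(peaks))
  if (length(domains))
    keep <- !IRanges::overlapsAny(peaks, domains, ignore.strand = TRUE)
  if (length(tetos)) {
    pc <- .centers(peaks); tc <- .centers(tetos)
    pch <- as.character(GenomicRanges::seqnames(peaks))
    tch <- as.character(GenomicRanges::seqnames(tetos))
    for (i in seq_along(tetos)) {
      same <- pch == tch[i]
      keep <- keep & !(same & abs(pc - tc[i]) < exclusion)
    }
  }
  peaks[keep]
}

#' Stratify peaks into binding-strength tertiles
#'
#' Thresholds are the 33rd and 66th quantiles of the signal (linear
#' interpolation between order statistics, R's default type 7): below the
#' 33rd is `low`, between them (inclusive) is `medium`, above the 66th is
#' `high`.
#'
#' @param signal numeric signal values (>= 3 required).
#' @return factor over `low`, `medium`, `high`.
#' @export
strength_classes <- function(signal) {
  if (length(signal) < 3) stop("at least 3 peaks required for tertiles")
  q <- stats::quantile(signal, c(0.33, 0.66), type = 7, names = FALSE)
  cls <- ifelse(signal < q[1], "low", ifelse(signal > q[2], "high", "medium"))
  factor(cls, levels = c("low", "medium", "high"))
}

#' Assign motif orientation to peaks
#'
#' A peak whose overlapping motif hits all lie on the plus strand is
#' `forward`; all on the minus strand, `reverse`; both strands,
#' `ambiguous`; no hits, `none`.
#'
#' @param peaks `GRanges` of CTCF peaks.
#' @param hits `GRanges` of motif hits with strand `+`/`-`.
#' @return factor over `forward`, `reverse`, `ambiguous`, `none`.
#' @export
orient_peaks <- function(peaks, hits) {
  hs <- as.character(GenomicRanges::strand(hits))
  if (length(hits) && any(!hs %in% c("+", "-")))
    stop("motif hits must be stranded")
  out <- rep("none", length(peaks))
  ov <- GenomicRanges::findOverlaps(peaks, hits, ignore.strand = TRUE)
  if (length(ov)) {
    q <- S4Vectors::queryHits(ov)
    plus <- tapply(hs[S4Vectors::subjectHits(ov)] == "+",
                   factor(q, levels = seq_along(peaks)),
                   function(z) c(any(z), all(z)))
    for (i in which(!vapply(plus, is.null, TRUE))) {
      z <- plus[[i]]
      out[i] <- if (z[2]) "forward" else if (!z[1]) "reverse" else "ambiguous"
    }
  }
  factor(out, levels = c("forward", "reverse", "ambiguous", "none"))
}

#' Classify oriented sites as convergent or divergent to a TetO
#'
#' Upstream means a smaller coordinate than the TetO position.  A forward
#' site upstream, or a reverse site downstream, points toward the TetO:
#' convergent.  The mirror cases point away: divergent.  Sites without a
#' unique orientation, or exactly at the TetO position, are `unassigned`
#' (the latter with a warning).
#'
#' @param positions site positions in bp (typically peak centers).
#' @param orientation factor from [orient_peaks()].
#' @param teto_pos TetO position in bp.
#' @return factor over `convergent`, `divergent`, `unassigned`.
#' @export
classify_relative_to_teto <- function(positions, orientation, teto_pos) {
  stopifnot(length(positions) == length(orientation))
  orientation <- as.character(orientation)
  out <- rep("unassigned", length(positions))
  at <- positions == teto_pos
  if (any(at & orientation %in% c("forward", "reverse")))
    warning("site exactly at the TetO position left unassigned")
  up <- positions < teto_pos
  down <- positions > teto_pos
  out[(orientation == "forward" & up) | (orientation == "reverse" & down)] <-
    "convergent"
  out[(orientation == "reverse" & up) | (orientation == "forward" & down)] <-
    "divergent"
  factor(out, levels = c("convergent", "divergent", "unassigned"))
}

#' Assign sites to inner/outer domain zones
#'
#' After acute STAG2 depletion the TetO-proximal part of a domain collapses;
#' the collapsed region defines the inner domain, the remainder of the
#' original call the outer domain.  Inner domains must be nested within
#' outer domains.
#'
#' @param sites `GRanges` of sites.
#' @param inner,outer `GRanges` of inner and outer domains.
#' @return factor over `inner`, `outer`, `outside`.
#' @export
zone_assignment <- function(sites, inner, outer) {
  if (length(inner)) {
    nested <- IRanges::overlapsAny(inner, outer, type = "within",
                                   ignore.strand = TRUE)
    if (!all(nested))
      stop("inner domains must be nested within outer domains")
  }
  out <- rep("outside", length(sites))
  out[IRanges::overlapsAny(sites, outer, ignore.strand = TRUE)] <- "outer"
  out[IRanges::overlapsAny(sites, inner, ignore.strand = TRUE)] <- "inner"
  factor(out, levels = c("inner", "outer", "outside"))
}

#' Full CTCF site classification table
#'
#' Convenience wrapper: strength tertiles on the genome-wide reference
#' distribution, motif orientation, TetO-relative class and domain zone for
#' one viewpoint.
#'
#' @param peaks `GRanges` of CTCF peaks with `signalValue`.
#' @param hits `GRanges` of stranded motif hits.
#' @param teto_pos TetO position in bp (peaks are classified against it by
#'   their centers).
#' @param inner,outer optional `GRanges` of inner/outer domains.
#' @return data.frame with one row per peak: `center`, `signal`,
#'   `strength`, `orientation`, `teto_relation` and (when domains are
#'   given) `zone`.
#' @export
classify_ctcf_sites <- function(peaks, hits, teto_pos,
                                inner = NULL, outer = NULL) {
  stopifnot(!is.null(peaks$signalValue))
  ori <- orient_peaks(peaks, hits)
  ctr <- .centers(peaks)
  out <- data.frame(center = ctr, signal = peaks$signalValue,
                    strength = strength_classes(peaks$signalValue),
                    orientation = ori,
                    teto_relation = classify_relative_to_teto(ctr, ori,
                                                              teto_pos))
  if (!is.null(outer))
    out$zone <- zone_assignment(peaks,
                                if (is.null(inner)) GenomicRanges::GRanges()
                                else inner, outer)
  out
}
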