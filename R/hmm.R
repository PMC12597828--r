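#' Parameters of the two-state domain HMM
#'
#' The caller models each restriction fragment as emitting a binary
#' observation — differential 4C signal above or below a threshold — from one
#' of two hidden states, `domain` (inside the induced looping domain) and
#' `no_change`.  Emission probabilities were fixed from manually curated
#' domains: a domain fragment exceeds the threshold with probability 0.6,
#' a background fragment stays below it with probability 0.98.  The
#' symmetric switching probability of 1e-6 makes state changes expensive, so
#' only sustained stretches of elevated signal are decoded as domain.
#'
#' @param binarize_threshold differential signal (per-million units) above
#'   which a fragment observes "positive".
#' @param p_emit_pos_given_domain P(positive | domain).
#' @param p_emit_neg_given_nochange P(negative | no_change).
#' @param transition_prob probability of switching state between adjacent
#'   fragments (both directions).
#' @param initial_probs initial distribution over (no_change, domain).
#' @return an `hmm_params` list.
#' @export
hmm_params <- function(binarize_threshold = 25,
                       p_emit_pos_given_domain = 0.6,
                       p_emit_neg_given_nochange = 0.98,
                       transition_prob = 1e-6,
                       initial_probs = c(0.5, 0.5)) {
  p <- c(p_emit_pos_given_domain, p_emit_neg_given_nochange, transition_prob)
  if (any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly inside (0, 1)")
  if (transition_prob >= 0.5)
    stop("transition_prob must be below 0.5")
  if (length(initial_probs) != 2 || any(initial_probs <= 0))
    stop("initial_probs must be two positive probabilities")
  structure(list(binarize_threshold = binarize_threshold,
                 p_emit_pos_given_domain = p_emit_pos_given_domain,
                 p_emit_neg_given_nochange = p_emit_neg_given_nochange,
                 transition_prob = transition_prob,
                 initial_probs = initial_probs / sum(initial_probs)),
            class = "hmm_params")
}

#' Binarize differential 4C signal into HMM observations
#'
#' Fragments with difference strictly greater than the threshold observe
#' positive; differences less than or equal to it observe negative.  Missing
#' fragments are dropped, and the index map back to the full fragment vector
#' is retained so that decoded states can be placed on the genome.
#'
#' @param diff per-fragment signed differential signal (`NA` = missing).
#' @param threshold binarization threshold (default 25).
#' @return list with `obs` (logical, `TRUE` = positive) and `index`
#'   (positions of the observed fragments in `diff`).
#' @export
binarize <- function(diff, threshold = 25) {
  if (!length(diff)) stop("empty differential profile")
  idx <- which(!is.na(diff))
  if (!length(idx)) stop("no observed fragments after dropping missing values")
  list(obs = diff[idx] > threshold, index = idx)
}

#' Viterbi decoding of the two-state domain HMM
#'
#' Returns the maximum a posteriori state path under the two-state model,
#' computed in log space.  Deterministic: repeated calls give identical
#' output.
#'
#' @param obs logical observation vector (`TRUE` = positive) as produced by
#'   [binarize()].
#' @param params an [hmm_params()] object.
#' @return character vector over `"no_change"`, `"domain"`, one per
#'   observation.
#' @export
decode_states <- function(obs, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  if (!length(obs)) stop("empty observation sequence")
  obs <- as.logical(obs)
  n <- length(obs)
  # state 1 = no_change, state 2 = domain
  le <- log(matrix(c(params$p_emit_neg_given_nochange,
                     1 - params$p_emit_pos_given_domain,
                     1 - params$p_emit_neg_given_nochange,
                     params$p_emit_pos_given_domain),
                   nrow = 2))                      # le[state, obs+1]
  lstay <- log(1 - params$transition_prob)
  lswitch <- log(params$transition_prob)
  v <- log(params$initial_probs) + le[, obs[1] + 1L]
  bp <- matrix(NA_integer_, 2, n)
  for (t in seq_len(n)[-1]) {
    e <- le[, obs[t] + 1L]
    # candidate scores arriving in each state
    from1 <- c(v[1] + lstay, v[1] + lswitch)   # no_change -> (1, 2)
    from2 <- c(v[2] + lswitch, v[2] + lstay)   # domain    -> (1, 2)
    pick <- ifelse(from1 >= from2, 1L, 2L)
    v <- pmax(from1, from2) + e
    bp[, t] <- pick
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (t in rev(seq_len(n)[-1])) path[t - 1L] <- bp[path[t], t]
  c("no_change", "domain")[path]
}
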