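# Shared fixtures and independent oracles, built in code.

# 1-based GRanges shorthand
gr1 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
}

# step track with a score column
make_track <- function(start, end, score, chrom = "chrT") {
  gr <- gr1(chrom, start, end)
  gr$score <- score
  gr
}

# peaks with signalValue (and optional summit)
make_peaks <- function(start, end, signal, chrom = "chrT", summit = NULL) {
  gr <- gr1(chrom, start, end)
  gr$signalValue <- signal
  if (!is.null(summit)) gr$summit <- summit
  gr
}

# fragment map with explicit fragment length and no blind fragments,
# for deterministic pipeline fixtures
uniform_map <- function(n, len = 256, chrom = "chrS") {
  ends <- len * seq_len(n)
  gr <- gr1(chrom, ends - len + 1, ends)
  gr$blind <- rep(FALSE, n)
  gr
}

# Brute-force HMM oracle: enumerate all 2^n state paths and score them in
# log space, independently of the Viterbi recursion under test.
# obs_mat: m x n logical matrix (rows = observation sequences).
# Returns list(best_score, best_path) with best_path an m x n matrix
# (TRUE = domain).
brute_force_decode <- function(obs_mat, params = taclr::hmm_params()) {
  obs_mat <- matrix(as.numeric(obs_mat), nrow = NROW(obs_mat))
  n <- ncol(obs_mat)
  paths <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))  # 2^n x n
  nsw <- if (n > 1)
    rowSums(paths[, -1, drop = FALSE] != paths[, -n, drop = FALSE])
  else rep(0, nrow(paths))
  ltrans <- nsw * log(params$transition_prob) +
    (n - 1 - nsw) * log(1 - params$transition_prob)
  linit <- log(params$initial_probs[1]) * (1 - paths[, 1]) +
    log(params$initial_probs[2]) * paths[, 1]
  # emission log-probs per position per obs sequence (n x m)
  e_dom <- t(obs_mat * log(params$p_emit_pos_given_domain) +
             (1 - obs_mat) * log(1 - params$p_emit_pos_given_domain))
  e_nc <- t(obs_mat * log(1 - params$p_emit_neg_given_nochange) +
            (1 - obs_mat) * log(params$p_emit_neg_given_nochange))
  scores <- paths %*% e_dom + (1 - paths) %*% e_nc + ltrans + linit
  best <- apply(scores, 2, which.max)
  list(best_score = scores[cbind(best, seq_len(ncol(scores)))],
       best_path = paths[best, , drop = FALSE] == 1)
}

# log-probability of one state path (TRUE = domain) for one obs sequence
path_log_prob <- function(obs, path, params = taclr::hmm_params()) {
  obs <- as.numeric(obs); path <- as.numeric(path)
  n <- length(obs)
  e <- ifelse(path == 1,
              obs * log(params$p_emit_pos_given_domain) +
                (1 - obs) * log(1 - params$p_emit_pos_given_domain),
              obs * log(1 - params$p_emit_neg_given_nochange) +
                (1 - obs) * log(params$p_emit_neg_given_nochange))
  nsw <- if (n > 1) sum(path[-1] != path[-n]) else 0
  sum(e) + nsw * log(params$transition_prob) +
    (n - 1 - nsw) * log(1 - params$transition_prob) +
    log(params$initial_probs[path[1] + 1])
}
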