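# Small in-code fixtures and independent oracles shared across tests.

# A tiny hand-checkable profile matrix.
toy_pm <- function(abund = NULL, groups = c("case", "case", "control", "control")) {
  if (is.null(abund))
    abund <- matrix(c(10, 12, 0, 1,
                      5, 0, 6, 7,
                      3, 3, 3, 3),
                    nrow = 3, byrow = TRUE)
  profile_matrix(abund,
                 compounds = data.frame(compound_id = paste0("c", seq_len(nrow(abund))),
                                        mass = 100 + seq_len(nrow(abund))),
                 sample_ids = paste0("s", seq_len(ncol(abund))),
                 groups = groups)
}

# Exact two-sided rank-sum p by full enumeration of all case/control
# relabelings of the pooled values (handles ties; independent of the
# package's computation path).
enumerate_rank_sum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  stat <- function(idx) abs(sum(r[idx]) - n1 * (length(pooled) + 1) / 2)
  obs <- stat(seq_len(n1))
  combos <- utils::combn(length(pooled), n1)
  stats <- apply(combos, 2, stat)
  mean(stats >= obs - 1e-9)
}

# AUC as the Mann-Whitney concordance probability, ties counted one half.
concordance_auc <- function(values, labels) {
  cs <- values[labels == "case"]
  ct <- values[labels == "control"]
  pairs <- outer(cs, ct, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Brute-force Youden maximisation over all midpoint cutoffs.
brute_force_best_j <- function(values, labels) {
  is_case <- labels == "case"
  s <- sort(unique(values))
  cand <- c(min(s) - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
            max(s) + 1)
  j <- vapply(cand, function(t)
    mean(values[is_case] >= t) + mean(values[!is_case] < t) - 1, numeric(1))
  max(j)
}
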