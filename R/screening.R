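# Per-compound univariate screening: normality gate, rank-sum test with
# Bonferroni correction, detection-frequency filter, and the combined
# two-phase screen.

# Core two-sided rank-sum p-value from the Mann-Whitney U of x and the
# pooled tie pattern. Exact enumeration (pwilcox) for small untied samples,
# tie- and continuity-corrected normal approximation otherwise.
.rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  tie_sizes <- tabulate(match(pooled, pooled))
  has_ties <- any(tie_sizes > 1)
  if (n1 + n2 <= 20 && !has_ties) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE))
    return(min(p, 1))
  }
  tie_sum <- sum(tie_sizes^3 - tie_sizes)  # sum over tie groups of t^3 - t
  z <- u - n1 * n2 / 2
  sigma2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - tie_sum / ((n1 + n2) * (n1 + n2 - 1)))
  if (sigma2 <= 0) return(1)  # all pooled values identical
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(2 * stats::pnorm(-abs(z)), 1)
}

#' Two-sided Wilcoxon rank-sum test p-value
#'
#' Tests whether the case and control abundance distributions differ in
#' location. Uses the exact null distribution of the Mann-Whitney U
#' statistic when the pooled sample has at most 20 untied values, and the
#' tie- and continuity-corrected normal approximation otherwise.
#'
#' @param x numeric vector of case values (non-empty).
#' @param y numeric vector of control values (non-empty).
#' @return A two-sided p-value in (0, 1].
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))  # 0.1 by exact enumeration
#' @export
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("abundances must be finite")
  .rank_sum_p(x, y)
}

# Row-wise rank-sum p-values for a compounds x samples matrix. One pass per
# compound; kept free of per-call validation so the LOOCV loop stays cheap.
.rank_sum_p_rows <- function(X, is_case) {
  n1 <- sum(is_case); n2 <- sum(!is_case)
  ord <- c(which(is_case), which(!is_case))
  X <- X[, ord, drop = FALSE]
  vapply(seq_len(nrow(X)), function(i) {
    v <- X[i, ]
    .rank_sum_p(v[seq_len(n1)], v[n1 + seq_len(n2)])
  }, numeric(1))
}

#' Bonferroni per-test significance threshold
#'
#' @param alpha family-wise error level in (0, 1).
#' @param m number of tests (>= 1).
#' @return \code{alpha / m}; e.g. 0.05 over 922 compounds gives 5.42e-5.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!length(m) || anyNA(m) || any(m < 1)) stop("'m' must be a positive count")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  alpha / m
}

#' Detection fraction of a compound among case samples
#'
#' A compound is only a usable marker if it is detected (abundance > 0) in
#' most case samples; this computes the detected fraction and applies a
#' strict cutoff ("more than 60 percent" means fraction > 0.6, not >=).
#'
#' @param pm a \code{profile_matrix}.
#' @param compound_id compound to assess.
#' @param case_ids sample ids over which to count detections.
#' @param cutoff strict lower bound on the detected fraction.
#' @return List with \code{fraction} and logical \code{passed}.
#' @export
detection_fraction_filter <- function(pm, compound_id, case_ids, cutoff = 0.6) {
  stopifnot(inherits(pm, "profile_matrix"))
  if (!compound_id %in% pm$compounds$compound_id)
    stop("unknown compound_id: ", compound_id)
  if (!length(case_ids)) stop("'case_ids' must be non-empty")
  missing <- setdiff(case_ids, pm$sample_ids)
  if (length(missing))
    stop("unknown sample id(s): ", paste(missing, collapse = ", "))
  frac <- mean(pm$abundance[compound_id, case_ids] > 0)
  list(fraction = frac, passed = frac > cutoff)
}

#' Two-phase candidate screen on a training cohort
#'
#' Phase 1 applies the Wilcoxon rank-sum test to every compound and keeps
#' those with p below the Bonferroni threshold \code{alpha / m}, where m is
#' the total number of compounds tested. Phase 2 keeps phase-1 survivors
#' detected in strictly more than \code{cutoff} of the training case
#' samples.
#'
#' @param pm a training \code{profile_matrix} containing both groups.
#' @param alpha family-wise level for the Bonferroni correction.
#' @param cutoff strict detection-fraction cutoff over case samples.
#' @return A data.frame of class \code{screening_result}, one row per
#'   compound, sorted by ascending p-value, with columns
#'   \code{compound_id}, \code{p_value}, \code{alpha_adjusted},
#'   \code{detection_fraction_case}, \code{passed_phase1},
#'   \code{passed_phase2}.
#' @export
screen_candidates <- function(pm, alpha = 0.05, cutoff = 0.6) {
  stopifnot(inherits(pm, "profile_matrix"))
  is_case <- pm$groups == "case"
  if (!any(is_case) || all(is_case)) stop("training matrix needs both groups")
  m <- nrow(pm$abundance)
  thr <- bonferroni_threshold(alpha, m)
  p <- .rank_sum_p_rows(pm$abundance, is_case)
  det <- rowMeans(pm$abundance[, is_case, drop = FALSE] > 0)
  res <- data.frame(compound_id = pm$compounds$compound_id,
                    p_value = p,
                    alpha_adjusted = thr,
                    detection_fraction_case = det,
                    passed_phase1 = p < thr,
                    stringsAsFactors = FALSE)
  res$passed_phase2 <- res$passed_phase1 & det > cutoff
  res <- res[order(res$p_value), ]
  rownames(res) <- NULL
  class(res) <- c("screening_result", "data.frame")
  res
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test per compound within each group and reports a
#' dataset-level verdict: \code{"non-normal"} if the smallest
#' Bonferroni-adjusted p-value is below 0.05, otherwise
#' \code{"not-rejected"}. The verdict is advisory only — the screening
#' pipeline is unconditionally nonparametric, as zero-inflated peak tables
#' essentially never pass a normality test. Compounds that are constant
#' within a group (commonly all-zero) have an undefined p there; these are
#' recorded as \code{NA}, not errors.
#'
#' @param pm a \code{profile_matrix}.
#' @return List with \code{table} (compound_id, p_case, p_control),
#'   \code{verdict}, and \code{min_p_adjusted}.
#' @export
shapiro_wilk_gate <- function(pm) {
  stopifnot(inherits(pm, "profile_matrix"))
  is_case <- pm$groups == "case"
  sw <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || length(v) > 5000 || length(unique(v)) == 1)
      return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  p_case <- apply(pm$abundance[, is_case, drop = FALSE], 1, sw)
  p_control <- apply(pm$abundance[, !is_case, drop = FALSE], 1, sw)
  all_p <- c(p_case, p_control)
  n_tests <- sum(!is.na(all_p))
  min_adj <- if (n_tests) min(pmin(all_p * n_tests, 1), na.rm = TRUE) else NA_real_
  list(table = data.frame(compound_id = pm$compounds$compound_id,
                          p_case = unname(p_case),
                          p_control = unname(p_control),
                          stringsAsFactors = FALSE),
       verdict = if (!is.na(min_adj) && min_adj < 0.05) "non-normal" else "not-rejected",
       min_p_adjusted = min_adj)
}

#' Pearson chi-square test for a 2x2 demographics table
#'
#' Compares a categorical variable between two cohorts (e.g. gender or
#' hematuria by diagnosis) with the Pearson chi-square test on 1 degree of
#' freedom, without continuity correction.
#'
#' @param counts 2x2 matrix of non-negative integer counts; both row and
#'   column margins must be positive.
#' @return List with \code{statistic}, \code{p_value} and \code{df}.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) stop("'counts' must be a 2x2 table")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("both margins must be positive")
  ht <- stats::chisq.test(counts, correct = FALSE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
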