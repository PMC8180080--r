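# Leave-one-out cross-validated marker discovery: per-round two-phase
# screening on n-1 samples, round-specific classifying thresholds, held-out
# predictions, intersection of the n candidate lists, and contaminant
# exclusion.

# Per-compound sufficient statistics for leave-one-out rank-sum screening.
# Removing one sample changes the Mann-Whitney U by exactly that sample's
# pairwise contribution and shrinks its tie group by one, so each round's
# statistic is recovered in O(1) per compound from these precomputed
# counts rather than by re-ranking n-1 values.
.loocv_stats <- function(abund, is_case) {
  n1 <- sum(is_case)
  m <- nrow(abund)
  n <- ncol(abund)
  U <- numeric(m); S <- numeric(m)
  drop_contrib <- matrix(0, m, n)  # U lost when dropping each sample
  tie_size <- matrix(0L, m, n)     # pooled tie-group size of each sample
  for (i in seq_len(m)) {
    v <- abund[i, ]
    r <- rank(v)
    U[i] <- sum(r[is_case]) - n1 * (n1 + 1) / 2
    sc <- sort(v[is_case]); sct <- sort(v[!is_case])
    leq_case <- findInterval(v, sc)
    lt_case <- findInterval(v, sc, left.open = TRUE)
    eq_case <- leq_case - lt_case
    leq_ctrl <- findInterval(v, sct)
    lt_ctrl <- findInterval(v, sct, left.open = TRUE)
    eq_ctrl <- leq_ctrl - lt_ctrl
    # dropping a case removes its (case, control) pairs; dropping a control
    # removes every case's pairs against it
    drop_contrib[i, ] <- ifelse(is_case,
                                lt_ctrl + 0.5 * eq_ctrl,
                                (n1 - leq_case) + 0.5 * eq_case)
    t_j <- eq_case + eq_ctrl
    tie_size[i, ] <- t_j
    S[i] <- sum(t_j^2 - 1)  # = sum over tie groups of t^3 - t
  }
  list(U = U, S = S, drop_contrib = drop_contrib, tie_size = tie_size,
       det_count_case = rowSums(abund[, is_case, drop = FALSE] > 0))
}

# Vectorised two-sided rank-sum p-values for one LOOCV round, from the
# leave-one-out statistics. Matches .rank_sum_p branch for branch.
.loocv_round_p <- function(stats, j, heldout_is_case, n1, n2) {
  u <- stats$U - stats$drop_contrib[, j]
  t_j <- stats$tie_size[, j]
  s <- stats$S - (t_j^3 - t_j) + ((t_j - 1)^3 - (t_j - 1))
  if (heldout_is_case) n1 <- n1 - 1 else n2 <- n2 - 1
  N <- n1 + n2
  p <- numeric(length(u))
  exact <- N <= 20 & s == 0
  if (any(exact))
    p[exact] <- pmin(1, 2 * pmin(
      stats::pwilcox(u[exact], n1, n2),
      stats::pwilcox(u[exact] - 1, n1, n2, lower.tail = FALSE)))
  if (any(!exact)) {
    z <- u[!exact] - n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - s[!exact] / (N * (N - 1)))
    zc <- (z - sign(z) * 0.5) / sqrt(sigma2)
    p[!exact] <- ifelse(sigma2 <= 0, 1, pmin(2 * stats::pnorm(-abs(zc)), 1))
  }
  p
}

# Screen + threshold one LOOCV round by direct re-ranking of the n-1
# training samples; the reference implementation the incremental path is
# tested against.
.loocv_round <- function(pm, heldout_idx, alpha, cutoff) {
  train_ids <- pm$sample_ids[-heldout_idx]
  groups_tr <- pm$groups[-heldout_idx]
  if (length(unique(groups_tr)) < 2)
    stop("training set of round ", heldout_idx, " lost a group")
  abund_tr <- pm$abundance[, -heldout_idx, drop = FALSE]
  is_case_tr <- groups_tr == "case"

  m <- nrow(abund_tr)
  thr <- alpha / m
  p <- .rank_sum_p_rows(abund_tr, is_case_tr)
  pass1 <- p < thr
  det <- rowMeans(abund_tr[, is_case_tr, drop = FALSE] > 0)
  pass2 <- pass1 & det > cutoff
  cand_idx <- which(pass2)[order(p[pass2])]

  .round_result(pm, heldout_idx, cand_idx)
}

# Fit per-candidate Youden thresholds on the round's training samples and
# predict the held-out sample.
.round_result <- function(pm, heldout_idx, cand_idx) {
  groups_tr <- as.character(pm$groups[-heldout_idx])
  heldout_abund <- pm$abundance[, heldout_idx]
  thresholds <- vapply(cand_idx, function(i) {
    roc <- roc_curve(pm$abundance[i, -heldout_idx], groups_tr)
    select_threshold(roc)$threshold
  }, numeric(1))
  list(heldout_sample_id = pm$sample_ids[heldout_idx],
       heldout_true_group = as.character(pm$groups[heldout_idx]),
       compound_id = pm$compounds$compound_id[cand_idx],
       threshold = thresholds,
       prediction = ifelse(heldout_abund[cand_idx] >= thresholds,
                           "case", "control"))
}

#' Leave-one-out cross-validated candidate screening
#'
#' Runs one round per discovery sample: the two-phase screen (Bonferroni-
#' corrected rank-sum test, then the detection-frequency filter) is fit on
#' the remaining n-1 samples, each surviving candidate gets a classifying
#' threshold selected on those training samples by Youden's J, and the
#' held-out sample is predicted case iff its abundance reaches the
#' threshold. The detection filter is computed on the round's training case
#' samples, keeping every training quantity blind to the held-out sample.
#'
#' @param pm the discovery-cohort \code{profile_matrix} (>= 4 samples, both
#'   groups present).
#' @param alpha family-wise level for the per-round Bonferroni screen.
#' @param cutoff strict detection-fraction cutoff over training case
#'   samples.
#' @param method \code{"incremental"} (default) derives each round's
#'   rank-sum statistic from precomputed leave-one-out sufficient
#'   statistics; \code{"direct"} re-ranks the n-1 training samples every
#'   round. The two are algebraically identical; \code{"direct"} is the
#'   plain-reading reference implementation.
#' @return A list of n rounds; each round is a list with
#'   \code{heldout_sample_id}, \code{heldout_true_group}, and parallel
#'   vectors \code{compound_id}, \code{threshold}, \code{prediction}.
#' @export
run_loocv <- function(pm, alpha = 0.05, cutoff = 0.6,
                      method = c("incremental", "direct")) {
  stopifnot(inherits(pm, "profile_matrix"))
  method <- match.arg(method)
  n <- length(pm$sample_ids)
  if (n < 4) stop("discovery cohort must have at least 4 samples")
  if (method == "direct")
    return(lapply(seq_len(n), function(i) .loocv_round(pm, i, alpha, cutoff)))

  is_case <- pm$groups == "case"
  n1 <- sum(is_case); n2 <- n - n1
  if (n1 < 2 || n2 < 2)
    stop("each group needs at least 2 samples so no round loses a group")
  stats <- .loocv_stats(pm$abundance, is_case)
  thr <- alpha / nrow(pm$abundance)
  lapply(seq_len(n), function(j) {
    hc <- is_case[j]
    p <- .loocv_round_p(stats, j, hc, n1, n2)
    det_cnt <- stats$det_count_case - if (hc) (pm$abundance[, j] > 0) else 0
    det <- det_cnt / (n1 - hc)
    pass <- p < thr & det > cutoff
    cand_idx <- which(pass)[order(p[pass])]
    .round_result(pm, j, cand_idx)
  })
}

#' Intersect candidate lists and drop contaminants
#'
#' Keeps the compounds present in every round's candidate list, then
#' removes compounds flagged as GC-MS background contaminants. The
#' surviving markers are ordered by ascending rank-sum p-value on the full
#' discovery cohort.
#'
#' @param rounds output of [run_loocv()].
#' @param pm the discovery \code{profile_matrix} (supplies contaminant
#'   flags and the ordering p-values).
#' @return Character vector of marker compound ids (possibly empty, with a
#'   warning).
#' @export
intersect_and_exclude <- function(rounds, pm) {
  stopifnot(inherits(pm, "profile_matrix"), length(rounds) >= 1)
  ids <- Reduce(intersect, lapply(rounds, `[[`, "compound_id"))
  contam <- pm$compounds$compound_id[pm$compounds$is_contaminant]
  ids <- setdiff(ids, contam)
  if (!length(ids)) {
    warning("candidate intersection is empty: no stable markers")
    return(character(0))
  }
  is_case <- pm$groups == "case"
  p_full <- vapply(ids, function(cid)
    .rank_sum_p(pm$abundance[cid, is_case], pm$abundance[cid, !is_case]),
    numeric(1))
  ids[order(p_full)]
}

#' Per-marker LOOCV classification performance
#'
#' Pools each marker's n held-out predictions across rounds into a
#' confusion matrix against the true groups.
#'
#' @param rounds output of [run_loocv()].
#' @param marker_ids compounds that must be present in every round's
#'   candidate list.
#' @return data.frame with one row per marker: \code{compound_id},
#'   \code{accuracy}, \code{sensitivity}, \code{specificity}.
#' @export
summarize_marker_performance <- function(rounds, marker_ids) {
  truth <- vapply(rounds, `[[`, character(1), "heldout_true_group")
  res <- lapply(marker_ids, function(cid) {
    pred <- vapply(rounds, function(r) {
      j <- match(cid, r$compound_id)
      if (is.na(j))
        stop("marker '", cid, "' missing from the round holding out ",
             r$heldout_sample_id)
      r$prediction[j]
    }, character(1))
    is_case <- truth == "case"
    data.frame(compound_id = cid,
               accuracy = mean(pred == truth),
               sensitivity = mean(pred[is_case] == "case"),
               specificity = mean(pred[!is_case] == "control"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Discover putative markers by LOOCV-embedded two-phase screening
#'
#' The main fitting function: given a discovery cohort, runs the full
#' leave-one-out screening loop, intersects the per-round candidate lists,
#' excludes flagged contaminants, summarises per-marker LOOCV performance,
#' derives each marker's final classifying threshold on the whole discovery
#' cohort, and fits the logistic-regression marker panel.
#'
#' @param pm the discovery-cohort \code{profile_matrix}.
#' @param alpha family-wise level for the Bonferroni-corrected rank-sum
#'   screen (default 0.05; over 922 compounds this is the 5.42e-5 per-test
#'   threshold).
#' @param cutoff strict detection-fraction cutoff over case samples
#'   (default 0.6: detected in more than 60 percent of case samples).
#' @param ridge ridge strength for the panel fit; default \code{1e-6 * n}.
#' @param log1p_transform passed to [fit_logistic_panel()].
#' @return An object of class \code{marker_discovery}: list with
#'   \code{marker_ids}, \code{performance} (per-marker LOOCV metrics),
#'   \code{thresholds} (per-marker discovery-cohort classifying threshold
#'   with its training sensitivity/specificity and AUC), \code{rounds},
#'   \code{panel} (a \code{marker_panel}, or NULL if no marker survived),
#'   \code{alpha}, \code{cutoff}, \code{n_compounds},
#'   \code{alpha_adjusted}.
#' @examples
#' sim <- simulate_profile(synthetic_config(n_case = 12, n_control = 12,
#'                                          m_compounds = 60, n_markers = 2,
#'                                          n_contaminants = 2, seed = 3))
#' fit <- discover_markers(sim$pm)
#' fit$marker_ids
#' @export
discover_markers <- function(pm, alpha = 0.05, cutoff = 0.6, ridge = NULL,
                             log1p_transform = FALSE) {
  stopifnot(inherits(pm, "profile_matrix"))
  rounds <- run_loocv(pm, alpha = alpha, cutoff = cutoff)
  marker_ids <- intersect_and_exclude(rounds, pm)
  performance <- if (length(marker_ids))
    summarize_marker_performance(rounds, marker_ids) else NULL

  thresholds <- NULL
  panel <- NULL
  if (length(marker_ids)) {
    thresholds <- do.call(rbind, lapply(marker_ids, function(cid) {
      roc <- roc_curve(pm$abundance[cid, ], as.character(pm$groups))
      sel <- select_threshold(roc)
      data.frame(compound_id = cid,
                 metabolite = pm$compounds$metabolite[
                   match(cid, pm$compounds$compound_id)],
                 classifying_threshold = sel$threshold,
                 train_sensitivity = sel$sensitivity,
                 train_specificity = sel$specificity,
                 train_auc = roc$auc,
                 stringsAsFactors = FALSE)
    }))
    panel <- fit_logistic_panel(pm, marker_ids, ridge = ridge,
                                log1p_transform = log1p_transform)
  }
  structure(list(marker_ids = marker_ids, performance = performance,
                 thresholds = thresholds, rounds = rounds, panel = panel,
                 alpha = alpha, cutoff = cutoff,
                 n_compounds = nrow(pm$abundance),
                 alpha_adjusted = alpha / nrow(pm$abundance),
                 n_samples = length(pm$sample_ids)),
            class = "marker_discovery")
}

#' @export
print.marker_discovery <- function(x, ...) {
  cat("marker_discovery: ", length(x$rounds), " LOOCV rounds over ",
      x$n_compounds, " compounds\n", sep = "")
  cat(sprintf("  per-test Bonferroni threshold: %.3g (alpha = %g)\n",
              x$alpha_adjusted, x$alpha))
  cat(sprintf("  detection cutoff: > %g of case samples\n", x$cutoff))
  cat("  stable markers after intersection and contaminant removal: ",
      length(x$marker_ids), "\n", sep = "")
  if (length(x$marker_ids))
    cat("    ", paste(x$marker_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.marker_discovery <- function(object, ...) {
  sizes <- lengths(lapply(object$rounds, `[[`, "compound_id"))
  out <- list(n_rounds = length(object$rounds),
              candidate_list_sizes = range(sizes),
              marker_ids = object$marker_ids,
              performance = object$performance,
              thresholds = object$thresholds,
              panel_train_auc = if (!is.null(object$panel))
                object$panel$roc_train$auc else NA_real_)
  class(out) <- "summary.marker_discovery"
  out
}

#' @export
print.summary.marker_discovery <- function(x, ...) {
  cat("LOOCV rounds:", x$n_rounds, " (candidate list sizes ",
      x$candidate_list_sizes[1], "-", x$candidate_list_sizes[2], ")\n", sep = "")
  if (!is.null(x$performance)) {
    cat("\nPer-marker LOOCV performance:\n")
    print(x$performance, row.names = FALSE)
    cat("\nDiscovery-cohort classifying thresholds:\n")
    print(x$thresholds, row.names = FALSE)
    cat(sprintf("\nPanel training AUC: %.3f\n", x$panel_train_auc))
  } else cat("\nNo stable markers found.\n")
  invisible(x)
}

#' Evaluate discovered markers on an independent test cohort
#'
#' Applies each marker's discovery-derived classifying threshold to the
#' test cohort and evaluates the logistic panel's ROC there, mirroring the
#' independent-validation step of the workflow.
#'
#' @param fit a \code{marker_discovery} object.
#' @param pm_test the independent-test \code{profile_matrix}.
#' @return List with \code{per_marker} (data.frame: compound_id,
#'   metabolite, accuracy, sensitivity, specificity,
#'   classifying_threshold) and \code{panel_roc} (a \code{roc_result}).
#' @export
evaluate_markers <- function(fit, pm_test) {
  stopifnot(inherits(fit, "marker_discovery"),
            inherits(pm_test, "profile_matrix"))
  if (!length(fit$marker_ids)) stop("no markers to evaluate")
  per_marker <- do.call(rbind, lapply(seq_along(fit$marker_ids), function(i) {
    cid <- fit$marker_ids[i]
    thr <- fit$thresholds$classifying_threshold[i]
    m <- apply_threshold_classifier(pm_test, cid, thr)
    data.frame(compound_id = cid,
               metabolite = fit$thresholds$metabolite[i],
               accuracy = m$accuracy, sensitivity = m$sensitivity,
               specificity = m$specificity, classifying_threshold = thr,
               stringsAsFactors = FALSE)
  }))
  list(per_marker = per_marker,
       panel_roc = evaluate_panel(fit$panel, pm_test))
}

#' Write per-round candidate lists as TSV
#'
#' One row per (round, candidate): columns \code{round},
#' \code{heldout_sample}, \code{compound_id}, \code{threshold},
#' \code{prediction}, \code{truth}.
#'
#' @param rounds output of [run_loocv()] (or the \code{rounds} element of a
#'   \code{marker_discovery}).
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_rounds <- function(rounds, path) {
  rows <- lapply(seq_along(rounds), function(i) {
    r <- rounds[[i]]
    if (!length(r$compound_id)) return(NULL)
    data.frame(round = i, heldout_sample = r$heldout_sample_id,
               compound_id = r$compound_id, threshold = r$threshold,
               prediction = r$prediction, truth = r$heldout_true_group,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(round = integer(0), heldout_sample = character(0),
                     compound_id = character(0), threshold = numeric(0),
                     prediction = character(0), truth = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
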