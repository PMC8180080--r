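test_that("LOOCV runs one round per sample, each blind to its held-out sample", {
  sim <- simulate_profile(synthetic_config(n_case = 10, n_control = 10,
                                           m_compounds = 50, n_markers = 2,
                                           n_contaminants = 1, seed = 31))
  rounds <- run_loocv(sim$pm)
  expect_length(rounds, 20)
  expect_setequal(vapply(rounds, `[[`, character(1), "heldout_sample_id"),
                  sim$pm$sample_ids)

  # leakage freedom: perturbing only the held-out sample's abundances never
  # changes that round's candidate list or thresholds
  pm_mut <- sim$pm
  j <- 7
  pm_mut$abundance[, j] <- pm_mut$abundance[, j] * 50 + 123
  r_orig <- rounds[[j]]
  r_mut <- run_loocv(pm_mut)[[j]]
  expect_identical(r_orig$compound_id, r_mut$compound_id)
  expect_identical(r_orig$threshold, r_mut$threshold)
})

test_that("incremental and direct LOOCV implementations agree exactly", {
  for (s in c(3, 17)) {
    sim <- simulate_profile(synthetic_config(n_case = 9, n_control = 8,
                                             m_compounds = 45, n_markers = 3,
                                             n_contaminants = 2,
                                             detect_p_background = 0.6,
                                             seed = s))
    fast <- run_loocv(sim$pm, alpha = 0.5, cutoff = 0.3, method = "incremental")
    slow <- run_loocv(sim$pm, alpha = 0.5, cutoff = 0.3, method = "direct")
    expect_identical(fast, slow)
  }
  # and at a tiny n where the exact rank-sum branch is in play
  sim <- simulate_profile(synthetic_config(n_case = 5, n_control = 5,
                                           m_compounds = 30, n_markers = 2,
                                           n_contaminants = 0,
                                           detect_p_background = 1,
                                           detection_limit = 0, seed = 23))
  expect_identical(run_loocv(sim$pm, alpha = 0.9, cutoff = 0.1),
                   run_loocv(sim$pm, alpha = 0.9, cutoff = 0.1, method = "direct"))
})

test_that("a perfectly separating compound survives every round of a toy LOOCV", {
  abund <- rbind(c(100, 120, 110, 1, 0, 2),     # perfect separator
                 c(5, 0, 6, 5, 0, 6))           # identical in both groups
  pm <- profile_matrix(abund, data.frame(compound_id = c("sep", "flat")),
                       paste0("s", 1:6), rep(c("case", "control"), each = 3))
  rounds <- run_loocv(pm, alpha = 0.9, cutoff = 0.5)
  expect_true(all(vapply(rounds, function(r) "sep" %in% r$compound_id,
                         logical(1))))
  # all 6 held-out predictions for the separator are correct
  pred <- vapply(rounds, function(r)
    r$prediction[match("sep", r$compound_id)], character(1))
  truth <- vapply(rounds, `[[`, character(1), "heldout_true_group")
  expect_identical(pred, truth)
})

test_that("intersection and contaminant exclusion", {
  pm <- toy_pm()
  pm$compounds$is_contaminant <- c(FALSE, TRUE, FALSE)
  mk_round <- function(ids) list(heldout_sample_id = "x",
                                 heldout_true_group = "case",
                                 compound_id = ids,
                                 threshold = rep(1, length(ids)),
                                 prediction = rep("case", length(ids)))
  rounds <- list(mk_round(c("c1", "c2", "c3")), mk_round(c("c1", "c2")),
                 mk_round(c("c1", "c2", "c3")))
  kept <- intersect_and_exclude(rounds, pm)
  expect_identical(sort(kept), "c1")  # c3 not in every list, c2 contaminated
  expect_warning(
    empty <- intersect_and_exclude(list(mk_round("c2")), pm),
    "empty")
  expect_length(empty, 0)
  # intersection is order-invariant over rounds
  expect_identical(intersect_and_exclude(rev(rounds), pm), kept)
})

test_that("per-marker LOOCV performance pools held-out predictions", {
  mk_round <- function(truth, pred)
    list(heldout_sample_id = "x", heldout_true_group = truth,
         compound_id = "m", threshold = 1, prediction = pred)
  all_correct <- list(mk_round("case", "case"), mk_round("control", "control"),
                      mk_round("case", "case"), mk_round("control", "control"))
  perf <- summarize_marker_performance(all_correct, "m")
  expect_equal(perf[, c("accuracy", "sensitivity", "specificity")],
               data.frame(accuracy = 1, sensitivity = 1, specificity = 1))

  always_case <- list(mk_round("case", "case"), mk_round("case", "case"),
                      mk_round("control", "case"))
  perf2 <- summarize_marker_performance(always_case, "m")
  expect_equal(perf2$sensitivity, 1)
  expect_equal(perf2$specificity, 0)
  expect_equal(perf2$accuracy, 2 / 3)  # the case fraction

  expect_error(summarize_marker_performance(all_correct, "absent"),
               "missing from the round")
})

test_that("marker performance is self-consistent with the stored rounds", {
  sim <- simulate_profile(synthetic_config(n_case = 15, n_control = 15,
                                           m_compounds = 80, n_markers = 3,
                                           n_contaminants = 1,
                                           marker_log_shift = 1.2, seed = 41))
  fit <- discover_markers(sim$pm, alpha = 0.05, cutoff = 0.6)
  expect_gt(length(fit$marker_ids), 0)
  # recompute every confusion matrix from the raw round records
  truth <- vapply(fit$rounds, `[[`, character(1), "heldout_true_group")
  for (i in seq_along(fit$marker_ids)) {
    cid <- fit$marker_ids[i]
    pred <- vapply(fit$rounds, function(r)
      r$prediction[match(cid, r$compound_id)], character(1))
    expect_equal(fit$performance$accuracy[i], mean(pred == truth))
    expect_equal(fit$performance$sensitivity[i],
                 mean(pred[truth == "case"] == "case"))
    expect_equal(fit$performance$specificity[i],
                 mean(pred[truth == "control"] == "control"))
  }
})

test_that("discovery recovers planted markers end to end", {
  sim <- simulate_profile(synthetic_config(seed = 52))
  split <- split_cohorts(sim$pm, 100, seed = 52)
  fit <- discover_markers(subset_samples(sim$pm, split$discovery_ids))
  expect_setequal(fit$marker_ids, sim$planted_marker_ids)
  expect_lte(length(fit$marker_ids),
             min(lengths(lapply(fit$rounds, `[[`, "compound_id"))))
  expect_equal(fit$alpha_adjusted, 0.05 / 922)
  # markers are reported in ascending discovery p-value order
  is_case <- subset_samples(sim$pm, split$discovery_ids)$groups == "case"
  expect_true(all(fit$performance$compound_id == fit$marker_ids))

  ev <- evaluate_markers(fit, subset_samples(sim$pm, split$test_ids))
  expect_gte(ev$panel_roc$auc, 0.9)
  expect_true(all(ev$per_marker$accuracy > 0.5))
})
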