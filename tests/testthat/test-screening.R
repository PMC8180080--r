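test_that("rank-sum worked examples", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)  # 2/20 assignments
  expect_equal(rank_sum_test(c(2, 9, 4), c(9, 2, 4)), 1.0)  # identical multisets
  expect_error(rank_sum_test(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum is symmetric and invariant to monotone transforms", {
  set.seed(101)
  for (i in 1:20) {
    x <- rpois(sample(3:15, 1), 5)
    y <- rpois(sample(3:15, 1), 6)
    p_xy <- rank_sum_test(x, y)
    expect_equal(p_xy, rank_sum_test(y, x))
    expect_equal(p_xy, rank_sum_test(exp(x / 3), exp(y / 3)))
    expect_equal(p_xy, rank_sum_test(rank(c(x, y))[seq_along(x)] * 7 + 2,
                                     rank(c(x, y))[-seq_along(x)] * 7 + 2))
  }
})

test_that("exact branch matches full enumeration for all small partitions", {
  # every (n1, n2) partition of untied pooled samples up to size 10
  for (n in 4:10) {
    v <- seq_len(n)
    for (n1 in 2:(n - 2)) {
      combos <- combn(n, n1)
      for (k in seq_len(min(ncol(combos), 25))) {
        x <- v[combos[, k]]
        y <- v[-combos[, k]]
        expect_equal(rank_sum_test(x, y), enumerate_rank_sum_p(x, y),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("rank-sum agrees with the standard test on tied and untied data", {
  set.seed(202)
  for (i in 1:25) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x <- sample(0:8, n1, replace = TRUE)  # heavy ties, incl. zeros
    y <- sample(0:8, n2, replace = TRUE) + rbinom(n2, 1, 0.5)
    ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
    expect_equal(rank_sum_test(x, y), ref$p.value, tolerance = 1e-12)
  }
  # untied exact branch vs wilcox.test exact
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1)); y <- rnorm(sample(3:9, 1))
    expect_equal(rank_sum_test(x, y), wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold arithmetic and monotonicity", {
  expect_equal(signif(bonferroni_threshold(0.05, 922), 3), 5.42e-5)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 10), 0.001)
  m <- c(1, 2, 10, 922, 5000)
  expect_true(all(diff(bonferroni_threshold(0.05, m)) < 0))
  expect_error(bonferroni_threshold(0.05, 0), "positive count")
})

test_that("detection-frequency filter applies a strict cutoff", {
  abund <- rbind(c(rep(1, 31), rep(0, 20)),   # 31/51 detected
                 c(rep(1, 30), rep(0, 21)))
  pm <- profile_matrix(cbind(abund, c(0, 0)),
                       data.frame(compound_id = c("a", "b")),
                       paste0("s", 1:52),
                       c(rep("case", 51), "control"))
  case_ids <- paste0("s", 1:51)
  r_a <- detection_fraction_filter(pm, "a", case_ids, cutoff = 0.6)
  expect_equal(r_a$fraction, 31 / 51)
  expect_true(r_a$passed)

  pm50 <- profile_matrix(cbind(abund[, 1:50], c(0, 0)),
                         data.frame(compound_id = c("a", "b")),
                         paste0("s", 1:51), c(rep("case", 50), "control"))
  r_b <- detection_fraction_filter(pm50, "b", paste0("s", 1:50), cutoff = 0.6)
  expect_equal(r_b$fraction, 0.6)
  expect_false(r_b$passed)  # exactly 60% is not "more than 60%"

  r_zero <- detection_fraction_filter(pm, "b", "s52", cutoff = 0.6)
  expect_equal(r_zero$fraction, 0)
  expect_false(r_zero$passed)
  expect_error(detection_fraction_filter(pm, "nope", case_ids), "unknown compound")
})

test_that("two-phase screen recovers planted markers and nothing else", {
  sim <- simulate_profile(synthetic_config(seed = 77))
  split <- split_cohorts(sim$pm, 100, seed = 77)
  scr <- screen_candidates(subset_samples(sim$pm, split$discovery_ids))
  hits <- scr$compound_id[scr$passed_phase2]
  expect_setequal(hits, sim$planted_marker_ids)
  expect_true(all(diff(scr$p_value) >= 0))  # sorted ascending
  expect_equal(scr$alpha_adjusted[1], 0.05 / 922)
  expect_identical(scr$passed_phase1, scr$p_value < scr$alpha_adjusted)
})

test_that("screening depends only on the training samples", {
  sim <- simulate_profile(synthetic_config(n_case = 12, n_control = 12,
                                           m_compounds = 60, n_markers = 2,
                                           n_contaminants = 0, seed = 88))
  disc <- subset_samples(sim$pm, sim$pm$sample_ids[1:20])
  scr1 <- screen_candidates(disc)
  # perturbing samples outside the training set must change nothing
  pm_mut <- sim$pm
  pm_mut$abundance[, 21:24] <- pm_mut$abundance[, 21:24] * 1000 + 5
  scr2 <- screen_candidates(subset_samples(pm_mut, sim$pm$sample_ids[1:20]))
  expect_identical(scr1, scr2)
})

test_that("Shapiro-Wilk gate flags zero-inflated data but tolerates constants", {
  set.seed(303)
  zi <- c(rep(0, 30), rlnorm(20, 8, 1))  # 60% zeros at n = 50
  abund <- rbind(zi, c(rep(1, 25), rep(1, 25)), rlnorm(50, 8, 1))
  pm <- profile_matrix(abund, data.frame(compound_id = c("zi", "const", "ln")),
                       paste0("s", 1:50), rep(c("case", "control"), 25))
  gate <- shapiro_wilk_gate(pm)
  expect_equal(gate$verdict, "non-normal")
  expect_lt(min(gate$table[gate$table$compound_id == "zi", -1]), 0.001)
  expect_true(all(is.na(gate$table[gate$table$compound_id == "const", -1])))
})

test_that("Shapiro-Wilk gate holds its type-I error under a Gaussian null", {
  set.seed(404)
  m <- 400
  pm <- profile_matrix(matrix(rnorm(m * 50, mean = 10), nrow = m),
                       data.frame(compound_id = paste0("g", seq_len(m))),
                       paste0("s", 1:50), rep(c("case", "control"), 25))
  gate <- shapiro_wilk_gate(pm)
  p_all <- c(gate$table$p_case, gate$table$p_control)
  rate <- mean(p_all < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(p_all)))
  expect_equal(gate$verdict, "not-rejected")  # Bonferroni-adjusted minimum
})

test_that("chi-square demographics comparison matches printed values", {
  # agrees with the reported 0.0005 to within one unit of the printed last
  # decimal; the continuity-corrected variant (0.0011) clearly does not
  gender <- compare_categorical(matrix(c(45, 58, 18, 3), 2, 2))
  expect_lt(abs(gender$p_value - 0.0005), 1e-4)
  expect_gt(abs(chisq.test(matrix(c(45, 58, 18, 3), 2, 2))$p.value - 0.0005),
            1e-4)
  expect_equal(gender$df, 1)

  flat <- compare_categorical(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)

  hematuria <- compare_categorical(matrix(c(30, 0, 33, 61), 2, 2))
  expect_lt(hematuria$p_value, 0.001)

  expect_error(compare_categorical(matrix(c(0, 0, 5, 5), 2, 2)), "margins")
})
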