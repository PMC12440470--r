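frame_10k <- function(seed = 1) {
  set.seed(seed)
  data.frame(patient_id = sprintf("v%05d", 1:10000), score = rnorm(10000))
}

test_that("the default design draws exactly 600 with valid probabilities", {
  rev <- draw_review_sample(frame_10k(), sampling_design(seed = 3))
  expect_identical(nrow(rev), 600L)
  expect_true(all(rev$pi > 0 & rev$pi <= 1))
  expect_true(all(is.finite(rev$weight)))
  # 200 drawn by SRS, 100 from the mid band, 30 per upper band
  expect_identical(unname(table(rev$stratum_id)["srs"]), 200L)
  expect_identical(unname(table(rev$stratum_id)["p75_90"]), 100L)
  expect_true(all(table(rev$stratum_id)[sprintf("p%d_%d", 90:99, 91:100)] == 30L))
  # reproducible given the design seed
  rev2 <- draw_review_sample(frame_10k(), sampling_design(seed = 3))
  expect_identical(rev, rev2)
})

test_that("an SRS census gives inclusion probability 1 for everyone", {
  frame <- data.frame(patient_id = sprintf("p%02d", 1:50),
                      score = rnorm(50))
  des <- sampling_design(n_srs = 50,
                         strata = data.frame(lo = 90, hi = 100, n = 0),
                         seed = 1)
  rev <- draw_review_sample(frame, des)
  expect_identical(nrow(rev), 50L)
  expect_true(all(rev$pi == 1))
})

test_that("two-band toy frame reproduces hand-computed probabilities", {
  # 20 patients, two percentile halves of 10; draw 5 from each, no SRS
  frame <- data.frame(patient_id = sprintf("p%02d", 1:20), score = 1:20)
  des <- sampling_design(n_srs = 0,
                         strata = data.frame(lo = c(0, 50), hi = c(50, 100),
                                             n = c(5, 5)),
                         seed = 7)
  rev <- draw_review_sample(frame, des)
  expect_identical(nrow(rev), 10L)
  expect_true(all(rev$pi == 0.5))
  # infeasible stratum demand errors out
  des_bad <- sampling_design(n_srs = 0,
                             strata = data.frame(lo = 0, hi = 100, n = 21),
                             seed = 1)
  expect_error(draw_review_sample(frame, des_bad), "unsampled")
})

test_that("IPW with equal weights reduces to the empirical proportions", {
  set.seed(4)
  n <- 200
  rev <- data.frame(patient_id = sprintf("p%03d", 1:n),
                    score = rnorm(n), stratum_id = "srs", band = "p0_75",
                    weight = 2.5,
                    review_label = sample(c("none", "possible"), n, TRUE,
                                          prob = c(0.8, 0.2)))
  all_scores <- rev$score
  est <- ipw_estimates(rev, all_scores, 50)
  cutoff <- quantile(all_scores, 0.5, type = 7, names = FALSE)
  flag <- rev$score > cutoff
  pos <- rev$review_label == "possible"
  expect_equal(est$prevalence, mean(pos))
  expect_equal(est$sensitivity, sum(pos & flag) / sum(pos))
  expect_equal(est$specificity, sum(!pos & !flag) / sum(!pos))
  expect_equal(est$accuracy, mean(pos == flag))
})

test_that("IPW estimates match a hand-computed weighted table", {
  rev <- data.frame(
    patient_id = sprintf("p%d", 1:6),
    score = c(5, 4, 3, 2, 1, 0),
    stratum_id = c("hi", "hi", "hi", "lo", "lo", "lo"),
    band = "b", weight = c(1, 1, 1, 4, 4, 4),
    review_label = c("probable", "none", "possible", "none", "possible",
                     "none"))
  all_scores <- c(5, 4, 3, 2, 1, 0)
  # cutoff at the 50th percentile of 0..5 -> 2.5; flagged: scores 3,4,5
  est <- ipw_estimates(rev, all_scores, 50)
  # weighted table: TP = 1 + 1 = 2, FP = 1, FN = 4, TN = 8
  expect_equal(est$prevalence, 6 / 15)
  expect_equal(est$sensitivity, 2 / 6)
  expect_equal(est$specificity, 8 / 9)
  expect_equal(est$ppv, 2 / 3)
  expect_equal(est$npv, 8 / 12)
  expect_equal(est$accuracy, 10 / 15)
})

test_that("a perfectly separating score yields sens = spec = accuracy = 1", {
  rev <- data.frame(patient_id = sprintf("p%d", 1:10),
                    score = c(10:6, 5:1),
                    stratum_id = "s", band = "b", weight = 1,
                    review_label = rep(c("probable", "none"), each = 5))
  est <- ipw_estimates(rev, rev$score, 50)
  expect_equal(est$sensitivity, 1)
  expect_equal(est$specificity, 1)
  expect_equal(est$accuracy, 1)
})

test_that("PPV always satisfies the Bayes identity from the same table", {
  for (seed in 1:10) {
    rev <- random_reviewed(60, seed)
    for (ct in c(25, 50, 75, 90)) {
      est <- suppressMessages(ipw_estimates(rev, rev$score, ct))
      if (anyNA(est[c("ppv", "sensitivity", "specificity", "prevalence")])) next
      bayes <- est$sensitivity * est$prevalence /
        (est$sensitivity * est$prevalence +
           (1 - est$specificity) * (1 - est$prevalence))
      expect_equal(est$ppv, bayes, tolerance = 1e-12)
    }
  }
})

test_that("sensitivity falls and specificity rises with the cutoff", {
  rev <- random_reviewed(80, 3)
  cuts <- seq(10, 90, by = 10)
  ests <- do.call(rbind, lapply(cuts, function(ct) {
    suppressMessages(ipw_estimates(rev, rev$score, ct))
  }))
  expect_true(all(diff(ests$sensitivity) <= 1e-12))
  expect_true(all(diff(ests$specificity) >= -1e-12))
})

test_that("weighted AUC follows tie conventions and the concordance oracle", {
  expect_equal(weighted_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_equal(weighted_auc(c(4, 3, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_message(expect_true(is.na(weighted_auc(1:4, rep(TRUE, 4)))),
                 "single class")
  set.seed(20)
  for (rep in 1:50) {
    n <- sample(5:25, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    positive <- runif(n) < 0.4
    if (!any(positive) || all(positive)) next
    weights <- runif(n, 0.2, 5)
    expect_equal(weighted_auc(scores, positive, weights),
                 auc_concordance_oracle(scores, positive, weights),
                 info = paste("toy set", rep))
  }
})

test_that("stratified bootstrap is deterministic with sane degenerate cases", {
  rev <- random_reviewed(50, 6)
  stat <- function(r) sum(r$weight * (r$review_label != "none")) / sum(r$weight)
  ci1 <- bootstrap_ci(stat, rev, B = 200, seed = 11)
  ci2 <- bootstrap_ci(stat, rev, B = 200, seed = 11)
  expect_identical(ci1[c("lower", "upper")], ci2[c("lower", "upper")])
  expect_true(ci1$lower <= ci1$upper)
  # constant statistic collapses to a zero-width interval with a warning
  expect_warning(ci0 <- bootstrap_ci(function(r) 0.7, rev, B = 100, seed = 1),
                 "degenerate")
  expect_identical(unname(c(ci0$lower, ci0$upper)), c(0.7, 0.7))
  expect_error(bootstrap_ci(stat, rev, B = 50, seed = 1), "B must be")
})

test_that("bootstrap CI of a weighted mean covers the truth near nominally", {
  # large-sample toy: stratified frame with known mean under the design
  set.seed(30)
  R <- 120
  cover <- logical(R)
  for (i in 1:R) {
    rev <- data.frame(stratum_id = rep(c("a", "b"), each = 150),
                      weight = rep(c(1, 2), each = 150),
                      y = c(rnorm(150, 1), rnorm(150, 2)))
    truth <- (1 * 1 + 2 * 2) / 3
    stat <- function(r) sum(r$weight * r$y) / sum(r$weight)
    ci <- bootstrap_ci(stat, rev, B = 300, seed = i)
    cover[i] <- ci$lower <= truth & truth <= ci$upper
  }
  expect_gt(mean(cover), 0.88)
  expect_lt(mean(cover), 1.0)
})

test_that("Cohen's kappa matches direct formula evaluation and null behaviour", {
  # identical ratings
  expect_equal(cohens_kappa(c("a", "b", "a"), c("a", "b", "a"))$kappa, 1)
  # hand 2x2 agreement table: a=40, b=10, c=10, d=40 -> kappa = 0.6
  a <- c(rep("x", 50), rep("y", 50))
  b <- c(rep("x", 40), rep("y", 10), rep("x", 10), rep("y", 40))
  k <- cohens_kappa(a, b)
  expect_equal(k$kappa, 0.6)
  expect_equal(k$se, sqrt(0.8 * 0.2 / (100 * 0.25)))
  # independent uniform ratings are near zero
  set.seed(14)
  r1 <- sample(letters[1:3], 10000, replace = TRUE)
  r2 <- sample(letters[1:3], 10000, replace = TRUE)
  expect_lt(abs(cohens_kappa(r1, r2)$kappa), 0.05)
  # both raters constant and equal -> 1 by convention
  expect_message(kc <- cohens_kappa(rep("z", 5), rep("z", 5)), "convention")
  expect_identical(kc$kappa, 1)
  expect_error(cohens_kappa("a", c("a", "b")), "paired")
})

test_that("per-band prevalence is flat, per-band, and handles empty bands", {
  # uniform labels -> flat profile
  rev <- random_reviewed(60, 8)
  rev$review_label <- "possible"
  prof <- prevalence_by_stratum(rev)
  expect_true(all(prof$prevalence == 1))

  # single-band frame equals the overall prevalence
  rev2 <- random_reviewed(40, 9)
  rev2$band <- "p0_75"
  prof2 <- prevalence_by_stratum(rev2)
  overall <- sum(rev2$weight * (rev2$review_label != "none")) /
    sum(rev2$weight)
  expect_identical(nrow(prof2), 1L)
  expect_equal(prof2$prevalence, overall)

  # design bands with no reviewed patients come back as NA
  prof3 <- prevalence_by_stratum(rev2, design = sampling_design(seed = 1))
  expect_true(all(is.na(prof3$prevalence[prof3$n_reviewed == 0])))
  expect_identical(nrow(prof3), 12L)  # p0_75 + mid + 10 upper bands
})

test_that("a planted monotone risk yields a rising per-band profile", {
  set.seed(16)
  n <- 10000
  score <- rnorm(n)
  p <- plogis(-4 + 1.5 * score)
  truth <- ifelse(runif(n) < p, "possible_probable", "none")
  frame <- data.frame(patient_id = sprintf("m%05d", 1:n), score = score)
  rev <- draw_review_sample(frame, sampling_design(seed = 18))
  rev$review_label <- simulate_review(truth[match(rev$patient_id,
                                                  frame$patient_id)],
                                      seed = 19)
  prof <- prevalence_by_stratum(rev)
  ord <- order(as.numeric(sub("^p([0-9.]+)_.*", "\\1", prof$band)))
  rho <- cor(seq_along(ord), prof$prevalence[ord], method = "spearman")
  expect_gt(rho, 0)
})

test_that("reviewer noise behaves like its operating characteristics", {
  lat <- rep(c("possible_probable", "none"), each = 5000)
  lab <- simulate_review(lat, sensitivity = 0.8, specificity = 0.9, seed = 21)
  sens_hat <- mean(lab[1:5000] != "none")
  spec_hat <- mean(lab[5001:10000] == "none")
  expect_lt(abs(sens_hat - 0.8), 0.03)
  expect_lt(abs(spec_hat - 0.9), 0.03)
  # perfect review reproduces the latent truth
  lab1 <- simulate_review(lat, seed = 22)
  expect_true(all((lab1 != "none") == (lat == "possible_probable")))
})
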