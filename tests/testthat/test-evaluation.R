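test_that("AUC equals explicit pair counting, with ties and symmetry", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(auc_mw(scores, labels), 0.75)
  expect_equal(auc_mw(scores, labels), naive_auc(scores, labels))
  # symmetry: AUC(s) + AUC(-s) = 1
  expect_equal(auc_mw(scores, labels) + auc_mw(-scores, labels), 1)
  # perfect ranking
  expect_equal(auc_mw(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # random fixtures incl. ties
  for (s in 1:6) {
    set.seed(s)
    sc <- sample(seq(0, 1, 0.1), 20, replace = TRUE)
    y <- sample(0:1, 20, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(sc, y), naive_auc(sc, y), tolerance = 1e-12)
  }
  expect_error(auc_mw(1:3, c(1, 1, 1)), "both classes")
})

test_that("AUC agrees with pROC and CIs use the DeLong variance", {
  skip_if_not_installed("pROC")
  set.seed(8)
  sc <- stats::rnorm(60)
  y <- as.integer(sc + stats::rnorm(60) > 0)
  ours <- roc_auc(sc, y)
  ref <- suppressMessages(pROC::roc(y, sc, direction = "<"))
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-10)
  ref_ci <- suppressMessages(as.numeric(pROC::ci.auc(ref, method = "delong")))
  expect_equal(ours$ci[1], ref_ci[1], tolerance = 1e-6)
  expect_equal(ours$ci[2], ref_ci[3], tolerance = 1e-6)
})

test_that("the Youden cutoff maximizes J over a brute-force scan", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  yj <- youden_cutoff(scores, labels)
  expect_equal(yj$J, 0.5, tolerance = 1e-12)
  expect_equal(yj$J, naive_youden_J(scores, labels))
  # two cutoffs achieve J = 0.5; the tie-break selects the one with the
  # higher specificity (the larger cutoff, between 0.4 and 0.8)
  expect_gt(yj$cutoff, 0.4)
  expect_equal(yj$SPE, 1)
  # perfect separation
  expect_equal(youden_cutoff(c(1, 2, 8, 9), c(0, 0, 1, 1))$J, 1)
  # random fixtures: J equals the brute-force maximum
  for (s in 1:6) {
    set.seed(s)
    sc <- stats::rnorm(25)
    y <- sample(0:1, 25, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(youden_cutoff(sc, y)$J, naive_youden_J(sc, y),
                 tolerance = 1e-12)
  }
})

test_that("the DeLong test is symmetric with exact degenerate behavior", {
  set.seed(3)
  y <- rep(0:1, 30)
  a <- stats::rnorm(60) + y
  b <- a * 0.7 + stats::rnorm(60, sd = 0.5)
  d1 <- delong_test(a, b, y)
  d2 <- delong_test(b, a, y)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
  expect_equal(d1$diff, -d2$diff, tolerance = 1e-12)
  # model against itself
  self <- delong_test(a, a, y)
  expect_equal(self$p, 1)
  expect_true(self$degenerate)
  expect_error(delong_test(a, b[1:10], y), "paired")
})

test_that("the DeLong variance approximates the bootstrap variance", {
  set.seed(14)
  n <- 120
  y <- rep(0:1, n / 2)
  latent <- stats::rnorm(n) + 0.8 * y
  a <- latent + stats::rnorm(n, sd = 0.6)
  b <- latent + stats::rnorm(n, sd = 0.6)
  dl <- delong_test(a, b, y)
  B <- 2000
  diffs <- vapply(seq_len(B), function(i) {
    idx <- sample(n, replace = TRUE)
    if (length(unique(y[idx])) < 2) return(NA_real_)
    auc_mw(a[idx], y[idx]) - auc_mw(b[idx], y[idx])
  }, numeric(1))
  vb <- stats::var(diffs, na.rm = TRUE)
  expect_lt(abs(dl$var - vb) / vb, 0.15)
})

test_that("AUPRC matches hand-stepped areas and null behavior", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(auprc(scores, labels)$auprc,
               naive_auprc(scores, labels), tolerance = 1e-12)
  expect_equal(auprc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auprc, 1)
  expect_error(auprc(1:4, c(0, 0, 0, 0)), "positive")
  # random scores: AUPRC concentrates near prevalence
  set.seed(31)
  vals <- replicate(50, {
    y <- stats::rbinom(150, 1, 0.3)
    if (sum(y) == 0) return(NA_real_)
    auprc(stats::runif(150), y)$auprc
  })
  expect_lt(abs(mean(vals, na.rm = TRUE) - 0.3), 0.05)
  # bootstrap CI brackets the point estimate
  set.seed(5)
  y <- rep(0:1, 40)
  sc <- stats::rnorm(80) + y
  pr <- auprc(sc, y, boot = 500, seed = 9)
  expect_gte(pr$auprc, pr$ci[1])
  expect_lte(pr$auprc, pr$ci[2])
  # exhaustive comparison on random small fixtures
  for (s in 1:5) {
    set.seed(s)
    sc <- sample(seq(0, 1, 0.05), 15, TRUE)
    y <- sample(0:1, 15, TRUE)
    if (sum(y) == 0) next
    expect_equal(auprc(sc, y)$auprc, naive_auprc(sc, y), tolerance = 1e-12)
  }
})

test_that("calibration recovers truth and detects miscalibration", {
  set.seed(12)
  p <- stats::runif(2000, 0.05, 0.95)
  y <- stats::rbinom(2000, 1, p)
  cal <- calibration_curve(p, y)
  expect_gt(cal$slope, 0.85); expect_lt(cal$slope, 1.15)
  expect_gt(cal$intercept, -0.2); expect_lt(cal$intercept, 0.2)
  expect_equal(nrow(cal$curve), 5)
  # overconfident probabilities flatten the slope below 1
  over <- stats::plogis(2.5 * stats::qlogis(p))
  cal_over <- calibration_curve(over, y)
  expect_lt(cal_over$slope, cal$slope)
  # all probabilities identical: single degenerate bin
  cal1 <- calibration_curve(rep(0.3, 50), stats::rbinom(50, 1, 0.3))
  expect_equal(nrow(cal1$curve), 1)
  expect_equal(cal1$curve$mean_pred, 0.3)
  expect_error(calibration_curve(c(1.2, 0.5), c(1, 0)), "\\[0, 1\\]")
})

test_that("net benefit follows the decision-analytic formula", {
  # N = 100, TP = 20, FP = 10 at pt = 0.2 -> NB = 0.2 - 0.1 * 0.25 = 0.175
  probs <- c(rep(0.9, 20), rep(0.8, 10), rep(0.05, 70))
  labels <- c(rep(1, 20), rep(0, 10), rep(0, 55), rep(1, 15))
  dc <- decision_curve(probs, labels, thresholds = 0.2)
  expect_equal(dc$nb_model, 20 / 100 - (10 / 100) * 0.2 / 0.8,
               tolerance = 1e-12)
  expect_equal(dc$nb_model, 0.175)
  # treat-all has zero net benefit exactly at pt = prevalence
  prev <- mean(labels)
  dc2 <- decision_curve(probs, labels, thresholds = prev)
  expect_equal(dc2$nb_all, 0, tolerance = 1e-12)
  expect_equal(dc2$nb_none, 0)
  # the model never beats the perfect classifier
  set.seed(2)
  p <- stats::runif(200); y <- stats::rbinom(200, 1, p)
  dcs <- decision_curve(p, y)
  perfect <- mean(y)   # TP = prevalence * N, FP = 0
  expect_true(all(dcs$nb_model <= perfect + 1e-12))
  # pt = 1 excluded
  expect_equal(nrow(decision_curve(p, y, thresholds = c(0.5, 1))), 1)
})

test_that("waterfall data are a sorted permutation with exact counts", {
  set.seed(6)
  probs <- stats::runif(30)
  labels <- stats::rbinom(30, 1, probs)
  wf <- waterfall(probs, labels, cutoff = 0.5,
                  patient_id = sprintf("P%02d", 1:30))
  expect_setequal(wf$patient_id, sprintf("P%02d", 1:30))
  expect_false(is.unsorted(wf$prob))
  cm <- habitrad:::confusion_metrics(probs, labels, 0.5)
  expect_equal(sum(wf$misclassified), unname(cm["FP"] + cm["FN"]))
  # perfectly separated probabilities -> no misclassification
  wf2 <- waterfall(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1), 0.5)
  expect_equal(sum(wf2$misclassified), 0)
})

test_that("cohort characteristics reproduce the smoking-contrast example", {
  # 2x2 table (11,3 / 13,26): smokers 11 of 24 positives vs 3 of 29
  # negatives; chi-square with Yates correction is clearly significant
  tab <- matrix(c(11, 3, 13, 26), 2, byrow = TRUE)
  p <- stats::chisq.test(tab, correct = TRUE)$p.value
  expect_lt(p, 0.05)
  clin <- data.frame(
    patient_id = sprintf("P%02d", 1:53),
    label = c(rep(1, 24), rep(0, 29)),
    split = "train",
    smoking = c(rep(1, 11), rep(0, 13), rep(1, 3), rep(0, 26)),
    age = c(stats::rnorm(24, 58.5, 7.9), stats::rnorm(29, 60.6, 11.6)))
  set.seed(1)
  cc <- cohort_characteristics(clin, continuous = "age",
                               categorical = "smoking")
  expect_lt(cc$p[cc$variable == "smoking"], 0.05)
  expect_equal(cc$p[cc$variable == "smoking"], p, tolerance = 1e-12)
  # constant column dropped with warning
  clin$gender <- "female"
  expect_warning(cohort_characteristics(clin, continuous = "age",
                                        categorical = c("smoking", "gender")),
                 "constant")
})

test_that("metrics are invariant under patient reordering", {
  set.seed(9)
  sc <- stats::rnorm(40); y <- sample(0:1, 40, TRUE)
  if (length(unique(y)) < 2) { y[1] <- 0; y[2] <- 1 }
  perm <- sample(40)
  expect_equal(auc_mw(sc, y), auc_mw(sc[perm], y[perm]))
  expect_equal(youden_cutoff(sc, y)$J, youden_cutoff(sc[perm], y[perm])$J)
  expect_equal(auprc(sc, y)$auprc, auprc(sc[perm], y[perm])$auprc)
  p <- stats::plogis(sc)
  expect_equal(decision_curve(p, y)$nb_model,
               decision_curve(p[perm], y[perm])$nb_model)
})

test_that("AUC is invariant to monotone score transforms", {
  set.seed(10)
  sc <- stats::rnorm(30); y <- rep(0:1, 15)
  expect_equal(auc_mw(sc, y), auc_mw(stats::plogis(sc), y))
  expect_equal(auc_mw(sc, y), auc_mw(exp(sc), y))
})

test_that("evaluate_predictions assembles a full per-split report", {
  set.seed(4)
  n <- 90
  pred <- data.frame(
    patient_id = sprintf("P%03d", 1:n),
    split = rep(c("train", "internal", "external"), each = n / 3),
    label = rep(0:1, length.out = n))
  pred$prob <- stats::plogis(stats::rnorm(n) + 1.5 * pred$label)
  ev <- evaluate_predictions(pred, cutoff = 0.5, boot = 100, seed = 3)
  expect_s3_class(ev, "evaluation_report")
  expect_setequal(ev$metrics$split, c("train", "internal", "external"))
  expect_true(all(ev$metrics$auc >= 0 & ev$metrics$auc <= 1))
  expect_true(all(c("ACC", "SEN", "SPE", "PPV", "NPV", "F1") %in%
                  names(ev$metrics)))
  expect_length(ev$decision, 3)
  expect_equal(unique(ev$decision$train$nb_none), 0)
})
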