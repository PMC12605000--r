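
test_that("the Mann-Whitney screen reproduces exact small-sample p-values", {
  X <- cbind(f = c(1, 2, 3, 4, 5, 6))
  y <- c(1, 1, 1, 0, 0, 0)       # positives {1,2,3}, negatives {4,5,6}
  res <- mann_whitney_screen(X, y, alpha = 0.05)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1, tolerance = 1e-12)   # 2 * 1/20
  expect_false(res$retained)
  # identical groups -> p = 1
  X2 <- cbind(f = rep(c(1, 2, 3), 2))
  expect_equal(mann_whitney_screen(X2, c(1, 1, 1, 0, 0, 0))$p, 1,
               tolerance = 1e-9)
  # constant feature -> p = 1, dropped
  X3 <- cbind(f = rep(1, 6))
  res3 <- mann_whitney_screen(X3, y)
  expect_equal(res3$p, 1)
  expect_false(res3$retained)
})

test_that("screening respects the null rate and alpha monotonicity", {
  set.seed(99)
  hits <- replicate(100, {
    X <- matrix(stats::rnorm(40 * 5), 40, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- sample(rep(0:1, 20))
    sum(mann_whitney_screen(X, y)$retained)
  })
  rate <- mean(hits) / 5
  expect_gt(rate, 0.01); expect_lt(rate, 0.12)   # nominal 5% null rate
  # lowering alpha never enlarges the retained set
  X <- matrix(stats::rnorm(40 * 30), 40, 30,
              dimnames = list(NULL, paste0("f", 1:30)))
  y <- rep(0:1, 20)
  r1 <- mann_whitney_screen(X, y, alpha = 0.05)$retained
  r2 <- mann_whitney_screen(X, y, alpha = 0.01)$retained
  expect_true(all(which(r2) %in% which(r1)))
})

test_that("the LASSO shrinks fully at large lambda and soft-thresholds", {
  set.seed(4)
  n <- 80
  y <- rep(0:1, n / 2)
  X <- matrix(stats::rnorm(n * 4), n, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        standardize = FALSE)
  co_big <- as.matrix(stats::coef(fit, s = max(fit$lambda) * 10))
  expect_true(all(co_big[-1, 1] == 0))
  # orthonormal-design soft-thresholding (gaussian case, where the
  # closed form beta_j = S(beta_ols, lambda) is exact)
  Q <- qr.Q(qr(matrix(stats::rnorm(n * 3), n, 3))) * sqrt(n)
  b_true <- c(2, -1, 0.2)
  yg <- as.numeric(Q %*% b_true + stats::rnorm(n, sd = 0.3))
  b_ols <- as.numeric(crossprod(Q, yg) / n)
  lam <- 0.5
  gfit <- glmnet::glmnet(Q, yg, family = "gaussian", alpha = 1,
                         lambda = lam, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-12)
  b_soft <- sign(b_ols) * pmax(abs(b_ols) - lam, 0)
  expect_equal(as.numeric(gfit$beta), b_soft, tolerance = 1e-4)
})

test_that("signatures compute the weighted linear combination exactly", {
  # RS with known weights: hand arithmetic
  sig <- structure(list(region = "S2", sequence = "T1W",
                        features = c("a", "b"),
                        weights = c(a = 2, b = -1), intercept = 0,
                        centre = c(a = 0, b = 0), scale = c(a = 1, b = 1),
                        logistic = c(0, 1), cutoff = 0.5),
                   class = "signature_model")
  tab <- data.frame(patient_id = "P1", sequence = "T1W", region = "S2",
                    label = 1, batch = "A", split = "train",
                    a = 1, b = 1, check.names = FALSE)
  class(tab) <- c("feature_table", "data.frame")
  pr <- predict(sig, tab)
  expect_equal(pr$rs, 1)               # 2*1 - 1*1 + 0
  expect_equal(pr$prob, stats::plogis(1))
  # affine transform of features moves RS predictably
  tab2 <- tab; tab2$a <- 3 * tab$a + 2; tab2$b <- 3 * tab$b + 2
  sig2 <- sig; sig2$centre <- c(a = 2, b = 2); sig2$scale <- c(a = 3, b = 3)
  expect_equal(predict(sig2, tab2)$rs, pr$rs)
})

test_that("build_signature learns cutoffs and flags separation", {
  tab <- make_sig_table(n = 60, p = 10, informative = 3, effect = 2,
                        seed = 7)
  sig <- suppressWarnings(build_signature(tab, "S2", "T1W", seed = 1))
  expect_s3_class(sig, "signature_model")
  expect_true(all(sig$features %in% paste0("f", 1:10)))
  expect_true(is.finite(sig$cutoff))
  pr <- predict(sig, tab)
  expect_gt(auc_mw(pr$prob, pr$label), 0.8)
})

test_that("fusion handles collinear parents and improves on split signal", {
  # two parents carrying independent halves of the signal
  set.seed(21)
  n <- 100
  y <- rep(0:1, n / 2)
  h1 <- stats::rnorm(n) + 0.9 * y
  h2 <- stats::rnorm(n) + 0.9 * y
  mk_parent <- function(f, nm) {
    structure(list(region = "S2", sequence = nm, features = "x",
                   weights = c(x = 1), intercept = 0,
                   centre = c(x = 0), scale = c(x = 1),
                   logistic = c(0, 1), cutoff = 0.5),
              class = "signature_model")
  }
  tab <- data.frame(patient_id = sprintf("P%03d", 1:n), label = y,
                    batch = "A", split = "train", check.names = FALSE)
  tab_a <- cbind(tab, sequence = "T1W", region = "S2", x = h1)
  tab_b <- cbind(tab, sequence = "T2FS", region = "S2", x = h2)
  full <- rbind(tab_a, tab_b)
  class(full) <- c("feature_table", "data.frame")
  fu <- build_fusion(mk_parent(h1, "T1W"), mk_parent(h2, "T2FS"), full)
  pf <- predict(fu, full)
  auc_f <- auc_mw(pf$prob, pf$label)
  expect_gte(auc_f, max(auc_mw(h1, y), auc_mw(h2, y)) - 1e-9)
  # collinear parents: identical scores still yield a usable model
  full2 <- full; full2$x[full2$sequence == "T2FS"] <- h1
  fu2 <- suppressWarnings(build_fusion(mk_parent(h1, "T1W"),
                                       mk_parent(h1, "T2FS"), full2))
  p2 <- predict(fu2, full2)
  expect_true(all(is.finite(p2$prob)))
  expect_equal(auc_mw(p2$prob, y), auc_mw(h1, y), tolerance = 0.02)
  # fusion probability is monotone in each parent RS when both
  # coefficients are positive
  co <- fu$coefficients
  if (all(co[2:3] > 0)) {
    g <- order(pf$prob)
    s_comb <- co[2] * h1 + co[3] * h2
    expect_identical(order(s_comb), g)
  }
})

test_that("nested CV is honest, leakage-free and passes controls", {
  tab <- make_sig_table(n = 80, p = 15, informative = 3, effect = 1.2,
                        seed = 5)
  # sentinel positive control: a feature equal to the label is selected in
  # every fold and drives outer AUC to ~1
  tab$sentinel <- tab$label + stats::rnorm(80, sd = 0.01)
  cv <- suppressWarnings(run_nested_cv(tab, "S2", "T1W", seed = 2))
  expect_true(all(vapply(cv$folds, function(f) "sentinel" %in% f$features,
                         logical(1))))
  expect_gt(cv$outer_auc, 0.95)
  # outer-fold predictions cover every training row exactly once
  expect_setequal(cv$outer_predictions$patient_id, tab$patient_id)
  # leakage audit: each fold's selection inputs exclude its test ids
  for (f in cv$folds)
    expect_length(intersect(f$train_ids, f$test_ids), 0)
  # changing rows outside the selection inputs changes nothing: refit with
  # fold-1 test rows replaced by noise must reproduce fold-1's selection
  tab2 <- tab
  t1 <- cv$folds[[1]]$test_ids
  fc <- feature_columns(tab2)
  tab2[tab2$patient_id %in% t1, fc] <-
    matrix(stats::rnorm(length(t1) * length(fc)), length(t1))
  cv2 <- suppressWarnings(run_nested_cv(tab2, "S2", "T1W", seed = 2))
  expect_identical(cv2$folds[[1]]$features, cv$folds[[1]]$features)
  expect_equal(cv2$folds[[1]]$lambda, cv$folds[[1]]$lambda)
})

test_that("permuted labels give chance-level outer performance", {
  aucs <- vapply(1:10, function(s) {
    tab <- make_sig_table(n = 60, p = 12, informative = 3, effect = 1.5,
                          seed = s)
    set.seed(s + 500)
    tab$label <- sample(tab$label)
    cv <- tryCatch(suppressWarnings(run_nested_cv(tab, "S2", "T1W",
                                                  seed = s)),
                   error = function(e) NULL)
    if (is.null(cv)) NA_real_ else cv$outer_auc
  }, numeric(1))
  aucs <- aucs[!is.na(aucs)]
  expect_gt(length(aucs), 4)
  expect_gt(mean(aucs), 0.33)
  expect_lt(mean(aucs), 0.67)
})

test_that("degenerate selection inputs raise informative errors", {
  tab <- make_sig_table(n = 20, p = 5, seed = 3)
  expect_error(lasso_select(as.matrix(tab[, "f1", drop = FALSE]),
                            tab$label), ">= 2 screened")
  expect_error(mann_whitney_screen(cbind(f = 1:5), rep(1, 5)),
               "both classes")
  # a pure-noise table usually fails the screen with a clear error
  tab0 <- make_sig_table(n = 30, p = 3, informative = 0, seed = 11)
  expect_error(suppressWarnings(build_signature(tab0, "S2", "T1W", seed = 1,
                                                alpha = 1e-6)),
               "pass the screen")
})
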