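# Leakage-safe signature construction: Mann-Whitney screening at P < 0.05,
# LASSO-logistic selection (glmnet) with lambda chosen by inner-CV
# deviance, a weighted-linear-combination radiomics score (RS), a logistic
# layer mapping RS to probability, and the multi-sequence regional fusion
# model on two parent RS scores. All fitting statistics (feature
# standardization, screening, lambda, Youden cutoff) are learned on
# training rows only.

#' Mann-Whitney screening of features against the label
#'
#' Two-sided Mann-Whitney U test per feature (exact when sample sizes
#' permit and there are no ties, normal approximation otherwise, the
#' `stats::wilcox.test` behavior). Features with `p < alpha` are retained;
#' constant features get `p = 1` and are dropped.
#'
#' @param X numeric matrix (rows = patients, columns = features).
#' @param y binary label vector.
#' @param alpha retention threshold (default 0.05).
#' @param fdr apply Benjamini-Hochberg correction before thresholding
#'   (default off, mirroring a plain `P < 0.05` screen).
#' @return a `screen_result` data frame: `feature`, `U`, `p`, `retained`.
#' @export
mann_whitney_screen <- function(X, y, alpha = 0.05, fdr = FALSE) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes must be present")
  res <- do.call(rbind, lapply(colnames(X) %||% seq_len(ncol(X)), function(f) {
    x <- X[, f]
    if (stats::sd(x) < 1e-12)
      return(data.frame(feature = as.character(f), U = NA_real_, p = 1))
    wt <- suppressWarnings(stats::wilcox.test(x[y == 1], x[y == 0]))
    data.frame(feature = as.character(f), U = unname(wt$statistic),
               p = wt$p.value)
  }))
  padj <- if (fdr) stats::p.adjust(res$p, "BH") else res$p
  res$retained <- padj < alpha & !is.na(res$U)
  class(res) <- c("screen_result", "data.frame")
  res
}

# Stratified fold ids (balanced label proportions per fold).
stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    id <- integer(length(y))
    for (l in unique(y)) {
      w <- which(y == l)
      id[w] <- sample(rep(seq_len(k), length.out = length(w)))
    }
    id
  })
}

#' LASSO-logistic feature selection
#'
#' L1-penalized logistic regression over the screened features; the
#' penalty is chosen by inner cross-validated binomial deviance
#' (`lambda.min` by default, `lambda.1se` available). Features are assumed
#' already standardized by the caller (the pipeline standardizes with
#' train-split mean/SD).
#'
#' @param X numeric matrix of screened (standardized) features.
#' @param y binary labels.
#' @param lambda_rule `"min"` or `"1se"`.
#' @param nfolds inner folds (default 5).
#' @param seed seed for the inner fold assignment.
#' @return a `lasso_selection`: `features` (nonzero-coefficient names),
#'   `coefficients` (named, including `(Intercept)`), `lambda`, `cv_fit`.
#' @export
lasso_select <- function(X, y, lambda_rule = c("min", "1se"), nfolds = 5L,
                         seed = 1L) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 screened features for the LASSO stage")
  if (nrow(X) < 10) stop("need >= 10 rows for the LASSO stage")
  foldid <- stratified_folds(y, nfolds, seed)
  cvfit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                             foldid = foldid, standardize = FALSE,
                             type.measure = "deviance")
  lam <- if (lambda_rule == "min") cvfit$lambda.min else cvfit$lambda.1se
  co <- as.matrix(stats::coef(cvfit, s = lam))
  nz <- rownames(co)[co[, 1] != 0 & rownames(co) != "(Intercept)"]
  if (!length(nz))
    stop("empty signature: no feature survives the LASSO at lambda = ",
         signif(lam, 3))
  structure(list(features = nz,
                 coefficients = stats::setNames(co[, 1], rownames(co)),
                 lambda = lam, lambda_rule = lambda_rule, cv_fit = cvfit),
            class = "lasso_selection")
}

#' Build a radiomics signature for one region x sequence
#'
#' Screens features (Mann-Whitney, `p < alpha`), selects with the LASSO,
#' and stores the weighted linear combination `RS(x) = sum w_f x_f + b`
#' together with a logistic layer mapping RS to probability and the
#' training Youden cutoff. Feature standardization (train mean/SD) is
#' learned here and applied frozen to any table scored later.
#'
#' @param table a `feature_table`.
#' @param region,sequence which rows to model (e.g. `"S2"`, `"T1W"`).
#' @param train_split split value identifying training rows.
#' @param alpha screening threshold.
#' @param icc_retained optional character vector of ICC-retained feature
#'   names; when given, selection is restricted to it.
#' @param lambda_rule,seed passed to [lasso_select()].
#' @return a `signature_model`.
#' @export
build_signature <- function(table, region, sequence, train_split = "train",
                            alpha = 0.05, icc_retained = NULL,
                            lambda_rule = "min", seed = 1L) {
  rows <- table$region == region & table$sequence == sequence
  tab <- table[rows, , drop = FALSE]
  tr <- tab[tab$split == train_split, , drop = FALSE]
  if (nrow(tr) < 10) stop("too few training rows for ", region, "/", sequence)
  feats <- feature_columns(tab)
  if (!is.null(icc_retained)) feats <- intersect(feats, icc_retained)
  Xtr <- as.matrix(tr[, feats, drop = FALSE])
  ytr <- tr$label
  centre <- colMeans(Xtr)
  scale_ <- apply(Xtr, 2, stats::sd)
  ok <- scale_ > 1e-12
  Xs <- sweep(sweep(Xtr[, ok, drop = FALSE], 2, centre[ok]), 2, scale_[ok], "/")
  scr <- mann_whitney_screen(Xs, ytr, alpha = alpha)
  kept <- scr$feature[scr$retained]
  if (length(kept) < 2)
    stop("fewer than 2 features pass the screen for ", region, "/", sequence)
  sel <- lasso_select(Xs[, kept, drop = FALSE], ytr,
                      lambda_rule = lambda_rule, seed = seed)
  w <- sel$coefficients[sel$features]
  b <- sel$coefficients["(Intercept)"]
  rs_tr <- as.numeric(Xs[, sel$features, drop = FALSE] %*% w + b)
  lg <- stats::glm(ytr ~ rs_tr, family = stats::binomial())
  sep_flag <- !lg$converged || any(abs(stats::coef(lg)) > 50)
  if (sep_flag) warning("near-separation in the logistic layer for ",
                        region, "/", sequence)
  prob_tr <- stats::predict(lg, type = "response")
  yj <- youden_cutoff(prob_tr, ytr)
  structure(list(region = region, sequence = sequence,
                 features = sel$features, weights = w, intercept = unname(b),
                 centre = centre[sel$features], scale = scale_[sel$features],
                 logistic = stats::coef(lg), cutoff = yj$cutoff,
                 screen = scr, selection = sel,
                 separation = sep_flag, train_split = train_split),
            class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat(sprintf("<signature_model> %s / %s: %d features, cutoff %.3f\n",
              x$sequence, x$region, length(x$features), x$cutoff))
  print(round(x$weights, 4))
  invisible(x)
}

#' Score patients with a signature
#'
#' @param object a `signature_model`.
#' @param table a `feature_table` (any split) holding the model's rows.
#' @param ... unused.
#' @return data frame with `patient_id`, `split`, `label`, `rs`
#'   (the linear radiomics score) and `prob` (logistic probability).
#' @export
predict.signature_model <- function(object, table, ...) {
  rows <- table$region == object$region & table$sequence == object$sequence
  tab <- table[rows, , drop = FALSE]
  X <- as.matrix(tab[, object$features, drop = FALSE])
  Xs <- sweep(sweep(X, 2, object$centre), 2, object$scale, "/")
  rs <- as.numeric(Xs %*% object$weights + object$intercept)
  eta <- object$logistic[1] + object$logistic[2] * rs
  data.frame(patient_id = tab$patient_id, split = tab$split,
             label = tab$label, rs = rs, prob = stats::plogis(eta))
}

#' Fuse two parent signatures into one model
#'
#' Logistic model on the two parent RS scores (two inputs plus intercept),
#' fitted on training rows only. Collinear or separated parents fall back
#' to a tiny-ridge fit so the two-input model stays solvable.
#'
#' @param sig_a,sig_b parent `signature_model`s (fitted on identical
#'   training rows; typically the best subregion of each sequence).
#' @param table the `feature_table` holding both parents' rows.
#' @param train_split split value identifying training rows.
#' @return a `fusion_model`.
#' @export
build_fusion <- function(sig_a, sig_b, table, train_split = "train") {
  pa <- predict(sig_a, table)
  pb <- predict(sig_b, table)
  if (!identical(pa$patient_id, pb$patient_id))
    stop("parent signatures score different patients")
  tr <- pa$split == train_split
  if (!any(tr)) stop("no training rows")
  y <- pa$label[tr]
  Z <- cbind(rs_a = pa$rs[tr], rs_b = pb$rs[tr])
  fit <- suppressWarnings(stats::glm(y ~ Z, family = stats::binomial()))
  co <- stats::coef(fit)
  ridge <- FALSE
  if (any(!is.finite(co)) || !fit$converged || any(abs(co) > 50)) {
    # tiny L2 keeps collinear parents identifiable
    rf <- glmnet::glmnet(Z, y, family = "binomial", alpha = 0,
                         lambda = 1e-6, standardize = FALSE)
    co <- c(as.numeric(rf$a0), as.numeric(rf$beta))
    ridge <- TRUE
  }
  names(co) <- c("(Intercept)", "rs_a", "rs_b")
  eta <- co[1] + co[2] * pa$rs[tr] + co[3] * pb$rs[tr]
  yj <- youden_cutoff(stats::plogis(eta), y)
  structure(list(parents = list(a = sig_a, b = sig_b), coefficients = co,
                 cutoff = yj$cutoff, ridge = ridge,
                 train_split = train_split),
            class = "fusion_model")
}

#' @export
predict.fusion_model <- function(object, table, ...) {
  pa <- predict(object$parents$a, table)
  pb <- predict(object$parents$b, table)
  co <- object$coefficients
  eta <- co[1] + co[2] * pa$rs + co[3] * pb$rs
  data.frame(patient_id = pa$patient_id, split = pa$split, label = pa$label,
             rs = as.numeric(eta), prob = stats::plogis(as.numeric(eta)))
}

#' Nested cross-validation over the training split
#'
#' Outer stratified 5-fold split of the training rows; screening, LASSO
#' and the logistic layer are fitted per outer-training fold and evaluated
#' on the held-out fold, so the pooled outer predictions are honest. A
#' final model is refit on the full training split for deployment. The
#' held-out rows of each outer fold never enter any selection input (an
#' audit record of the row ids used per fold is returned).
#'
#' @param table a `feature_table` restricted to one region x sequence via
#'   the arguments.
#' @param region,sequence rows to model.
#' @param k_outer outer folds.
#' @param alpha,lambda_rule,icc_retained as in [build_signature()].
#' @param seed master seed (outer folds and inner lambda folds).
#' @param train_split split holding the modeling rows.
#' @param fold_ids optional precomputed outer-fold assignment (integer per
#'   modeling row); by default folds are drawn stratified by label. Fixing
#'   the folds lets audits vary held-out labels without also changing the
#'   partition.
#' @return a `nested_cv` result: `outer_predictions` (pooled), `folds`
#'   (per-fold selections and audit of training ids), `final_model`,
#'   `outer_auc`.
#' @export
run_nested_cv <- function(table, region, sequence, k_outer = 5L,
                          alpha = 0.05, lambda_rule = "min",
                          icc_retained = NULL, seed = 1L,
                          train_split = "train", fold_ids = NULL) {
  rows <- table$region == region & table$sequence == sequence &
    table$split == train_split
  tab <- table[rows, , drop = FALSE]
  y <- tab$label
  if (min(table(y)) < k_outer * 2)
    stop("need >= ", 2 * k_outer, " rows per class for nested CV")
  fold <- fold_ids %||% stratified_folds(y, k_outer,
                                         child_seed(seed, "outer"))
  stopifnot(length(fold) == nrow(tab))
  preds <- list(); folds <- list()
  for (k in seq_len(k_outer)) {
    tr_tab <- tab[fold != k, , drop = FALSE]
    te_tab <- tab[fold == k, , drop = FALSE]
    if (length(unique(tr_tab$label)) < 2 || length(unique(te_tab$label)) < 2)
      stop("stratification failure: single-class fold")
    tr_tab$split <- "train"; te_tab$split <- "outer_test"
    sig <- tryCatch(
      build_signature(rbind(tr_tab, te_tab), region, sequence,
                      train_split = "train", alpha = alpha,
                      icc_retained = icc_retained,
                      lambda_rule = lambda_rule,
                      seed = child_seed(seed, paste0("fold", k))),
      error = function(e) e)
    if (inherits(sig, "error")) {
      # nothing selected in this fold (typical under a null signal): the
      # honest prediction is the training prevalence for every test row
      pr <- data.frame(patient_id = te_tab$patient_id, split = "outer_test",
                       label = te_tab$label,
                       rs = 0, prob = mean(tr_tab$label))
      folds[[k]] <- list(fold = k, features = character(0),
                         lambda = NA_real_, n_screened = 0L,
                         train_ids = tr_tab$patient_id,
                         test_ids = te_tab$patient_id,
                         note = conditionMessage(sig))
    } else {
      pr <- predict(sig, te_tab)
      folds[[k]] <- list(fold = k, features = sig$features,
                         lambda = sig$selection$lambda,
                         n_screened = sum(sig$screen$retained),
                         train_ids = tr_tab$patient_id,
                         test_ids = te_tab$patient_id)
    }
    pr$fold <- k
    preds[[k]] <- pr
  }
  outer_pred <- do.call(rbind, preds)
  final <- tryCatch(
    build_signature(tab, region, sequence, train_split = train_split,
                    alpha = alpha, icc_retained = icc_retained,
                    lambda_rule = lambda_rule,
                    seed = child_seed(seed, "final")),
    error = function(e) {
      warning("final refit selected no features: ", conditionMessage(e))
      NULL
    })
  structure(list(outer_predictions = outer_pred, folds = folds,
                 final_model = final,
                 outer_auc = auc_mw(outer_pred$prob, outer_pred$label)),
            class = "nested_cv")
}
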