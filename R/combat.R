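# Parametric empirical-Bayes ComBat with a train-fit / apply split, so
# validation and external rows can be harmonized with parameters learned
# on training rows only. The algorithm is the standard location-scale
# model: per-feature standardization against the grand (batch-weighted)
# mean and pooled variance, EB shrinkage of per-batch means toward a
# normal prior and of per-batch variances toward an inverse-gamma prior,
# then removal of the shrunk batch effects.

# EB hyperpriors for one batch: the normal prior on the batch means and
# the inverse-gamma prior on the batch variances are estimated across
# features (method of moments), as in standard ComBat.
combat_priors_batch <- function(g_hat, d_hat) {
  m <- mean(d_hat); v <- stats::var(d_hat)
  list(gamma_bar = mean(g_hat),
       t2 = stats::var(g_hat),
       a_prior = if (!is.finite(v) || v == 0) 3 else (2 * v + m^2) / v,
       b_prior = if (!is.finite(v) || v == 0) m else (m * v + m^3) / v)
}

# Iterative EB solution for one batch (vectors over features, scalar
# hyperpriors).
combat_it_sol <- function(z_batch, gamma_hat, delta_hat, gamma_bar, t2,
                          a_prior, b_prior, conv = 1e-4, max_it = 200) {
  n <- nrow(z_batch)
  g_old <- gamma_hat; d_old <- delta_hat
  for (it in seq_len(max_it)) {
    g_new <- (t2 * n * gamma_hat + d_old * gamma_bar) / (t2 * n + d_old)
    sum2 <- colSums((t(t(z_batch) - g_new))^2)
    d_new <- (0.5 * sum2 + b_prior) / (n / 2 + a_prior - 1)
    change <- max(abs(g_new - g_old) / abs(g_old + 1e-12),
                  abs(d_new - d_old) / abs(d_old + 1e-12))
    g_old <- g_new; d_old <- d_new
    if (change < conv) break
  }
  list(gamma_star = g_old, delta_star = d_old)
}

#' Fit a ComBat harmonization model
#'
#' @param table a `feature_table` (or plain data frame) holding the
#'   training rows.
#' @param batch_col name of the batch column.
#' @param covariates optional character vector of column names whose
#'   effects (e.g. the class label) must be preserved.
#' @param eb use empirical-Bayes shrinkage (default) or plain
#'   location-scale adjustment.
#' @return an object of class `combat_model`.
#' @export
fit_combat <- function(table, batch_col = "batch", covariates = NULL,
                       eb = TRUE) {
  feats <- feature_columns(table)
  X <- as.matrix(table[, feats, drop = FALSE])
  batch <- factor(table[[batch_col]])
  batches <- levels(batch)
  if (length(batches) < 2) {
    warning("single batch: returning an identity harmonization model")
    return(structure(list(identity = TRUE, features = feats,
                          batch_col = batch_col, batches = batches),
                     class = "combat_model"))
  }
  if (any(table(batch) < 3)) stop("every batch needs >= 3 rows")
  n <- nrow(X); p <- ncol(X)
  keep <- apply(X, 2, function(x) stats::sd(x) > 1e-12)
  mod <- NULL
  if (!is.null(covariates)) {
    mod <- stats::model.matrix(~ ., data = table[, covariates, drop = FALSE])[, -1, drop = FALSE]
  }
  bm <- stats::model.matrix(~ 0 + batch)
  nb <- length(batches)
  batch_w <- as.numeric(table(batch)) / n
  Xk <- X[, keep, drop = FALSE]
  confounded <- !is.null(mod) &&
    qr(cbind(bm, mod))$rank < nb + ncol(mod)
  if (confounded) {
    # batch and covariates are collinear: the joint model cannot split the
    # shared variation, so attribute it to the covariates (protecting the
    # biological effect) and estimate batch effects on the residuals
    warning("covariate(s) confounded with batch; shared variation is ",
            "attributed to the covariates")
    cf <- stats::lm.fit(cbind(1, mod), Xk)
    beta_cov <- cf$coefficients[-1, , drop = FALSE]
    Xw <- Xk - mod %*% beta_cov
    beta_b <- solve(crossprod(bm), crossprod(bm, Xw))
    resid <- Xw - bm %*% beta_b
  } else {
    design <- cbind(bm, mod)
    beta <- solve(crossprod(design), crossprod(design, Xk))
    beta_b <- beta[seq_len(nb), , drop = FALSE]
    beta_cov <- if (!is.null(mod)) beta[-seq_len(nb), , drop = FALSE]
                else NULL
    resid <- Xk - design %*% beta
  }
  grand_mean <- crossprod(batch_w, beta_b)
  stand_mean <- matrix(grand_mean, n, sum(keep), byrow = TRUE)
  mod_effect <- if (!is.null(mod)) mod %*% beta_cov else 0
  var_pooled <- colSums(resid^2) / n
  var_pooled[var_pooled < 1e-12] <- 1e-12
  Z <- (Xk - stand_mean - mod_effect) /
    matrix(sqrt(var_pooled), n, sum(keep), byrow = TRUE)
  gamma_hat <- t(vapply(batches, function(b)
    colMeans(Z[batch == b, , drop = FALSE]), numeric(sum(keep))))
  # population (n) divisor keeps the pipeline self-consistent: refitting
  # on harmonized data yields gamma = 0, delta = 1 exactly
  delta_hat <- t(vapply(batches, function(b) {
    Zb <- Z[batch == b, , drop = FALSE]
    colMeans(sweep(Zb, 2, colMeans(Zb))^2)
  }, numeric(sum(keep))))
  delta_hat[!is.finite(delta_hat) | delta_hat < 1e-12] <- 1e-12
  if (eb) {
    gamma_star <- gamma_hat; delta_star <- delta_hat
    for (bi in seq_along(batches)) {
      pri <- combat_priors_batch(gamma_hat[bi, ], delta_hat[bi, ])
      sol <- combat_it_sol(Z[batch == batches[bi], , drop = FALSE],
                           gamma_hat[bi, ], delta_hat[bi, ],
                           pri$gamma_bar, pri$t2, pri$a_prior, pri$b_prior)
      gamma_star[bi, ] <- sol$gamma_star
      delta_star[bi, ] <- sol$delta_star
    }
  } else {
    gamma_star <- gamma_hat; delta_star <- delta_hat
  }
  delta_star[delta_star < 1e-12] <- 1e-12
  structure(list(identity = FALSE, features = feats, kept = keep,
                 batch_col = batch_col, batches = batches,
                 covariates = covariates, confounded = confounded,
                 beta_cov = beta_cov,
                 grand_mean = as.numeric(grand_mean),
                 var_pooled = var_pooled,
                 gamma_star = gamma_star, delta_star = delta_star,
                 eb = eb),
            class = "combat_model")
}

#' Apply a fitted ComBat model to a feature table
#'
#' Rows are adjusted with the batch parameters learned at fit time; batch
#' ids unseen at fit time raise an error (no silent pass-through).
#' Zero-variance (at fit time) features pass through untouched.
#'
#' @param model a [fit_combat()] model.
#' @param table a `feature_table` whose feature columns are a superset of
#'   the model's.
#' @return the adjusted table, same shape, same row order.
#' @export
apply_combat <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  if (nrow(table) == 0) return(table)
  if (isTRUE(model$identity)) return(table)
  if (!all(model$features %in% names(table)))
    stop("table is missing model features")
  batch <- as.character(table[[model$batch_col]])
  unknown <- setdiff(unique(batch), model$batches)
  if (length(unknown))
    stop("unknown batch id(s): ", paste(unknown, collapse = ", "))
  X <- as.matrix(table[, model$features, drop = FALSE])
  keep <- model$kept
  n <- nrow(X)
  stand_mean <- matrix(model$grand_mean, n, sum(keep), byrow = TRUE)
  mod_effect <- 0
  if (!is.null(model$beta_cov)) {
    mod <- stats::model.matrix(~ ., data = table[, model$covariates,
                                                 drop = FALSE])[, -1, drop = FALSE]
    mod_effect <- mod %*% model$beta_cov
  }
  sdp <- matrix(sqrt(model$var_pooled), n, sum(keep), byrow = TRUE)
  Z <- (X[, keep, drop = FALSE] - stand_mean - mod_effect) / sdp
  bi <- match(batch, model$batches)
  Zadj <- (Z - model$gamma_star[bi, , drop = FALSE]) /
    sqrt(model$delta_star[bi, , drop = FALSE])
  Xadj <- Zadj * sdp + stand_mean + mod_effect
  out <- table
  out[, model$features[keep]] <- Xadj
  out
}
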