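# Closed-form Shapley attributions for the linear signature and fusion
# models. On the margin (logit) scale every model here is exactly linear
# in its standardized features, so the Shapley value with mean imputation
# has the closed form phi_f(x) = w_f (x_f - mean_background(x_f)) and
# local accuracy holds exactly.

# Effective per-feature weights of a model on the logit scale, plus the
# standardization parameters needed to score raw features.
margin_weights <- function(model) {
  if (inherits(model, "signature_model")) {
    w <- model$logistic[2] * model$weights
    list(weights = stats::setNames(as.numeric(w), names(model$weights)),
         centre = model$centre, scale = model$scale,
         const = unname(model$logistic[1] + model$logistic[2] * model$intercept),
         region = stats::setNames(rep(model$region, length(w)), names(w)),
         sequence = stats::setNames(rep(model$sequence, length(w)), names(w)))
  } else if (inherits(model, "fusion_model")) {
    co <- model$coefficients
    wa <- margin_weights_rs(model$parents$a, co["rs_a"])
    wb <- margin_weights_rs(model$parents$b, co["rs_b"])
    nm <- c(paste(wa$sequence, names(wa$weights), sep = "."),
            paste(wb$sequence, names(wb$weights), sep = "."))
    list(weights = stats::setNames(c(wa$weights, wb$weights), nm),
         centre = stats::setNames(c(wa$centre, wb$centre), nm),
         scale = stats::setNames(c(wa$scale, wb$scale), nm),
         const = unname(co["(Intercept)"] + wa$const + wb$const),
         feature = stats::setNames(c(names(wa$weights), names(wb$weights)), nm),
         region = stats::setNames(c(wa$region, wb$region), nm),
         sequence = stats::setNames(c(wa$sequence, wb$sequence), nm))
  } else stop("model must be a signature_model or fusion_model")
}

margin_weights_rs <- function(sig, coef_parent) {
  w <- as.numeric(coef_parent) * sig$weights
  list(weights = w, centre = sig$centre, scale = sig$scale,
       const = as.numeric(coef_parent) * sig$intercept,
       region = stats::setNames(rep(sig$region, length(w)), names(w)),
       sequence = stats::setNames(rep(sig$sequence, length(w)), names(w)))
}

# Raw feature matrix (patients x model features) for a model from a
# feature_table; fusion models draw each parent's features from its own
# region x sequence rows.
model_feature_matrix <- function(model, table) {
  if (inherits(model, "signature_model")) {
    rows <- table$region == model$region & table$sequence == model$sequence
    tab <- table[rows, , drop = FALSE]
    X <- as.matrix(tab[, model$features, drop = FALSE])
    rownames(X) <- tab$patient_id
    return(list(X = X, patient_id = tab$patient_id, split = tab$split,
                label = tab$label))
  }
  ma <- model_feature_matrix(model$parents$a, table)
  mb <- model_feature_matrix(model$parents$b, table)
  common <- intersect(ma$patient_id, mb$patient_id)
  ia <- match(common, ma$patient_id); ib <- match(common, mb$patient_id)
  X <- cbind(ma$X[ia, , drop = FALSE], mb$X[ib, , drop = FALSE])
  colnames(X) <- c(paste(model$parents$a$sequence, colnames(ma$X), sep = "."),
                   paste(model$parents$b$sequence, colnames(mb$X), sep = "."))
  list(X = X, patient_id = common, split = ma$split[ia], label = ma$label[ia])
}

#' Exact Shapley attributions for a linear model
#'
#' Margin-scale (logit) attributions
#' `phi_f(x) = w_f (x_f - mean_background(x_f))` with base value equal to
#' the model margin at the background means; `sum(phi) + base` equals the
#' patient's margin exactly. For a fusion model the attributions are
#' chain-ruled through the fusion coefficients down to the underlying
#' features (the model is linear end to end on the margin scale, so this
#' remains exact); a parent-level attribution over the two RS inputs is
#' included as well.
#'
#' @param model a `signature_model` or `fusion_model`.
#' @param table a `feature_table` with the rows to explain.
#' @param background_split split used as the background distribution
#'   (default `"train"`).
#' @return a `shap_report`: `phi` (patients x features), `base`,
#'   `margin`, `mean_abs` ranking, `feature_values`, and for fusion
#'   models `parent_phi`.
#' @export
linear_shap <- function(model, table, background_split = "train") {
  mw <- margin_weights(model)
  fm <- model_feature_matrix(model, table)
  missing <- setdiff(names(mw$weights), colnames(fm$X))
  if (length(missing)) stop("features missing from table: ",
                            paste(missing, collapse = ", "))
  X <- fm$X[, names(mw$weights), drop = FALSE]
  bg <- fm$split == background_split
  if (!any(bg)) stop("empty background split: ", background_split)
  Xs <- sweep(sweep(X, 2, mw$centre), 2, mw$scale, "/")
  bg_mean <- colMeans(Xs[bg, , drop = FALSE])
  phi <- sweep(Xs, 2, bg_mean) %*% diag(mw$weights, length(mw$weights))
  colnames(phi) <- names(mw$weights)
  base <- mw$const + sum(mw$weights * bg_mean)
  margin <- as.numeric(Xs %*% mw$weights + mw$const)
  parent_phi <- NULL
  if (inherits(model, "fusion_model")) {
    pa <- predict(model$parents$a, table); pb <- predict(model$parents$b, table)
    ia <- match(fm$patient_id, pa$patient_id)
    ib <- match(fm$patient_id, pb$patient_id)
    co <- model$coefficients
    rs <- cbind(rs_a = pa$rs[ia], rs_b = pb$rs[ib])
    rs_bg <- colMeans(rs[bg, , drop = FALSE])
    parent_phi <- sweep(rs, 2, rs_bg) %*% diag(co[c("rs_a", "rs_b")])
    colnames(parent_phi) <- c(
      paste(model$parents$a$sequence, model$parents$a$region, sep = "-"),
      paste(model$parents$b$sequence, model$parents$b$region, sep = "-"))
  }
  structure(list(phi = phi, base = base, margin = margin,
                 patient_id = fm$patient_id, split = fm$split,
                 label = fm$label,
                 feature_values = X,
                 mean_abs = sort(colMeans(abs(phi)), decreasing = TRUE),
                 parent_phi = parent_phi),
            class = "shap_report")
}

#' SHAP summary artifacts
#'
#' Bar chart of mean absolute attributions and a beeswarm-style plot of
#' per-patient attributions colored by feature value.
#'
#' @param report a [linear_shap()] report.
#' @param file_prefix when given, `<prefix>_bar.png` and
#'   `<prefix>_beeswarm.png` are written.
#' @return invisibly, the mean-|phi| ranking (named, decreasing).
#' @export
shap_summaries <- function(report, file_prefix = NULL) {
  stopifnot(inherits(report, "shap_report"))
  rk <- report$mean_abs
  if (!is.null(file_prefix)) {
    grDevices::png(paste0(file_prefix, "_bar.png"), width = 700, height = 450)
    graphics::par(mar = c(4, 16, 2, 1))
    graphics::barplot(rev(rk), horiz = TRUE, las = 1,
                      xlab = "mean |SHAP| (logit scale)", cex.names = 0.7)
    grDevices::dev.off()
    grDevices::png(paste0(file_prefix, "_beeswarm.png"), width = 700,
                   height = 450)
    graphics::par(mar = c(4, 16, 2, 1))
    nf <- length(rk)
    graphics::plot(NULL, xlim = range(report$phi), ylim = c(0.5, nf + 0.5),
                   yaxt = "n", xlab = "SHAP value (logit scale)", ylab = "")
    graphics::axis(2, at = seq_len(nf), labels = rev(names(rk)), las = 1,
                   cex.axis = 0.7)
    for (i in seq_len(nf)) {
      f <- rev(names(rk))[i]
      v <- report$feature_values[, f]
      colv <- grDevices::rgb(stats::ecdf(v)(v), 0.2, 1 - stats::ecdf(v)(v))
      graphics::points(report$phi[, f],
                       i + stats::runif(nrow(report$phi), -0.2, 0.2),
                       col = colv, pch = 16, cex = 0.6)
    }
    grDevices::dev.off()
  }
  invisible(rk)
}

#' Feature correlation and clustered heatmaps
#'
#' Spearman correlation matrix of the selected features and a patient x
#' feature heatmap with rows and columns ordered by Ward dendrograms.
#' Constant features are excluded with a warning.
#'
#' @param X numeric matrix (patients x selected features).
#' @param labels binary labels (row annotation).
#' @param file_prefix when given, `<prefix>_cor.png` and
#'   `<prefix>_clustered.png` are written.
#' @return list with `cor` (Spearman matrix), `row_order`, `col_order`.
#' @export
feature_heatmaps <- function(X, labels, file_prefix = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 features")
  keep <- apply(X, 2, function(x) stats::sd(x) > 1e-12)
  if (any(!keep)) warning(sum(!keep), " constant feature(s) excluded")
  X <- X[, keep, drop = FALSE]
  cm <- stats::cor(X, method = "spearman")
  Z <- scale(X)
  ro <- stats::hclust(stats::dist(Z), method = "ward.D2")$order
  co <- stats::hclust(stats::dist(t(Z)), method = "ward.D2")$order
  if (!is.null(file_prefix)) {
    grDevices::png(paste0(file_prefix, "_cor.png"), width = 650, height = 600)
    graphics::par(mar = c(12, 12, 2, 1))
    graphics::image(seq_len(ncol(cm)), seq_len(ncol(cm)),
                    cm[co, co], zlim = c(-1, 1),
                    col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                    xlab = "", ylab = "", axes = FALSE,
                    main = "Spearman correlation")
    graphics::axis(1, seq_len(ncol(cm)), colnames(cm)[co], las = 2, cex.axis = 0.6)
    graphics::axis(2, seq_len(ncol(cm)), colnames(cm)[co], las = 1, cex.axis = 0.6)
    grDevices::dev.off()
    grDevices::png(paste0(file_prefix, "_clustered.png"), width = 700,
                   height = 600)
    graphics::par(mar = c(12, 4, 2, 6))
    graphics::image(seq_len(ncol(Z)), seq_len(nrow(Z)), t(Z[ro, co]),
                    col = grDevices::hcl.colors(64, "viridis"),
                    xlab = "", ylab = "patients (Ward order)", axes = FALSE,
                    main = "patients x features")
    graphics::axis(1, seq_len(ncol(Z)), colnames(Z)[co], las = 2,
                   cex.axis = 0.6)
    lab_col <- ifelse(labels[ro] == 1, "red", "blue")
    graphics::mtext(side = 4, at = seq_len(nrow(Z)),
                    text = rep("|", nrow(Z)), col = lab_col, line = 0.5,
                    cex = 0.4, las = 1)
    grDevices::dev.off()
  }
  list(cor = cm, row_order = ro, col_order = co)
}
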