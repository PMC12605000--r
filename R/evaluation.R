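# Discrimination, calibration and clinical-utility metrics. AUC uses the
# Mann-Whitney pair-counting identity (ties count 1/2); its CI and the
# paired model comparison use the DeLong placement-value covariance.

#' AUC by the Mann-Whitney identity
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels.
#' @return scalar AUC.
#' @export
auc_mw <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: V10 (per positive) and V01 (per negative).
delong_placements <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  V10 <- vapply(pos, function(x) mean((x > neg) + 0.5 * (x == neg)),
                numeric(1))
  V01 <- vapply(neg, function(y) mean((pos > y) + 0.5 * (pos == y)),
                numeric(1))
  list(V10 = V10, V01 = V01, auc = mean(V10))
}

#' ROC AUC with a DeLong confidence interval
#'
#' @inheritParams auc_mw
#' @param conf confidence level.
#' @return list with `auc`, `se`, `ci` (clamped to \[0, 1\]).
#' @export
roc_auc <- function(scores, labels, conf = 0.95) {
  pl <- delong_placements(scores, labels)
  s2 <- stats::var(pl$V10) / length(pl$V10) +
        stats::var(pl$V01) / length(pl$V01)
  se <- sqrt(s2)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  list(auc = pl$auc, se = se,
       ci = c(max(0, pl$auc - z * se), min(1, pl$auc + z * se)))
}

confusion_metrics <- function(scores, labels, cutoff) {
  pred <- as.integer(scores >= cutoff)
  labels <- as.integer(labels)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  sen <- tp / (tp + fn); spe <- tn / (tn + fp)
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (is.na(ppv) || ppv + sen == 0) NA_real_
        else 2 * ppv * sen / (ppv + sen)
  c(ACC = (tp + tn) / length(labels), SEN = sen, SPE = spe,
    PPV = ppv, NPV = npv, F1 = f1, TP = tp, FP = fp, TN = tn, FN = fn)
}

#' Youden-optimal cutoff and operating metrics
#'
#' Scans the midpoints of adjacent distinct scores (plus outer sentinels);
#' the cutoff maximizing `J = SEN + SPE - 1` is returned, ties broken
#' toward higher specificity. Classification is `score >= cutoff`.
#'
#' @inheritParams auc_mw
#' @return list with `cutoff`, `J`, and the confusion-matrix metrics at
#'   the cutoff.
#' @export
youden_cutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  s <- sort(unique(scores))
  cand <- if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)
  cand <- c(min(s) - 1, cand, max(s) + 1)
  stats_ <- vapply(cand, function(ct) {
    m <- confusion_metrics(scores, labels, ct)
    c(J = unname(m["SEN"] + m["SPE"] - 1), SPE = unname(m["SPE"]))
  }, numeric(2))
  jmax <- max(stats_["J", ])
  at <- which(stats_["J", ] >= jmax - 1e-12)
  best <- at[which.max(stats_["SPE", at])]
  ct <- cand[best]
  out <- as.list(confusion_metrics(scores, labels, ct))
  c(list(cutoff = ct, J = jmax), out)
}

#' DeLong test for two correlated AUCs
#'
#' Paired comparison of two score vectors on identical patients via the
#' placement-value covariance; two-sided z-test on the AUC difference.
#' Identical score vectors (zero variance of the difference) return
#' `p = 1` with a degeneracy flag.
#'
#' @param scores_a,scores_b paired score vectors.
#' @param labels binary labels.
#' @return list with `auc_a`, `auc_b`, `diff`, `var`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must be paired")
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  n1 <- length(pa$V10); n0 <- length(pa$V01)
  s10 <- stats::cov(cbind(pa$V10, pb$V10))
  s01 <- stats::cov(cbind(pa$V01, pb$V01))
  S <- s10 / n1 + s01 / n0
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (v < 1e-14)
    return(list(auc_a = pa$auc, auc_b = pb$auc, diff = d, var = v,
                z = NA_real_, p = 1, degenerate = TRUE))
  z <- d / sqrt(v)
  list(auc_a = pa$auc, auc_b = pb$auc, diff = d, var = v, z = z,
       p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area (precision steps at each recall increment, tied
#' scores grouped), with an optional seeded percentile-bootstrap CI.
#'
#' @inheritParams auc_mw
#' @param boot bootstrap replicates for the CI (0 = point estimate only).
#' @param conf confidence level.
#' @param seed bootstrap seed.
#' @return list with `auprc` and (when `boot > 0`) `ci`.
#' @export
auprc <- function(scores, labels, boot = 0L, conf = 0.95, seed = 1L) {
  labels <- as.integer(labels)
  if (sum(labels == 1) == 0) stop("need at least one positive")
  point <- function(sc, y) {
    o <- order(sc, decreasing = TRUE)
    y <- y[o]; sc <- sc[o]
    grp <- cumsum(!duplicated(sc))
    tp <- cumsum(y); fp <- cumsum(1 - y)
    last <- !duplicated(grp, fromLast = TRUE)    # end of each tie group
    tp <- tp[last]; fp <- fp[last]
    rec <- tp / sum(y); prec <- tp / (tp + fp)
    sum(diff(c(0, rec)) * prec)
  }
  est <- point(scores, labels)
  if (boot <= 0) return(list(auprc = est))
  bs <- with_seed(seed, vapply(seq_len(boot), function(b) {
    i <- sample(length(labels), replace = TRUE)
    if (sum(labels[i]) == 0 || sum(1 - labels[i]) == 0) return(NA_real_)
    point(scores[i], labels[i])
  }, numeric(1)))
  a <- (1 - conf) / 2
  list(auprc = est,
       ci = unname(stats::quantile(bs, c(a, 1 - a), na.rm = TRUE)))
}

#' Calibration curve and logistic recalibration
#'
#' Quantile-binned observed-vs-predicted points plus the recalibration
#' intercept (offset model) and slope (logit model).
#'
#' @param probs predicted probabilities in \[0, 1\].
#' @param labels binary outcomes.
#' @param bins quantile bins (default 5).
#' @return list with `curve` (data frame of bin mean predicted/observed),
#'   `intercept`, `slope`.
#' @export
calibration_curve <- function(probs, labels, bins = 5L) {
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  if (length(unique(probs)) < 2) {
    if (length(unique(probs)) < 1) stop("need probabilities")
    # all probabilities identical: a single degenerate bin
    return(list(curve = data.frame(mean_pred = probs[1],
                                   mean_obs = mean(labels),
                                   n = length(labels)),
                intercept = NA_real_, slope = NA_real_))
  }
  eps <- 1e-8
  lp <- stats::qlogis(pmin(pmax(probs, eps), 1 - eps))
  qs <- unique(stats::quantile(probs, seq(0, 1, length.out = bins + 1)))
  bin <- cut(probs, qs, include.lowest = TRUE)
  curve <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    data.frame(mean_pred = mean(probs[i]), mean_obs = mean(labels[i]),
               n = sum(i))
  }))
  slope_fit <- suppressWarnings(stats::glm(labels ~ lp, family = stats::binomial()))
  int_fit <- suppressWarnings(stats::glm(labels ~ offset(lp),
                                         family = stats::binomial()))
  list(curve = curve, intercept = unname(stats::coef(int_fit)[1]),
       slope = unname(stats::coef(slope_fit)[2]))
}

#' Decision-curve analysis
#'
#' Net benefit `NB(pt) = TP/N - (FP/N) pt/(1 - pt)` for the model
#' thresholded at each `pt`, alongside treat-all and treat-none curves.
#'
#' @param probs predicted probabilities.
#' @param labels binary outcomes.
#' @param thresholds threshold-probability grid in (0, 1); 1 is excluded.
#' @return data frame with `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.60, by = 0.01)) {
  thresholds <- thresholds[thresholds > 0 & thresholds < 1]
  labels <- as.integer(labels)
  N <- length(labels)
  prev <- mean(labels)
  do.call(rbind, lapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
    w <- pt / (1 - pt)
    data.frame(threshold = pt,
               nb_model = tp / N - (fp / N) * w,
               nb_all = prev - (1 - prev) * w,
               nb_none = 0)
  }))
}

#' Waterfall data of per-patient predictions
#'
#' Patients sorted by predicted probability with label coloring data and
#' misclassification flags at the supplied cutoff; `high_conf_misclass`
#' counts misclassified patients whose probability is far (> `margin`)
#' from the cutoff.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels.
#' @param cutoff operating cutoff.
#' @param patient_id optional ids.
#' @param margin high-confidence margin (default 0.2).
#' @return data frame sorted by probability (attribute
#'   `"high_conf_misclass"` holds the count).
#' @export
waterfall <- function(probs, labels, cutoff, patient_id = NULL,
                      margin = 0.2) {
  patient_id <- patient_id %||% seq_along(probs)
  o <- order(probs)
  df <- data.frame(patient_id = patient_id[o], prob = probs[o],
                   label = as.integer(labels)[o])
  df$bar <- df$prob - cutoff
  df$predicted <- as.integer(df$prob >= cutoff)
  df$misclassified <- df$predicted != df$label
  attr(df, "high_conf_misclass") <-
    sum(df$misclassified & abs(df$prob - cutoff) > margin)
  df
}

#' Cohort characteristics table
#'
#' Per split: mean +/- SD with Mann-Whitney p for continuous covariates;
#' counts (%) with chi-square p (Yates continuity correction for 2x2) for
#' categorical ones. Expected cell counts below 1 trigger a flagged
#' Fisher-exact fallback; constant columns are dropped with a warning.
#'
#' @param clinical the clinical table (needs `label` and `split`).
#' @param continuous,categorical covariate column names.
#' @return data frame of per-split, per-variable summaries and p-values.
#' @export
cohort_characteristics <- function(clinical,
                                   continuous = c("age", "cea", "cyfra", "nse"),
                                   categorical = c("gender", "smoking",
                                                   "ps_score")) {
  rows <- list()
  for (sp in unique(clinical$split)) {
    sub <- clinical[clinical$split == sp, ]
    if (min(table(sub$label)) < 2)
      stop("need >= 2 patients per class in split ", sp)
    for (v in continuous) {
      x <- sub[[v]]
      if (stats::sd(x) < 1e-12) { warning("constant column dropped: ", v); next }
      p <- suppressWarnings(
        stats::wilcox.test(x[sub$label == 1], x[sub$label == 0])$p.value)
      rows[[length(rows) + 1]] <- data.frame(
        split = sp, variable = v, type = "continuous",
        summary_pos = sprintf("%.2f ± %.2f", mean(x[sub$label == 1]),
                              stats::sd(x[sub$label == 1])),
        summary_neg = sprintf("%.2f ± %.2f", mean(x[sub$label == 0]),
                              stats::sd(x[sub$label == 0])),
        test = "mann-whitney", p = p)
    }
    for (v in categorical) {
      x <- factor(sub[[v]])
      if (nlevels(x) < 2) { warning("constant column dropped: ", v); next }
      tab <- table(x, sub$label)
      exp_ <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_ < 1)) {
        p <- stats::fisher.test(tab)$p.value
        test <- "fisher (exact fallback)"
      } else {
        p <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
        test <- "chi-square (Yates for 2x2)"
      }
      fmt <- function(cl) paste(sprintf("%s:%d (%.1f%%)", rownames(tab),
                                        tab[, cl],
                                        100 * tab[, cl] / sum(tab[, cl])),
                                collapse = "; ")
      rows[[length(rows) + 1]] <- data.frame(
        split = sp, variable = v, type = "categorical",
        summary_pos = fmt("1"), summary_neg = fmt("0"), test = test, p = p)
    }
  }
  do.call(rbind, rows)
}

#' Evaluate a model on every split
#'
#' Computes per-split AUC (DeLong CI), AUPRC (bootstrap CI), operating
#' metrics at the training-frozen cutoff, calibration and decision
#' curves, and waterfall data.
#'
#' @param pred a prediction frame from [predict.signature_model()] or
#'   [predict.fusion_model()].
#' @param cutoff operating cutoff (the model's training Youden cutoff; a
#'   per-split Youden refit is available via `refit_cutoff`).
#' @param boot bootstrap replicates for the AUPRC CI.
#' @param refit_cutoff re-derive the Youden cutoff per split (default
#'   off: the training cutoff is frozen).
#' @param seed bootstrap seed.
#' @return an `evaluation_report`: one row per split (`metrics`), plus
#'   lists of calibration, decision and waterfall artifacts per split.
#' @export
evaluate_predictions <- function(pred, cutoff, boot = 200L,
                                 refit_cutoff = FALSE, seed = 1L) {
  splits <- unique(pred$split)
  metrics <- list(); calib <- list(); dca <- list(); wf <- list()
  for (sp in splits) {
    sub <- pred[pred$split == sp, ]
    if (length(unique(sub$label)) < 2) next
    ra <- roc_auc(sub$prob, sub$label)
    pr <- auprc(sub$prob, sub$label, boot = boot,
                seed = child_seed(seed, sp))
    ct <- if (refit_cutoff) youden_cutoff(sub$prob, sub$label)$cutoff
          else cutoff
    cm <- confusion_metrics(sub$prob, sub$label, ct)
    metrics[[sp]] <- data.frame(
      split = sp, n = nrow(sub), auc = ra$auc,
      auc_lo = ra$ci[1], auc_hi = ra$ci[2],
      auprc = pr$auprc,
      auprc_lo = if (!is.null(pr$ci)) pr$ci[1] else NA_real_,
      auprc_hi = if (!is.null(pr$ci)) pr$ci[2] else NA_real_,
      cutoff = ct, ACC = cm["ACC"], SEN = cm["SEN"], SPE = cm["SPE"],
      PPV = cm["PPV"], NPV = cm["NPV"], F1 = cm["F1"])
    calib[[sp]] <- calibration_curve(sub$prob, sub$label)
    dca[[sp]] <- decision_curve(sub$prob, sub$label)
    wf[[sp]] <- waterfall(sub$prob, sub$label, ct, sub$patient_id)
  }
  structure(list(metrics = do.call(rbind, metrics), calibration = calib,
                 decision = dca, waterfall = wf),
            class = "evaluation_report")
}
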