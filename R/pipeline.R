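# Config-driven orchestration: simulate -> partition -> extract ->
# harmonize -> fit -> evaluate -> explain, with per-stage caching so a
# rerun recomputes only deleted stages, and every random draw seeded from
# the single config seed.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] (to simulate) or a directory written by
#'   [write_cohort()] (to load).
#' @param sequences sequences to analyze.
#' @param w,B,M,K_range partitioning parameters (entropy window and bins,
#'   superpixels per lesion, candidate cluster counts).
#' @param preprocess a [preprocess_spec()].
#' @param harmonize `"combat"` or `"none"` (both are first-class paths;
#'   the config records which ran).
#' @param icc use ICC mask-jitter reproducibility filtering.
#' @param icc_threshold retention threshold.
#' @param icc_patients how many patients for the repeat extraction.
#' @param alpha,lambda_rule selection parameters.
#' @param boot bootstrap replicates for AUPRC CIs.
#' @param seed master seed; every stochastic call derives its stream from
#'   it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            sequences = c("T1W", "T2FS"),
                            w = 9L, B = 32L, M = 30L, K_range = 2:10,
                            preprocess = preprocess_spec(),
                            harmonize = c("none", "combat"),
                            icc = TRUE, icc_threshold = 0.80,
                            icc_patients = 30L,
                            alpha = 0.05, lambda_rule = "min",
                            boot = 200L, seed = 1L) {
  harmonize <- match.arg(harmonize)
  structure(list(cohort = cohort, sequences = sequences, w = w, B = B,
                 M = M, K_range = K_range, preprocess = preprocess,
                 harmonize = harmonize, icc = icc,
                 icc_threshold = icc_threshold, icc_patients = icc_patients,
                 alpha = alpha, lambda_rule = lambda_rule, boot = boot,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; the `cohort`
#' section is passed to [cohort_spec()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- if (is.character(y$cohort)) y$cohort
            else do.call(cohort_spec, y$cohort %||% list())
  pp <- do.call(preprocess_spec, y$preprocess %||% list())
  args <- y[setdiff(names(y), c("cohort", "preprocess"))]
  do.call(pipeline_config, c(list(cohort = cohort, preprocess = pp), args))
}

stage_cached <- function(out_dir, name, compute) {
  f <- file.path(out_dir, "cache", paste0(name, ".rds"))
  if (file.exists(f)) return(readRDS(f))
  val <- compute()
  dir.create(dirname(f), showWarnings = FALSE, recursive = TRUE)
  saveRDS(val, f)
  val
}

#' Validate cohort inputs
#'
#' Checks image/mask grid agreement, nonempty masks, and completeness of
#' split, batch and label columns; patients missing a sequence are
#' flagged as warnings (excluded downstream), geometry mismatches are
#' hard errors.
#'
#' @param cohort a `habitat_cohort`.
#' @param sequences sequences every patient must carry.
#' @return data frame of findings (`severity` is `"error"` or
#'   `"warning"`); zero rows means a clean manifest.
#' @export
validate_inputs <- function(cohort, sequences = c("T1W", "T2FS")) {
  findings <- list()
  note <- function(sev, pid, msg)
    findings[[length(findings) + 1]] <<- data.frame(
      severity = sev, patient_id = pid, message = msg)
  cl <- cohort$clinical
  for (col in c("label", "split", "batch"))
    if (any(is.na(cl[[col]])))
      note("error", "*", paste("missing values in", col))
  if (!all(cl$label %in% 0:1)) note("error", "*", "label not in {0,1}")
  for (pid in cl$patient_id) {
    vols <- cohort$volumes[[pid]]
    if (is.null(vols)) { note("error", pid, "no image data"); next }
    miss <- setdiff(sequences, names(vols))
    if (length(miss))
      note("warning", pid,
           paste("missing sequence(s):", paste(miss, collapse = ","),
                 "- patient excluded"))
    for (sq in intersect(sequences, names(vols))) {
      v <- vols[[sq]]
      if (!identical(dim(v$image), dim(v$mask)))
        note("error", pid, paste(sq, "image/mask grid mismatch"))
      else if (!any(v$mask)) note("error", pid, paste(sq, "empty mask"))
    }
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(severity = character(), patient_id = character(),
                  message = character())
}

#' Run the full habitat-radiomics pipeline
#'
#' Executes every stage on the configured cohort and writes artifacts
#' (JSON/CSV tables, plots) under `out_dir`. Stages are cached as RDS
#' under `out_dir/cache`; deleting one cache file recomputes only that
#' stage and those after it that depend on it. Models fitted: per
#' sequence, signatures for S1, S2 and the whole tumor; a combined
#' whole-tumor model across sequences; and the multi-sequence regional
#' fusion model built on the best subregion (by training AUC) of each
#' sequence.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory.
#' @return a `pipeline_run` list: cohort, partition run, feature tables,
#'   models, evaluation tables (`report$metrics` mirrors the model x
#'   split layout), DeLong comparisons, SHAP report, file manifest.
#' @export
run_pipeline <- function(config, out_dir = tempfile("habitrad_run_")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(config = rapply(unclass(config), unclass, how = "replace"),
         package_version = as.character(utils::packageVersion("habitrad"))),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  cohort <- stage_cached(out_dir, "cohort", function() {
    if (is.character(config$cohort)) read_cohort(config$cohort)
    else generate_cohort(config$cohort)
  })
  val <- validate_inputs(cohort, config$sequences)
  if (any(val$severity == "error"))
    stop("input validation failed:\n",
         paste(val$message[val$severity == "error"], collapse = "\n"))

  part <- stage_cached(out_dir, "partition", function()
    partition_cohort(cohort, sequences = config$sequences, w = config$w,
                     B = config$B, M = config$M, K_range = config$K_range,
                     seed = child_seed(config$seed, "partition")))

  feats <- stage_cached(out_dir, "features", function()
    extract_features(cohort, part, config$preprocess))

  icc_retained <- stage_cached(out_dir, "icc", function() {
    if (!config$icc) return(NULL)
    ids <- with_seed(child_seed(config$seed, "icc_subset"),
                     sample(names(cohort$volumes),
                            min(config$icc_patients,
                                length(cohort$volumes))))
    tab_a <- feats[feats$patient_id %in% ids, , drop = FALSE]
    tab_b <- extract_features_repeat(cohort, part, config$preprocess,
                                     patients = ids,
                                     seed = child_seed(config$seed, "icc"))
    key <- function(t) paste(t$patient_id, t$sequence, t$region)
    common <- intersect(key(tab_a), key(tab_b))
    tab_a <- tab_a[key(tab_a) %in% common, , drop = FALSE]
    tab_b <- tab_b[key(tab_b) %in% common, , drop = FALSE]
    # reproducibility is judged per sequence x region: a feature can be
    # stable in the inner habitat yet boundary-sensitive in the rim
    out <- list()
    for (sq in unique(tab_a$sequence)) for (rg in unique(tab_a$region)) {
      sel_a <- tab_a$sequence == sq & tab_a$region == rg
      sel_b <- tab_b$sequence == sq & tab_b$region == rg
      if (sum(sel_a) < 3) next
      rep_ <- suppressWarnings(
        icc_filter(tab_a[sel_a, , drop = FALSE],
                   tab_b[sel_b, , drop = FALSE],
                   threshold = config$icc_threshold))
      out[[paste(sq, rg)]] <- rep_$feature[rep_$retained]
    }
    out
  })

  feats_h <- stage_cached(out_dir, "harmonize", function() {
    if (config$harmonize != "combat") return(feats)
    tr <- feats[feats$split == "train", , drop = FALSE]
    model <- fit_combat(tr, batch_col = "batch", covariates = "label")
    apply_combat(model, feats)
  })

  models <- stage_cached(out_dir, "fit", function() {
    out <- list()
    for (sq in config$sequences) {
      for (rg in c("S1", "S2", "whole")) {
        nm <- sprintf("RS-%s-%s", sq, if (rg == "whole") "W" else rg)
        icc_rg <- if (is.null(icc_retained)) NULL
                  else icc_retained[[paste(sq, rg)]]
        out[[nm]] <- tryCatch(
          build_signature(feats_h, rg, sq, alpha = config$alpha,
                          icc_retained = icc_rg,
                          lambda_rule = config$lambda_rule,
                          seed = child_seed(config$seed, nm)),
          error = function(e) structure(list(error = conditionMessage(e)),
                                        class = "failed_model"))
      }
    }
    ok <- !vapply(out, inherits, logical(1), "failed_model")
    train_auc <- function(m) {
      p <- predict(m, feats_h)
      auc_mw(p$prob[p$split == "train"], p$label[p$split == "train"])
    }
    # best subregion per sequence by training AUC -> fusion parents
    parents <- list()
    for (sq in config$sequences) {
      cand <- sprintf("RS-%s-%s", sq, c("S1", "S2"))
      cand <- cand[cand %in% names(out)[ok]]
      if (length(cand))
        parents[[sq]] <- out[[cand[which.max(vapply(out[cand], train_auc,
                                                    numeric(1)))]]]
    }
    failed <- function(msg) structure(list(error = msg),
                                      class = "failed_model")
    wnames <- sprintf("RS-%s-W", config$sequences)
    out[["RS-W-combined"]] <-
      if (all(wnames %in% names(out)[ok]) && length(wnames) == 2)
        build_fusion(out[[wnames[1]]], out[[wnames[2]]], feats_h)
      else failed("a whole-tumor parent signature is unavailable")
    out[["fusion"]] <-
      if (length(parents) == 2)
        build_fusion(parents[[1]], parents[[2]], feats_h)
      else failed("a subregion parent signature is unavailable")
    out
  })

  report <- stage_cached(out_dir, "evaluate", function() {
    metrics <- list(); preds <- list()
    for (nm in names(models)) {
      m <- models[[nm]]
      if (inherits(m, "failed_model")) next
      p <- predict(m, feats_h)
      preds[[nm]] <- p
      ev <- evaluate_predictions(p, cutoff = m$cutoff, boot = config$boot,
                                 seed = child_seed(config$seed, nm))
      mt <- ev$metrics; mt$model <- nm
      metrics[[nm]] <- mt
    }
    # DeLong comparisons against the fusion model, per split
    dl <- list()
    if ("fusion" %in% names(preds)) {
      for (nm in setdiff(names(preds), "fusion")) {
        pf <- preds[["fusion"]]; pm <- preds[[nm]]
        common <- intersect(pf$patient_id, pm$patient_id)
        for (sp in unique(pf$split)) {
          i_f <- match(common, pf$patient_id); i_m <- match(common, pm$patient_id)
          sel <- pf$split[i_f] == sp
          if (sum(sel) < 4 || length(unique(pf$label[i_f][sel])) < 2) next
          dt <- delong_test(pf$prob[i_f][sel], pm$prob[i_m][sel],
                            pf$label[i_f][sel])
          dl[[length(dl) + 1]] <- data.frame(
            model_a = "fusion", model_b = nm, split = sp,
            auc_a = dt$auc_a, auc_b = dt$auc_b, p = dt$p)
        }
      }
    }
    list(metrics = do.call(rbind, metrics), predictions = preds,
         delong = if (length(dl)) do.call(rbind, dl) else NULL)
  })

  shap <- stage_cached(out_dir, "explain", function() {
    if (!"fusion" %in% names(models)) return(NULL)
    rep_ <- linear_shap(models[["fusion"]], feats_h)
    shap_summaries(rep_, file.path(out_dir, "shap"))
    feature_heatmaps(rep_$feature_values, rep_$label,
                     file.path(out_dir, "features"))
    rep_
  })

  utils::write.csv(report$metrics, file.path(out_dir, "model_metrics.csv"),
                   row.names = FALSE)
  if (!is.null(report$delong))
    utils::write.csv(report$delong, file.path(out_dir, "delong_tests.csv"),
                     row.names = FALSE)
  jsonlite::write_json(
    list(metrics = report$metrics, delong = report$delong,
         shap_mean_abs = if (!is.null(shap)) as.list(shap$mean_abs)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    force = TRUE)

  structure(list(out_dir = out_dir, cohort = cohort, partition = part,
                 features = feats, features_harmonized = feats_h,
                 icc_retained = icc_retained, models = models,
                 report = report, shap = shap, validation = val),
            class = "pipeline_run")
}
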