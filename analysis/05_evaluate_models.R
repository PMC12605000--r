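#!/usr/bin/env Rscript
# Full evaluation: per-model, per-split AUC (DeLong CI), AUPRC (bootstrap
# CI), operating metrics at the training-frozen Youden cutoff, DeLong
# comparisons against the fusion model, decision curves, calibration and
# waterfall plots.

source(file.path("analysis", "00_config.R"))

cfg <- analysis_config()
run <- run_pipeline(cfg, RUN_DIR)

m <- run$report$metrics
m$split <- factor(m$split, levels = c("train", "internal", "external"))
m <- m[order(m$model, m$split), ]
cat("model x split performance (AUC with DeLong 95% CI):\n")
print(m[, c("model", "split", "n", "auc", "auc_lo", "auc_hi", "auprc",
            "ACC", "SEN", "SPE", "PPV", "NPV", "F1")],
      row.names = FALSE, digits = 3)
utils::write.csv(m, file.path(RESULTS, "table2_model_performance.csv"),
                 row.names = FALSE)

if (!is.null(run$report$delong)) {
  cat("\nDeLong comparisons vs the fusion model:\n")
  print(run$report$delong, row.names = FALSE, digits = 3)
  utils::write.csv(run$report$delong,
                   file.path(RESULTS, "delong_vs_fusion.csv"),
                   row.names = FALSE)
}

# decision-curve, calibration and waterfall artifacts for the fusion model
fus <- run$models[["fusion"]]
pred <- predict(fus, run$features_harmonized)
for (sp in unique(pred$split)) {
  sub <- pred[pred$split == sp, ]
  dc <- decision_curve(sub$prob, sub$label)
  cal <- calibration_curve(sub$prob, sub$label)
  wf <- waterfall(sub$prob, sub$label, fus$cutoff, sub$patient_id)
  utils::write.csv(dc, file.path(RESULTS, sprintf("dca_fusion_%s.csv", sp)),
                   row.names = FALSE)
  grDevices::png(file.path(RESULTS, sprintf("fusion_%s_diagnostics.png", sp)),
                 width = 1200, height = 400)
  graphics::par(mfrow = c(1, 3))
  graphics::plot(dc$threshold, dc$nb_model, type = "l", lwd = 2,
                 xlab = "threshold probability", ylab = "net benefit",
                 main = sprintf("decision curve (%s)", sp))
  graphics::lines(dc$threshold, dc$nb_all, lty = 2)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("fusion", "treat all", "treat none"),
                   lty = c(1, 2, 3), lwd = c(2, 1, 1))
  graphics::plot(cal$curve$mean_pred, cal$curve$mean_obs, type = "b",
                 xlim = 0:1, ylim = 0:1, xlab = "predicted",
                 ylab = "observed",
                 main = sprintf("calibration (%s): slope %.2f", sp,
                                cal$slope))
  graphics::abline(0, 1, lty = 3)
  graphics::barplot(wf$bar, col = ifelse(wf$label == 1, "firebrick",
                                         "steelblue"), border = NA,
                    main = sprintf("waterfall (%s)", sp),
                    ylab = "probability - cutoff")
  grDevices::dev.off()
  cat(sprintf("%s: %d high-confidence misclassification(s)\n", sp,
              attr(wf, "high_conf_misclass")))
}
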