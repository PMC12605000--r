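#' Intraclass correlation coefficient, ICC(A,1)
#'
#' Two-way mixed-effects, absolute-agreement, single-measures ICC from the
#' two-way ANOVA mean squares:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n) (MSC - MSE))`.
#'
#' @param ratings numeric matrix, subjects x raters (here: repeated
#'   extractions).
#' @return scalar ICC in \[-1, 1\].
#' @export
icc_a1 <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 ratings")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}

#' Reproducibility filter over repeated feature extractions
#'
#' Per-feature ICC(A,1) between two extraction passes on the same
#' patients; features with ICC above the threshold are retained. The model
#' form (two-way mixed, absolute agreement, single measures) is recorded
#' in the report. Zero-variance features have undefined ICC and are
#' dropped.
#'
#' @param table_a,table_b `feature_table`s with identical patients and
#'   columns (e.g. original and jittered-mask extractions).
#' @param threshold retention threshold (default 0.80; retained means
#'   strictly greater).
#' @return an `icc_report` data frame: `feature`, `icc`, `retained`; the
#'   model form is in attribute `"model"`.
#' @export
icc_filter <- function(table_a, table_b, threshold = 0.80) {
  key <- c("patient_id", "sequence", "region")
  ka <- do.call(paste, c(table_a[intersect(key, names(table_a))], sep = "|"))
  kb <- do.call(paste, c(table_b[intersect(key, names(table_b))], sep = "|"))
  if (!setequal(ka, kb)) stop("the two tables cover different rows")
  table_b <- table_b[match(ka, kb), , drop = FALSE]
  feats <- intersect(feature_columns(table_a), feature_columns(table_b))
  if (!length(feats)) stop("no shared feature columns")
  rows <- lapply(feats, function(f) {
    x <- cbind(table_a[[f]], table_b[[f]])
    if (stats::sd(x) < 1e-12)
      return(data.frame(feature = f, icc = NA_real_, retained = FALSE))
    icc <- icc_a1(x)
    data.frame(feature = f, icc = icc, retained = icc > threshold)
  })
  rep_ <- do.call(rbind, rows)
  drop <- is.na(rep_$icc)
  if (any(drop)) {
    warning(sum(drop), " zero-variance feature(s) dropped from the ICC report")
    rep_ <- rep_[!drop, , drop = FALSE]
  }
  attr(rep_, "model") <- "two-way mixed effects, absolute agreement, single measures (ICC(A,1))"
  attr(rep_, "threshold") <- threshold
  class(rep_) <- c("icc_report", "data.frame")
  rep_
}

#' Jitter a mask by one voxel for repeat extraction
#'
#' Emulates a second delineation: randomly removes a fraction of boundary
#' voxels and adds a fraction of the outer boundary (1-voxel morphological
#' jitter), seeded. Used to produce the second extraction pass for ICC
#' when no second reader exists.
#'
#' @param mask logical 3D array.
#' @param seed RNG seed.
#' @param frac fraction of the (inner/outer) boundary to toggle.
#' @return jittered logical array (never empty).
#' @export
jitter_mask <- function(mask, seed = 1L, frac = 0.5) {
  with_seed(seed, {
    d <- dim(mask)
    nb <- array(0L, d)
    for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)))
      nb <- nb + shift3d(mask + 0L, off[1], off[2], off[3])
    inner_b <- which(mask & nb < 4)          # boundary of the mask
    outer_b <- which(!mask & nb > 0)         # adjacent background
    rm_ <- inner_b[stats::runif(length(inner_b)) < frac]
    add <- outer_b[stats::runif(length(outer_b)) < frac]
    out <- mask
    out[rm_] <- FALSE
    out[add] <- TRUE
    if (!any(out)) out <- mask
    out
  })
}

#' Repeat feature extraction with jittered masks
#'
#' @param cohort a `habitat_cohort`.
#' @param partition_run a [partition_cohort()] result.
#' @param spec a [preprocess_spec()].
#' @param patients patient ids to re-extract (default: all).
#' @param seed RNG seed for the jitter.
#' @param regions regions, as in [extract_features()].
#' @return a `feature_table` from the jittered masks.
#' @export
extract_features_repeat <- function(cohort, partition_run,
                                    spec = preprocess_spec(),
                                    patients = NULL, seed = 1L,
                                    regions = c("S1", "S2", "whole")) {
  run2 <- partition_run
  ids <- patients %||% names(cohort$volumes)
  for (sq in names(run2$partitions)) {
    for (pid in ids) {
      p <- run2$partitions[[sq]][[pid]]
      jm <- jitter_mask(p$label_array > 0L,
                        seed = child_seed(seed, paste0(sq, pid)))
      la <- p$label_array
      la[!jm] <- 0L
      # voxels added by the jitter join the nearest labeled habitat: the
      # marginal habitat, since additions lie on the outer boundary
      la[jm & p$label_array == 0L] <- 1L
      p$label_array <- la
      run2$partitions[[sq]][[pid]] <- p
    }
    run2$partitions[[sq]] <- run2$partitions[[sq]][ids]
  }
  sub <- cohort
  sub$volumes <- cohort$volumes[ids]
  extract_features(sub, run2, spec, regions)
}
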