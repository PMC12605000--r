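#' Voxelwise local-entropy map of a lesion
#'
#' Shannon entropy (bits) of the intensity histogram in a `w` x `w`
#' in-plane neighborhood around every mask voxel, stride 1. Neighborhoods
#' are clipped to the lesion mask so background voxels never contaminate
#' the histogram. Intensities are binned into `B` equal-width bins over the
#' ROI's min-max range. Z-scored copies of entropy and raw intensity
#' (within the ROI) are attached, since both feed the partitioning stage.
#'
#' @param volume a [lesion_volume()].
#' @param w odd window side length (default 9).
#' @param B histogram bin count (default 32).
#' @return an object of class `entropy_map`: `H` (3D array, `NA` outside
#'   the mask), `z_entropy`, `z_intensity` (vectors over mask voxels in
#'   array index order), `mask_idx`, `w`, `B`.
#' @export
local_entropy <- function(volume, w = 9L, B = 32L) {
  stopifnot(inherits(volume, "lesion_volume"))
  w <- as.integer(w); B <- as.integer(B)
  if (w < 3L || w %% 2L == 0L) stop("w must be an odd integer >= 3")
  img <- volume$image; mask <- volume$mask
  d <- dim(img)
  vals <- img[mask]
  rng <- range(vals)
  if (diff(rng) < .Machine$double.eps) {
    bins <- array(1L, d)
  } else {
    bins <- array(0L, d)
    bins[mask] <- pmin(B, 1L + floor(B * (img[mask] - rng[1]) / diff(rng)))
  }
  r <- (w - 1L) %/% 2L
  H <- array(NA_real_, d)
  for (z in seq_len(d[3])) {
    m <- mask[, , z]
    if (!any(m)) next
    bz <- bins[, , z]
    idx <- which(m)
    counts <- matrix(0L, length(idx), B)
    rowpos <- ((idx - 1L) %% d[1]) + 1L
    colpos <- ((idx - 1L) %/% d[1]) + 1L
    for (dx in -r:r) for (dy in -r:r) {
      nr <- rowpos + dx; nc <- colpos + dy
      ok <- nr >= 1L & nr <= d[1] & nc >= 1L & nc <= d[2]
      nidx <- (nc[ok] - 1L) * d[1] + nr[ok]
      inm <- m[nidx]
      rows <- which(ok)[inm]
      bv <- bz[nidx[inm]]
      ind <- cbind(rows, bv)
      counts[ind] <- counts[ind] + 1L
    }
    tot <- rowSums(counts)
    p <- counts / tot
    hl <- p * log2(p)
    hl[!is.finite(hl)] <- 0
    H[, , z][idx] <- -rowSums(hl)
  }
  mask_idx <- which(mask)
  structure(list(H = H, w = w, B = B, mask_idx = mask_idx,
                 z_entropy = zscore(H[mask_idx]),
                 z_intensity = zscore(img[mask_idx]),
                 intensity = img[mask_idx],
                 entropy = H[mask_idx],
                 dims = d, patient_id = volume$patient_id,
                 sequence_id = volume$sequence_id),
            class = "entropy_map")
}

#' Cluster a lesion into superpixels
#'
#' K-means with `M` centers on the per-voxel 2-D vectors (Z-scored
#' intensity, Z-scored local entropy), Euclidean metric, multiple random
#' restarts under a fixed seed. Each superpixel is summarized by the mean
#' of its member voxels' values.
#'
#' @param entropy_map an [local_entropy()] result.
#' @param M number of superpixels (default 30, reduced with a warning when
#'   the mask holds fewer voxels).
#' @param seed RNG seed for the restarts.
#' @param nstart random restarts (guards against local optima).
#' @return an object of class `superpixel_set`: `voxel_label` (per mask
#'   voxel, in `mask_idx` order), `summary` (M x 2 matrix of mean Z-scored
#'   intensity and entropy), `summary_raw`, `sizes`, ids.
#' @export
superpixelize <- function(entropy_map, M = 30L, seed = 1L, nstart = 10L) {
  stopifnot(inherits(entropy_map, "entropy_map"))
  n <- length(entropy_map$mask_idx)
  M <- as.integer(M)
  if (n < M) {
    warning(sprintf("mask has %d voxels < M=%d; reducing M", n, M))
    M <- n
  }
  X <- cbind(entropy_map$z_intensity, entropy_map$z_entropy)
  if (n == M) {
    lab <- seq_len(n)
  } else {
    lab <- with_seed(seed, {
      km <- NULL
      for (try in 0:5) {
        km <- tryCatch(stats::kmeans(X, centers = M, nstart = nstart,
                                     iter.max = 100L),
                       error = function(e) NULL)
        if (!is.null(km)) break
      }
      if (is.null(km)) stop("k-means failed to find ", M,
                            " nonempty superpixels")
      km$cluster
    })
  }
  summ <- t(vapply(seq_len(M), function(k) colMeans(X[lab == k, , drop = FALSE]),
                   numeric(2)))
  raw <- cbind(entropy_map$intensity, entropy_map$entropy)
  summ_raw <- t(vapply(seq_len(M),
                       function(k) colMeans(raw[lab == k, , drop = FALSE]),
                       numeric(2)))
  colnames(summ) <- c("z_intensity", "z_entropy")
  colnames(summ_raw) <- c("intensity", "entropy")
  structure(list(voxel_label = lab, summary = summ, summary_raw = summ_raw,
                 sizes = tabulate(lab, M), M = M,
                 mask_idx = entropy_map$mask_idx, dims = entropy_map$dims,
                 patient_id = entropy_map$patient_id,
                 sequence_id = entropy_map$sequence_id),
            class = "superpixel_set")
}

#' Calinski-Harabasz index
#'
#' `CH = [B/(K-1)] / [W/(N-K)]` with `B` the between-cluster and `W` the
#' within-cluster sum of squared Euclidean distances to centroids.
#'
#' @param X numeric matrix (points x dims).
#' @param labels integer cluster labels.
#' @return the CH index (scalar).
#' @export
ch_index <- function(X, labels) {
  X <- as.matrix(X)
  N <- nrow(X); K <- length(unique(labels))
  if (K < 2) stop("need at least 2 clusters")
  g <- colMeans(X)
  Wss <- 0; Bss <- 0
  for (k in unique(labels)) {
    Xi <- X[labels == k, , drop = FALSE]
    ck <- colMeans(Xi)
    Wss <- Wss + sum(sweep(Xi, 2, ck)^2)
    Bss <- Bss + nrow(Xi) * sum((ck - g)^2)
  }
  (Bss / (K - 1)) / (Wss / (N - K))
}

#' Mean Silhouette coefficient
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean distance to
#' the own cluster and `b` the smallest mean distance to another cluster;
#' singletons score 0 (the usual convention).
#'
#' @inheritParams ch_index
#' @return mean silhouette over all points.
#' @export
silhouette_mean <- function(X, labels) {
  X <- as.matrix(X)
  D <- as.matrix(stats::dist(X))
  labs <- unique(labels)
  if (length(labs) < 2) stop("need at least 2 clusters")
  s <- numeric(nrow(X))
  for (i in seq_len(nrow(X))) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Population-level clustering of pooled superpixels
#'
#' Gathers all patients' superpixel summary vectors and clusters them with
#' agglomerative Ward linkage. Every `K` in `K_range` is scored with the
#' Calinski-Harabasz index and the mean Silhouette; the selected `K*`
#' maximizes the mean Silhouette, ties broken by higher CH. Cluster
#' centroids are stored so new patients can be assigned without refitting.
#'
#' @param superpixels list of [superpixelize()] results (training patients).
#' @param K_range candidate cluster counts (default 2:10).
#' @param seed kept for interface symmetry; Ward clustering is
#'   deterministic.
#' @return an object of class `partition_model` with `K_star`, `scores`
#'   (per-K CH and Silhouette), `centroids` (K* x 2, ordered by increasing
#'   mean Z-scored entropy so the last row is the inner habitat), and the
#'   linkage description.
#' @export
population_cluster <- function(superpixels, K_range = 2:10, seed = 1L) {
  if (length(superpixels) < 2) stop("need superpixels from >= 2 patients")
  pooled <- do.call(rbind, lapply(superpixels, `[[`, "summary"))
  if (nrow(pooled) < max(K_range))
    stop("fewer pooled superpixels than max(K_range)")
  if (all(apply(pooled, 2, stats::sd) < 1e-12))
    stop("degenerate dispersion: all pooled superpixel vectors identical")
  hc <- stats::hclust(stats::dist(pooled), method = "ward.D2")
  scores <- data.frame(K = K_range, CH = NA_real_, silhouette = NA_real_)
  cuts <- list()
  for (j in seq_along(K_range)) {
    lab <- stats::cutree(hc, k = K_range[j])
    cuts[[j]] <- lab
    scores$CH[j] <- ch_index(pooled, lab)
    scores$silhouette[j] <- silhouette_mean(pooled, lab)
  }
  best <- which(scores$silhouette == max(scores$silhouette))
  if (length(best) > 1) best <- best[which.max(scores$CH[best])]
  K_star <- K_range[best]
  lab <- cuts[[best]]
  cent <- t(vapply(seq_len(K_star), function(k)
    colMeans(pooled[lab == k, , drop = FALSE]), numeric(2)))
  colnames(cent) <- colnames(pooled)
  ord <- order(cent[, "z_entropy"])       # S1 = lowest entropy ... SK* = highest
  cent <- cent[ord, , drop = FALSE]
  rownames(cent) <- paste0("S", seq_len(K_star))
  structure(list(K_star = K_star, scores = scores, centroids = cent,
                 linkage = "ward.D2", K_range = K_range,
                 n_pooled = nrow(pooled)),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("<partition_model> Ward linkage, K* = %d (of %d pooled superpixels)\n",
              x$K_star, x$n_pooled))
  print(x$scores, row.names = FALSE)
  invisible(x)
}

#' Assign a patient's voxels to population habitats
#'
#' Each superpixel inherits the nearest population centroid (Euclidean, in
#' the Z-scored intensity-entropy plane); voxels inherit their
#' superpixel's habitat. Habitats are then renamed per patient in order of
#' increasing realized mean Z-scored entropy, so S2 (the inner habitat
#' under K*=2) always has entropy at least that of S1 (the marginal one).
#'
#' @param patient a [superpixelize()] result.
#' @param model a [population_cluster()] model.
#' @return an object of class `subregion_partition`: `label_array` (0
#'   background, 1..K* habitat), `voxel_habitat`, per-habitat `counts` and
#'   mean intensity/entropy (raw and Z-scored).
#' @export
assign_subregions <- function(patient, model) {
  stopifnot(inherits(patient, "superpixel_set"),
            inherits(model, "partition_model"))
  cent <- model$centroids
  d2 <- vapply(seq_len(nrow(cent)), function(k)
    rowSums(sweep(patient$summary, 2, cent[k, ])^2), numeric(nrow(patient$summary)))
  sp_hab <- max.col(-d2, ties.method = "first")
  vox_hab <- sp_hab[patient$voxel_label]
  # patient-level renaming: nonempty habitats sorted by realized mean
  # z-entropy; empty habitats keep their centroid-order slot
  K <- nrow(cent)
  zent <- patient$summary[, "z_entropy"][patient$voxel_label] # per voxel
  realized <- vapply(seq_len(K), function(k)
    if (any(vox_hab == k)) mean(zent[vox_hab == k]) else NA_real_, numeric(1))
  present <- which(!is.na(realized))
  new_id <- seq_len(K)
  new_id[present[order(realized[present])]] <- sort(present)
  vox_hab <- new_id[vox_hab]
  lab <- array(0L, patient$dims)
  lab[patient$mask_idx] <- vox_hab
  stats_tab <- do.call(rbind, lapply(seq_len(K), function(k) {
    sel <- vox_hab == k
    data.frame(habitat = paste0("S", k), n_voxels = sum(sel),
               mean_intensity = if (any(sel)) mean(patient$summary_raw[patient$voxel_label, "intensity"][sel]) else NA_real_,
               mean_entropy = if (any(sel)) mean(patient$summary_raw[patient$voxel_label, "entropy"][sel]) else NA_real_,
               mean_z_intensity = if (any(sel)) mean(patient$summary[patient$voxel_label, "z_intensity"][sel]) else NA_real_,
               mean_z_entropy = if (any(sel)) mean(zent[sel]) else NA_real_)
  }))
  structure(list(label_array = lab, voxel_habitat = vox_hab,
                 habitat_stats = stats_tab, K = K,
                 mask_idx = patient$mask_idx, dims = patient$dims,
                 patient_id = patient$patient_id,
                 sequence_id = patient$sequence_id),
            class = "subregion_partition")
}

#' Habitat mask for one subregion
#'
#' @param partition a `subregion_partition`.
#' @param habitat habitat id (1 = marginal S1, 2 = inner S2, ...) or
#'   `"whole"` for the full lesion.
#' @return logical 3D array.
#' @export
habitat_mask <- function(partition, habitat) {
  if (identical(habitat, "whole")) return(partition$label_array > 0L)
  partition$label_array == as.integer(habitat)
}

#' Run the full partitioning stage on a cohort
#'
#' Entropy maps and superpixels for every patient, population clustering on
#' the training split only (leakage-safe), then centroid assignment for all
#' patients. Each sequence is partitioned independently.
#'
#' @param cohort a `habitat_cohort`.
#' @param sequences which sequences to partition.
#' @param w,B entropy window and bin count.
#' @param M superpixels per lesion.
#' @param K_range candidate cluster counts.
#' @param seed master seed for the k-means restarts.
#' @return list with per-sequence `model` and per-patient `partitions`
#'   (`partitions[[sequence]][[patient_id]]`), plus the superpixel sets.
#' @export
partition_cohort <- function(cohort, sequences = c("T1W", "T2FS"),
                             w = 9L, B = 32L, M = 30L, K_range = 2:10,
                             seed = 1L) {
  stopifnot(inherits(cohort, "habitat_cohort"))
  train_ids <- cohort$clinical$patient_id[cohort$clinical$split == "train"]
  out <- list(models = list(), partitions = list(), superpixels = list())
  for (sq in sequences) {
    sps <- list()
    for (pid in names(cohort$volumes)) {
      em <- local_entropy(cohort$volumes[[pid]][[sq]], w = w, B = B)
      sps[[pid]] <- superpixelize(em, M = M,
                                  seed = child_seed(seed, paste0(sq, pid)))
    }
    model <- population_cluster(sps[names(sps) %in% train_ids],
                                K_range = K_range, seed = seed)
    parts <- lapply(sps, assign_subregions, model = model)
    out$models[[sq]] <- model
    out$partitions[[sq]] <- parts
    out$superpixels[[sq]] <- sps
  }
  out
}

#' Habitat-contrast diagnostics
#'
#' Per split and sequence, the per-patient habitat means of intensity and
#' local entropy, with paired two-sided t-tests of the S2-vs-S1 gap.
#' Mirrors the boxplot-style summary used to verify that the inner habitat
#' shows higher intensity and entropy than the marginal one. Patients whose
#' partition collapsed to one habitat are excluded with a warning.
#'
#' @param partition_run a [partition_cohort()] result.
#' @param cohort the cohort.
#' @param plot_dir optional directory for boxplot PNGs.
#' @return data frame of per-split, per-sequence paired t-test results plus
#'   the per-patient habitat means (attribute `"patient_means"`).
#' @export
partition_diagnostics <- function(partition_run, cohort, plot_dir = NULL) {
  cl <- cohort$clinical
  rows <- list(); pm <- list()
  for (sq in names(partition_run$partitions)) {
    parts <- partition_run$partitions[[sq]]
    tab <- do.call(rbind, lapply(names(parts), function(pid) {
      st <- parts[[pid]]$habitat_stats
      st$patient_id <- pid; st$sequence <- sq
      st$split <- cl$split[match(pid, cl$patient_id)]
      st
    }))
    pm[[sq]] <- tab
    for (sp in unique(tab$split)) {
      sub <- tab[tab$split == sp, ]
      wide_e <- stats::reshape(sub[, c("patient_id", "habitat", "mean_entropy")],
                               idvar = "patient_id", timevar = "habitat",
                               direction = "wide")
      wide_i <- stats::reshape(sub[, c("patient_id", "habitat", "mean_intensity")],
                               idvar = "patient_id", timevar = "habitat",
                               direction = "wide")
      if (nrow(wide_e) < 2) stop("need >= 2 patients per split for diagnostics")
      ok <- stats::complete.cases(wide_e)
      if (any(!ok)) warning(sum(!ok), " single-habitat patient(s) excluded")
      if (sum(ok) < 2) stop("need >= 2 two-habitat patients per split")
      te <- stats::t.test(wide_e[ok, "mean_entropy.S2"],
                          wide_e[ok, "mean_entropy.S1"], paired = TRUE)
      ti <- stats::t.test(wide_i[ok, "mean_intensity.S2"],
                          wide_i[ok, "mean_intensity.S1"], paired = TRUE)
      rows[[length(rows) + 1]] <- data.frame(
        sequence = sq, split = sp, n = sum(ok),
        entropy_gap = unname(te$estimate), entropy_p = te$p.value,
        intensity_gap = unname(ti$estimate), intensity_p = ti$p.value)
    }
    if (!is.null(plot_dir)) {
      dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
      f <- file.path(plot_dir, sprintf("habitat_boxplots_%s.png", sq))
      grDevices::png(f, width = 900, height = 450)
      graphics::par(mfrow = c(1, 2))
      graphics::boxplot(mean_entropy ~ habitat + split, data = tab,
                        main = paste(sq, "local entropy"), las = 2,
                        ylab = "mean entropy (bits)")
      graphics::boxplot(mean_intensity ~ habitat + split, data = tab,
                        main = paste(sq, "intensity"), las = 2,
                        ylab = "mean intensity (a.u.)")
      grDevices::dev.off()
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "patient_means") <- do.call(rbind, pm)
  res
}
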