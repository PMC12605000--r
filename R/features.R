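# Texture matrices and radiomic features. Matrices are computed in 3-D
# with distance-1, 26-connectivity offsets and angle averaging by default
# (an in-plane 2-D mode is available), on the bounding box of the region
# mask padded by one voxel so neighbor arithmetic never wraps.

#' Discretize intensities into a fixed number of gray levels
#'
#' Equal-width bins over the region's min-max range; levels are exactly
#' `1..n_bins` (a constant region maps to level 1).
#'
#' @param img numeric 3D array.
#' @param mask logical 3D array.
#' @param n_bins bin count.
#' @return integer array, 0 outside the mask.
#' @export
discretize <- function(img, mask, n_bins = 32L) {
  lv <- array(0L, dim(img))
  v <- img[mask]
  r <- range(v)
  if (diff(r) < .Machine$double.eps) lv[mask] <- 1L
  else lv[mask] <- pmin(as.integer(n_bins),
                        1L + as.integer(floor(n_bins * (v - r[1]) / diff(r))))
  lv
}

crop_region <- function(img, mask) {
  idx <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - 1L, 1L)
  hi <- pmin(apply(idx, 2, max) + 1L, dim(mask))
  ci <- img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  cm <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # pad by one so every in-mask voxel has all neighbors inside the box
  d <- dim(cm) + 2L
  pi_ <- array(0, d); pm <- array(FALSE, d)
  pi_[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- ci
  pm[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- cm
  list(img = pi_, mask = pm)
}

# Unique direction offsets (half of the symmetric neighbor set).
texture_offsets <- function(mode = "3D") {
  if (mode == "2D")
    return(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0)))
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[!(offs[, 1] == 0 & offs[, 2] == 0 & offs[, 3] == 0), ]
  keep <- offs[, 3] > 0 | (offs[, 3] == 0 & offs[, 2] > 0) |
    (offs[, 3] == 0 & offs[, 2] == 0 & offs[, 1] > 0)
  unname(offs[keep, , drop = FALSE])
}

full_neighbor_offsets <- function(mode = "3D") {
  h <- texture_offsets(mode)
  rbind(h, -h)
}

# Linear-index offsets in a (padded) array for a set of coordinate offsets.
linear_offsets <- function(dims, offs) {
  offs[, 1] + dims[1] * offs[, 2] + dims[1] * dims[2] * offs[, 3]
}

# Symmetric, normalized co-occurrence matrices, one per direction offset.
glcm_matrices <- function(levels, mask, n_levels, distance = 1L,
                          mode = "3D") {
  cr <- crop_region(levels, mask)
  lev <- cr$img; m <- cr$mask
  d <- dim(m)
  idx <- which(m)
  offs <- texture_offsets(mode) * distance
  loffs <- linear_offsets(d, offs)
  out <- list()
  for (k in seq_along(loffs)) {
    nb <- idx + loffs[k]
    ok <- m[nb]
    if (!any(ok)) next
    i <- lev[idx[ok]]; j <- lev[nb[ok]]
    counts <- tabulate((i - 1L) * n_levels + j, nbins = n_levels^2)
    P <- matrix(counts, n_levels, n_levels, byrow = TRUE)
    P <- P + t(P)
    out[[length(out) + 1]] <- P / sum(P)
  }
  if (!length(out)) stop("no valid voxel pairs for the co-occurrence matrix")
  out
}

glcm_iv_from_matrix <- function(P) {
  nl <- nrow(P)
  ij <- outer(seq_len(nl), seq_len(nl), `-`)
  off <- ij != 0
  sum(P[off] / ij[off]^2)
}

glcm_mcc_from_matrix <- function(P) {
  px <- rowSums(P)
  keep <- px > 0
  if (sum(keep) < 2) stop("MCC undefined for a single gray level")
  P <- P[keep, keep, drop = FALSE]
  px <- rowSums(P); py <- colSums(P)
  # Q(i,j) = sum_k P(i,k) P(j,k) / (px(i) py(k))
  Q <- (P / px) %*% t(P / matrix(py, nrow(P), ncol(P), byrow = TRUE))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(max(0, min(1, ev[2])))
}

#' GLCM Inverse Variance
#'
#' `IV = sum_{i != j} p(i,j) / (i - j)^2` on the symmetric, normalized
#' gray-level co-occurrence matrix, averaged over the direction offsets.
#'
#' @param img numeric 3D array (or a pre-discretized integer array when
#'   `discretized = TRUE`).
#' @param mask logical 3D array selecting the region.
#' @param n_bins gray-level count for discretization.
#' @param distance offset distance in voxels.
#' @param mode `"3D"` (13 offsets) or `"2D"` (4 in-plane offsets).
#' @param discretized set when `img` already holds levels `1..n_bins`.
#' @return scalar feature value.
#' @export
glcm_inverse_variance <- function(img, mask, n_bins = 32L, distance = 1L,
                                  mode = "3D", discretized = FALSE) {
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  mats <- glcm_matrices(lev, mask, n_bins, distance, mode)
  mean(vapply(mats, glcm_iv_from_matrix, numeric(1)))
}

#' GLCM Maximal Correlation Coefficient
#'
#' Square root of the second-largest eigenvalue of
#' `Q(i,j) = sum_k p(i,k) p(j,k) / (p_x(i) p_y(k))`, angle-averaged.
#' Requires at least two distinct gray levels.
#'
#' @inheritParams glcm_inverse_variance
#' @return scalar in \[0, 1\].
#' @export
glcm_mcc <- function(img, mask, n_bins = 32L, distance = 1L, mode = "3D",
                     discretized = FALSE) {
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  if (length(unique(lev[mask])) < 2)
    stop("MCC undefined for a single gray level")
  mats <- glcm_matrices(lev, mask, n_bins, distance, mode)
  mean(vapply(mats, glcm_mcc_from_matrix, numeric(1)))
}

gldm_matrix <- function(levels, mask, n_levels, alpha = 0, mode = "3D") {
  cr <- crop_region(levels, mask)
  lev <- cr$img; m <- cr$mask
  d <- dim(m)
  idx <- which(m)
  loffs <- linear_offsets(d, full_neighbor_offsets(mode))
  dep <- rep(1L, length(idx))          # the voxel itself
  centre <- lev[idx]
  for (k in seq_along(loffs)) {
    nb <- idx + loffs[k]
    ok <- m[nb] & abs(lev[nb] - centre) <= alpha
    dep <- dep + ok
  }
  maxd <- max(dep)
  counts <- tabulate((centre - 1L) * maxd + dep, nbins = n_levels * maxd)
  matrix(counts, n_levels, maxd, byrow = TRUE)
}

#' GLDM Dependence Non-Uniformity Normalized
#'
#' `DNN = sum_j (sum_i P(i,j))^2 / N_z^2` where `P(i,j)` counts voxels of
#' level `i` whose dependence (number of neighbors within `alpha` of the
#' center level, plus the voxel itself) equals `j`.
#'
#' @inheritParams glcm_inverse_variance
#' @param alpha dependence tolerance on the gray level (default 0).
#' @return scalar in (0, 1\].
#' @export
gldm_dnn <- function(img, mask, n_bins = 32L, alpha = 0, mode = "3D",
                     discretized = FALSE) {
  if (!any(mask)) stop("empty region")
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  P <- gldm_matrix(lev, mask, n_bins, alpha, mode)
  Nz <- sum(P)
  sum(colSums(P)^2) / Nz^2
}

# Connected zones of equal gray level (26- or 8-connectivity): BFS on the
# padded crop. Returns a data.frame of (level, size) per zone.
glszm_zones <- function(levels, mask, mode = "3D") {
  cr <- crop_region(levels, mask)
  lev <- cr$img; m <- cr$mask
  d <- dim(m)
  loffs <- linear_offsets(d, full_neighbor_offsets(mode))
  todo <- m
  zones_level <- integer(0); zones_size <- integer(0)
  idx_all <- which(m)
  for (v in idx_all) {
    if (!todo[v]) next
    lv <- lev[v]
    size <- 0L
    frontier <- v
    todo[v] <- FALSE
    while (length(frontier)) {
      size <- size + length(frontier)
      nb <- as.vector(outer(frontier, loffs, `+`))
      nb <- unique(nb[todo[nb] & lev[nb] == lv])
      todo[nb] <- FALSE
      frontier <- nb
    }
    zones_level <- c(zones_level, lv)
    zones_size <- c(zones_size, size)
  }
  data.frame(level = zones_level, size = zones_size)
}

#' GLSZM Small Area Emphasis
#'
#' `SAE = (1/N_z) sum_{i,j} P(i,j) / j^2` over the gray-level size-zone
#' matrix; zones are connected components of equal discretized level
#' (26-connectivity in 3-D mode).
#'
#' @inheritParams glcm_inverse_variance
#' @return scalar in (0, 1\].
#' @export
glszm_sae <- function(img, mask, n_bins = 32L, mode = "3D",
                      discretized = FALSE) {
  if (!any(mask)) stop("empty region")
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  z <- glszm_zones(lev, mask, mode)
  sum(1 / z$size^2) / nrow(z)
}

# Runs of consecutive equal levels along each direction; returns run sizes
# per direction (list), for the run-length features.
glrlm_runs <- function(levels, mask, mode = "3D") {
  cr <- crop_region(levels, mask)
  lev <- cr$img; m <- cr$mask
  d <- dim(m)
  offs <- texture_offsets(mode)
  loffs <- linear_offsets(d, offs)
  idx <- which(m)
  out <- list()
  for (k in seq_along(loffs)) {
    lo <- loffs[k]
    prev <- idx - lo
    is_start <- !(m[prev] & lev[prev] == lev[idx])
    starts <- idx[is_start]
    lens <- integer(length(starts))
    cur <- starts
    alive <- seq_along(starts)
    while (length(alive)) {
      lens[alive] <- lens[alive] + 1L
      nxt <- cur[alive] + lo
      cont <- m[nxt] & lev[nxt] == lev[cur[alive]]
      cur[alive[cont]] <- nxt[cont]
      alive <- alive[cont]
    }
    out[[k]] <- data.frame(level = lev[starts], length = lens)
  }
  out
}

#' GLRLM Short Run Emphasis
#'
#' `SRE = (1/N_r) sum_{i,j} P(i,j) / j^2` over the run-length matrix,
#' averaged over directions.
#'
#' @inheritParams glcm_inverse_variance
#' @return scalar in (0, 1\].
#' @export
glrlm_sre <- function(img, mask, n_bins = 32L, mode = "3D",
                      discretized = FALSE) {
  if (!any(mask)) stop("empty region")
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  runs <- glrlm_runs(lev, mask, mode)
  mean(vapply(runs, function(r) sum(1 / r$length^2) / nrow(r), numeric(1)))
}

#' NGTDM Coarseness
#'
#' `1 / sum_i p_i s_i` with `s_i` the summed absolute difference between
#' level `i` and the mean level of each such voxel's valid neighborhood.
#' Capped at 1e6 when the denominator vanishes (constant region).
#'
#' @inheritParams glcm_inverse_variance
#' @return scalar.
#' @export
ngtdm_coarseness <- function(img, mask, n_bins = 32L, mode = "3D",
                             discretized = FALSE) {
  if (!any(mask)) stop("empty region")
  lev <- if (discretized) img else discretize(img, mask, n_bins)
  cr <- crop_region(lev, mask)
  lv <- cr$img; m <- cr$mask
  d <- dim(m)
  idx <- which(m)
  loffs <- linear_offsets(d, full_neighbor_offsets(mode))
  ssum <- numeric(length(idx)); scnt <- numeric(length(idx))
  for (k in seq_along(loffs)) {
    nb <- idx + loffs[k]
    ok <- m[nb]
    ssum <- ssum + ifelse(ok, lv[nb], 0)
    scnt <- scnt + ok
  }
  has <- scnt > 0
  abar <- ssum[has] / scnt[has]
  li <- lv[idx[has]]
  n_i <- tabulate(li, n_bins)
  s_i <- vapply(seq_len(n_bins), function(i) sum(abs(i - abar)[li == i]),
                numeric(1))
  p_i <- n_i / sum(n_i)
  denom <- sum(p_i * s_i)
  if (denom < 1e-12) return(1e6)
  1 / denom
}

#' 90th percentile of region intensities
#'
#' Linear interpolation between order statistics (quantile type 7).
#'
#' @param values numeric vector of region intensities.
#' @return scalar.
#' @export
firstorder_p90 <- function(values) {
  if (!length(values)) stop("empty region")
  unname(stats::quantile(values, 0.9, type = 7))
}

firstorder_features <- function(values, n_bins = 32L) {
  r <- range(values)
  if (diff(r) < .Machine$double.eps) {
    h <- 0
  } else {
    lev <- pmin(as.integer(n_bins),
                1L + as.integer(floor(n_bins * (values - r[1]) / diff(r))))
    p <- tabulate(lev, n_bins) / length(lev)
    p <- p[p > 0]
    h <- -sum(p * log2(p))
  }
  c(Mean = mean(values),
    StandardDeviation = stats::sd(values),
    `90Percentile` = firstorder_p90(values),
    Entropy = h)
}

# All configured features for one region of one derived image.
region_feature_vector <- function(img, mask, spec, filter_name) {
  n_bins <- spec$n_bins; mode <- spec$texture_mode
  lev <- discretize(img, mask, n_bins)
  fo <- firstorder_features(img[mask], n_bins)
  tex <- c(
    glcm_InverseVariance = tryCatch(
      glcm_inverse_variance(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_),
    glcm_MCC = tryCatch(
      glcm_mcc(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_),
    gldm_DependenceNonUniformityNormalized = tryCatch(
      gldm_dnn(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_),
    glszm_SmallAreaEmphasis = tryCatch(
      glszm_sae(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_),
    glrlm_ShortRunEmphasis = tryCatch(
      glrlm_sre(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_),
    ngtdm_Coarseness = tryCatch(
      ngtdm_coarseness(lev, mask, n_bins, mode = mode, discretized = TRUE),
      error = function(e) NA_real_))
  v <- c(stats::setNames(fo, paste0("firstorder_", names(fo))), tex)
  nm <- if (filter_name == "lbp") spec$lbp_name else filter_name
  stats::setNames(v, paste0(nm, "_", names(v)))
}

#' Extract subregion radiomic features for a cohort
#'
#' For every patient x sequence x region (S1, S2, whole tumor), computes
#' the configured filter x feature combinations. Rows whose region is
#' smaller than `spec$min_region_voxels`, or where a texture feature is
#' undefined (e.g. a single gray level), are dropped and logged in the
#' `"dropped"` attribute.
#'
#' @param cohort a `habitat_cohort`.
#' @param partition_run a [partition_cohort()] result.
#' @param spec a [preprocess_spec()].
#' @param regions regions to extract (habitat ids and/or `"whole"`).
#' @return a `feature_table` data frame: id columns
#'   (`patient_id, sequence, region, label, batch, split`) plus one column
#'   per feature (named `<filter>_<class>_<name>`).
#' @export
extract_features <- function(cohort, partition_run,
                             spec = preprocess_spec(),
                             regions = c("S1", "S2", "whole")) {
  cl <- cohort$clinical
  rows <- list(); dropped <- list()
  for (sq in names(partition_run$partitions)) {
    parts <- partition_run$partitions[[sq]]
    for (pid in names(parts)) {
      vol <- cohort$volumes[[pid]][[sq]]
      stack <- preprocess(vol, spec)
      part <- parts[[pid]]
      for (rg in regions) {
        msk <- if (rg == "whole") habitat_mask(part, "whole")
               else habitat_mask(part, as.integer(sub("S", "", rg)))
        if (sum(msk) < spec$min_region_voxels) {
          dropped[[length(dropped) + 1]] <- data.frame(
            patient_id = pid, sequence = sq, region = rg,
            reason = sprintf("region below %d voxels (%d)",
                             spec$min_region_voxels, sum(msk)))
          next
        }
        feats <- unlist(lapply(names(stack), function(fn)
          region_feature_vector(stack[[fn]], msk, spec, fn)))
        if (anyNA(feats)) {
          dropped[[length(dropped) + 1]] <- data.frame(
            patient_id = pid, sequence = sq, region = rg,
            reason = paste("undefined feature:",
                           paste(names(feats)[is.na(feats)], collapse = ",")))
          next
        }
        i <- match(pid, cl$patient_id)
        rows[[length(rows) + 1]] <- c(
          list(patient_id = pid, sequence = sq, region = rg,
               label = cl$label[i], batch = cl$batch[i], split = cl$split[i]),
          as.list(feats))
      }
    }
  }
  if (!length(rows)) stop("no feature rows survived extraction")
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, check.names = FALSE)))
  class(tab) <- c("feature_table", "data.frame")
  attr(tab, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
                          else NULL
  attr(tab, "spec") <- spec
  tab
}

#' Feature column names of a feature table
#' @param table a `feature_table`.
#' @return character vector of feature column names.
#' @export
feature_columns <- function(table) {
  setdiff(names(table), c("patient_id", "sequence", "region", "label",
                          "batch", "split"))
}
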