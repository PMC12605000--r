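# Image filters applied before feature extraction. Each returns a derived
# image on the same grid. Conventions follow the common radiomics ones:
# intensity-range-preserving monotone maps for square / squareroot /
# logarithm / exponential, scale-normalized LoG, undecimated single-level
# Haar wavelet subbands, gradient magnitude, and 2-D rotation-invariant
# uniform LBP per slice.

filter_square <- function(img, mask) {
  m <- max(abs(img[mask])); if (m == 0) return(img)
  img^2 / m
}

filter_squareroot <- function(img, mask) {
  m <- max(abs(img[mask])); if (m == 0) return(img)
  sign(img) * sqrt(m * abs(img))
}

filter_logarithm <- function(img, mask) {
  m <- max(abs(img[mask])); if (m == 0) return(img)
  c1 <- m / log1p(m)
  sign(img) * c1 * log1p(abs(img))
}

filter_exponential <- function(img, mask) {
  m <- max(abs(img[mask])); if (m == 0) return(exp(img * 0))
  c1 <- log(m) / m
  exp(c1 * img)
}

filter_gradient <- function(img, mask, spacing = c(1, 1, 1)) {
  gx <- (shift3d(img, -1L, 0L, 0L) - shift3d(img, 1L, 0L, 0L)) / (2 * spacing[1])
  gy <- (shift3d(img, 0L, -1L, 0L) - shift3d(img, 0L, 1L, 0L)) / (2 * spacing[2])
  gz <- if (dim(img)[3] > 1)
    (shift3d(img, 0L, 0L, -1L) - shift3d(img, 0L, 0L, 1L)) / (2 * spacing[3])
  else img * 0
  sqrt(gx^2 + gy^2 + gz^2)
}

# Scale-normalized Laplacian of Gaussian. sigma_mm is converted to voxels
# per axis via the spacing; the response is sigma^2 * Laplacian(G * I).
filter_log <- function(img, mask, sigma_mm = 5, spacing = c(1, 1, 4)) {
  ext <- dim(img) * spacing
  if (sigma_mm > max(ext)) {
    warning("LoG sigma exceeds lesion extent; filter skipped")
    return(NULL)
  }
  sv <- sigma_mm / spacing
  sm <- img
  sm <- conv1d_dim(sm, gaussian_kernel_1d(sv[1]), 1L)
  sm <- conv1d_dim(sm, gaussian_kernel_1d(sv[2]), 2L)
  if (dim(img)[3] > 2) sm <- conv1d_dim(sm, gaussian_kernel_1d(sv[3]), 3L)
  lap <- (shift3d(sm, -1L, 0L, 0L) + shift3d(sm, 1L, 0L, 0L) - 2 * sm) / spacing[1]^2 +
         (shift3d(sm, 0L, -1L, 0L) + shift3d(sm, 0L, 1L, 0L) - 2 * sm) / spacing[2]^2
  if (dim(img)[3] > 2)
    lap <- lap + (shift3d(sm, 0L, 0L, -1L) + shift3d(sm, 0L, 0L, 1L) - 2 * sm) / spacing[3]^2
  sigma_mm^2 * lap
}

# Undecimated single-level Haar wavelet. Returns the requested subband
# ("LLL" ... "HHH"); for single-slice grids the third letter is ignored.
filter_wavelet <- function(img, mask, subband = "HHH") {
  stopifnot(nchar(subband) == 3)
  haar <- function(a, dim, high) {
    sh <- switch(dim, shift3d(a, 1L, 0L, 0L), shift3d(a, 0L, 1L, 0L),
                 shift3d(a, 0L, 0L, 1L))
    if (high) (a - sh) / sqrt(2) else (a + sh) / sqrt(2)
  }
  out <- img
  letters3 <- strsplit(subband, "")[[1]]
  for (dmn in 1:3) {
    if (dmn == 3 && dim(img)[3] == 1) next
    out <- haar(out, dmn, letters3[dmn] == "H")
  }
  out
}

# 2-D rotation-invariant uniform LBP (8 neighbors, radius 1) per slice.
# Codes: 0..8 = number of set bits for uniform patterns, 9 = non-uniform.
filter_lbp2d <- function(img, mask) {
  d <- dim(img)
  out <- array(0, d)
  offs <- cbind(dx = c(-1, -1, -1, 0, 1, 1, 1, 0),
                dy = c(-1, 0, 1, 1, 1, 0, -1, -1))
  for (z in seq_len(d[3])) {
    sl <- img[, , z]
    bits <- array(0L, c(d[1], d[2], 8L))
    for (k in 1:8) {
      ix <- pmin(pmax(seq_len(d[1]) + offs[k, 1], 1L), d[1])
      iy <- pmin(pmax(seq_len(d[2]) + offs[k, 2], 1L), d[2])
      bits[, , k] <- (sl[ix, iy] >= sl) + 0L
    }
    ones <- apply(bits, c(1, 2), sum)
    trans <- array(0L, c(d[1], d[2]))
    for (k in 1:8) {
      k2 <- if (k == 8) 1L else k + 1L
      trans <- trans + (bits[, , k] != bits[, , k2])
    }
    code <- ifelse(trans <= 2, ones, 9L)
    out[, , z] <- code
  }
  out
}

#' Preprocess a lesion volume into a stack of derived images
#'
#' Applies the configured image filters; discretization happens later, at
#' feature-computation time. The original image is always included.
#'
#' @param volume a [lesion_volume()].
#' @param spec a [preprocess_spec()].
#' @return named list of 3D arrays (one per derived image); filters whose
#'   scale exceeds the lesion are skipped with a warning.
#' @export
preprocess <- function(volume, spec = preprocess_spec()) {
  img <- volume$image; mask <- volume$mask
  if (isTRUE(spec$normalize)) {
    mu <- mean(img[mask]); s <- stats::sd(img[mask])
    if (is.finite(s) && s > 0) {
      img <- (img - mu) / s * 100 + 300   # positive range for log/exp maps
    }
  }
  out <- list(original = img)
  for (f in spec$filters) {
    if (f == "original") next
    der <- switch(f,
      square = filter_square(img, mask),
      squareroot = filter_squareroot(img, mask),
      logarithm = filter_logarithm(img, mask),
      exponential = filter_exponential(img, mask),
      gradient = filter_gradient(img, mask, volume$spacing),
      `wavelet-HHH` = filter_wavelet(img, mask, "HHH"),
      `wavelet-LLL` = filter_wavelet(img, mask, "LLL"),
      lbp = filter_lbp2d(img, mask),
      {
        if (grepl("^log-sigma-", f)) {
          sg <- as.numeric(sub("^log-sigma-([0-9]+)-([0-9]+).*$", "\\1.\\2", f))
          filter_log(img, mask, sigma_mm = sg, spacing = volume$spacing)
        } else stop("unknown filter: ", f)
      })
    if (!is.null(der)) out[[f]] <- der
  }
  out
}

#' Preprocessing / extraction settings
#'
#' @param normalize Z-score the image within the ROI before filtering
#'   (then rescaled to a positive working range, as the intensity-map
#'   filters require positive inputs).
#' @param filters derived images to compute; `"original"` is always
#'   present. LoG filters are named `"log-sigma-<a>-<b>-mm-3D"` with sigma
#'   `a.b` mm.
#' @param n_bins fixed discretization bin count for texture matrices.
#' @param texture_mode `"3D"` (26-connectivity, distance-1 offsets,
#'   angle-averaged) or `"2D"` (in-plane).
#' @param min_region_voxels rows for regions smaller than this are dropped.
#' @param lbp_name name under which LBP-derived features are emitted; the
#'   default keeps the honest 2-D name, `"lbp-3D-m2"` is accepted as an
#'   alias for catalogue parity with the reference naming.
#' @return an object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(normalize = TRUE,
                            filters = c("original", "log-sigma-5-0-mm-3D",
                                        "wavelet-HHH", "exponential", "lbp"),
                            n_bins = 32L,
                            texture_mode = c("3D", "2D"),
                            min_region_voxels = 10L,
                            lbp_name = "lbp-2D") {
  texture_mode <- match.arg(texture_mode)
  stopifnot(n_bins >= 2)
  structure(list(normalize = normalize, filters = filters,
                 n_bins = as.integer(n_bins), texture_mode = texture_mode,
                 min_region_voxels = as.integer(min_region_voxels),
                 lbp_name = lbp_name),
            class = "preprocess_spec")
}
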