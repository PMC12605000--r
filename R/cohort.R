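#' Specify a synthetic lesion cohort
#'
#' Defines the study conditions for a simulated multi-sequence MRI cohort of
#' spinal-metastasis-like lesions. Each lesion is an ellipsoidal mask holding
#' two spatially organized habitats: a marginal rim and a nested inner core
#' whose mean intensity and local texture roughness exceed the rim. The
#' binary molecular label perturbs the texture of the inner habitat only,
#' and scanner batches add location-scale intensity effects after the class
#' effect, so the generator exercises partition recovery, class signal and
#' batch harmonization downstream.
#'
#' @param n_patients number of patients.
#' @param prevalence fraction of label-positive patients, in (0, 1).
#' @param n_slices,height,width voxel grid dimensions (slices are the third
#'   axis; in-plane dimensions must be at least 9 so the local-entropy
#'   window fits).
#' @param habitat_contrast intensity mean gap between inner and marginal
#'   habitat, in units of `noise_sd`.
#' @param entropy_contrast texture-roughness gap between habitats; 0 means
#'   both habitats share the same correlation length.
#' @param class_effect effect size of the label on inner-habitat texture
#'   parameters (roughness and amplitude), in relative units.
#' @param batch_ids data frame with columns `batch`, `shift`, `scale`
#'   giving per-scanner additive and multiplicative intensity effects.
#' @param noise_sd voxel noise standard deviation (arbitrary units).
#' @param inner_fraction target fraction of lesion voxels in the inner
#'   habitat (kept within \[0.2, 0.8\]).
#' @param external_fraction fraction of patients assigned to the external
#'   split (second scanner); the rest are split 2:1 train:internal,
#'   stratified by label.
#' @param habitat_mode `"concentric"` (default) nests the inner habitat as
#'   an eroded core; `"scattered"` places it as random blobs for
#'   robustness tests.
#' @param batch_mode `"by_center"` (default) puts the external split on
#'   the second scanner, mirroring a two-center design (note that a
#'   train-only harmonization fit then sees a single batch);
#'   `"interleaved"` alternates scanners across all patients so batch
#'   effects span every split, the design harmonization tests need.
#' @param spacing voxel spacing in mm (in-plane, in-plane, slice).
#' @param seed RNG seed; together with the other fields it fully
#'   determines the generated cohort.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 60,
                        prevalence = 0.45,
                        n_slices = 3, height = 40, width = 40,
                        habitat_contrast = 3,
                        entropy_contrast = 1.5,
                        class_effect = 0.3,
                        batch_ids = data.frame(
                          batch = c("scanner1", "scanner2"),
                          shift = c(0, 15),
                          scale = c(1, 1.2)),
                        noise_sd = 1,
                        inner_fraction = 0.3,
                        external_fraction = 0.25,
                        habitat_mode = c("concentric", "scattered"),
                        batch_mode = c("by_center", "interleaved"),
                        spacing = c(1, 1, 4),
                        seed = 1L) {
  habitat_mode <- match.arg(habitat_mode)
  batch_mode <- match.arg(batch_mode)
  spec <- structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    n_slices = as.integer(n_slices), height = as.integer(height),
    width = as.integer(width),
    habitat_contrast = habitat_contrast, entropy_contrast = entropy_contrast,
    class_effect = class_effect, batch_ids = batch_ids,
    noise_sd = noise_sd, inner_fraction = inner_fraction,
    external_fraction = external_fraction, habitat_mode = habitat_mode,
    batch_mode = batch_mode,
    spacing = spacing, seed = as.integer(seed)), class = "cohort_spec")
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$height < 9 || spec$width < 9)
    stop("in-plane dimensions must be >= 9 (the 9x9 entropy window must fit)")
  if (spec$prevalence <= 0 || spec$prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  if (spec$prevalence * spec$n_patients < 2 ||
      (1 - spec$prevalence) * spec$n_patients < 2)
    stop("each class needs an expected count of at least 2 patients")
  if (spec$inner_fraction < 0.2 || spec$inner_fraction > 0.8)
    stop("inner_fraction must lie in [0.2, 0.8]")
  # the concentric core shrinks in-plane radii by inner_fraction^(1/3);
  # it must still admit a 9x9 in-plane window at the equatorial slice
  r_in <- 0.5 * (min(spec$height, spec$width) / 2 - 1) *
    spec$inner_fraction^(1/3) * 2
  if (r_in < 4.5)
    stop("inner habitat cannot fit a 9x9 in-plane window; enlarge the grid ",
         "or inner_fraction")
  if (spec$noise_sd <= 0) stop("noise_sd must be positive")
  if (!all(c("batch", "shift", "scale") %in% names(spec$batch_ids)))
    stop("batch_ids needs columns batch, shift, scale")
  invisible(spec)
}

#' A single-sequence lesion volume
#'
#' @param patient_id,sequence_id identifiers; `sequence_id` is typically
#'   `"T1W"` or `"T2FS"`.
#' @param image 3D numeric array of intensities (arbitrary units).
#' @param mask 3D logical array on the same grid; must be nonempty.
#' @param spacing voxel spacing in mm.
#' @return an object of class `lesion_volume`.
#' @export
lesion_volume <- function(patient_id, sequence_id, image, mask,
                          spacing = c(1, 1, 4)) {
  image <- as.array(image); mask <- array(as.logical(mask), dim(mask))
  if (!identical(dim(image), dim(mask)))
    stop("image and mask grids differ for patient ", patient_id)
  if (!any(mask)) stop("empty mask for patient ", patient_id)
  if (!all(is.finite(image[mask])))
    stop("non-finite intensities inside the mask for patient ", patient_id)
  structure(list(patient_id = patient_id, sequence_id = sequence_id,
                 image = image, mask = mask, spacing = spacing),
            class = "lesion_volume")
}

#' @export
print.lesion_volume <- function(x, ...) {
  cat(sprintf("<lesion_volume> %s / %s  grid %s  %d mask voxels\n",
              x$patient_id, x$sequence_id,
              paste(dim(x$image), collapse = "x"), sum(x$mask)))
  invisible(x)
}

# Ellipsoid mask centred in the grid. Radii in voxels.
ellipsoid_mask <- function(dims, centre, radii) {
  gx <- (seq_len(dims[1]) - centre[1]) / radii[1]
  gy <- (seq_len(dims[2]) - centre[2]) / radii[2]
  gz <- (seq_len(dims[3]) - centre[3]) / radii[3]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  d2 <= 1
}

# Build lesion + inner-habitat masks for one patient.
make_habitat_geometry <- function(spec) {
  dims <- c(spec$height, spec$width, spec$n_slices)
  centre <- (dims + 1) / 2
  rx <- (dims[1] / 2 - 1.5) * stats::runif(1, 0.85, 0.98)
  ry <- (dims[2] / 2 - 1.5) * stats::runif(1, 0.85, 0.98)
  # near-cylindrical through-plane extent: edge slices keep most of the
  # equatorial radius, so their marginal rim is not all boundary ring
  rz <- max(dims[3] * 1.1, 1.2)
  lesion <- ellipsoid_mask(dims, centre, c(rx, ry, rz))
  if (spec$habitat_mode == "concentric") {
    s <- spec$inner_fraction^(1/3)
    inner <- ellipsoid_mask(dims, centre, c(rx * s, ry * s, max(rz * s, 1.01)))
    inner <- inner & lesion
    # nudge the core scale so the realized fraction stays in [0.2, 0.8]
    frac <- sum(inner) / sum(lesion)
    tries <- 0
    while ((frac < 0.2 || frac > 0.8) && tries < 8) {
      s <- s * ifelse(frac < 0.2, 1.12, 0.9)
      inner <- ellipsoid_mask(dims, centre, c(rx * s, ry * s, max(rz * s, 1.01))) & lesion
      frac <- sum(inner) / sum(lesion)
      tries <- tries + 1
    }
  } else {
    idx <- which(lesion)
    n_in <- round(spec$inner_fraction * length(idx))
    seedvox <- sample(idx, 3)
    coords <- arrayInd(idx, dims)
    sc <- arrayInd(seedvox, dims)
    d <- sapply(seq_len(nrow(sc)), function(j)
      sqrt(rowSums(sweep(coords, 2, sc[j, ])^2)))
    ord <- order(apply(d, 1, min))
    inner <- array(FALSE, dims)
    inner[idx[ord[seq_len(n_in)]]] <- TRUE
  }
  list(lesion = lesion, inner = inner)
}

# Per-sequence appearance parameters; the two sequences share geometry and
# class effects but have independent noise and distinct base contrast.
sequence_params <- function(sequence_id) {
  switch(sequence_id,
    T1W  = list(base = 100, contrast_mult = 1.0),
    T2FS = list(base = 140, contrast_mult = 1.2),
    list(base = 100, contrast_mult = 1.0))
}

# Texture correlation lengths (voxels): the marginal habitat is smooth
# (correlation length 3); the inner habitat gets rougher (shorter
# correlation) and slightly louder as entropy_contrast grows, so its local
# entropy exceeds the rim's. A positive label further roughens and
# amplifies the inner-habitat texture only.
texture_sigmas <- function(spec, label) {
  sig_marg <- 3.0
  sig_in <- 3.0 / (1 + spec$entropy_contrast)
  amp_in <- 1 + spec$entropy_contrast / 3
  if (label == 1) {
    sig_in <- sig_in / (1 + 0.4 * spec$class_effect)
    amp_in <- amp_in * (1 + 0.35 * spec$class_effect)
  }
  list(sig_marg = sig_marg, sig_in = sig_in, amp_in = amp_in)
}

#' Generate a synthetic lesion cohort
#'
#' Draws lesions, clinical covariates, split and batch assignments from a
#' [cohort_spec()]. Identical specs (including the seed) produce
#' bit-identical cohorts.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `habitat_cohort`: a list with `volumes` (per
#'   patient, a named list of [lesion_volume()]s per sequence), `truth`
#'   (per patient, the integer habitat array: 0 background, 1 marginal,
#'   2 inner), `clinical` (one row per patient) and `spec`.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  with_seed(spec$seed, {
    n <- spec$n_patients
    dims <- c(spec$height, spec$width, spec$n_slices)
    ids <- sprintf("P%03d", seq_len(n))
    label <- stats::rbinom(n, 1, spec$prevalence)
    # guarantee the hard class-count floor even at small n
    while (sum(label) < 2 || sum(1 - label) < 2)
      label <- stats::rbinom(n, 1, spec$prevalence)

    n_ext <- round(spec$external_fraction * n)
    split <- rep("train", n)
    ext_idx <- seq_len(n) > (n - n_ext)
    split[ext_idx] <- "external"
    # 2:1 train:internal within the first scanner, stratified by label
    for (l in 0:1) {
      cand <- which(!ext_idx & label == l)
      n_int <- round(length(cand) / 3)
      if (n_int > 0) split[sample(cand, n_int)] <- "internal"
    }
    batches <- spec$batch_ids
    batch <- if (spec$batch_mode == "interleaved")
      rep_len(batches$batch, n)
    else ifelse(ext_idx, batches$batch[min(2, nrow(batches))],
                batches$batch[1])

    clinical <- data.frame(
      patient_id = ids, label = label, split = split, batch = batch,
      age = round(stats::rnorm(n, 60, 10)),
      gender = sample(c("male", "female"), n, TRUE, prob = c(0.4, 0.6)),
      smoking = stats::rbinom(n, 1, ifelse(label == 1, 0.45, 0.10)),
      ps_score = sample(0:2, n, TRUE, prob = c(0.15, 0.75, 0.10)),
      cea = round(exp(stats::rnorm(n, log(40), 1.4)), 2),
      cyfra = round(exp(stats::rnorm(n, log(6), 0.9)), 2),
      nse = round(exp(stats::rnorm(n, log(20), 0.7)), 2),
      stringsAsFactors = FALSE)

    volumes <- vector("list", n); names(volumes) <- ids
    truth <- vector("list", n); names(truth) <- ids
    for (i in seq_len(n)) {
      geom <- make_habitat_geometry(spec)
      tru <- array(0L, dims)
      tru[geom$lesion] <- 1L
      tru[geom$inner] <- 2L
      truth[[i]] <- tru
      sig <- texture_sigmas(spec, label[i])
      b <- batches[batches$batch == batch[i], ]
      vols <- list()
      for (sq in c("T1W", "T2FS")) {
        pars <- sequence_params(sq)
        img <- array(0, dims)
        f_marg <- correlated_field(dims, sig$sig_marg) * spec$noise_sd
        f_in <- correlated_field(dims, sig$sig_in) * spec$noise_sd * sig$amp_in
        img[geom$lesion] <- pars$base + f_marg[geom$lesion]
        img[geom$inner] <- pars$base +
          pars$contrast_mult * spec$habitat_contrast * spec$noise_sd +
          f_in[geom$inner]
        img <- b$shift + b$scale * img           # batch after class effect
        img[!geom$lesion] <- 0
        vols[[sq]] <- lesion_volume(ids[i], sq, img, geom$lesion,
                                    spec$spacing)
      }
      volumes[[i]] <- vols
    }
    structure(list(volumes = volumes, truth = truth, clinical = clinical,
                   spec = spec), class = "habitat_cohort")
  })
}

#' @export
print.habitat_cohort <- function(x, ...) {
  cat(sprintf(paste0("<habitat_cohort> %d patients, prevalence %.2f ",
                     "(realized %.2f), splits: %s\n"),
              x$spec$n_patients, x$spec$prevalence,
              mean(x$clinical$label),
              paste(names(table(x$clinical$split)),
                    table(x$clinical$split), sep = "=", collapse = " ")))
  invisible(x)
}

#' Write a cohort to disk in standard formats
#'
#' One NIfTI image and one NIfTI mask per patient-sequence, a NIfTI
#' ground-truth habitat volume per patient, the clinical table as CSV and a
#' JSON manifest carrying the full spec (including the seed) so the cohort
#' can be regenerated or re-read.
#'
#' @param cohort a `habitat_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the manifest as a list.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "habitat_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  files <- list()
  for (pid in names(cohort$volumes)) {
    for (sq in names(cohort$volumes[[pid]])) {
      v <- cohort$volumes[[pid]][[sq]]
      fi <- file.path(dir, sprintf("%s_%s_image.nii.gz", pid, sq))
      fm <- file.path(dir, sprintf("%s_%s_mask.nii.gz", pid, sq))
      RNifti::writeNifti(RNifti::asNifti(v$image, pixdim = v$spacing), fi)
      RNifti::writeNifti(RNifti::asNifti(v$mask + 0L, pixdim = v$spacing), fm)
      files[[length(files) + 1]] <- list(patient_id = pid, sequence = sq,
                                         image = basename(fi),
                                         mask = basename(fm))
    }
    ft <- file.path(dir, sprintf("%s_habitat_truth.nii.gz", pid))
    RNifti::writeNifti(RNifti::asNifti(cohort$truth[[pid]],
                                       pixdim = cohort$spec$spacing), ft)
  }
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  spec_json <- cohort$spec
  spec_json$batch_ids <- as.list(spec_json$batch_ids)
  manifest <- list(format = "habitrad-cohort", version = 1L,
                   spec = unclass(spec_json), files = files,
                   clinical = "clinical.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir the cohort directory.
#' @return a `habitat_cohort` (voxelwise identical to the written one).
#' @export
read_cohort <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  if (!identical(mf$format, "habitrad-cohort"))
    stop("not a cohort directory: ", dir)
  sp <- mf$spec
  spec <- cohort_spec(
    n_patients = sp$n_patients, prevalence = sp$prevalence,
    n_slices = sp$n_slices, height = sp$height, width = sp$width,
    habitat_contrast = sp$habitat_contrast,
    entropy_contrast = sp$entropy_contrast, class_effect = sp$class_effect,
    batch_ids = as.data.frame(sp$batch_ids), noise_sd = sp$noise_sd,
    inner_fraction = sp$inner_fraction,
    external_fraction = sp$external_fraction, habitat_mode = sp$habitat_mode,
    batch_mode = sp$batch_mode %||% "by_center",
    spacing = unlist(sp$spacing), seed = sp$seed)
  clinical <- utils::read.csv(file.path(dir, mf$clinical),
                              stringsAsFactors = FALSE)
  files <- mf$files
  ids <- unique(files$patient_id)
  volumes <- truth <- stats::setNames(vector("list", length(ids)), ids)
  for (pid in ids) {
    rows <- files[files$patient_id == pid, ]
    vols <- list()
    for (j in seq_len(nrow(rows))) {
      img <- array(as.numeric(RNifti::readNifti(file.path(dir, rows$image[j]))),
                   dim = c(spec$height, spec$width, spec$n_slices))
      msk <- array(as.numeric(RNifti::readNifti(file.path(dir, rows$mask[j]))) > 0,
                   dim = dim(img))
      vols[[rows$sequence[j]]] <- lesion_volume(pid, rows$sequence[j], img,
                                                msk, spec$spacing)
    }
    volumes[[pid]] <- vols
    tf <- file.path(dir, sprintf("%s_habitat_truth.nii.gz", pid))
    if (file.exists(tf))
      truth[[pid]] <- array(as.integer(RNifti::readNifti(tf)),
                            dim = c(spec$height, spec$width, spec$n_slices))
  }
  structure(list(volumes = volumes, truth = truth, clinical = clinical,
                 spec = spec), class = "habitat_cohort")
}
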