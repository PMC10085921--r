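#' Voxel grid container
#'
#' A 3D integer intensity field with voxel spacing and a tooth mask. The
#' mask delimits the tooth (the manual delineation convention, including
#' the apical end of each root, is assumed to be embodied in it).
#'
#' @param intensities 3D numeric array of non-negative intensities.
#' @param spacing_mm Positive length-3 voxel edge lengths in mm.
#' @param mask Logical array of the same shape; `TRUE` inside the tooth.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(intensities, spacing_mm, mask) {
  if (!is.array(intensities) || length(dim(intensities)) != 3)
    stop("intensities must be a 3D array")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing_mm must be three positive lengths")
  if (!identical(dim(mask), dim(intensities)))
    stop("mask shape does not match intensity shape")
  if (any(intensities < 0, na.rm = TRUE))
    stop("intensities must be non-negative")
  structure(list(intensities = intensities, spacing_mm = spacing_mm,
                 mask = array(as.logical(mask), dim = dim(mask))),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat("voxel_grid:", paste(dim(x$intensities), collapse = " x "),
      "voxels,", paste(format(x$spacing_mm), collapse = " x "),
      "mm spacing,", sum(x$mask), "masked\n")
  invisible(x)
}

#' T2 intensity thresholds separating the three tooth tissues
#'
#' Closed upper band edges: intensities up to `hard_max` are hard tooth
#' tissue (dentine + enamel + cementum, indistinguishable on T2), up to
#' `predentine_max` predentine, and above that pulp. Defaults are the
#' values established against tooth ground sections (63 and 100); they
#' presuppose the acquisition's intensity normalisation and are
#' configurable for other scanners.
#'
#' @param hard_max Upper intensity bound of hard tissue (default 63).
#' @param predentine_max Upper intensity bound of predentine (default 100).
#' @return An object of class `threshold_scheme`.
#' @export
threshold_scheme <- function(hard_max = 63, predentine_max = 100) {
  if (hard_max < 0 || hard_max >= predentine_max)
    stop("require 0 <= hard_max < predentine_max")
  structure(list(hard_max = hard_max, predentine_max = predentine_max),
            class = "threshold_scheme")
}

#' Tissue label codes used in label maps
#' @return Named integer vector: background 0, hard 1, predentine 2, pulp 3.
#' @export
tissue_labels <- function() {
  c(background = 0L, hard = 1L, predentine = 2L, pulp = 3L)
}

#' Classify masked voxels into hard tissue, predentine and pulp
#'
#' Every masked voxel receives exactly one tissue label by intensity
#' thresholding; unmasked voxels are background. Non-integer intensities
#' are floored before comparison, so band edges are closed exactly as the
#' integer scheme states (63 is hard, 100 is predentine, 101 is pulp).
#'
#' @param grid A [voxel_grid()].
#' @param scheme A [threshold_scheme()].
#' @return Integer array of the grid's shape with codes from
#'   [tissue_labels()].
#' @export
classify_voxels <- function(grid, scheme = threshold_scheme()) {
  stopifnot(inherits(grid, "voxel_grid"), inherits(scheme, "threshold_scheme"))
  intens <- floor(grid$intensities)
  labels <- array(0L, dim = dim(intens))
  labels[grid$mask & intens <= scheme$hard_max] <- 1L
  labels[grid$mask & intens > scheme$hard_max &
           intens <= scheme$predentine_max] <- 2L
  labels[grid$mask & intens > scheme$predentine_max] <- 3L
  labels
}

#' Volume of one voxel in millilitres
#'
#' At the acquisition's 0.37 mm iso-voxels one millilitre (roughly one
#' tooth) corresponds to about 20,000 voxels.
#'
#' @param spacing_mm Positive length-3 voxel edge lengths in mm.
#' @return Volume of one voxel in ml (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(spacing_mm) {
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3 || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("spacing must be three positive lengths")
  prod(spacing_mm) / 1000
}

#' Tissue volumes of one tooth
#'
#' @param tooth_id FDI code, one of 18, 28, 38, 48.
#' @param pulp_ml,predentine_ml,hard_ml Non-negative volumes in ml.
#' @return Object of class `tooth_volumes` with derived `total_ml`.
#' @export
tooth_volumes <- function(tooth_id, pulp_ml, predentine_ml, hard_ml) {
  tooth_id <- as.integer(tooth_id)
  if (!tooth_id %in% third_molars())
    stop("unknown tooth_id: ", tooth_id, " (FDI third molars are 18/28/38/48)")
  vols <- c(pulp_ml, predentine_ml, hard_ml)
  if (any(!is.finite(vols)) || any(vols < 0))
    stop("tissue volumes must be non-negative")
  structure(list(tooth_id = tooth_id, pulp_ml = pulp_ml,
                 predentine_ml = predentine_ml, hard_ml = hard_ml,
                 total_ml = pulp_ml + predentine_ml + hard_ml),
            class = "tooth_volumes")
}

#' @export
print.tooth_volumes <- function(x, ...) {
  cat(sprintf("tooth %d: pulp %.4f ml, predentine %.4f ml, hard %.4f ml (total %.4f ml)\n",
              x$tooth_id, x$pulp_ml, x$predentine_ml, x$hard_ml, x$total_ml))
  invisible(x)
}

#' Quantify tissue volumes from a label map
#'
#' Each tissue volume is its voxel count times the voxel volume; the total
#' equals the masked (non-background) volume by construction.
#'
#' @param labels Integer label array from [classify_voxels()].
#' @param spacing_mm Voxel spacing in mm.
#' @param tooth_id FDI code of the segmented tooth.
#' @return A [tooth_volumes()] object.
#' @export
compute_volumes <- function(labels, spacing_mm, tooth_id) {
  vv <- voxel_volume_ml(spacing_mm)
  tooth_volumes(tooth_id,
                pulp_ml = sum(labels == 3L) * vv,
                predentine_ml = sum(labels == 2L) * vv,
                hard_ml = sum(labels == 1L) * vv)
}

#' Segment a voxel grid and quantify its tissue volumes
#'
#' Convenience wrapper: [classify_voxels()] followed by [compute_volumes()].
#'
#' @inheritParams classify_voxels
#' @param tooth_id FDI code of the tooth.
#' @return A [tooth_volumes()] object.
#' @export
segment_tooth <- function(grid, tooth_id, scheme = threshold_scheme()) {
  compute_volumes(classify_voxels(grid, scheme), grid$spacing_mm, tooth_id)
}

#' Read an image and tooth mask from NIfTI files
#'
#' @param image_path Path to the intensity image (NIfTI).
#' @param mask_path Path to the mask image (NIfTI; non-zero = tooth).
#' @return A [voxel_grid()] with spacing taken from the image header.
#' @export
read_voxel_grid <- function(image_path, mask_path) {
  img <- RNifti::readNifti(image_path)
  msk <- RNifti::readNifti(mask_path)
  spacing <- RNifti::pixdim(img)[1:3]
  voxel_grid(array(as.numeric(img), dim = dim(img)[1:3]), spacing,
             array(as.numeric(msk) != 0, dim = dim(msk)[1:3]))
}

#' Write a voxel grid as NIfTI image + mask
#'
#' @param grid A [voxel_grid()].
#' @param image_path,mask_path Output paths.
#' @return `image_path`, invisibly.
#' @export
write_voxel_grid <- function(grid, image_path, mask_path) {
  img <- RNifti::asNifti(grid$intensities)
  RNifti::pixdim(img) <- grid$spacing_mm
  RNifti::writeNifti(img, image_path)
  msk <- RNifti::asNifti(array(as.integer(grid$mask), dim = dim(grid$mask)))
  RNifti::pixdim(msk) <- grid$spacing_mm
  RNifti::writeNifti(msk, mask_path)
  invisible(image_path)
}

#' Write a label map as NIfTI
#'
#' Integer codes per [tissue_labels()].
#'
#' @param labels Integer label array.
#' @param spacing_mm Voxel spacing in mm.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, spacing_mm, path) {
  img <- RNifti::asNifti(labels)
  RNifti::pixdim(img) <- as.numeric(spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
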