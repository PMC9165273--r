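#' Manifest of the standardised radiomic feature set
#'
#' The frozen catalogue of the 107 features extracted per modality: 14 shape,
#' 18 first-order intensity and 75 texture features (24 GLCM, 16 GLRLM, 16
#' GLSZM, 14 GLDM, 5 NGTDM). Any drift of the extracted names or counts from
#' this manifest is a defect.
#'
#' @return Tibble with columns `family` and `feature` (107 rows).
#' @export
feature_manifest <- function() {
  fam <- list(
    shape = c(
      "MeshVolume", "VoxelVolume", "SurfaceArea", "SurfaceVolumeRatio",
      "Sphericity", "Maximum3DDiameter", "Maximum2DDiameterSlice",
      "Maximum2DDiameterColumn", "Maximum2DDiameterRow", "MajorAxisLength",
      "MinorAxisLength", "LeastAxisLength", "Elongation", "Flatness"
    ),
    firstorder = c(
      "Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
      "90Percentile", "Maximum", "Mean", "Median", "InterquartileRange",
      "Range", "MeanAbsoluteDeviation", "RobustMeanAbsoluteDeviation",
      "RootMeanSquared", "Skewness", "Kurtosis", "Variance", "Uniformity"
    ),
    glcm = c(
      "Autocorrelation", "JointAverage", "ClusterProminence", "ClusterShade",
      "ClusterTendency", "Contrast", "Correlation", "DifferenceAverage",
      "DifferenceEntropy", "DifferenceVariance", "JointEnergy",
      "JointEntropy", "Imc1", "Imc2", "Idm", "Idmn", "Id", "Idn",
      "InverseVariance", "MaximumProbability", "SumAverage", "SumEntropy",
      "SumSquares", "MCC"
    ),
    glrlm = unname(.glrlm_names),
    glszm = unname(.glszm_names),
    gldm = unname(.gldm_names),
    ngtdm = c("Coarseness", "Contrast", "Busyness", "Complexity", "Strength")
  )
  tibble::tibble(
    family = rep(names(fam), lengths(fam)),
    feature = unlist(fam, use.names = FALSE)
  )
}

#' Extract the standardised radiomic feature set from one VOI
#'
#' Computes the 107 standardised features (see [feature_manifest()]) on a
#' volume/mask pair that is already interpolated to the analysis grid and
#' carries the modality's fixed bin width. For a single-voxel mask the shape
#' features are returned and all intensity/texture features are `NA`
#' (undefined, never silently zero).
#'
#' @param vol An [image_volume()], interpolated to the analysis grid.
#' @param mask A [voi_mask()] on the same grid.
#' @param bin_width Discretisation bin width (0.5 g/mL for PET, 25 HU for
#'   low-dose CT).
#' @param modality Label stored in the output (`"PET"` or `"CT"`).
#' @param families Character vector of families to extract (default all).
#' @return Tibble with columns `modality`, `family`, `feature`, `value`,
#'   with attribute `bin_width` and `spacing`.
#' @export
extract_features <- function(vol, mask, bin_width,
                             modality = c("PET", "CT"),
                             families = c(
                               "shape", "firstorder", "glcm", "glrlm",
                               "glszm", "gldm", "ngtdm"
                             )) {
  modality <- match.arg(modality)
  families <- match.arg(families, several.ok = TRUE)
  check_same_grid(vol, mask)
  nv <- mask_voxel_count(mask)
  if (nv == 0) stop("mask is empty", call. = FALSE)
  manifest <- feature_manifest()
  single <- nv == 1L

  vals <- list()
  if ("shape" %in% families) vals$shape <- shape_features(mask)
  if (single) {
    for (f in setdiff(families, "shape")) {
      nm <- manifest$feature[manifest$family == f]
      vals[[f]] <- stats::setNames(rep(NA_real_, length(nm)), nm)
    }
    warning("single-voxel mask: intensity and texture features are undefined")
  } else {
    disc <- discretise(vol, mask, bin_width)
    lev <- disc$levels
    ng <- disc$n_levels
    if ("firstorder" %in% families) {
      vals$firstorder <- firstorder_features(vol, mask, disc = disc)
    }
    if ("glcm" %in% families) vals$glcm <- glcm_features(lev, ng)
    if ("glrlm" %in% families) vals$glrlm <- glrlm_features(lev, ng)
    if ("glszm" %in% families) vals$glszm <- glszm_features(lev, ng)
    if ("gldm" %in% families) vals$gldm <- gldm_features(lev, ng)
    if ("ngtdm" %in% families) vals$ngtdm <- ngtdm_features(lev, ng)
  }

  out <- purrr::map_dfr(names(vals), function(f) {
    tibble::tibble(
      modality = modality, family = f,
      feature = names(vals[[f]]), value = unname(vals[[f]])
    )
  })
  expect <- manifest[manifest$family %in% families, ]
  if (!identical(
    paste(out$family, out$feature),
    paste(expect$family, expect$feature)
  )) {
    stop("extracted feature set drifted from the manifest", call. = FALSE)
  }
  attr(out, "bin_width") <- bin_width
  attr(out, "spacing") <- vol$spacing
  out
}

#' Total lesion glycolysis
#'
#' `TLG = SUVmean * MTV` where the metabolic tumour volume MTV is the
#' segmented volume in mL (voxel volume times voxel count). Equal to the sum
#' of in-mask SUVs times the voxel volume.
#'
#' @param pet PET [image_volume()] in g/mL.
#' @param mask A [voi_mask()] on the same grid.
#' @return TLG in grams.
#' @export
compute_tlg <- function(pet, mask) {
  check_same_grid(pet, mask)
  x <- pet$data[mask$data != 0L]
  if (length(x) == 0) stop("mask is empty", call. = FALSE)
  mean(x) * (length(x) * voxel_volume(pet, "ml"))
}

#' Radiomic feature table for one case (PET + low-dose CT)
#'
#' Full per-case feature pipeline: interpolates PET and CT to their isotropic
#' analysis grids (4 mm and 2 mm by default), resamples the PET-defined VOI
#' to each grid by nearest neighbour, extracts the 107-feature set per
#' modality with the modality's fixed bin width, and appends PET TLG (108
#' PET values in total).
#'
#' @param pet,ct [image_volume()]s (CT may be `NULL` for a PET-only table).
#' @param mask PET-space [voi_mask()].
#' @param pet_spacing,ct_spacing Isotropic analysis spacings in mm.
#' @param pet_bin,ct_bin Fixed bin widths (g/mL, HU).
#' @return Tibble `modality`, `family`, `feature`, `value`; feature names
#'   prefixed `PET_` / `CT_` in the column `name`.
#' @export
radiomic_features <- function(pet, ct, mask, pet_spacing = 4, ct_spacing = 2,
                              pet_bin = 0.5, ct_bin = 25) {
  pet_i <- interpolate_volume(pet, pet_spacing)
  mask_pet <- resample_mask(mask, list(
    spacing = pet_i$spacing, dim = dim(pet_i$data), origin = pet_i$origin
  ))
  if (mask_voxel_count(mask_pet) == 0) {
    stop("VOI vanished on the PET analysis grid", call. = FALSE)
  }
  out <- extract_features(pet_i, mask_pet, pet_bin, modality = "PET")
  tlg <- tibble::tibble(
    modality = "PET", family = "firstorder", feature = "TLG",
    value = compute_tlg(pet_i, mask_pet)
  )
  out <- dplyr::bind_rows(out, tlg)
  if (!is.null(ct)) {
    ct_i <- interpolate_volume(ct, ct_spacing)
    mask_ct <- resample_mask(mask, list(
      spacing = ct_i$spacing, dim = dim(ct_i$data), origin = ct_i$origin
    ))
    if (mask_voxel_count(mask_ct) == 0) {
      stop("VOI vanished on the CT analysis grid", call. = FALSE)
    }
    out <- dplyr::bind_rows(out, extract_features(ct_i, mask_ct, ct_bin, modality = "CT"))
  }
  # family kept in the name: several families share feature names (e.g.
  # glcm and ngtdm both have a Contrast)
  dplyr::mutate(
    out,
    name = paste(.data$modality, .data$family, .data$feature, sep = "_")
  )
}
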