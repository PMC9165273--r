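#' SUVmax within a region
#'
#' Maximum voxel SUV over the in-mask voxels.
#'
#' @param pet PET [image_volume()] in SUV units (g/mL).
#' @param region A [voi_mask()] on the same grid.
#' @return SUVmax in g/mL.
#' @export
compute_suvmax <- function(pet, region) {
  check_same_grid(pet, region)
  vals <- pet$data[region$data != 0L]
  if (length(vals) == 0) stop("region is empty", call. = FALSE)
  max(vals)
}

# Stencil of voxel index offsets whose centres lie within a sphere of
# radius r_mm on a grid with the given spacing.
sphere_stencil <- function(spacing, r_mm) {
  nr <- floor(r_mm / spacing)
  off <- expand.grid(
    i = -nr[1]:nr[1], j = -nr[2]:nr[2], k = -nr[3]:nr[3]
  )
  d2 <- (off$i * spacing[1])^2 + (off$j * spacing[2])^2 + (off$k * spacing[3])^2
  as.matrix(off[d2 <= r_mm^2, , drop = FALSE])
}

#' SUVpeak: maximum mean SUV over a 1 cm^3 sphere
#'
#' SUVpeak is the maximum, over candidate sphere positions, of the mean SUV
#' of voxels whose centres lie within a sphere of volume `sphere_ml`
#' (default 1 mL, diameter about 12.4 mm). Candidate centres are the voxel
#' centres whose sphere contains at least one in-region voxel centre, so the
#' sphere may extend beyond the region itself. Sphere membership is by voxel
#' centre inclusion; spheres are clipped at the volume border.
#'
#' @inheritParams compute_suvmax
#' @param sphere_ml Sphere volume in mL.
#' @return SUVpeak in g/mL.
#' @export
compute_suvpeak <- function(pet, region, sphere_ml = 1) {
  check_same_grid(pet, region)
  if (mask_voxel_count(region) == 0) stop("region is empty", call. = FALSE)
  r_mm <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  if (any(pet$spacing > 2 * r_mm)) {
    stop("grid is coarser than the sphere diameter", call. = FALSE)
  }
  sten <- sphere_stencil(pet$spacing, r_mm)
  d <- dim(pet$data)
  reg_idx <- mask_indices(region)
  # candidate centres: voxels within r of any region voxel = region dilated
  # by the (symmetric) stencil
  cand <- matrix(FALSE, nrow = prod(d), ncol = 1)
  dim(cand) <- d
  for (t in seq_len(nrow(sten))) {
    ii <- reg_idx[, 1] + sten[t, 1]
    jj <- reg_idx[, 2] + sten[t, 2]
    kk <- reg_idx[, 3] + sten[t, 3]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    cand[cbind(ii[ok], jj[ok], kk[ok])] <- TRUE
  }
  cand_idx <- which(cand, arr.ind = TRUE)
  best <- -Inf
  for (c_i in seq_len(nrow(cand_idx))) {
    ii <- cand_idx[c_i, 1] + sten[, 1]
    jj <- cand_idx[c_i, 2] + sten[, 2]
    kk <- cand_idx[c_i, 3] + sten[, 3]
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    m <- mean(pet$data[cbind(ii[ok], jj[ok], kk[ok])])
    if (m > best) best <- m
  }
  best
}

#' Background SUVmax of contralateral normal thyroid tissue
#'
#' Maximum voxel SUV in the contralateral background region. The region must
#' not overlap the nodule mask.
#'
#' @inheritParams compute_suvmax
#' @param contralateral_region Background [voi_mask()].
#' @param nodule_mask Optional nodule [voi_mask()] checked for overlap.
#' @return Background SUVmax in g/mL.
#' @export
compute_background <- function(pet, contralateral_region, nodule_mask = NULL) {
  check_same_grid(pet, contralateral_region)
  if (mask_voxel_count(contralateral_region) == 0) {
    stop("background region is empty", call. = FALSE)
  }
  if (!is.null(nodule_mask) &&
    any(contralateral_region$data != 0L & nodule_mask$data != 0L)) {
    stop("background region overlaps the nodule mask", call. = FALSE)
  }
  max(pet$data[contralateral_region$data != 0L])
}

#' Mirror a nodule box into the contralateral lobe
#'
#' In phantom mode the background region is an automatically mirrored copy of
#' the nodule box, reflected across the mid-sagittal (first-axis) plane of
#' the volume.
#'
#' @param vol An [image_volume()] defining the grid.
#' @param box A box as returned by [apply_boxing()] (`list(lo, hi)` voxel
#'   index bounds).
#' Voxels of the mirrored box that fall inside the original (nodule) box are
#' excluded, so a weakly lateralised nodule cannot contaminate its own
#' background region.
#'
#' @return A [voi_mask()] covering the mirrored box.
#' @export
mirror_background_mask <- function(vol, box) {
  d <- dim(vol$data)
  lo <- box$lo
  hi <- box$hi
  m_lo <- d[1] + 1L - hi[1]
  m_hi <- d[1] + 1L - lo[1]
  arr <- array(0L, d)
  arr[m_lo:m_hi, lo[2]:hi[2], lo[3]:hi[3]] <- 1L
  arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 0L
  if (!any(arr != 0L)) {
    stop("mirrored background region is empty (nodule box spans the mid-plane)",
      call. = FALSE
    )
  }
  voi_mask(arr, vol$spacing, vol$origin,
    provenance = list(kind = "mirrored background box")
  )
}

#' SUV ratios relative to the contralateral background
#'
#' @param suv_max,suv_peak Nodule SUVmax and SUVpeak (g/mL).
#' @param background Background SUVmax (g/mL), `> 0`.
#' @return Named numeric `c(suv_max_ratio, suv_peak_ratio)` at full
#'   precision; tabular presentation rounds to one decimal.
#' @examples
#' round(compute_ratios(9.7, 7.0, 1.6), 1) # 6.1, 4.4
#' @export
compute_ratios <- function(suv_max, suv_peak, background) {
  if (!is.finite(background) || background <= 0) {
    stop("background SUV must be positive", call. = FALSE)
  }
  c(suv_max_ratio = suv_max / background, suv_peak_ratio = suv_peak / background)
}

#' Full SUV report for one nodule
#'
#' Computes SUVmax, SUVpeak, the contralateral background SUVmax and both
#' SUV-ratios for an index nodule.
#'
#' @inheritParams compute_suvmax
#' @param nodule_region Nodule [voi_mask()].
#' @param background_region Contralateral background [voi_mask()].
#' @return One-row tibble: `suv_max`, `suv_peak`, `background_suv_max`,
#'   `suv_max_ratio`, `suv_peak_ratio`.
#' @export
suv_report <- function(pet, nodule_region, background_region) {
  smax <- compute_suvmax(pet, nodule_region)
  speak <- compute_suvpeak(pet, nodule_region)
  bg <- compute_background(pet, background_region, nodule_mask = nodule_region)
  r <- compute_ratios(smax, speak, bg)
  tibble::tibble(
    suv_max = smax, suv_peak = speak, background_suv_max = bg,
    suv_max_ratio = r[["suv_max_ratio"]], suv_peak_ratio = r[["suv_peak_ratio"]]
  )
}
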