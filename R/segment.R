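#' Axis-aligned boxing around a nodule locator
#'
#' Crops the analysis to a box centred on the (ultrasound-derived) nodule
#' locator, to exclude FDG-positive tissue surrounding the index nodule. The
#' box half-extent per axis is `margin * extent_mm / 2`.
#'
#' @param vol An [image_volume()].
#' @param centre_mm Locator centre in world mm.
#' @param extent_mm Locator size (mm), scalar or length 3.
#' @param margin Multiplicative margin on the extent (default 1.5).
#' @return `list(lo, hi)` of 1-based voxel index bounds (inclusive). Boxes
#'   partly outside the volume are clipped with a warning; a box fully
#'   outside is an error.
#' @export
apply_boxing <- function(vol, centre_mm, extent_mm, margin = 1.5) {
  d <- dim(vol$data)
  extent_mm <- rep(as.numeric(extent_mm), length.out = 3)
  half <- margin * extent_mm / 2
  lo_w <- centre_mm - half
  hi_w <- centre_mm + half
  lo <- ceiling((lo_w - vol$origin) / vol$spacing - 1e-9) + 1L
  hi <- floor((hi_w - vol$origin) / vol$spacing + 1e-9) + 1L
  if (any(hi < 1L) || any(lo > d)) {
    stop("box lies fully outside the volume", call. = FALSE)
  }
  clipped <- any(lo < 1L) || any(hi > d)
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, d)
  if (clipped) warning("box clipped to the volume extent")
  if (any(hi < lo)) stop("box is empty", call. = FALSE)
  list(lo = as.integer(lo), hi = as.integer(hi))
}

box_mask <- function(vol, box) {
  arr <- array(0L, dim(vol$data))
  arr[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- 1L
  voi_mask(arr, vol$spacing, vol$origin)
}

# 26-connected component of `candidate` (logical array) containing `seed`
# (length-3 index). Vectorised frontier dilation.
connected_component <- function(candidate, seed) {
  d <- dim(candidate)
  comp <- array(FALSE, d)
  comp[seed[1], seed[2], seed[3]] <- TRUE
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  frontier <- which(comp)
  while (length(frontier) > 0) {
    fi <- arrayInd(frontier, d)
    nxt <- logical(0)
    grown <- array(FALSE, d)
    for (t in seq_len(nrow(offs))) {
      ii <- fi[, 1] + offs[t, 1]
      jj <- fi[, 2] + offs[t, 2]
      kk <- fi[, 3] + offs[t, 3]
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
      if (!any(ok)) next
      lin <- cbind(ii[ok], jj[ok], kk[ok])
      hit <- candidate[lin] & !comp[lin] & !grown[lin]
      if (any(hit)) grown[lin[hit, , drop = FALSE]] <- TRUE
    }
    frontier <- which(grown)
    comp[frontier] <- TRUE
  }
  comp
}

#' Background-corrected isocontour segmentation
#'
#' Delineates the nodule VOI on PET. SUVpeak is computed within the box, a
#' threshold is derived from it with correction for the local background, and
#' the mask is the 26-connected component (voxels `>= T`) containing the
#' in-box SUVmax voxel.
#'
#' The default background correction is
#' `T = background + 0.5 * (SUVpeak - background)`; the additive variant
#' `T = 0.5 * SUVpeak + background` is available via `method`.
#'
#' @param pet PET [image_volume()].
#' @param box `list(lo, hi)` voxel bounds from [apply_boxing()].
#' @param background_suv Local background SUV (g/mL), `>= 0`. Defaults in the
#'   pipeline to the contralateral background SUVmax.
#' @param method `"background_corrected"` (default) or `"additive"`.
#' @param level Isocontour level as a fraction of the (corrected) peak,
#'   default 0.5.
#' @return A [voi_mask()] whose `provenance` records the threshold, SUVpeak,
#'   background and box.
#' @export
segment_nodule <- function(pet, box, background_suv,
                           method = c("background_corrected", "additive"),
                           level = 0.5) {
  method <- match.arg(method)
  if (!is.finite(background_suv) || background_suv < 0) {
    stop("background SUV must be non-negative", call. = FALSE)
  }
  bmask <- box_mask(pet, box)
  peak <- compute_suvpeak(pet, bmask)
  if (peak <= background_suv) {
    stop("nodule not above background (SUVpeak <= background)", call. = FALSE)
  }
  thr <- switch(method,
    background_corrected = background_suv + level * (peak - background_suv),
    additive = level * peak + background_suv
  )
  candidate <- pet$data >= thr & bmask$data != 0L
  if (!any(candidate)) stop("empty mask at threshold", call. = FALSE)
  # seed: in-box SUVmax voxel (first in array order on ties)
  inbox <- pet$data
  inbox[bmask$data == 0L] <- -Inf
  seed <- arrayInd(which.max(inbox), dim(pet$data))[1, ]
  if (!candidate[seed[1], seed[2], seed[3]]) {
    # SUVmax voxel is always >= T by construction; guard for degenerate input
    stop("in-box SUVmax voxel falls below the threshold", call. = FALSE)
  }
  comp <- connected_component(candidate, seed)
  voi_mask(array(as.integer(comp), dim(pet$data)), pet$spacing, pet$origin,
    provenance = list(
      kind = "isocontour", method = method, threshold = thr,
      suv_peak = peak, background_suv = background_suv, level = level,
      box = box
    )
  )
}

#' Nearest-neighbour mask resampling
#'
#' Transfers a mask to a different grid sharing the same world frame: each
#' target voxel takes the value of the source voxel whose centre is nearest
#' to the target voxel centre (used to derive the low-dose CT VOI from the
#' PET VOI).
#'
#' @param mask A [voi_mask()].
#' @param target_grid List with `spacing` and either `dim` or nothing (the
#'   target dimension then covers the source extent); optional `origin`
#'   (defaults to the source origin).
#' @return A [voi_mask()] on the target grid.
#' @export
resample_mask <- function(mask, target_grid) {
  sp_t <- as.numeric(target_grid$spacing)
  if (length(sp_t) == 1) sp_t <- rep(sp_t, 3)
  if (any(sp_t <= 0)) stop("non-positive target spacing", call. = FALSE)
  org_t <- if (is.null(target_grid$origin)) mask$origin else as.numeric(target_grid$origin)
  d_s <- dim(mask$data)
  d_t <- if (is.null(target_grid$dim)) {
    as.integer(ceiling(d_s * mask$spacing / sp_t))
  } else {
    as.integer(target_grid$dim)
  }
  # world extents must overlap
  lo_s <- mask$origin - mask$spacing / 2
  hi_s <- mask$origin + (d_s - 0.5) * mask$spacing
  lo_t <- org_t - sp_t / 2
  hi_t <- org_t + (d_t - 0.5) * sp_t
  if (any(hi_t < lo_s) || any(lo_t > hi_s)) {
    stop("target grid is disjoint from the mask field of view", call. = FALSE)
  }
  ax <- lapply(1:3, function(a) {
    w <- org_t[a] + (seq_len(d_t[a]) - 1) * sp_t[a]
    # consistent tie-break toward +infinity (round() would alternate on the
    # exact half-way ties of nested 2:1 grids and distort volumes)
    src <- floor((w - mask$origin[a]) / mask$spacing[a] + 0.5) + 1L
    as.integer(pmin(pmax(src, 0L), d_s[a] + 1L)) # 0 / d+1 flag out-of-range
  })
  out <- array(0L, d_t)
  ok1 <- ax[[1]] >= 1L & ax[[1]] <= d_s[1]
  ok2 <- ax[[2]] >= 1L & ax[[2]] <= d_s[2]
  ok3 <- ax[[3]] >= 1L & ax[[3]] <= d_s[3]
  out[ok1, ok2, ok3] <- mask$data[ax[[1]][ok1], ax[[2]][ok2], ax[[3]][ok3]]
  voi_mask(out, sp_t, org_t,
    provenance = c(mask$provenance, list(resampled_from_spacing = mask$spacing))
  )
}

#' Minimum-size check for radiomic analysis
#'
#' Flags whether a VOI meets the minimal size recommendation for radiomic
#' analysis (64 voxels by default).
#'
#' @param mask A [voi_mask()].
#' @param minimum Minimum voxel count (inclusive).
#' @return `TRUE` if the mask has at least `minimum` voxels.
#' @export
check_min_voxels <- function(mask, minimum = 64) {
  mask_voxel_count(mask) >= minimum
}
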