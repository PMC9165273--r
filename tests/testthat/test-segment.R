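make_plateau <- function(value = 10, background = 2, dim = c(16, 16, 16),
                         spacing = 3) {
  arr <- array(background, dim)
  arr[6:11, 6:11, 6:11] <- value
  image_volume(arr, spacing = rep(spacing, 3))
}

test_that("background-corrected threshold follows T = bg + 0.5 (peak - bg)", {
  pet <- make_plateau(10, 2)
  box <- list(lo = c(3L, 3L, 3L), hi = c(14L, 14L, 14L))
  mk <- segment_nodule(pet, box, background_suv = 2)
  expect_equal(mk$provenance$threshold, 6) # 2 + 0.5 * (10 - 2)
  plateau <- pet$data == 10
  expect_equal(mk$data == 1L, plateau)

  mk0 <- segment_nodule(pet, box, background_suv = 0)
  expect_equal(mk0$provenance$threshold, 5) # pure 50% isocontour

  mk_add <- segment_nodule(pet, box, background_suv = 2, method = "additive")
  expect_equal(mk_add$provenance$threshold, 7) # 0.5 * 10 + 2
  expect_error(segment_nodule(pet, box, background_suv = 11), "not above background")
})

test_that("segmented boundary matches the analytic blurred-sphere isocontour", {
  R <- 12
  sigma_mm <- 6 / (2 * sqrt(2 * log(2)))
  sp <- nodule_spec(c(40, 40, 40), c(2 * R, 2 * R, 2 * R), 10, 2,
    texture_amplitude = 0, psf_fwhm_mm = 6
  )
  grid <- list(spacing = 2, dim = c(40, 40, 40))
  ph <- generate_phantom(sp, grid, seed = 1, noise_sd_frac = 0)
  box <- apply_boxing(ph$pet, c(40, 40, 40), rep(2 * R, 3), margin = 1.4)
  mk <- segment_nodule(ph$pet, box, background_suv = 2)
  thr <- mk$provenance$threshold
  # analytic radius where the blurred radial profile crosses the threshold
  r_star <- uniroot(
    function(r) blurred_sphere_profile(r, R, sigma_mm, 8, 2) - thr,
    c(0.1, 2 * R)
  )$root
  idx <- which(mk$data == 1L, arr.ind = TRUE)
  pos <- sweep(sweep(idx - 1, 2, mk$spacing, "*"), 2, mk$origin, "+")
  rr <- sqrt(rowSums(sweep(pos, 2, c(40, 40, 40))^2))
  expect_lt(abs(max(rr) - r_star), max(grid$spacing)) # within one voxel
  # mask must be a filled ball: every in-mask voxel within r_star + 1 voxel
  expect_true(all(rr < r_star + max(grid$spacing)))
})

test_that("mask is one 26-connected component inside the box containing SUVmax", {
  set.seed(9)
  pet <- make_plateau(8, 1.5)
  pet$data <- pet$data + array(rnorm(length(pet$data), sd = 0.1), dim(pet$data))
  # a second hot nodule outside the box must be excluded
  pet$data[14:16, 14:16, 14:16] <- 9
  box <- list(lo = c(3L, 3L, 3L), hi = c(12L, 12L, 12L))
  mk <- segment_nodule(pet, box, background_suv = 1.5)
  bm <- thyropet:::box_mask(pet, box)
  expect_true(all(mk$data <= bm$data))
  expect_equal(sum(mk$data[14:16, 14:16, 14:16]), 0L)
  inbox <- pet$data
  inbox[bm$data == 0L] <- -Inf
  seed_vox <- arrayInd(which.max(inbox), dim(pet$data))
  expect_equal(mk$data[seed_vox], 1L)
  comp <- thyropet:::connected_component(mk$data == 1L, seed_vox[1, ])
  expect_equal(sum(comp), sum(mk$data))
})

test_that("raising the background never enlarges the mask; scaling leaves it fixed", {
  ph <- generate_phantom(
    nodule_spec(c(30, 30, 30), c(20, 20, 20), 10, 2, texture_amplitude = 0.2),
    grid = list(spacing = 3, dim = c(20, 20, 20)), seed = 4
  )
  box <- apply_boxing(ph$pet, c(30, 30, 30), rep(20, 3))
  sizes <- vapply(c(0, 1, 2, 3), function(bg) {
    mask_voxel_count(segment_nodule(ph$pet, box, bg))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))

  mk1 <- segment_nodule(ph$pet, box, 2)
  pet_s <- image_volume(3 * ph$pet$data, ph$pet$spacing)
  mk2 <- segment_nodule(pet_s, box, 6)
  expect_identical(mk1$data, mk2$data)
  expect_equal(mk2$provenance$threshold, 3 * mk1$provenance$threshold)
})

test_that("boxing contains the locator, respects margins and clips at edges", {
  vol <- image_volume(array(0, c(20, 20, 20)), spacing = c(2, 2, 2))
  # margin-0 box equals the stated extent
  b <- apply_boxing(vol, c(20, 20, 20), c(8, 8, 8), margin = 1)
  expect_equal((b$hi - b$lo + 1) * 2, c(10, 10, 10)) # 8 mm extent on 2 mm grid
  set.seed(2)
  for (rep in 1:20) {
    ctr <- runif(3, 5, 33)
    b <- suppressWarnings(apply_boxing(vol, ctr, runif(3, 4, 12)))
    ci <- floor(ctr / 2) + 1
    expect_true(all(b$lo <= ci & ci <= b$hi))
  }
  expect_warning(apply_boxing(vol, c(2, 2, 2), c(10, 10, 10)), "clipped")
  expect_error(apply_boxing(vol, c(100, 100, 100), c(4, 4, 4)), "outside")
})

test_that("nearest-neighbour resampling preserves identity and volume", {
  mk <- make_sphere_mask(4, spacing = c(4, 4, 4))
  # identical grid is the identity
  same <- resample_mask(mk, list(
    spacing = mk$spacing, dim = dim(mk$data),
    origin = mk$origin
  ))
  expect_identical(same$data, mk$data)
  # 4 mm -> 2 mm: volume preserved within one source voxel
  fine <- resample_mask(mk, list(spacing = 2))
  v0 <- mask_voxel_count(mk) * voxel_volume(mk, "ml")
  v1 <- mask_voxel_count(fine) * voxel_volume(fine, "ml")
  expect_lt(abs(v0 - v1), voxel_volume(mk, "ml"))
  expect_error(
    resample_mask(mk, list(spacing = 2, dim = c(4, 4, 4), origin = c(1e5, 0, 0))),
    "disjoint"
  )
})

test_that("downsample-then-upsample keeps Dice >= 0.8 on spheres", {
  # radii of 3, 4, 5 voxels on the coarse 4 mm grid (6, 8, 10 on the fine);
  # pad chosen so the sphere centre is representable on the 4 mm grid
  for (rv in c(6, 8, 10)) {
    mk <- make_sphere_mask(rv, spacing = c(2, 2, 2), pad = 4)
    down <- resample_mask(mk, list(spacing = 4))
    up <- resample_mask(down, list(
      spacing = 2, dim = dim(mk$data),
      origin = mk$origin
    ))
    inter <- sum(mk$data == 1L & up$data == 1L)
    dice <- 2 * inter / (sum(mk$data) + sum(up$data))
    expect_gte(dice, 0.8)
  }
})

test_that("minimum voxel check is boundary inclusive", {
  cube <- voi_mask(array(1L, c(4, 4, 4)), spacing = c(4, 4, 4))
  expect_true(check_min_voxels(cube)) # 64 voxels
  arr <- array(1L, c(4, 4, 4))
  arr[1, 1, 1] <- 0L
  expect_false(check_min_voxels(voi_mask(arr, spacing = c(4, 4, 4)))) # 63
  # cohort flagging equals a brute-force recount
  set.seed(5)
  masks <- lapply(1:10, function(s) random_mask(c(6, 6, 6), c(4, 4, 4), seed = s, p = 0.35))
  flags <- vapply(masks, check_min_voxels, logical(1))
  recount <- vapply(masks, function(m) sum(m$data) >= 64, logical(1))
  expect_identical(flags, recount)
})
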