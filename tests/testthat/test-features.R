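test_that("trilinear interpolation is exact for constants and linear ramps", {
  # constant
  v <- image_volume(array(3.3, c(7, 7, 7)), spacing = c(3, 3, 3))
  vi <- interpolate_volume(v, 2)
  expect_true(all(abs(vi$data - 3.3) < 1e-12))
  # already at target spacing: unchanged
  v4 <- image_volume(array(runif(5^3), c(5, 5, 5)), spacing = c(4, 4, 4))
  expect_equal(interpolate_volume(v4, 4)$data, v4$data)
  # linear ramp reproduced exactly inside the volume
  d <- c(9, 9, 9)
  ax <- function(a) (seq_len(d[a]) - 1) * 3
  ramp <- outer(outer(2 * ax(1), 0.5 * ax(2), `+`), -1 * ax(3), `+`) + 7
  vr <- image_volume(ramp, spacing = c(3, 3, 3))
  vi <- interpolate_volume(vr, 2)
  w <- thyropet::voxel_world(vi)
  expected <- 2 * w[, 1] + 0.5 * w[, 2] - w[, 3] + 7
  inside <- w[, 1] <= 24 & w[, 2] <= 24 & w[, 3] <= 24
  expect_equal(as.vector(vi$data)[inside], expected[inside], tolerance = 1e-10)
  vbad <- image_volume(array(c(NA, rep(1, 7)), c(2, 2, 2)), spacing = 1)
  expect_error(interpolate_volume(vbad, 1), "non-finite")
})

test_that("fixed-bin discretisation follows the floor rule", {
  arr <- array(0, c(3, 1, 1))
  arr[, 1, 1] <- c(0.2, 0.7, 1.2)
  v <- image_volume(arr, spacing = c(4, 4, 4))
  m <- voi_mask(array(1L, c(3, 1, 1)), spacing = c(4, 4, 4))
  dc <- discretise(v, m, 0.5)
  expect_equal(as.vector(dc$levels), c(1L, 2L, 3L))
  expect_equal(dc$n_levels, 3L)
  # constant region: one level, with a warning
  vc <- image_volume(array(2, c(3, 3, 3)), spacing = 4)
  mc <- voi_mask(array(1L, c(3, 3, 3)), spacing = 4)
  expect_warning(dcc <- discretise(vc, mc, 0.5), "single grey level")
  expect_equal(dcc$n_levels, 1L)
  # random values: level histogram equals direct binning
  set.seed(31)
  vr <- random_volume(c(5, 5, 5), c(4, 4, 4), seed = 31)
  mr <- random_mask(c(5, 5, 5), c(4, 4, 4), seed = 32)
  dr <- discretise(vr, mr, 0.7)
  x <- vr$data[mr$data == 1L]
  expect_equal(
    tabulate(dr$levels[mr$data == 1L], dr$n_levels),
    tabulate(floor((x - min(x)) / 0.7) + 1, dr$n_levels)
  )
})

test_that("the feature set matches the frozen manifest (107 per modality)", {
  man <- feature_manifest()
  expect_equal(nrow(man), 107)
  expect_equal(
    as.integer(table(man$family)[c(
      "shape", "firstorder", "glcm", "glrlm", "glszm", "gldm", "ngtdm"
    )]),
    c(14, 18, 24, 16, 16, 14, 5)
  )
  expect_false(any(duplicated(paste(man$family, man$feature))))

  ph <- generate_phantom(
    nodule_spec(c(24, 24, 24), c(16, 16, 16), 10, 2),
    grid = list(spacing = 3, dim = c(16, 16, 16)), seed = 2
  )
  ft <- extract_features(ph$pet, ph$truth_mask, bin_width = 0.5, modality = "PET")
  expect_equal(nrow(ft), 107)
  expect_equal(ft$feature, man$feature)
  # shape features ignore intensities entirely
  ft2 <- extract_features(
    image_volume(ph$pet$data^2 + 1, ph$pet$spacing),
    ph$truth_mask,
    bin_width = 0.5, modality = "PET"
  )
  expect_equal(
    ft$value[ft$family == "shape"],
    ft2$value[ft2$family == "shape"]
  )
})

test_that("homogeneity limits: constant VOI degenerates as specified", {
  vc <- image_volume(array(5, c(6, 6, 6)), spacing = 4)
  mc <- voi_mask(array(1L, c(6, 6, 6)), spacing = 4)
  suppressWarnings(
    ft <- extract_features(vc, mc, bin_width = 0.5, modality = "PET")
  )
  val <- function(fam, feat) ft$value[ft$family == fam & ft$feature == feat]
  expect_equal(val("firstorder", "Variance"), 0)
  expect_equal(val("glcm", "Contrast"), 0)
  expect_equal(val("glcm", "Correlation"), 1)
  expect_equal(val("ngtdm", "Coarseness"), 1e6) # degenerate convention value
  expect_equal(val("firstorder", "Uniformity"), 1)
})

test_that("single-voxel masks keep shape defined and texture undefined", {
  v <- image_volume(array(1:27 / 3, c(3, 3, 3)), spacing = 2)
  arr <- array(0L, c(3, 3, 3))
  arr[2, 2, 2] <- 1L
  m <- voi_mask(arr, spacing = 2)
  expect_warning(ft <- extract_features(v, m, bin_width = 0.5, modality = "PET"), "single-voxel")
  expect_true(all(is.finite(ft$value[ft$family == "shape"][1:5])))
  expect_true(all(is.na(ft$value[ft$family == "glcm"])))
})

test_that("GLCM matrices equal explicit pair enumeration", {
  set.seed(41)
  for (rep in 1:6) {
    lev <- array(sample(1:4, 4 * 4 * 2, replace = TRUE), c(4, 4, 2))
    lev[sample(length(lev), 6)] <- NA # ragged VOI
    dirs <- thyropet:::directions13()
    for (t in c(1, 5, 9, 13)) {
      expect_equal(
        thyropet:::glcm_matrix(lev, dirs[t, ], 4),
        brute_glcm(lev, dirs[t, ], 4),
        tolerance = 1e-12
      )
    }
  }
})

test_that("GLRLM and GLSZM matrices equal brute-force runs and zones", {
  set.seed(43)
  for (rep in 1:4) {
    lev <- array(sample(1:3, 4 * 4 * 2, replace = TRUE), c(4, 4, 2))
    lev[sample(length(lev), 5)] <- NA
    dirs <- thyropet:::directions13()
    for (t in c(2, 7, 12)) {
      a <- thyropet:::glrlm_matrix(lev, dirs[t, ], 3)
      b <- brute_glrlm(lev, dirs[t, ], 3)
      expect_equal(a[, seq_len(ncol(b)), drop = FALSE], b, ignore_attr = TRUE)
    }
    a <- thyropet:::glszm_matrix(lev, 3)
    b <- brute_glszm(lev, 3)
    expect_equal(a[, seq_len(ncol(b)), drop = FALSE], b, ignore_attr = TRUE)
  }
})

test_that("a worked 4x4x1 grid yields the hand-enumerated texture matrices", {
  lev <- array(NA_integer_, c(4, 4, 1))
  lev[, , 1] <- matrix(
    c(
      1, 2, 2, 3,
      1, 2, 3, 3,
      2, 1, 1, 1,
      3, 3, 2, 1
    ),
    nrow = 4, byrow = TRUE
  )
  # GLCM along +columns (offset (0,1,0)): count adjacent horizontal pairs
  cm <- thyropet:::glcm_matrix(lev, c(0L, 1L, 0L), 3) * 24 # 12 pairs, symmetric
  hand <- matrix(0, 3, 3)
  pairs <- rbind(
    c(1, 2), c(2, 2), c(2, 3), c(1, 2), c(2, 3), c(3, 3),
    c(2, 1), c(1, 1), c(1, 1), c(3, 3), c(3, 2), c(2, 1)
  )
  for (r in seq_len(nrow(pairs))) {
    hand[pairs[r, 1], pairs[r, 2]] <- hand[pairs[r, 1], pairs[r, 2]] + 1
    hand[pairs[r, 2], pairs[r, 1]] <- hand[pairs[r, 2], pairs[r, 1]] + 1
  }
  expect_equal(cm, hand, ignore_attr = TRUE)
  # GLRLM along columns: runs per row are (1)(22)(3) / (1)(2)(33) /
  # (2)(111) / (33)(2)(1)
  rl <- thyropet:::glrlm_matrix(lev, c(0L, 1L, 0L), 3)
  hand_rl <- matrix(0, 3, 3)
  hand_rl[1, 1] <- 3 # "1" singles: rows 1, 2, 4
  hand_rl[1, 3] <- 1 # "111"
  hand_rl[2, 1] <- 3 # "2" singles
  hand_rl[2, 2] <- 1 # "22"
  hand_rl[3, 1] <- 1 # "3" single in row 1
  hand_rl[3, 2] <- 2 # "33" twice
  expect_equal(rl[, 1:3], hand_rl, ignore_attr = TRUE)
  # GLSZM with 26-connectivity: level 1 is one diagonal-connected zone of 6
  # ((1,1),(2,1),(3,2),(3,3),(3,4),(4,4)); level 2 splits into
  # {(1,2),(1,3),(2,2),(3,1)} and the isolated (4,3); level 3 into
  # {(1,4),(2,3),(2,4)} and {(4,1),(4,2)}
  sz <- thyropet:::glszm_matrix(lev, 3)
  expect_equal(sum(sz), 5)
  expect_equal(sz[1, 6], 1)
  expect_equal(sz[2, 4], 1)
  expect_equal(sz[2, 1], 1)
  expect_equal(sz[3, 3], 1)
  expect_equal(sz[3, 2], 1)
})

test_that("direction-averaged texture features are invariant to flips and 90-degree rotations", {
  ph <- generate_phantom(
    nodule_spec(c(21, 21, 21), c(16, 16, 16), 10, 2, texture_amplitude = 0.3),
    grid = list(spacing = 3, dim = c(14, 14, 14)), seed = 6
  )
  dc <- discretise(ph$pet, ph$truth_mask, 0.5)
  base <- c(
    thyropet:::glcm_features(dc$levels, dc$n_levels),
    thyropet:::glrlm_features(dc$levels, dc$n_levels),
    thyropet:::glszm_features(dc$levels, dc$n_levels),
    thyropet:::gldm_features(dc$levels, dc$n_levels),
    thyropet:::ngtdm_features(dc$levels, dc$n_levels)
  )
  transforms <- list(
    function(a) a[dim(a)[1]:1, , ], # flip axis 1
    function(a) aperm(a, c(2, 1, 3)), # rotate in-plane
    function(a) aperm(a, c(3, 2, 1)) # swap axes 1/3
  )
  for (tr in transforms) {
    lev_t <- tr(dc$levels)
    got <- c(
      thyropet:::glcm_features(lev_t, dc$n_levels),
      thyropet:::glrlm_features(lev_t, dc$n_levels),
      thyropet:::glszm_features(lev_t, dc$n_levels),
      thyropet:::gldm_features(lev_t, dc$n_levels),
      thyropet:::ngtdm_features(lev_t, dc$n_levels)
    )
    expect_equal(got, base, tolerance = 1e-10)
  }
})

test_that("sphericity approaches 1 for digitised spheres at fine resolution", {
  s_coarse <- shape_features(make_sphere_mask(4, spacing = c(2, 2, 2)))
  s_fine <- shape_features(make_sphere_mask(8, spacing = c(1, 1, 1)))
  # same physical 8 mm radius; finer grid must be closer to the ideal 1
  expect_lt(abs(s_fine[["Sphericity"]] - 1), abs(s_coarse[["Sphericity"]] - 1) + 1e-9)
  expect_lt(abs(s_fine[["Sphericity"]] - 1), 0.02) # within 2% at 1 mm
  expect_equal(s_fine[["Maximum3DDiameter"]], 16, tolerance = 0.1)
})

test_that("TLG equals SUVmean times MTV and is linear in intensity", {
  # uniform 5 g/mL over 2 mL
  arr <- array(0, c(10, 10, 10))
  m <- array(0L, c(10, 10, 10))
  m[1:5, 1:4, 1:4] <- 1L # 80 voxels of 25 mm^3 = 2 mL
  arr[m == 1L] <- 5
  v <- image_volume(arr, spacing = c(5, 2.5, 2))
  vm <- voi_mask(m, spacing = v$spacing)
  expect_equal(voxel_volume(v, "ml") * 80, 2, tolerance = 1e-12)
  expect_equal(compute_tlg(v, vm), 10)
  v2 <- image_volume(2 * arr, v$spacing)
  expect_equal(compute_tlg(v2, vm), 20)
  # algebraic identity on a random phantom
  vr <- random_volume(c(6, 6, 6), c(4, 4, 4), seed = 77)
  mr <- random_mask(c(6, 6, 6), c(4, 4, 4), seed = 78)
  expect_equal(
    compute_tlg(vr, mr),
    sum(vr$data[mr$data == 1L]) * voxel_volume(vr, "ml"),
    tolerance = 1e-12
  )
})

test_that("per-case radiomic table carries 108 PET values plus 107 CT values", {
  ph <- generate_phantom(
    nodule_spec(c(30, 30, 30), c(22, 22, 22), 10, 2),
    grid = list(spacing = 3, dim = c(20, 20, 20)), seed = 8
  )
  ft <- radiomic_features(ph$pet, ph$ct, ph$truth_mask)
  expect_equal(sum(ft$modality == "PET"), 108)
  expect_equal(sum(ft$modality == "CT"), 107)
  expect_true("PET_firstorder_TLG" %in% ft$name)
  expect_false(any(duplicated(ft$name)))
})
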