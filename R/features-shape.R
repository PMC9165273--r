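# Shape features from the VOI mask.
#
# The surface mesh is extracted by marching tetrahedra from an anti-aliased
# indicator: the binary mask is smoothed with a Gaussian of one voxel
# standard deviation and the 0.5 iso-surface is triangulated, with vertices
# linearly interpolated along cell edges. Meshing the smoothed indicator
# (rather than the raw binary mask) removes the voxel staircase, so surface
# area and sphericity converge to their analytic values as the grid is
# refined; meshing a binary mask at iso 0.5 would overestimate the area of a
# sphere by roughly a quarter at any resolution.

# corner offsets of the unit cell, row = corner id 1..8
.cube_corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))[, c(1, 2, 3)]
# six tetrahedra around the diagonal corner1 -> corner8 (ids into .cube_corners)
.cube_tets <- matrix(
  c(
    1, 2, 4, 8,
    1, 4, 3, 8,
    1, 3, 7, 8,
    1, 7, 5, 8,
    1, 5, 6, 8,
    1, 6, 2, 8
  ),
  ncol = 4, byrow = TRUE
)

# triangles (as lists of edges, an edge = c(inside_corner, outside_corner))
# for a sign pattern over the 4 tet vertices
tet_case_edges <- function(pattern) {
  inside <- which(pattern)
  outside <- which(!pattern)
  if (length(inside) == 1) {
    a <- inside
    o <- outside
    list(list(c(a, o[1]), c(a, o[2]), c(a, o[3])))
  } else if (length(inside) == 3) {
    d <- outside
    a <- inside
    list(list(c(a[1], d), c(a[2], d), c(a[3], d)))
  } else if (length(inside) == 2) {
    a <- inside[1]
    b <- inside[2]
    c_ <- outside[1]
    d <- outside[2]
    list(
      list(c(a, c_), c(a, d), c(b, d)),
      list(c(a, c_), c(b, d), c(b, c_))
    )
  } else {
    list()
  }
}

cross3 <- function(a, b) {
  cbind(
    a[, 2] * b[, 3] - a[, 3] * b[, 2],
    a[, 3] * b[, 1] - a[, 1] * b[, 3],
    a[, 1] * b[, 2] - a[, 2] * b[, 1]
  )
}

# Iso-surface (level 0.5) of the smoothed mask indicator.
# Returns area (mm^2), enclosed volume (mm^3) and the mesh vertices.
mask_mesh <- function(mask, smooth_sigma_vox = 1, level = 0.5) {
  m <- mask_mesh_impl(mask, smooth_sigma_vox, level)
  if (m$volume <= 0 && smooth_sigma_vox > 0) {
    # VOI too small to survive smoothing (diameter of order one voxel):
    # mesh the binary indicator directly (vertices at edge midpoints)
    m <- mask_mesh_impl(mask, 0, level)
  }
  m
}

mask_mesh_impl <- function(mask, smooth_sigma_vox = 1, level = 0.5) {
  sp <- mask$spacing
  dm <- dim(mask$data)
  padw <- as.integer(ceiling(4 * smooth_sigma_vox) + 1)
  pad <- array(0, dm + 2L * padw)
  pad[
    padw + seq_len(dm[1]), padw + seq_len(dm[2]),
    padw + seq_len(dm[3])
  ] <- mask$data
  f <- gauss_blur3(pad, rep(smooth_sigma_vox, 3))
  d <- dim(f)
  nc <- d - 1L
  corner_val <- lapply(seq_len(8), function(ci) {
    o <- .cube_corners[ci, ]
    f[
      (1 + o[1]):(nc[1] + o[1]), (1 + o[2]):(nc[2] + o[2]),
      (1 + o[3]):(nc[3] + o[3])
    ]
  })
  inside_any <- Reduce(`+`, lapply(corner_val, function(v) v > level))
  mixed <- which(inside_any > 0L & inside_any < 8L)
  area <- 0
  vol6 <- 0 # six times the signed enclosed volume
  verts <- list()
  if (length(mixed) > 0) {
    cvals <- vapply(corner_val, function(v) v[mixed], numeric(length(mixed)))
    if (length(mixed) == 1) cvals <- matrix(cvals, nrow = 1)
    cell_idx <- arrayInd(mixed, nc)
    # world position of cell corner 1 (padded index -> original index)
    cell_pos <- sweep(
      sweep(cell_idx - padw - 1, 2, sp, "*"), 2, mask$origin, "+"
    )
    corner_pos <- lapply(seq_len(8), function(ci) {
      sweep(cell_pos, 2, .cube_corners[ci, ] * sp, "+")
    })
    for (t in seq_len(nrow(.cube_tets))) {
      tet <- .cube_tets[t, ]
      tv <- cvals[, tet, drop = FALSE] > level
      code <- as.integer(tv %*% c(1L, 2L, 4L, 8L))
      for (cd in setdiff(unique(code), c(0L, 15L))) {
        sel <- which(code == cd)
        pattern <- bitwAnd(cd, c(1L, 2L, 4L, 8L)) > 0
        # outward reference: from mean inside corner to mean outside corner
        ref_in <- Reduce(`+`, lapply(which(pattern), function(v) {
          corner_pos[[tet[v]]][sel, , drop = FALSE]
        })) / sum(pattern)
        ref_out <- Reduce(`+`, lapply(which(!pattern), function(v) {
          corner_pos[[tet[v]]][sel, , drop = FALSE]
        })) / sum(!pattern)
        ref <- ref_out - ref_in
        for (tri in tet_case_edges(pattern)) {
          vs <- lapply(tri, function(edge) {
            a <- tet[edge[1]]
            b <- tet[edge[2]]
            fa <- cvals[sel, a, drop = FALSE]
            fb <- cvals[sel, b, drop = FALSE]
            tt <- as.numeric((level - fa) / (fb - fa))
            pa <- corner_pos[[a]][sel, , drop = FALSE]
            pb <- corner_pos[[b]][sel, , drop = FALSE]
            pa + tt * (pb - pa)
          })
          e1 <- vs[[2]] - vs[[1]]
          e2 <- vs[[3]] - vs[[1]]
          n <- cross3(e1, e2)
          flip <- rowSums(n * ref) < 0
          if (any(flip)) n[flip, ] <- -n[flip, ]
          area <- area + sum(sqrt(rowSums(n^2))) / 2
          v2 <- vs[[2]]
          v3 <- vs[[3]]
          if (any(flip)) {
            tmp <- v2[flip, , drop = FALSE]
            v2[flip, ] <- v3[flip, , drop = FALSE]
            v3[flip, ] <- tmp
          }
          vol6 <- vol6 + sum(rowSums(vs[[1]] * cross3(v2, v3)))
          verts[[length(verts) + 1]] <- do.call(rbind, vs)
        }
      }
    }
  }
  vmat <- if (length(verts)) do.call(rbind, verts) else matrix(numeric(0), 0, 3)
  list(area = area, volume = abs(vol6) / 6, vertices = vmat)
}

max_pairwise_dist <- function(pts) {
  if (nrow(pts) < 2) {
    return(0)
  }
  g <- tcrossprod(pts)
  n2 <- diag(g)
  sqrt(max(0, max(outer(n2, n2, `+`) - 2 * g)))
}

# max pairwise in-plane distance among points sharing the same index along
# `axis`; distance uses the remaining two coordinates
max_2d_diameter <- function(pts, groups, axis) {
  keep <- setdiff(1:3, axis)
  best <- 0
  for (gv in unique(groups)) {
    p <- pts[groups == gv, keep, drop = FALSE]
    if (nrow(p) >= 2) best <- max(best, max_pairwise_dist(p))
  }
  best
}

#' Shape features of a VOI
#'
#' The 14 standardised shape descriptors: mesh volume and surface area from
#' a marching-tetrahedra triangulation of the (anti-aliased) mask indicator,
#' voxel-counting volume, surface-to-volume ratio, sphericity, maximum 3-D
#' and in-plane diameters (computed on boundary voxel centres, grouped by
#' slice/column/row for the in-plane variants), and the principal-axis
#' lengths `4*sqrt(lambda)` of the voxel-coordinate covariance with
#' elongation and flatness.
#'
#' @param mask A [voi_mask()].
#' @return Named numeric vector of 14 features.
#' @export
shape_features <- function(mask) {
  nv <- mask_voxel_count(mask)
  if (nv == 0) stop("mask is empty", call. = FALSE)
  mesh <- mask_mesh(mask)
  voxvol <- voxel_volume(mask)
  idx <- mask_indices(mask)
  pts <- voxel_world(mask, idx)

  # boundary voxels: at least one 6-neighbour outside the mask
  d <- dim(mask$data)
  inm <- mask$data != 0L
  boundary <- rep(FALSE, nrow(idx))
  for (a in 1:3) {
    for (s in c(-1L, 1L)) {
      nb <- idx
      nb[, a] <- nb[, a] + s
      out <- nb[, a] < 1L | nb[, a] > d[a]
      nb[out, a] <- idx[out, a] # placeholder, flagged outside anyway
      boundary <- boundary | out | !inm[nb]
    }
  }
  bpts <- pts[boundary, , drop = FALSE]
  bidx <- idx[boundary, , drop = FALSE]

  cv <- if (nrow(pts) > 1) stats::cov(pts) else matrix(0, 3, 3)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev[ev < 0] <- 0
  axis_len <- 4 * sqrt(ev)

  mv <- mesh$volume
  sa <- mesh$area
  c(
    MeshVolume = mv,
    VoxelVolume = nv * voxvol,
    SurfaceArea = sa,
    SurfaceVolumeRatio = sa / mv,
    Sphericity = (36 * pi * mv^2)^(1 / 3) / sa,
    Maximum3DDiameter = max_pairwise_dist(bpts),
    Maximum2DDiameterSlice = max_2d_diameter(bpts, bidx[, 3], 3),
    Maximum2DDiameterColumn = max_2d_diameter(bpts, bidx[, 2], 2),
    Maximum2DDiameterRow = max_2d_diameter(bpts, bidx[, 1], 1),
    MajorAxisLength = axis_len[1],
    MinorAxisLength = axis_len[2],
    LeastAxisLength = axis_len[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else NA_real_,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else NA_real_
  )
}
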