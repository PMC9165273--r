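# Grey-level texture matrices and their standardised features.
#
# All families operate on the fixed-bin-width discretised level array
# (integer levels 1..Ng, NA outside the VOI). GLCM and GLRLM are computed
# for the 13 unique 3-D directions at distance one voxel (symmetric
# co-occurrence) and the feature value is the mean over directions; GLSZM
# and GLDM use 26-connectivity, NGTDM the 26-neighbourhood.

.eps <- 2.220446e-16

directions13 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  # unique half: lexicographically positive
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

offsets26 <- function() {
  g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  unname(g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE])
}

# sub-array pair views for an offset: returns list(a, b) of level vectors at
# p and p + off over the overlap region
shifted_pairs <- function(lev, off) {
  d <- dim(lev)
  r <- lapply(1:3, function(ax) {
    s <- off[ax]
    list(src = max(1, 1 - s):min(d[ax], d[ax] - s))
  })
  a <- lev[r[[1]]$src, r[[2]]$src, r[[3]]$src, drop = FALSE]
  b <- lev[r[[1]]$src + off[1], r[[2]]$src + off[2], r[[3]]$src + off[3], drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  list(a = a[ok], b = b[ok])
}

## ---------------------------------------------------------------- GLCM ----

glcm_matrix <- function(lev, off, n_levels) {
  pr <- shifted_pairs(lev, off)
  if (length(pr$a) == 0) {
    return(matrix(0, n_levels, n_levels))
  }
  cnt <- tabulate((pr$a - 1L) * n_levels + pr$b, n_levels * n_levels)
  cm <- matrix(cnt, n_levels, n_levels, byrow = TRUE)
  cm <- cm + t(cm) # symmetric co-occurrence
  cm / sum(cm)
}

glcm_features_one <- function(P) {
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  py <- colSums(P) # equals px for symmetric P
  mux <- sum(i * P)
  muy <- sum(j * P)
  sx <- sqrt(sum((i - mux)^2 * P))
  sy <- sqrt(sum((j - muy)^2 * P))
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(P[(i + j) == k]), numeric(1))
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(P[abs(i - j) == k]), numeric(1))
  hxy <- -sum(P * log2(P + .eps))
  hx <- -sum(px * log2(px + .eps))
  hy <- -sum(py * log2(py + .eps))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + .eps))
  hxy2 <- -sum(pxy * log2(pxy + .eps))
  da <- sum(k_diff * p_diff)

  mcc <- {
    keep <- px > 0
    pk <- P[keep, keep, drop = FALSE]
    pxk <- px[keep]
    if (sum(keep) <= 1) {
      1
    } else {
      q <- sweep(pk, 1, pxk, "/") %*% t(sweep(pk, 2, pxk, "/"))
      ev <- sort(Mod(eigen(q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(1, ev[2])))
    }
  }

  c(
    Autocorrelation = sum(i * j * P),
    JointAverage = mux,
    ClusterProminence = sum((i + j - mux - muy)^4 * P),
    ClusterShade = sum((i + j - mux - muy)^3 * P),
    ClusterTendency = sum((i + j - mux - muy)^2 * P),
    Contrast = sum((i - j)^2 * P),
    Correlation = if (sx * sy > 0) (sum(i * j * P) - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_diff * log2(p_diff + .eps)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    Idm = sum(P / (1 + (i - j)^2)),
    Idmn = sum(P / (1 + ((i - j) / ng)^2)),
    Id = sum(P / (1 + abs(i - j))),
    Idn = sum(P / (1 + abs(i - j) / ng)),
    InverseVariance = sum(P[i != j] / (i[i != j] - j[i != j])^2),
    MaximumProbability = max(P),
    SumAverage = sum(k_sum * p_sum),
    SumEntropy = -sum(p_sum * log2(p_sum + .eps)),
    SumSquares = sum((i - mux)^2 * P),
    MCC = mcc
  )
}

glcm_features <- function(lev, n_levels) {
  dirs <- directions13()
  f <- lapply(seq_len(nrow(dirs)), function(t) {
    glcm_features_one(glcm_matrix(lev, dirs[t, ], n_levels))
  })
  Reduce(`+`, f) / length(f)
}

## --------------------------------------------------------------- GLRLM ----

glrlm_matrix <- function(lev, off, n_levels) {
  d <- dim(lev)
  inm <- !is.na(lev)
  idx <- which(inm, arr.ind = TRUE)
  lev_at <- function(p) lev[p[1], p[2], p[3]]
  valid <- function(p) {
    all(p >= 1L) && all(p <= d) && inm[p[1], p[2], p[3]]
  }
  runs_i <- integer(0)
  runs_l <- integer(0)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    prev <- p - off
    is_start <- !(valid(prev) && lev_at(prev) == lev_at(p))
    if (!is_start) next
    len <- 1L
    nxt <- p + off
    while (valid(nxt) && lev_at(nxt) == lev_at(p)) {
      len <- len + 1L
      nxt <- nxt + off
    }
    runs_i <- c(runs_i, lev_at(p))
    runs_l <- c(runs_l, len)
  }
  max_r <- max(runs_l, 1L)
  cnt <- tabulate((runs_i - 1L) * max_r + runs_l, n_levels * max_r)
  matrix(cnt, n_levels, max_r, byrow = TRUE)
}

# Shared feature set for run-length (r = run length), size-zone (r = zone
# size) and dependence (r = dependence size) matrices.
rlm_style_features <- function(P, n_voxels, prefix_map) {
  nr <- sum(P)
  p <- P / nr
  i <- matrix(seq_len(nrow(P)), nrow(P), ncol(P))
  r <- t(matrix(seq_len(ncol(P)), ncol(P), nrow(P)))
  pg <- rowSums(P)
  pr <- colSums(P)
  mu_i <- sum(i * p)
  mu_r <- sum(r * p)
  pp <- p[p > 0]
  vals <- c(
    sre = sum(p / r^2),
    lre = sum(p * r^2),
    gln = sum(pg^2) / nr,
    glnn = sum(pg^2) / nr^2,
    rln = sum(pr^2) / nr,
    rlnn = sum(pr^2) / nr^2,
    rp = nr / n_voxels,
    glv = sum(p * (i - mu_i)^2),
    rv = sum(p * (r - mu_r)^2),
    re = -sum(pp * log2(pp)),
    lgl = sum(p / i^2),
    hgl = sum(p * i^2),
    srlgl = sum(p / (i^2 * r^2)),
    srhgl = sum(p * i^2 / r^2),
    lrlgl = sum(p * r^2 / i^2),
    lrhgl = sum(p * i^2 * r^2)
  )
  out <- vals[names(prefix_map)]
  names(out) <- unname(prefix_map)
  out
}

.glrlm_names <- c(
  sre = "ShortRunEmphasis", lre = "LongRunEmphasis",
  gln = "GrayLevelNonUniformity", glnn = "GrayLevelNonUniformityNormalized",
  rln = "RunLengthNonUniformity", rlnn = "RunLengthNonUniformityNormalized",
  rp = "RunPercentage", glv = "GrayLevelVariance", rv = "RunVariance",
  re = "RunEntropy", lgl = "LowGrayLevelRunEmphasis",
  hgl = "HighGrayLevelRunEmphasis", srlgl = "ShortRunLowGrayLevelEmphasis",
  srhgl = "ShortRunHighGrayLevelEmphasis", lrlgl = "LongRunLowGrayLevelEmphasis",
  lrhgl = "LongRunHighGrayLevelEmphasis"
)

glrlm_features <- function(lev, n_levels) {
  np <- sum(!is.na(lev))
  dirs <- directions13()
  f <- lapply(seq_len(nrow(dirs)), function(t) {
    rlm_style_features(glrlm_matrix(lev, dirs[t, ], n_levels), np, .glrlm_names)
  })
  Reduce(`+`, f) / length(f)
}

## --------------------------------------------------------------- GLSZM ----

# label 26-connected zones of equal grey level; returns matrix P(level, size)
glszm_matrix <- function(lev, n_levels) {
  d <- dim(lev)
  inm <- !is.na(lev)
  seen <- array(FALSE, d)
  offs <- offsets26()
  zones_i <- integer(0)
  zones_s <- integer(0)
  todo <- which(inm)
  for (lin in todo) {
    if (seen[lin]) next
    p0 <- arrayInd(lin, d)[1, ]
    g <- lev[lin]
    stack <- matrix(p0, ncol = 3)
    seen[lin] <- TRUE
    size <- 0L
    while (nrow(stack) > 0) {
      p <- stack[nrow(stack), ]
      stack <- stack[-nrow(stack), , drop = FALSE]
      size <- size + 1L
      for (t in seq_len(nrow(offs))) {
        q <- p + offs[t, ]
        if (any(q < 1L) || any(q > d)) next
        if (seen[q[1], q[2], q[3]]) next
        lq <- lev[q[1], q[2], q[3]]
        if (is.na(lq) || lq != g) next
        seen[q[1], q[2], q[3]] <- TRUE
        stack <- rbind(stack, q)
      }
    }
    zones_i <- c(zones_i, g)
    zones_s <- c(zones_s, size)
  }
  max_s <- max(zones_s, 1L)
  cnt <- tabulate((zones_i - 1L) * max_s + zones_s, n_levels * max_s)
  matrix(cnt, n_levels, max_s, byrow = TRUE)
}

.glszm_names <- c(
  sre = "SmallAreaEmphasis", lre = "LargeAreaEmphasis",
  gln = "GrayLevelNonUniformity", glnn = "GrayLevelNonUniformityNormalized",
  rln = "SizeZoneNonUniformity", rlnn = "SizeZoneNonUniformityNormalized",
  rp = "ZonePercentage", glv = "GrayLevelVariance", rv = "ZoneVariance",
  re = "ZoneEntropy", lgl = "LowGrayLevelZoneEmphasis",
  hgl = "HighGrayLevelZoneEmphasis", srlgl = "SmallAreaLowGrayLevelEmphasis",
  srhgl = "SmallAreaHighGrayLevelEmphasis", lrlgl = "LargeAreaLowGrayLevelEmphasis",
  lrhgl = "LargeAreaHighGrayLevelEmphasis"
)

glszm_features <- function(lev, n_levels) {
  np <- sum(!is.na(lev))
  rlm_style_features(glszm_matrix(lev, n_levels), np, .glszm_names)
}

## ---------------------------------------------------------------- GLDM ----

# dependence size = 1 + number of 26-neighbours with |level difference| <=
# alpha (the centre voxel is dependent on itself)
gldm_matrix <- function(lev, n_levels, alpha = 0) {
  d <- dim(lev)
  dep <- array(0L, d)
  for (t in seq_len(nrow(offsets26()))) {
    off <- offsets26()[t, ]
    r <- lapply(1:3, function(ax) max(1, 1 - off[ax]):min(d[ax], d[ax] - off[ax]))
    a <- lev[r[[1]], r[[2]], r[[3]], drop = FALSE]
    b <- lev[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
    hit <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    sub <- array(0L, dim(a))
    sub[hit] <- 1L
    dep[r[[1]], r[[2]], r[[3]]] <- dep[r[[1]], r[[2]], r[[3]]] + sub
  }
  inm <- !is.na(lev)
  j <- dep[inm] + 1L
  i <- lev[inm]
  max_j <- max(j)
  cnt <- tabulate((i - 1L) * max_j + j, n_levels * max_j)
  matrix(cnt, n_levels, max_j, byrow = TRUE)
}

.gldm_names <- c(
  sre = "SmallDependenceEmphasis", lre = "LargeDependenceEmphasis",
  gln = "GrayLevelNonUniformity", rln = "DependenceNonUniformity",
  rlnn = "DependenceNonUniformityNormalized", glv = "GrayLevelVariance",
  rv = "DependenceVariance", re = "DependenceEntropy",
  lgl = "LowGrayLevelEmphasis", hgl = "HighGrayLevelEmphasis",
  srlgl = "SmallDependenceLowGrayLevelEmphasis",
  srhgl = "SmallDependenceHighGrayLevelEmphasis",
  lrlgl = "LargeDependenceLowGrayLevelEmphasis",
  lrhgl = "LargeDependenceHighGrayLevelEmphasis"
)

gldm_features <- function(lev, n_levels, alpha = 0) {
  np <- sum(!is.na(lev))
  rlm_style_features(gldm_matrix(lev, n_levels, alpha), np, .gldm_names)
}

## --------------------------------------------------------------- NGTDM ----

ngtdm_features <- function(lev, n_levels) {
  d <- dim(lev)
  nb_sum <- array(0, d)
  nb_cnt <- array(0L, d)
  offs <- offsets26()
  for (t in seq_len(nrow(offs))) {
    off <- offs[t, ]
    r <- lapply(1:3, function(ax) max(1, 1 - off[ax]):min(d[ax], d[ax] - off[ax]))
    b <- lev[r[[1]] + off[1], r[[2]] + off[2], r[[3]] + off[3], drop = FALSE]
    ok <- !is.na(b)
    add_s <- array(0, dim(b))
    add_s[ok] <- b[ok]
    add_c <- array(0L, dim(b))
    add_c[ok] <- 1L
    nb_sum[r[[1]], r[[2]], r[[3]]] <- nb_sum[r[[1]], r[[2]], r[[3]]] + add_s
    nb_cnt[r[[1]], r[[2]], r[[3]]] <- nb_cnt[r[[1]], r[[2]], r[[3]]] + add_c
  }
  inm <- !is.na(lev) & nb_cnt > 0L
  gl <- lev[inm]
  abar <- nb_sum[inm] / nb_cnt[inm]
  nvp <- sum(inm)
  n_i <- tabulate(gl, n_levels)
  s_i <- vapply(seq_len(n_levels), function(g) {
    sum(abs(g - abar[gl == g]))
  }, numeric(1))
  p_i <- n_i / nvp
  act <- which(n_i > 0)
  ngp <- length(act)
  iv <- seq_len(n_levels)

  coarse_den <- sum(p_i * s_i)
  coarseness <- if (coarse_den > 0) 1 / coarse_den else 1e6

  contrast <- if (ngp > 1) {
    pij <- outer(p_i[act], p_i[act])
    dij2 <- outer(iv[act], iv[act], `-`)^2
    sum(pij * dij2) / (ngp * (ngp - 1)) * sum(s_i) / nvp
  } else {
    0
  }

  busy_den <- sum(abs(outer(iv[act] * p_i[act], iv[act] * p_i[act], `-`)))
  busyness <- if (busy_den > 0) sum(p_i * s_i) / busy_den else 0

  complexity <- if (ngp > 0) {
    pi_a <- p_i[act]
    si_a <- s_i[act]
    num <- outer(iv[act], iv[act], function(a, b) abs(a - b)) *
      (outer(pi_a * si_a, rep(1, ngp)) + outer(rep(1, ngp), pi_a * si_a)) /
      (outer(pi_a, rep(1, ngp)) + outer(rep(1, ngp), pi_a))
    sum(num) / nvp
  } else {
    0
  }

  strength_den <- sum(s_i)
  strength <- if (strength_den > 0 && ngp > 1) {
    sum((outer(p_i[act], p_i[act], `+`)) * outer(iv[act], iv[act], `-`)^2) /
      strength_den
  } else {
    0
  }

  c(
    Coarseness = coarseness, Contrast = contrast, Busyness = busyness,
    Complexity = complexity, Strength = strength
  )
}
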