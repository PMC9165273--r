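# Fixture builders and independent brute-force oracles. Oracles deliberately
# share no code with the implementation they check.

make_sphere_mask <- function(radius_vox, spacing = c(1, 1, 1), pad = 4) {
  d <- as.integer(2 * ceiling(radius_vox) + 2 * pad + 1)
  ctr <- (d + 1) / 2
  ax <- (1:d) - ctr
  rsq <- outer(outer(ax^2, ax^2, `+`), ax^2, `+`)
  arr <- array(0L, c(d, d, d))
  arr[rsq <= radius_vox^2] <- 1L
  voi_mask(arr, spacing = spacing)
}

random_volume <- function(dim, spacing, seed) {
  set.seed(seed)
  image_volume(array(runif(prod(dim), 0.5, 10), dim), spacing = spacing)
}

random_mask <- function(dim, spacing, seed, p = 0.4) {
  set.seed(seed)
  arr <- array(as.integer(runif(prod(dim)) < p), dim)
  if (!any(arr == 1L)) arr[1] <- 1L
  voi_mask(arr, spacing = spacing)
}

# exhaustive SUVpeak: every voxel centre is a candidate, sphere membership
# recomputed from scratch by pairwise distances
brute_suvpeak <- function(pet, region, sphere_ml = 1) {
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  d <- dim(pet$data)
  all_idx <- as.matrix(expand.grid(seq_len(d[1]), seq_len(d[2]), seq_len(d[3])))
  pos <- sweep(sweep(all_idx - 1, 2, pet$spacing, "*"), 2, pet$origin, "+")
  reg <- which(region$data != 0L)
  best <- -Inf
  for (c_i in seq_len(nrow(all_idx))) {
    d2 <- colSums((t(pos) - pos[c_i, ])^2)
    memb <- d2 <= r^2
    if (!any(memb & seq_len(nrow(all_idx)) %in% reg)) next
    m <- mean(pet$data[all_idx[memb, , drop = FALSE]])
    if (m > best) best <- m
  }
  best
}

# O(n^2) pairwise AUC
brute_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) {
    for (b in neg) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(pos) * length(neg))
}

# symmetric GLCM by explicit pair enumeration
brute_glcm <- function(lev, off, n_levels) {
  d <- dim(lev)
  cm <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        a <- lev[i, j, k]
        if (is.na(a)) next
        q <- c(i, j, k) + off
        if (any(q < 1) || any(q > d)) next
        b <- lev[q[1], q[2], q[3]]
        if (is.na(b)) next
        cm[a, b] <- cm[a, b] + 1
        cm[b, a] <- cm[b, a] + 1
      }
    }
  }
  cm / sum(cm)
}

# run-length counts by walking every maximal run explicitly
brute_glrlm <- function(lev, off, n_levels) {
  d <- dim(lev)
  ok <- function(p) all(p >= 1) && all(p <= d) && !is.na(lev[p[1], p[2], p[3]])
  runs <- list()
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      for (k in seq_len(d[3])) {
        p <- c(i, j, k)
        if (!ok(p)) next
        prev <- p - off
        if (ok(prev) && lev[prev[1], prev[2], prev[3]] == lev[p[1], p[2], p[3]]) next
        len <- 1
        q <- p + off
        while (ok(q) && lev[q[1], q[2], q[3]] == lev[p[1], p[2], p[3]]) {
          len <- len + 1
          q <- q + off
        }
        runs[[length(runs) + 1]] <- c(lev[p[1], p[2], p[3]], len)
      }
    }
  }
  rmax <- max(vapply(runs, `[`, numeric(1), 2))
  m <- matrix(0, n_levels, rmax)
  for (r in runs) m[r[1], r[2]] <- m[r[1], r[2]] + 1
  m
}

# zone sizes via igraph connected components (independent of the package's
# flood fill)
brute_glszm <- function(lev, n_levels) {
  d <- dim(lev)
  vox <- which(!is.na(lev), arr.ind = TRUE)
  n <- nrow(vox)
  key <- function(p) paste(p, collapse = ",")
  id <- stats::setNames(seq_len(n), apply(vox, 1, key))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- integer(0)
  for (v in seq_len(n)) {
    for (t in seq_len(nrow(offs))) {
      q <- vox[v, ] + offs[t, ]
      if (any(q < 1) || any(q > d)) next
      if (is.na(lev[q[1], q[2], q[3]])) next
      if (lev[q[1], q[2], q[3]] != lev[vox[v, 1], vox[v, 2], vox[v, 3]]) next
      w <- id[[key(q)]]
      if (w > v) edges <- c(edges, v, w)
    }
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)
  sizes <- tabulate(comp$membership)
  glev <- vapply(seq_len(comp$no), function(cc) {
    v <- which(comp$membership == cc)[1]
    lev[vox[v, 1], vox[v, 2], vox[v, 3]]
  }, numeric(1))
  m <- matrix(0, n_levels, max(sizes))
  for (cc in seq_len(comp$no)) m[glev[cc], sizes[cc]] <- m[glev[cc], sizes[cc]] + 1
  m
}

# radial profile of a Gaussian-blurred uniform sphere (closed form)
blurred_sphere_profile <- function(r, R, sigma, contrast, background) {
  s2 <- sigma * sqrt(2)
  erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1
  term1 <- (erf((R - r) / s2) + erf((R + r) / s2)) / 2
  term2 <- sigma / (r * sqrt(2 * pi)) *
    (exp(-(R - r)^2 / (2 * sigma^2)) - exp(-(R + r)^2 / (2 * sigma^2)))
  background + contrast * (term1 - term2)
}

make_cohort_from_counts <- function(tp, fp, tn, fn, pos_hi = 10, neg_lo = 1) {
  # labels + test results realising a 2x2 table
  tibble::tibble(
    label = c(
      rep("malignant_or_borderline", tp + fn),
      rep("benign", fp + tn)
    ),
    test_positive = c(rep(TRUE, tp), rep(FALSE, fn), rep(TRUE, fp), rep(FALSE, tn))
  )
}
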