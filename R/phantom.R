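#' Fit a log-normal distribution to a published median and IQR
#'
#' SUV summaries are published as median (Q1--Q3). SUVs are positive and
#' right-skewed, so the simulator draws them from log-normal distributions
#' calibrated to those summaries. A two-parameter log-normal cannot in general
#' reproduce all three quantiles of an asymmetric summary, so the fit matches
#' the median exactly (`mu = log(median)`) and solves numerically for the
#' `sigma` whose interquartile *width* `q3 - q1` equals the published one.
#'
#' @param median,q1,q3 Published median and quartiles, `0 < q1 < median < q3`.
#' @return Named numeric `c(mu, sigma)` of the fitted log-normal.
#' @examples
#' p <- fit_lognormal_from_median_iqr(8.3, 3.6, 16.3)
#' qlnorm(0.5, p["mu"], p["sigma"]) # 8.3
#' @export
fit_lognormal_from_median_iqr <- function(median, q1, q3) {
  if (!(is.finite(median) && is.finite(q1) && is.finite(q3))) {
    stop("quantiles must be finite", call. = FALSE)
  }
  if (!(0 < q1 && q1 < median && median < q3)) {
    stop("need 0 < q1 < median < q3", call. = FALSE)
  }
  mu <- log(median)
  z <- stats::qnorm(0.75)
  width <- function(sigma) {
    stats::qlnorm(0.75, mu, sigma) - stats::qlnorm(0.25, mu, sigma)
  }
  target <- q3 - q1
  # width is strictly increasing in sigma; bracket then root-find
  hi <- 1
  while (width(hi) < target) hi <- hi * 2
  sigma <- stats::uniroot(function(s) width(s) - target,
    lower = 1e-12, upper = hi, tol = 1e-12
  )$root
  # closed form asinh((q3 - q1) / (2 median)) / z agrees; the root-finder is
  # kept as the single code path so the round-trip test is meaningful
  c(mu = mu, sigma = sigma)
}

#' Nodule phantom specification
#'
#' Describes one simulated thyroid nodule: an ellipsoidal region of elevated
#' tracer uptake over the background uptake of normal thyroid tissue,
#' modulated by a band-limited texture field, imaged through a Gaussian
#' point-spread function.
#'
#' @param centre_mm World coordinates (mm) of the ellipsoid centre.
#' @param diameters_mm Ellipsoid axis diameters (mm), all `> 0`.
#' @param peak_suv Pre-blur nodule uptake (g/mL), `> 0`.
#' @param background_suv Background thyroid uptake (g/mL), `> 0`.
#' @param texture_amplitude Relative amplitude (fraction of the nodule
#'   contrast) of the multiplicative texture field, in `[0, 1)`.
#' @param ct_mean_hu Mean nodule attenuation on low-dose CT (HU).
#' @param psf_fwhm_mm Full width at half maximum of the Gaussian PSF (mm);
#'   `0` disables blurring.
#' @return A `nodule_spec` list.
#' @export
nodule_spec <- function(centre_mm, diameters_mm, peak_suv, background_suv,
                        texture_amplitude = 0.15, ct_mean_hu = 45,
                        psf_fwhm_mm = 7) {
  stopifnot(
    length(centre_mm) == 3, length(diameters_mm) == 3,
    all(diameters_mm > 0), peak_suv > 0, background_suv > 0,
    texture_amplitude >= 0, texture_amplitude < 1, psf_fwhm_mm >= 0
  )
  structure(
    list(
      centre_mm = as.numeric(centre_mm), diameters_mm = as.numeric(diameters_mm),
      peak_suv = peak_suv, background_suv = background_suv,
      texture_amplitude = texture_amplitude, ct_mean_hu = ct_mean_hu,
      psf_fwhm_mm = psf_fwhm_mm
    ),
    class = "nodule_spec"
  )
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  )
  set.seed(seed)
  force(code)
}

# Separable Gaussian blur along the three array axes, sigma in voxels.
# Edges are replicated so a constant field stays constant.
gauss_blur3 <- function(arr, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    arr <- conv_axis(arr, k, axis, r)
  }
  arr
}

conv_axis <- function(arr, k, axis, r) {
  d <- dim(arr)
  n <- d[axis]
  out <- array(0, d)
  idx_all <- lapply(d, seq_len)
  for (t in seq_along(k)) {
    off <- t - r - 1L
    src <- pmin(pmax(seq_len(n) + off, 1L), n) # replicate edges
    idx <- idx_all
    idx[[axis]] <- src
    out <- out + k[t] * do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  }
  out
}

#' Generate a PET/CT nodule phantom
#'
#' Builds a PET volume (SUV, g/mL) containing one ellipsoidal nodule over a
#' uniform background, a matching low-dose CT volume (HU), and the ground
#' truth mask (the pre-blur ellipsoid support). The PET nodule contrast is
#' modulated by a band-limited (Gaussian-filtered white noise) texture field,
#' the scene is convolved with a Gaussian PSF, and Gaussian noise is added.
#'
#' @param spec A [nodule_spec()].
#' @param grid List with `spacing` (mm, scalar or length 3) and `dim`
#'   (voxels, length 3); optional `origin` (default 0).
#' @param seed Integer seed; the caller's RNG state is restored afterwards.
#' @param noise_sd_frac PET noise standard deviation as a fraction of the
#'   background SUV (default 0.05).
#' @param texture_corr_mm Correlation length of the texture field (mm).
#' @param ct_background_hu Soft-tissue background for the CT volume.
#' @param ct_noise_sd CT noise standard deviation (HU).
#' @return List with elements `pet`, `ct` ([image_volume()]s) and
#'   `truth_mask` ([voi_mask()]).
#' @examples
#' ph <- generate_phantom(
#'   nodule_spec(c(24, 24, 24), c(16, 16, 16), 10, 2),
#'   grid = list(spacing = 3, dim = c(16, 16, 16)), seed = 1
#' )
#' max(ph$pet$data)
#' @export
generate_phantom <- function(spec, grid, seed = NULL, noise_sd_frac = 0.05,
                             texture_corr_mm = 6, ct_background_hu = 40,
                             ct_noise_sd = 10) {
  stopifnot(inherits(spec, "nodule_spec"))
  spacing <- as.numeric(grid$spacing)
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  if (any(spacing <= 0)) stop("non-positive voxel spacing", call. = FALSE)
  dm <- as.integer(grid$dim)
  origin <- if (is.null(grid$origin)) c(0, 0, 0) else as.numeric(grid$origin)
  extent_lo <- origin - spacing / 2
  extent_hi <- origin + (dm - 0.5) * spacing
  half <- spec$diameters_mm / 2
  if (any(spec$centre_mm - half < extent_lo) || any(spec$centre_mm + half > extent_hi)) {
    stop("nodule extends beyond the image grid", call. = FALSE)
  }

  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dm[a]) - 1) * spacing[a])
  # squared normalised ellipsoid coordinate, evaluated separably
  u1 <- ((ax[[1]] - spec$centre_mm[1]) / half[1])^2
  u2 <- ((ax[[2]] - spec$centre_mm[2]) / half[2])^2
  u3 <- ((ax[[3]] - spec$centre_mm[3]) / half[3])^2
  rsq <- outer(outer(u1, u2, `+`), u3, `+`)
  inside <- rsq <= 1

  with_seed(seed, {
    contrast <- spec$peak_suv - spec$background_suv
    pet_arr <- array(spec$background_suv, dm)
    if (spec$texture_amplitude > 0) {
      field <- gauss_blur3(array(stats::rnorm(prod(dm)), dm), texture_corr_mm / spacing)
      field <- (field - mean(field)) / stats::sd(field)
      tex <- 1 + spec$texture_amplitude * field
    } else {
      tex <- 1
    }
    pet_arr[inside] <- spec$background_suv +
      contrast * (if (is.array(tex)) tex[inside] else tex)
    sig <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
    if (sig > 0) pet_arr <- gauss_blur3(pet_arr, sig / spacing)
    if (noise_sd_frac > 0) {
      pet_arr <- pet_arr + stats::rnorm(prod(dm), sd = noise_sd_frac * spec$background_suv)
    }
    pet_arr[pet_arr < 0] <- 0

    ct_arr <- array(ct_background_hu, dm)
    ct_arr[inside] <- spec$ct_mean_hu
    if (sig > 0) ct_arr <- gauss_blur3(ct_arr, sig / spacing)
    if (ct_noise_sd > 0) ct_arr <- ct_arr + stats::rnorm(prod(dm), sd = ct_noise_sd)

    list(
      pet = image_volume(pet_arr, spacing, origin),
      ct = image_volume(ct_arr, spacing, origin),
      truth_mask = voi_mask(array(as.integer(inside), dm), spacing, origin,
        provenance = list(kind = "phantom truth", spec = unclass(spec))
      )
    )
  })
}

#' SUV calibration tables
#'
#' Published cohort summaries of nodule SUVmax and contralateral background
#' SUVmax, as median (Q1--Q3) per outcome stratum, used to calibrate the
#' cohort simulator. `suv_reference_by_group()` carries separate non-Hurthle
#' and Hurthle cell strata; `suv_reference_pooled()` the all-nodules stratum
#' applied to every cytology group.
#'
#' @return A tibble with columns `cytology_group`, `label`, `suv_max_med`,
#'   `suv_max_q1`, `suv_max_q3`, `bg_med`, `bg_q1`, `bg_q3`.
#' @export
suv_reference_by_group <- function() {
  nh <- list(
    mal = c(5.8, 3.3, 15.2, 1.9, 1.7, 2.4),
    ben = c(3.1, 2.3, 4.7, 2.0, 1.8, 2.5)
  )
  hu <- list(
    mal = c(12.3, 8.0, 28.4, 1.8, 1.6, 2.1),
    ben = c(12.2, 5.0, 35.3, 1.9, 1.6, 2.5)
  )
  rows <- list(
    c(group = "AUS/FLUS", label = "malignant_or_borderline", nh$mal),
    c(group = "AUS/FLUS", label = "benign", nh$ben),
    c(group = "FN/SFN", label = "malignant_or_borderline", nh$mal),
    c(group = "FN/SFN", label = "benign", nh$ben),
    c(group = "HCN/SHCN", label = "malignant_or_borderline", hu$mal),
    c(group = "HCN/SHCN", label = "benign", hu$ben)
  )
  ref <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(
      cytology_group = r[["group"]], label = r[["label"]],
      suv_max_med = as.numeric(r[[3]]), suv_max_q1 = as.numeric(r[[4]]),
      suv_max_q3 = as.numeric(r[[5]]), bg_med = as.numeric(r[[6]]),
      bg_q1 = as.numeric(r[[7]]), bg_q3 = as.numeric(r[[8]])
    )
  })
  ref
}

#' @rdname suv_reference_by_group
#' @export
suv_reference_pooled <- function() {
  ref <- suv_reference_by_group()
  ref[ref$label == "malignant_or_borderline", 3:8] <-
    tibble::tibble(a = 8.3, b = 3.6, c = 16.3, d = 1.8, e = 1.7, f = 2.2)
  ref[ref$label == "benign", 3:8] <-
    tibble::tibble(a = 3.4, b = 2.3, c = 7.3, d = 2.0, e = 1.8, f = 2.5)
  ref
}

#' Cohort simulation configuration
#'
#' Defaults reproduce the structure of the study cohort: 123 cases, cytology
#' mix 55/39/29 (AUS/FLUS, FN/SFN, HCN/SHCN), group-wise malignant/borderline
#' prevalence 24/94 (non-Hurthle) and 9/29 (Hurthle), and SUV distributions
#' calibrated to the published stratum medians/IQRs.
#'
#' @param n_total Number of cases.
#' @param subgroup_fractions Named fractions per cytology group (must sum
#'   to 1).
#' @param prevalence Named malignant/borderline fraction per cytology group,
#'   or a single pooled value.
#' @param suv_reference Calibration table, see [suv_reference_by_group()].
#' @param peak_fraction_shape Beta shape parameters for SUVpeak/SUVmax.
#' @param visual_eps Visual positivity margin: a nodule is visually
#'   FDG-positive when `suv_max / background_suv_max > 1 + visual_eps`.
#' @param allocation `"exact"` (largest-remainder rounding of group and label
#'   counts) or `"sampled"` (multinomial/binomial draws).
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_total = 123,
                          subgroup_fractions = c(
                            "AUS/FLUS" = 55 / 123, "FN/SFN" = 39 / 123,
                            "HCN/SHCN" = 29 / 123
                          ),
                          prevalence = c(
                            "AUS/FLUS" = 24 / 94, "FN/SFN" = 24 / 94,
                            "HCN/SHCN" = 9 / 29
                          ),
                          suv_reference = suv_reference_by_group(),
                          peak_fraction_shape = c(24, 6),
                          visual_eps = 0.1,
                          allocation = c("exact", "sampled"),
                          seed = NULL) {
  allocation <- match.arg(allocation)
  if (abs(sum(subgroup_fractions) - 1) > 1e-8) {
    stop("subgroup fractions must sum to 1", call. = FALSE)
  }
  if (length(prevalence) == 1) {
    prevalence <- stats::setNames(
      rep(prevalence, length(subgroup_fractions)), names(subgroup_fractions)
    )
  }
  if (any(prevalence < 0 | prevalence > 1)) {
    stop("prevalence must lie in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_total = n_total, subgroup_fractions = subgroup_fractions,
      prevalence = prevalence, suv_reference = suv_reference,
      peak_fraction_shape = peak_fraction_shape, visual_eps = visual_eps,
      allocation = allocation, seed = seed
    ),
    class = "cohort_config"
  )
}

# Largest-remainder apportionment of n among fractions; deterministic,
# remainder ties broken by name order.
allocate_counts <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), names(fractions))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

#' Simulate a tabular cohort of indeterminate thyroid nodules
#'
#' Draws, per case, a cytology group, an outcome label, a nodule SUVmax and a
#' contralateral background SUVmax from the calibrated log-normals, an
#' SUVpeak as a Beta-distributed fraction of SUVmax, and applies the visual
#' positivity rule. Group sizes and group-wise malignant counts follow the
#' configured fractions (largest-remainder rounding by default).
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per case: `case_id`, `cytology_group`,
#'   `hurthle`, `label`, `suv_max`, `suv_peak`, `background_suv_max`,
#'   `suv_max_ratio`, `suv_peak_ratio`, `visual_positive`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_total = 50, seed = 1))
#' dplyr::count(cohort, cytology_group, label)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    groups <- names(config$subgroup_fractions)
    if (config$allocation == "exact") {
      n_group <- allocate_counts(config$n_total, config$subgroup_fractions)
    } else {
      draw <- stats::rmultinom(1, config$n_total, config$subgroup_fractions)[, 1]
      n_group <- stats::setNames(as.integer(draw), groups)
    }
    recs <- purrr::map_dfr(groups, function(g) {
      n_g <- n_group[[g]]
      if (n_g == 0) {
        return(NULL)
      }
      p <- config$prevalence[[g]]
      n_mal <- if (config$allocation == "exact") {
        as.integer(round(n_g * p))
      } else {
        stats::rbinom(1, n_g, p)
      }
      lab <- c(
        rep("malignant_or_borderline", n_mal),
        rep("benign", n_g - n_mal)
      )
      tibble::tibble(cytology_group = g, label = lab)
    })
    # permute case order so strata are interleaved, then draw SUVs
    recs <- recs[sample.int(nrow(recs)), ]
    ref <- config$suv_reference
    key <- paste(recs$cytology_group, recs$label)
    ref_key <- paste(ref$cytology_group, ref$label)
    ri <- match(key, ref_key)
    if (anyNA(ri)) stop("suv_reference lacks a (group, label) stratum", call. = FALSE)
    n <- nrow(recs)
    suv_max <- numeric(n)
    bg <- numeric(n)
    for (s in unique(ri)) {
      sel <- ri == s
      pm <- fit_lognormal_from_median_iqr(
        ref$suv_max_med[s], ref$suv_max_q1[s], ref$suv_max_q3[s]
      )
      pb <- fit_lognormal_from_median_iqr(
        ref$bg_med[s], ref$bg_q1[s], ref$bg_q3[s]
      )
      suv_max[sel] <- stats::rlnorm(sum(sel), pm["mu"], pm["sigma"])
      bg[sel] <- stats::rlnorm(sum(sel), pb["mu"], pb["sigma"])
    }
    frac <- stats::rbeta(
      n, config$peak_fraction_shape[1],
      config$peak_fraction_shape[2]
    )
    suv_peak <- suv_max * frac
    tibble::tibble(
      case_id = sprintf("case_%03d", seq_len(n)),
      cytology_group = recs$cytology_group,
      hurthle = recs$cytology_group == "HCN/SHCN",
      label = recs$label,
      suv_max = suv_max,
      suv_peak = suv_peak,
      background_suv_max = bg,
      suv_max_ratio = suv_max / bg,
      suv_peak_ratio = suv_peak / bg,
      visual_positive = suv_max / bg > 1 + config$visual_eps
    )
  })
}
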