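#' Pipeline run configuration
#'
#' Bundles the stage configurations for an end-to-end run. `"tabular"` mode
#' simulates per-case SUV metrics and runs the rule-out threshold analysis;
#' `"imaging"` mode additionally generates PET/ldCT phantoms per case and
#' runs segmentation, radiomic feature extraction and the repeated-split
#' classifier on the visually FDG-positive cases.
#'
#' @param mode `"tabular"` or `"imaging"`.
#' @param cohort A [cohort_config()].
#' @param seed Integer master seed, propagated to every stochastic stage.
#' @param out_dir Output directory (created if missing); `NULL` disables
#'   file output.
#' @param min_sensitivity Sensitivity floor for the threshold analysis.
#' @param rounded_cutoffs Select cut-offs among 1-decimal rounded values.
#' @param k_splits,train_frac,l1_ratio Classifier evaluation settings.
#' @param redundancy_threshold `|r|` threshold of the redundancy filter.
#' @param pet_grid,ct_grid Phantom grids (`spacing`, `dim`) for imaging mode.
#' @param boxing_margin Margin factor for [apply_boxing()].
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("tabular", "imaging"),
                       cohort = cohort_config(),
                       seed = 1L,
                       out_dir = NULL,
                       min_sensitivity = 0.95,
                       rounded_cutoffs = FALSE,
                       k_splits = 20, train_frac = 0.8, l1_ratio = 0.5,
                       redundancy_threshold = 0.9,
                       pet_grid = list(spacing = 3.18, dim = c(40, 40, 40)),
                       ct_grid = list(spacing = 1, dim = c(127, 127, 127)),
                       boxing_margin = 1.5) {
  mode <- match.arg(mode)
  structure(
    list(
      mode = mode, cohort = cohort, seed = as.integer(seed),
      out_dir = out_dir, min_sensitivity = min_sensitivity,
      rounded_cutoffs = rounded_cutoffs, k_splits = k_splits,
      train_frac = train_frac, l1_ratio = l1_ratio,
      redundancy_threshold = redundancy_threshold,
      pet_grid = pet_grid, ct_grid = ct_grid, boxing_margin = boxing_margin
    ),
    class = "run_config"
  )
}

#' Generate phantom images and quantify one cohort record
#'
#' Builds the PET/ldCT phantom for one simulated case, applies boxing around
#' the known locator, segments the nodule with the background-corrected
#' isocontour and returns the images, masks and measured SUV report.
#'
#' @param record One-row cohort tibble (from [generate_cohort()]).
#' @param config A [run_config()].
#' @param case_seed Integer seed for this case's phantom.
#' @return List: `phantom`, `box`, `mask`, `suv` (tibble row), `n_voxels`.
#' @export
quantify_case <- function(record, config, case_seed) {
  g <- config$pet_grid
  sp <- rep(as.numeric(g$spacing), length.out = 3)
  fov <- g$dim * sp
  centre <- fov / 2 + c(fov[1] / 6, 0, 0) # lateralised nodule, one lobe
  size <- min(record$nodule_size_mm, fov[1] / 3)
  spec <- nodule_spec(
    centre_mm = centre, diameters_mm = rep(size, 3),
    peak_suv = record$suv_max, background_suv = record$background_suv_max,
    texture_amplitude = record$texture_amplitude %||% 0.15
  )
  ph <- generate_phantom(spec, g, seed = case_seed)
  box <- apply_boxing(ph$pet, centre, rep(size, 3), margin = config$boxing_margin)
  bg_mask <- mirror_background_mask(ph$pet, box)
  bg <- compute_background(ph$pet, bg_mask)
  mask <- segment_nodule(ph$pet, box, bg)
  nodule_box <- box_mask(ph$pet, box)
  suv <- suv_report(ph$pet, mask, bg_mask)
  list(
    phantom = ph, box = box, mask = mask, suv = suv,
    n_voxels = mask_voxel_count(mask)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes simulate -> (quantify -> segment -> features) -> reduce/train ->
#' report under a single configuration and seed, returning a manifest of all
#' stage outputs. Tabular outputs are written as CSV/JSON when `out_dir` is
#' set.
#'
#' @param config A [run_config()].
#' @return List: `cohort`, `threshold_analysis`, `evaluation` (imaging mode),
#'   `features` (imaging mode), `manifest`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  config$cohort$seed <- config$seed
  cohort <- generate_cohort(config$cohort)
  warnings_log <- character(0)

  features_tbl <- NULL
  evaluation <- NULL
  if (config$mode == "imaging") {
    cohort$nodule_size_mm <- with_seed(config$seed + 1L, {
      p <- fit_lognormal_from_median_iqr(35, 22, 44) # ultrasound size, mm
      stats::rlnorm(nrow(cohort), p["mu"], p["sigma"])
    })
    cohort$texture_amplitude <- 0.15
    pos <- which(cohort$visual_positive)
    rows <- vector("list", length(pos))
    for (ii in seq_along(pos)) {
      rec <- cohort[pos[ii], ]
      q <- tryCatch(
        quantify_case(rec, config, case_seed = config$seed + 1000L + ii),
        error = function(e) e
      )
      if (inherits(q, "error")) {
        # a nodule indistinguishable from background on the image is,
        # by definition, visually FDG-negative: reclassify and skip
        cohort$visual_positive[pos[ii]] <- FALSE
        warnings_log <- c(warnings_log, sprintf(
          "%s: excluded from radiomics (%s)", rec$case_id, conditionMessage(q)
        ))
        next
      }
      # measured (image-derived) SUV metrics replace the generative ones
      cohort[pos[ii], names(q$suv)] <- q$suv
      if (q$n_voxels < 64) {
        warnings_log <- c(warnings_log, sprintf(
          "%s: VOI below 64 voxels (%d)", rec$case_id, q$n_voxels
        ))
      }
      ft <- radiomic_features(q$phantom$pet, q$phantom$ct, q$mask)
      ft$case_id <- rec$case_id
      rows[[ii]] <- ft
    }
    features_tbl <- dplyr::bind_rows(rows)
    wide <- tidyr::pivot_wider(
      features_tbl[, c("case_id", "name", "value")],
      names_from = "name", values_from = "value"
    )
    lab <- cohort$label[match(wide$case_id, cohort$case_id)]
    xmat <- as.matrix(wide[, -1])
    keep <- apply(xmat, 2, function(v) all(is.finite(v)))
    evaluation <- repeated_split_eval(
      xmat[, keep, drop = FALSE], lab,
      k = config$k_splits, train_frac = config$train_frac,
      seed = config$seed + 2L,
      fit_fun = default_split_fitter(
        threshold = config$redundancy_threshold,
        l1_ratio = config$l1_ratio
      )
    )
  }

  thr <- stratified_analysis(
    cohort,
    min_sensitivity = config$min_sensitivity,
    rounded = config$rounded_cutoffs
  )

  manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    mode = config$mode,
    n_cases = nrow(cohort),
    timestamp = format(t0),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    warnings = warnings_log
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cohort,
      file.path(config$out_dir, "cohort.csv"),
      row.names = FALSE
    )
    utils::write.csv(thr$tables,
      file.path(config$out_dir, "threshold_analysis.csv"),
      row.names = FALSE
    )
    if (!is.null(features_tbl)) {
      utils::write.csv(features_tbl,
        file.path(config$out_dir, "features.csv"),
        row.names = FALSE
      )
    }
    if (!is.null(evaluation)) {
      jsonlite::write_json(
        glance(evaluation),
        file.path(config$out_dir, "split_evaluation.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA
    )
  }

  list(
    cohort = cohort, threshold_analysis = thr,
    evaluation = evaluation, features = features_tbl, manifest = manifest
  )
}
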