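#' Digital phantom specification
#'
#' Describes a synthetic, geometrically simple (slab/block) brain phantom
#' emulating the sparse T1-mapping protocol: a precontrast T1 volume, a
#' 90-volume dynamic blood series at 1.86-s spacing with the bolus peak
#' near the 30th volume, postcontrast T1 volumes at the scheme times, and
#' disjoint WM/GM/SSS masks with known ground truth.
#'
#' Baseline T1 defaults (WM 1.2 s, GM 2.0 s, blood 2.4 s) are plausible
#' 7 T values; only the T1 *change* carries pharmacokinetic information,
#' so they set realism, not correctness. The default T1-map noise of
#' 0.012 s is calibrated so that the WM concentration-domain noise is
#' about 2.0e-3 mM (sigma_C = sigma_T1 / (r1 T1^2)).
#'
#' @param grid Voxel counts per axis (default 32x32x32).
#' @param voxel_size Voxel size (mm), default 1.2 mm isotropic.
#' @param tissues Named list of [tissue_params()] for `WM` and `GM`.
#' @param baseline_t1 Named numeric: precontrast T1 (s) for `WM`, `GM`,
#'   `SSS`.
#' @param vif A [vif_model()] for the plasma curve.
#' @param scheme A [make_scheme()] scheme for the postcontrast maps.
#' @param consts A [relaxation_constants()].
#' @param map_noise_sd Additive Gaussian T1-domain noise on the
#'   postcontrast maps (s).
#' @param dynamic_noise_sd Additive Gaussian noise on the dynamic blood
#'   series (mM).
#' @param n_dynamic Number of dynamic volumes (default 90).
#' @param dynamic_spacing Dynamic volume spacing (s), default 1.86.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(32, 32, 32), voxel_size = c(1.2, 1.2, 1.2),
                         tissues = list(WM = reference_tissue("WM"),
                                        GM = reference_tissue("GM")),
                         baseline_t1 = c(WM = 1.2, GM = 2.0, SSS = 2.4),
                         vif = vif_model(),
                         scheme = make_scheme(4.333, 25, 0),
                         consts = relaxation_constants(),
                         map_noise_sd = 0.012, dynamic_noise_sd = 0.02,
                         n_dynamic = 90L, dynamic_spacing = 1.86,
                         seed = 42L) {
  stopifnot(length(grid) == 3, all(grid >= 4),
            inherits(vif, "vif_model"), inherits(scheme, "sampling_scheme"),
            inherits(consts, "relaxation_constants"))
  if (!all(c("WM", "GM") %in% names(tissues))) {
    stop("`tissues` must include WM and GM.", call. = FALSE)
  }
  if (!all(c("WM", "GM", "SSS") %in% names(baseline_t1)) ||
      any(baseline_t1 <= 0)) {
    stop("`baseline_t1` must give positive T1 for WM, GM and SSS.",
         call. = FALSE)
  }
  if (map_noise_sd < 0 || dynamic_noise_sd < 0) {
    stop("noise SDs must be non-negative.", call. = FALSE)
  }
  structure(
    list(grid = as.integer(grid), voxel_size = voxel_size, tissues = tissues,
         baseline_t1 = baseline_t1, vif = vif, scheme = scheme,
         consts = consts, map_noise_sd = map_noise_sd,
         dynamic_noise_sd = dynamic_noise_sd, n_dynamic = as.integer(n_dynamic),
         dynamic_spacing = dynamic_spacing, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# slab geometry: WM in the lower-x third, GM in the middle, a small SSS
# block in the upper third, the rest background
phantom_masks <- function(grid) {
  nx <- grid[1]
  third <- floor(nx / 3)
  wm <- array(FALSE, grid); wm[seq_len(third), , ] <- TRUE
  gm <- array(FALSE, grid); gm[(third + 1):(2 * third), , ] <- TRUE
  cy <- seq(max(1, floor(grid[2] / 2) - 1), min(grid[2], floor(grid[2] / 2) + 2))
  cz <- seq(max(1, floor(grid[3] / 2) - 1), min(grid[3], floor(grid[3] / 2) + 2))
  sss <- array(FALSE, grid)
  sss[(2 * third + 1):min(nx, 2 * third + 4), cy, cz] <- TRUE
  list(WM = wm, GM = gm, SSS = sss)
}

#' Generate a phantom dataset
#'
#' Forward-simulates the acquisition: per tissue voxel the extended Tofts
#' concentration at each scheme time, converted to a postcontrast T1 by
#' inverting the linear relaxation relation
#' (\eqn{1/T_{1,post} = 1/T_{1,pre} + r_1 C}); vessel (SSS) voxels carry
#' whole-blood concentration \eqn{C_b = C_p (1 - Hct)}; the dynamic
#' series samples the blood curve at every volume time. Gaussian noise is
#' added in the T1 domain for the postcontrast maps and in the
#' concentration domain for the dynamic series, all under one seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom_dataset`: `pre_t1`, `post_t1`
#'   (list of [volume_image()]s with time stamps), `masks` (WM/GM/SSS),
#'   `dynamic_blood` (4D array, mM), `dynamic_times` (min), `truth`
#'   (tibble of per-class generating parameters and noiseless Patlak
#'   values), and the `spec`.
#' @examples
#' ph <- make_phantom(phantom_spec(grid = c(8, 8, 8)))
#' ph$truth
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  masks <- phantom_masks(spec$grid)
  overlap <- masks$WM & masks$GM | masks$WM & masks$SSS | masks$GM & masks$SSS
  if (any(overlap)) stop("tissue masks overlap.", call. = FALSE)

  times <- spec$scheme$times
  cp <- vif_eval(spec$vif, times)
  cb <- cp * (1 - spec$consts$hct)

  class_conc <- lapply(spec$tissues, function(tp) {
    extended_tofts(spec$vif, tp, times)$conc
  })

  truth <- purrr::imap_dfr(spec$tissues, function(tp, class) {
    nb <- noiseless_bias(tp, spec$scheme, spec$vif)
    tibble::tibble(
      class = class, ktrans = tp$ktrans, vp = tp$vp, ve = tp$ve,
      baseline_t1 = unname(spec$baseline_t1[class]),
      patlak_ki = nb$ki, patlak_vp = nb$vp, pct_diff = nb$pct_diff
    )
  })

  withr::with_seed(spec$seed, {
    pre <- array(1.0, spec$grid)  # background T1 (s), arbitrary positive
    pre[masks$WM] <- spec$baseline_t1[["WM"]]
    pre[masks$GM] <- spec$baseline_t1[["GM"]]
    pre[masks$SSS] <- spec$baseline_t1[["SSS"]]

    post <- lapply(seq_along(times), function(j) {
      conc <- array(0, spec$grid)
      conc[masks$WM] <- class_conc$WM[j]
      conc[masks$GM] <- class_conc$GM[j]
      conc[masks$SSS] <- cb[j]
      t1 <- concentration_to_t1(pre, conc, spec$consts)
      if (spec$map_noise_sd > 0) {
        t1 <- t1 + array(stats::rnorm(prod(spec$grid), sd = spec$map_noise_sd),
                         spec$grid)
      }
      volume_image(t1, voxel_size = spec$voxel_size, units = "s",
                   timestamp = times[j])
    })

    dyn_times <- (seq_len(spec$n_dynamic) - 1) * spec$dynamic_spacing / 60
    cb_dyn <- vif_eval(spec$vif, dyn_times) * (1 - spec$consts$hct)
    tissue_dyn <- lapply(spec$tissues, function(tp) {
      ts_pos <- dyn_times[dyn_times > 0]
      out <- numeric(length(dyn_times))
      out[dyn_times > 0] <- extended_tofts(spec$vif, tp, ts_pos)$conc
      out
    })
    dynamic <- array(0, c(spec$grid, spec$n_dynamic))
    for (j in seq_len(spec$n_dynamic)) {
      vol <- array(0, spec$grid)
      vol[masks$WM] <- tissue_dyn$WM[j]
      vol[masks$GM] <- tissue_dyn$GM[j]
      vol[masks$SSS] <- cb_dyn[j]
      dynamic[, , , j] <- vol
    }
    if (spec$dynamic_noise_sd > 0) {
      dynamic <- dynamic + array(
        stats::rnorm(length(dynamic), sd = spec$dynamic_noise_sd), dim(dynamic))
    }
  })

  structure(
    list(
      pre_t1 = volume_image(pre, voxel_size = spec$voxel_size, units = "s"),
      post_t1 = post,
      masks = lapply(masks, function(m) {
        volume_image(m, voxel_size = spec$voxel_size, units = "")
      }),
      dynamic_blood = dynamic, dynamic_times = dyn_times,
      truth = truth, spec = spec
    ),
    class = "phantom_dataset"
  )
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %s grid, %d postcontrast maps at %s min, %d dynamic volumes, seed %d\n",
    paste(x$spec$grid, collapse = "x"), length(x$post_t1),
    paste(format(x$spec$scheme$times, digits = 4), collapse = ", "),
    x$spec$n_dynamic, x$spec$seed))
  invisible(x)
}

#' Run the quantification pipeline on a phantom
#'
#' Extracts the blood curve from the phantom's SSS voxels (dynamic series
#' plus the two map-derived vessel points), fits the plasma model, and
#' computes the voxelwise leakage-rate and plasma-volume maps.
#'
#' @param dataset A [make_phantom()] result.
#' @param trim Central fraction for ROI summaries. Default 0.95.
#' @return A list: `plasma` model, `ki`/`vp` maps, and `roi` (tibble of
#'   trimmed per-class summaries for both maps).
#' @export
quantify_phantom <- function(dataset, trim = 0.95) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  consts <- dataset$spec$consts
  dyn_curve <- extract_blood_curve(dataset$dynamic_blood, dataset$masks$SSS,
                                   times = dataset$dynamic_times)
  sss_idx <- mask_indices(dataset$masks$SSS)
  pre_sss <- mean(as.numeric(dataset$pre_t1)[sss_idx])
  map_points <- purrr::map_dfr(dataset$post_t1, function(p) {
    t1_sss <- mean(as.numeric(p)[sss_idx])
    tibble::tibble(
      time = attr(p, "timestamp"),
      conc = t1_to_concentration(pre_sss, t1_sss, consts)
    )
  })
  plasma <- fit_plasma_model(dyn_curve, map_points, consts)
  brain <- array(as.logical(dataset$masks$WM) | as.logical(dataset$masks$GM),
                 dim(dataset$pre_t1))
  maps <- voxelwise_patlak(dataset$pre_t1, dataset$post_t1, plasma,
                           consts = consts, mask = brain)
  roi <- purrr::map_dfr(c("WM", "GM"), function(class) {
    dplyr::bind_rows(
      dplyr::mutate(roi_summary(maps$ki, dataset$masks[[class]], trim),
                    class = class, map = "ki", .before = 1),
      dplyr::mutate(roi_summary(maps$vp, dataset$masks[[class]], trim),
                    class = class, map = "vp", .before = 1)
    )
  })
  list(plasma = plasma, ki = maps$ki, vp = maps$vp, roi = roi)
}

#' Ground-truth recovery report
#'
#' Compares pipeline outputs against the phantom's stored truth, per
#' tissue class. Relative error is computed against the noiseless Patlak
#' value (which absorbs the known backflux bias), not against the
#' generating `ktrans`.
#'
#' @param dataset A [make_phantom()] result.
#' @param quantified Output of [quantify_phantom()] on the same dataset
#'   (computed if omitted).
#' @return A tibble with one row per class and map: true value, noiseless
#'   Patlak value, recovered (trimmed) mean, and relative error.
#' @export
recovery_report <- function(dataset, quantified = quantify_phantom(dataset)) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  roi <- quantified$roi
  if (!all(c("WM", "GM") %in% roi$class)) {
    stop("ROI summaries missing a tissue class.", call. = FALSE)
  }
  truth_long <- dataset$truth |>
    dplyr::transmute(
      class = .data$class,
      ki_true = .data$ktrans, ki_ref = .data$patlak_ki,
      vp_true = .data$vp, vp_ref = .data$patlak_vp
    ) |>
    tidyr::pivot_longer(-"class", names_to = c("map", "kind"),
                        names_sep = "_", values_to = "value") |>
    tidyr::pivot_wider(names_from = "kind", values_from = "value")
  roi |>
    dplyr::select("class", "map", recovered_mean = "mean",
                  recovered_sd = "sd", "n_kept") |>
    dplyr::inner_join(truth_long, by = c("class", "map")) |>
    dplyr::mutate(
      rel_error = (.data$recovered_mean - .data$ref) / .data$ref
    ) |>
    dplyr::select("class", "map", true = "true", noiseless_patlak = "ref",
                  "recovered_mean", "recovered_sd", "n_kept", "rel_error")
}

#' Write a phantom dataset to disk
#'
#' NIfTI volumes (pre/post T1 maps, masks, 4D dynamic series) plus a
#' `truth.json` sidecar recording all generating parameters, the seed and
#' the per-class noiseless Patlak values.
#'
#' @param dataset A [make_phantom()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_phantom <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_volume(dataset$pre_t1, file.path(out_dir, "pre_t1.nii.gz"))
  for (j in seq_along(dataset$post_t1)) {
    write_volume(dataset$post_t1[[j]],
                 file.path(out_dir, sprintf("post_t1_%d.nii.gz", j)))
  }
  for (nm in names(dataset$masks)) {
    write_volume(dataset$masks[[nm]],
                 file.path(out_dir, sprintf("mask_%s.nii.gz", tolower(nm))))
  }
  dyn <- dataset$dynamic_blood
  attr(dyn, "voxel_size") <- dataset$spec$voxel_size
  write_volume(dyn, file.path(out_dir, "dyn.nii.gz"),
               voxel_size = dataset$spec$voxel_size)
  spec <- dataset$spec
  truth <- list(
    seed = spec$seed,
    grid = spec$grid,
    voxel_size = spec$voxel_size,
    scheme_times_min = spec$scheme$times,
    dynamic_times_min = dataset$dynamic_times,
    constants = list(r1 = spec$consts$r1, hct = spec$consts$hct),
    vif = spec$vif[c("t0", "t_peak", "a_peak", "m", "shape")],
    baseline_t1_s = as.list(spec$baseline_t1),
    map_noise_sd_s = spec$map_noise_sd,
    dynamic_noise_sd_mM = spec$dynamic_noise_sd,
    classes = dataset$truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
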