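#' Voxelwise Patlak leakage-rate and plasma-volume maps
#'
#' For every voxel in the mask: converts each postcontrast T1 map to a
#' contrast-agent concentration against the precontrast map, forms Patlak
#' coordinates against the plasma model evaluated analytically at the map
#' time stamps, and fits the Patlak line. The per-voxel math is identical
#' to [patlak_fit()]; the voxel loop is a single matrix product. Voxels
#' with non-positive T1 anywhere are set to `NA` and excluded.
#'
#' @param pre_t1 Precontrast T1 [volume_image()] (s).
#' @param post_t1_maps List of >= 2 postcontrast T1 [volume_image()]s (s),
#'   each carrying a `timestamp` (min).
#' @param plasma A [fit_plasma_model()] result (or [vif_model()]).
#' @param consts A [relaxation_constants()].
#' @param mask Brain mask volume; only masked voxels are fitted.
#' @return A list with `ki` (units 1/min) and `vp` (dimensionless)
#'   [volume_image()]s; unmasked or invalid voxels are `NA`.
#' @export
voxelwise_patlak <- function(pre_t1, post_t1_maps, plasma,
                             consts = relaxation_constants(), mask = NULL) {
  stopifnot(is.list(post_t1_maps), length(post_t1_maps) >= 2)
  dims <- dim(pre_t1)
  for (p in post_t1_maps) {
    if (!identical(dim(p), dims)) {
      stop(sprintf("grid mismatch: pre %s vs post %s.",
                   paste(dims, collapse = "x"),
                   paste(dim(p), collapse = "x")), call. = FALSE)
    }
  }
  if (is.null(mask)) mask <- array(TRUE, dims)
  if (!identical(dim(mask)[1:3], dims)) {
    stop(sprintf("grid mismatch: mask %s vs volumes %s.",
                 paste(dim(mask), collapse = "x"),
                 paste(dims, collapse = "x")), call. = FALSE)
  }
  times <- vapply(post_t1_maps, function(p) {
    ts <- attr(p, "timestamp")
    if (is.null(ts)) stop("every postcontrast map needs a timestamp.",
                          call. = FALSE)
    ts
  }, numeric(1))
  if (inherits(plasma, "vif_model")) {
    cp <- vif_eval(plasma, times)
    cp_int <- vif_integral(plasma, times)
  } else {
    cp <- plasma_eval(plasma, times)
    cp_int <- plasma_integral(plasma, times)
  }
  if (any(cp <= 0)) {
    stop("plasma concentration non-positive at a map time stamp.",
         call. = FALSE)
  }
  x <- cp_int / cp
  idx <- mask_indices(mask)
  pre <- as.numeric(pre_t1)[idx]
  post <- vapply(post_t1_maps, function(p) as.numeric(p)[idx],
                 numeric(length(idx)))
  valid <- pre > 0 & apply(post > 0, 1, all) & !is.na(pre) &
    !apply(is.na(post), 1, any)
  # concentration per voxel and time, then y = C_t / C_p
  conc <- (1 / post[valid, , drop = FALSE] - 1 / pre[valid]) / consts$r1
  y <- sweep(conc, 2, cp, "/")
  xbar <- mean(x)
  w <- (x - xbar) / sum((x - xbar)^2)
  ki_v <- drop(y %*% w)
  vp_v <- rowMeans(y) - ki_v * xbar
  ki_arr <- array(NA_real_, dims)
  vp_arr <- array(NA_real_, dims)
  ki_arr[idx[valid]] <- ki_v
  vp_arr[idx[valid]] <- vp_v
  vs <- attr(pre_t1, "voxel_size") %||% c(1, 1, 1)
  list(
    ki = volume_image(ki_arr, voxel_size = vs, units = "1/min"),
    vp = volume_image(vp_arr, voxel_size = vs, units = "")
  )
}

#' Outlier-trimmed region-of-interest summary
#'
#' Summarizes a parameter map over a region of interest after discarding
#' voxels outside the central `trim` fraction of the ROI's own value
#' distribution (percentiles (1-trim)/2 and 1-(1-trim)/2, both bounds
#' inclusive so ties are kept). The default keeps the central 95%.
#'
#' @param map A [volume_image()] (or array).
#' @param mask ROI mask on the same grid.
#' @param trim Central fraction kept, in (0, 1]. Default 0.95.
#' @return A one-row tibble: `mean`, `sd`, `n_total`, `n_kept`,
#'   `trim_low`, `trim_high`.
#' @export
roi_summary <- function(map, mask, trim = 0.95) {
  if (!identical(dim(map)[1:3], dim(mask)[1:3])) {
    stop("map and mask grids differ.", call. = FALSE)
  }
  if (trim <= 0 || trim > 1) stop("`trim` must be in (0, 1].", call. = FALSE)
  vals <- as.numeric(map)[mask_indices(mask)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no finite voxels in the ROI.", call. = FALSE)
  alpha <- (1 - trim) / 2
  bounds <- stats::quantile(vals, c(alpha, 1 - alpha), names = FALSE)
  kept <- vals[vals >= bounds[1] & vals <= bounds[2]]
  tibble::tibble(
    mean = mean(kept),
    sd = if (length(kept) > 1) stats::sd(kept) else 0,
    n_total = length(vals), n_kept = length(kept),
    trim_low = bounds[1], trim_high = bounds[2]
  )
}

#' Paired white-matter versus gray-matter comparison
#'
#' Paired two-sided Wilcoxon signed-rank test on per-subject (WM, GM)
#' value pairs. The default mode uses the normal approximation without
#' continuity correction; `mode = "exact"` enumerates the exact signed-rank
#' distribution (no ties/zeros allowed, which the small leakage-rate
#' samples here satisfy).
#'
#' @param wm,gm Numeric vectors of per-subject values (same length >= 2).
#' @param mode `"asymptotic"` (default) or `"exact"`.
#' @return A one-row tibble: `statistic` (V, signed-rank sum of positive
#'   GM-WM differences), `p_value`, `mode`, `n`.
#' @examples
#' compare_wm_gm(wm = c(4.1, 4.8, 5.0, 3.9, 4.5),
#'               gm = c(7.9, 8.2, 8.0, 7.0, 8.4))
#' @export
compare_wm_gm <- function(wm, gm, mode = c("asymptotic", "exact")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(wm), is.numeric(gm), length(wm) == length(gm))
  if (length(wm) < 2) stop("need at least 2 pairs.", call. = FALSE)
  if (any(is.na(wm)) || any(is.na(gm))) {
    stop("missing values are not allowed.", call. = FALSE)
  }
  d <- gm - wm
  if (all(d == 0)) {
    stop("all paired differences are zero; the test is undefined.",
         call. = FALSE)
  }
  ht <- if (mode == "exact") {
    stats::wilcox.test(gm, wm, paired = TRUE, exact = TRUE)
  } else {
    stats::wilcox.test(gm, wm, paired = TRUE, exact = FALSE, correct = FALSE)
  }
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 mode = mode, n = length(wm))
}
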