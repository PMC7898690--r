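#' Monte-Carlo simulation configuration
#'
#' Bundles the ingredients of one simulated acquisition condition: the
#' tissue ground truth, the plasma input, the sampling scheme, the tissue
#' concentration noise level, the number of Monte-Carlo repetitions, and
#' the RNG seed. The default noise of 2.0e-3 mM matches the
#' concentration-domain noise of 7 T in vivo T1-map data; the default
#' repetition count is 250,000.
#'
#' @param tissue A [tissue_params()].
#' @param vif A [vif_model()].
#' @param scheme A [make_scheme()] sampling scheme.
#' @param noise_sd SD of Gaussian noise added to tissue concentrations (mM).
#' @param n_runs Number of Monte-Carlo repetitions (>= 1).
#' @param seed Integer RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tissue = reference_tissue("WM"), vif = vif_model(),
                       scheme = make_scheme(4.333, 30, 0),
                       noise_sd = 2.0e-3, n_runs = 250000L, seed = 20201208L) {
  stopifnot(inherits(tissue, "tissue_params"), inherits(vif, "vif_model"),
            inherits(scheme, "sampling_scheme"))
  if (noise_sd < 0) stop("`noise_sd` must be non-negative.", call. = FALSE)
  if (n_runs < 1) stop("`n_runs` must be at least 1.", call. = FALSE)
  structure(
    list(tissue = tissue, vif = vif, scheme = scheme, noise_sd = noise_sd,
         n_runs = as.integer(n_runs), seed = as.integer(seed)),
    class = "sim_config"
  )
}

# Noiseless scaffolding shared by the per-run and vectorized paths:
# scheme-time plasma values, Patlak x coordinates, and noiseless C_t.
sim_scaffold <- function(config) {
  times <- config$scheme$times
  cp <- vif_eval(config$vif, times)
  if (any(cp <= 0)) {
    stop("plasma concentration non-positive at a scheme time.", call. = FALSE)
  }
  x <- vif_integral(config$vif, times) / cp
  ct0 <- extended_tofts(config$vif, config$tissue, times)$conc
  list(times = times, cp = cp, x = x, ct0 = ct0)
}

#' Simulate a single noisy acquisition
#'
#' Generates the noiseless tissue curve at the scheme times with the
#' extended Tofts model, adds i.i.d. Gaussian noise to the tissue
#' concentrations only (the plasma input stays noiseless), forms Patlak
#' coordinates against the noiseless plasma input, and fits the Patlak
#' line.
#'
#' @param config A [sim_config()]. Its `seed` is used unless the caller
#'   manages the RNG stream (`use_seed = FALSE`).
#' @param use_seed Set the config seed before drawing noise? Default TRUE.
#' @return A [patlak_fit()] object.
#' @export
simulate_once <- function(config, use_seed = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  sc <- sim_scaffold(config)
  draw <- function() {
    noise <- stats::rnorm(length(sc$times), sd = config$noise_sd)
    patlak_fit(tibble::tibble(x = sc$x, y = (sc$ct0 + noise) / sc$cp))
  }
  if (use_seed) withr::with_seed(config$seed, draw()) else draw()
}

#' Run a Monte-Carlo precision/accuracy experiment
#'
#' Repeats [simulate_once()] `n_runs` times (vectorized: the Patlak slope
#' is a fixed linear functional of the noisy ratios, so all runs reduce to
#' one matrix product) and summarizes the sampling distribution of the
#' leakage-rate and plasma-volume estimates. Accuracy is the percentage
#' difference \eqn{(K_{i,calc}/K_{i,true} - 1)\times 100}.
#'
#' The noise stream is identical to calling [simulate_once()] sequentially
#' under the same seed.
#'
#' @param config A [sim_config()].
#' @return A one-row tibble: `mean_ki`, `sd_ki`, `pct_diff`, `mean_vp`,
#'   `sd_vp`, `noiseless_ki`, `noiseless_vp`, `n_runs`, `seed`.
#' @export
run_monte_carlo <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- sim_scaffold(config)
  k <- length(sc$times)
  n <- config$n_runs
  xbar <- mean(sc$x)
  w <- (sc$x - xbar) / sum((sc$x - xbar)^2)  # slope weights
  y0 <- sc$ct0 / sc$cp
  ki0 <- sum(w * y0)
  vp0 <- mean(y0) - ki0 * xbar
  if (config$noise_sd == 0) {
    ki <- rep(ki0, n)
    vp <- rep(vp0, n)
  } else {
    noise <- withr::with_seed(
      config$seed,
      matrix(stats::rnorm(n * k, sd = config$noise_sd), nrow = n, byrow = TRUE)
    )
    e <- sweep(noise, 2, sc$cp, "/")      # noise contribution to y
    dki <- drop(e %*% w)
    ki <- ki0 + dki
    vp <- vp0 + rowMeans(e) - dki * xbar
  }
  tibble::tibble(
    mean_ki = mean(ki), sd_ki = stats::sd(ki),
    pct_diff = (mean(ki) / config$tissue$ktrans - 1) * 100,
    mean_vp = mean(vp), sd_vp = stats::sd(vp),
    noiseless_ki = ki0, noiseless_vp = vp0,
    n_runs = n, seed = config$seed
  )
}

#' Deterministic (noiseless) accuracy of a scheme
#'
#' The percentage difference of the noiseless Patlak estimate from the
#' true leakage rate. Because the Patlak estimator is linear in the tissue
#' concentrations and the noise is zero-mean, this equals the Monte-Carlo
#' mean bias, but is deterministic.
#'
#' @param tissue A [tissue_params()].
#' @param scheme A [make_scheme()] scheme.
#' @param vif A [vif_model()].
#' @return A list with `ki`, `vp`, and `pct_diff` (%).
#' @examples
#' noiseless_bias(reference_tissue("WM"), make_scheme(4.333, 25, 0))
#' @export
noiseless_bias <- function(tissue, scheme, vif = vif_model()) {
  ct <- extended_tofts(vif, tissue, scheme$times)
  fit <- patlak_fit(patlak_coords(ct, vif))
  list(ki = fit$ki, vp = fit$vp,
       pct_diff = (fit$ki / tissue$ktrans - 1) * 100)
}

# deterministic per-condition substream below 2^31
condition_seed <- function(root_seed, index) {
  as.integer((as.numeric(root_seed) * 7919 + index * 104729) %% 2147483629)
}

sim_conditions <- function(impaired_factor) {
  tidyr::expand_grid(
    tissue = c("WM", "GM"),
    impaired = c(FALSE, TRUE)
  ) |>
    dplyr::mutate(
      ktrans_scale = ifelse(.data$impaired, 1 + impaired_factor / 100, 1)
    )
}

scaled_tissue <- function(class, scale) {
  base <- reference_tissue(class)
  tissue_params(ktrans = base$ktrans * scale, vp = base$vp, ve = base$ve)
}

#' Sweep the number of postcontrast T1 maps
#'
#' For each tissue condition (WM and GM, normal and impaired — impaired
#' means the leakage rate scaled up by `impaired_factor` percent) and each
#' requested number of interior maps, runs the Monte-Carlo experiment on a
#' scheme spanning `first`..`last` minutes and reports precision and
#' accuracy. Each table row gets its own reproducible seed substream
#' derived from the base config seed.
#'
#' @param config A [sim_config()] providing the VIF, noise level, run
#'   count, scheme endpoints, and root seed.
#' @param n_additional Integer vector of interior-map counts (0 = two maps).
#' @param impaired_factor Percent increase of `ktrans` for the impaired
#'   condition (default 20).
#' @return A tibble with one row per condition and map count: columns
#'   `tissue`, `impaired`, `n_maps`, `mean_ki`, `sd_ki`, `pct_diff`,
#'   `mean_vp`, `sd_vp`, `n_runs`, `seed`.
#' @export
sweep_num_maps <- function(config, n_additional = 0:5, impaired_factor = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (length(n_additional) == 0) {
    return(tibble::tibble(
      tissue = character(), impaired = logical(), n_maps = integer(),
      mean_ki = numeric(), sd_ki = numeric(), pct_diff = numeric(),
      mean_vp = numeric(), sd_vp = numeric(), n_runs = integer(),
      seed = integer()
    ))
  }
  if (any(n_additional < 0)) {
    stop("`n_additional` values must be non-negative.", call. = FALSE)
  }
  grid <- sim_conditions(impaired_factor) |>
    tidyr::expand_grid(n_additional = as.integer(n_additional)) |>
    dplyr::mutate(row = dplyr::row_number())
  purrr::pmap_dfr(grid, function(tissue, impaired, ktrans_scale, n_additional, row) {
    cfg <- sim_config(
      tissue = scaled_tissue(tissue, ktrans_scale),
      vif = config$vif,
      scheme = make_scheme(config$scheme$first, config$scheme$last, n_additional),
      noise_sd = config$noise_sd, n_runs = config$n_runs,
      seed = condition_seed(config$seed, row)
    )
    dplyr::bind_cols(
      tibble::tibble(tissue = tissue, impaired = impaired,
                     n_maps = n_additional + 2L),
      run_monte_carlo(cfg)
    )
  })
}

#' Sweep the timing of the last T1 map
#'
#' Two-point schemes only: the first map stays at `config$scheme$first`
#' and the last-map time takes each value in `last_times` (default 9 to 39
#' minutes in steps of 2). One row per tissue condition and last-map time.
#'
#' @inheritParams sweep_num_maps
#' @param last_times Last-map times (min), all greater than the first-map
#'   time.
#' @return A tibble like [sweep_num_maps()] but with a `t_last_min` column
#'   in place of `n_maps`.
#' @export
sweep_last_time <- function(config, last_times = seq(9, 39, by = 2),
                            impaired_factor = 20) {
  stopifnot(inherits(config, "sim_config"))
  if (length(last_times) == 0) {
    return(tibble::tibble(
      tissue = character(), impaired = logical(), t_last_min = numeric(),
      mean_ki = numeric(), sd_ki = numeric(), pct_diff = numeric(),
      mean_vp = numeric(), sd_vp = numeric(), n_runs = integer(),
      seed = integer()
    ))
  }
  if (any(last_times <= config$scheme$first)) {
    stop("all `last_times` must exceed the first-map time.", call. = FALSE)
  }
  grid <- sim_conditions(impaired_factor) |>
    tidyr::expand_grid(t_last = as.numeric(last_times)) |>
    dplyr::mutate(row = dplyr::row_number())
  purrr::pmap_dfr(grid, function(tissue, impaired, ktrans_scale, t_last, row) {
    cfg <- sim_config(
      tissue = scaled_tissue(tissue, ktrans_scale),
      vif = config$vif,
      scheme = make_scheme(config$scheme$first, t_last, 0),
      noise_sd = config$noise_sd, n_runs = config$n_runs,
      seed = condition_seed(config$seed, 1000L + row)
    )
    dplyr::bind_cols(
      tibble::tibble(tissue = tissue, impaired = impaired, t_last_min = t_last),
      run_monte_carlo(cfg)
    )
  })
}

#' Plot a protocol sweep
#'
#' Mean estimated leakage rate with +/- 1 SD error bars per condition,
#' against the swept variable (`n_maps` or `t_last_min`).
#'
#' @param sweep A tibble from [sweep_num_maps()] or [sweep_last_time()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  xvar <- if ("n_maps" %in% names(sweep)) "n_maps" else "t_last_min"
  xlab <- if (xvar == "n_maps") "Number of postcontrast T1 maps" else
    "Time of last T1 map (min)"
  ggplot2::ggplot(sweep, ggplot2::aes(
    x = .data[[xvar]], y = .data$mean_ki,
    colour = .data$tissue, linetype = .data$impaired
  )) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_ki - .data$sd_ki,
                                        ymax = .data$mean_ki + .data$sd_ki),
                           width = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = expression(K[i] ~ ("min"^-1)),
                  colour = "Tissue", linetype = "Impaired")
}
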