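# a small phantom reused across tests (masks still have hundreds of voxels)
small_spec <- function(...) {
  phantom_spec(grid = c(12, 12, 12), ...)
}

test_that("phantom masks are disjoint and the truth records the inputs", {
  ph <- make_phantom(small_spec())
  m <- lapply(ph$masks, as.logical)
  expect_false(any(m$WM & m$GM | m$WM & m$SSS | m$GM & m$SSS))
  expect_setequal(ph$truth$class, c("WM", "GM"))
  wm <- dplyr::filter(ph$truth, class == "WM")
  expect_equal(wm$ktrans, 5.0e-4)
  expect_equal(wm$vp, 0.036)
  expect_equal(wm$ve, 0.05)
  gm <- dplyr::filter(ph$truth, class == "GM")
  expect_equal(gm$ktrans, 8.0e-4)
  expect_equal(gm$vp, 0.049)
})

test_that("the same seed gives a bit-identical dataset", {
  a <- make_phantom(small_spec(seed = 7L))
  b <- make_phantom(small_spec(seed = 7L))
  expect_identical(as.numeric(a$post_t1[[1]]), as.numeric(b$post_t1[[1]]))
  expect_identical(a$dynamic_blood, b$dynamic_blood)
  c <- make_phantom(small_spec(seed = 8L))
  expect_false(identical(a$dynamic_blood, c$dynamic_blood))
})

test_that("zero-noise maps invert exactly to the programmed concentrations", {
  spec <- small_spec(map_noise_sd = 0, dynamic_noise_sd = 0)
  ph <- make_phantom(spec)
  conc_wm <- extended_tofts(spec$vif, spec$tissues$WM, spec$scheme$times)$conc
  idx <- which(as.logical(ph$masks$WM))[1]
  for (j in seq_along(ph$post_t1)) {
    got <- t1_to_concentration(as.numeric(ph$pre_t1)[idx],
                               as.numeric(ph$post_t1[[j]])[idx], spec$consts)
    expect_equal(got, conc_wm[j], tolerance = 1e-12)
  }
})

test_that("zero-noise pipeline recovers the noiseless Patlak truth exactly", {
  ph <- make_phantom(small_spec(map_noise_sd = 0, dynamic_noise_sd = 0))
  rep <- recovery_report(ph)
  expect_equal(nrow(rep), 4)
  expect_lt(max(abs(rep$rel_error)), 1e-6)
})

test_that("default-noise phantom recovers class means within tolerance", {
  ph <- make_phantom(phantom_spec())  # 32^3: >= 1000 voxels per class
  q <- quantify_phantom(ph)
  rep <- recovery_report(ph, q)
  ki <- dplyr::filter(rep, map == "ki")
  expect_gt(min(ki$n_kept), 1000)
  expect_lt(max(abs(ki$rel_error)), 0.05)
  # recovered GM leakage exceeds WM leakage
  expect_gt(ki$recovered_mean[ki$class == "GM"],
            ki$recovered_mean[ki$class == "WM"])
  # vp estimates in a plausible physiological range
  vp <- dplyr::filter(rep, map == "vp")
  expect_true(all(vp$recovered_mean > 0 & vp$recovered_mean < 0.2))
  # plasma tail rate recovered within 5% of the programmed washout
  expect_equal(q$plasma$tail_rate, ph$spec$vif$m, tolerance = 0.05)
})

test_that("phantom SSS curve recovers the programmed blood curve", {
  ph <- make_phantom(phantom_spec())
  curve <- extract_blood_curve(ph$dynamic_blood, ph$masks$SSS,
                               times = ph$dynamic_times)
  programmed <- vif_eval(ph$spec$vif, ph$dynamic_times) *
    (1 - ph$spec$consts$hct)
  n_sss <- sum(as.logical(ph$masks$SSS))
  se <- ph$spec$dynamic_noise_sd / sqrt(n_sss)
  expect_lt(max(abs(curve$conc - programmed)), 5 * se)
})

test_that("per-voxel ki dispersion matches the Monte-Carlo prediction", {
  # choose the map noise that makes WM concentration noise exactly 2e-3 mM,
  # then compare the voxel SD of ki with the protocol simulator's SD
  t1_wm <- 1.2
  sigma_c <- 2e-3
  consts <- relaxation_constants()
  spec <- phantom_spec(map_noise_sd = sigma_c * consts$r1 * t1_wm^2,
                       dynamic_noise_sd = 0, seed = 77L)
  ph <- make_phantom(spec)
  q <- quantify_phantom(ph, trim = 1)
  voxel_sd <- dplyr::filter(q$roi, class == "WM", map == "ki")$sd
  mc <- run_monte_carlo(sim_config(
    tissue = spec$tissues$WM, vif = spec$vif, scheme = spec$scheme,
    noise_sd = sigma_c, n_runs = 50000L, seed = 78L))
  expect_equal(voxel_sd, mc$sd_ki, tolerance = 0.1)
})

test_that("phantom datasets round-trip through NIfTI", {
  ph <- make_phantom(small_spec())
  out <- withr::local_tempdir()
  write_phantom(ph, out)
  expect_true(file.exists(file.path(out, "truth.json")))
  pre <- read_volume(file.path(out, "pre_t1.nii.gz"), units = "s")
  expect_equal(as.numeric(pre), as.numeric(ph$pre_t1), tolerance = 1e-12)
  expect_equal(attr(pre, "voxel_size"), c(1.2, 1.2, 1.2), tolerance = 1e-6)
  dyn <- read_volume(file.path(out, "dyn.nii.gz"))
  expect_equal(dim(dyn), dim(ph$dynamic_blood))
  expect_equal(as.numeric(dyn), as.numeric(ph$dynamic_blood),
               tolerance = 1e-12)
  truth <- jsonlite::read_json(file.path(out, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, ph$spec$seed)
  expect_equal(truth$constants$r1, 4.2)
})
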