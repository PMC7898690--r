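make_uniform_volumes <- function(params, scheme, vif = default_vif(),
                                 consts = relaxation_constants(),
                                 dims = c(5, 5, 5), t1_pre = 1.4) {
  conc <- extended_tofts(vif, params, scheme$times)$conc
  pre <- volume_image(array(t1_pre, dims), units = "s")
  post <- lapply(seq_along(scheme$times), function(j) {
    volume_image(
      array(sparsedce:::concentration_to_t1(t1_pre, conc[j], consts), dims),
      units = "s", timestamp = scheme$times[j])
  })
  list(pre = pre, post = post)
}

test_that("voxelwise Patlak on uniform volumes equals the scalar fit", {
  scheme <- make_scheme(4.333, 25, 1)
  vif <- default_vif()
  vols <- make_uniform_volumes(gm_params(), scheme, vif)
  maps <- voxelwise_patlak(vols$pre, vols$post, vif)
  ct <- extended_tofts(vif, gm_params(), scheme$times)
  ref <- patlak_fit(patlak_coords(ct, vif))
  expect_equal(range(maps$ki), rep(ref$ki, 2), tolerance = 1e-10)
  expect_equal(range(maps$vp), rep(ref$vp, 2), tolerance = 1e-10)
  expect_equal(attr(maps$ki, "units"), "1/min")
  expect_equal(attr(maps$vp, "units"), "")
})

test_that("grid mismatches and invalid voxels are handled", {
  scheme <- make_scheme(4.333, 25, 0)
  vols <- make_uniform_volumes(wm_params(), scheme)
  bad_post <- vols$post
  bad_post[[1]] <- volume_image(array(1, c(4, 5, 5)), units = "s",
                                timestamp = 4.333)
  expect_error(voxelwise_patlak(vols$pre, bad_post, default_vif()),
               "4x5x5")
  # a voxel with non-positive T1 becomes NA, the rest still fit
  pre2 <- vols$pre
  pre2[1, 1, 1] <- -1
  maps <- voxelwise_patlak(pre2, vols$post, default_vif())
  expect_true(is.na(maps$ki[1, 1, 1]))
  expect_false(anyNA(maps$ki[-1]))
})

test_that("roi_summary trims the central fraction and keeps ties", {
  dims <- c(10, 10, 10)
  const_map <- volume_image(array(2.5, dims))
  mask <- array(TRUE, dims)
  s <- roi_summary(const_map, mask)
  expect_equal(s$mean, 2.5)
  expect_equal(s$sd, 0)
  expect_equal(s$n_kept, s$n_total)
  withr::with_seed(21, {
    vals <- rnorm(10000)
    m <- volume_image(array(vals, c(10, 10, 100)))
    s2 <- roi_summary(m, array(TRUE, c(10, 10, 100)))
    expect_equal(s2$n_kept / s2$n_total, 0.95, tolerance = 0.01)
    expect_lt(abs(s2$mean), 0.02)
  })
  # one extreme outlier among many is excluded
  vals3 <- c(rnorm(63), 1e6)
  m3 <- volume_image(array(vals3, c(4, 4, 4)))
  s3 <- roi_summary(m3, array(TRUE, c(4, 4, 4)))
  expect_lt(s3$mean, 1)
  expect_lt(s3$trim_high, 1e6)             # the outlier is outside the bounds
  expect_lte(s3$n_total - s3$n_kept, 4)    # at most ~2.5% per tail
})

test_that("roi_summary is invariant under voxel ordering", {
  withr::with_seed(4, {
    vals <- rnorm(4^3)
    a <- roi_summary(volume_image(array(vals, c(4, 4, 4))),
                     array(TRUE, c(4, 4, 4)))
    b <- roi_summary(volume_image(array(sample(vals), c(4, 4, 4))),
                     array(TRUE, c(4, 4, 4)))
    expect_equal(a$mean, b$mean)
    expect_equal(a$sd, b$sd)
    expect_equal(a$n_kept, b$n_kept)
  })
  expect_error(roi_summary(volume_image(array(1, c(2, 2, 2))),
                           array(FALSE, c(2, 2, 2))), "empty")
})
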