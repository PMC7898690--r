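test_that("T1 change converts to concentration by the linear relation", {
  consts <- relaxation_constants(r1 = 4.2, hct = 0.45)
  expect_equal(t1_to_concentration(2.0, 2.0, consts), 0)
  # hand arithmetic: (1/1.8 - 1/2)/4.2
  expect_equal(t1_to_concentration(2.0, 1.8, consts), 0.013228, tolerance = 1e-4)
  # a 4.2 /s relaxation-rate change is exactly 1 mM at r1 = 4.2 /mM/s
  t1_post <- 1 / (1 / 1.5 + 4.2)
  expect_equal(t1_to_concentration(1.5, t1_post, consts), 1.0, tolerance = 1e-12)
})

test_that("non-positive T1 is flagged as NA, not propagated", {
  expect_warning(out <- t1_to_concentration(c(2, -1), c(1.8, 1.8)),
                 "non-positive")
  expect_true(is.na(out[2]) && !is.na(out[1]))
})

test_that("forward and inverse T1-concentration maps are mutually inverse", {
  consts <- relaxation_constants()
  t1_pre <- c(0.8, 1.2, 2.0, 2.4)
  conc <- c(0, 1e-3, 0.05, 1.2)
  t1_post <- sparsedce:::concentration_to_t1(t1_pre, conc, consts)
  expect_equal(t1_to_concentration(t1_pre, t1_post, consts), conc,
               tolerance = 1e-10)
})

test_that("whole-blood to plasma correction divides by one minus hematocrit", {
  expect_equal(blood_to_plasma(0, relaxation_constants()), 0)
  expect_equal(blood_to_plasma(0.7, relaxation_constants(hct = 0)), 0.7)
  expect_equal(blood_to_plasma(0.55, relaxation_constants(hct = 0.45)), 1.0)
  expect_error(relaxation_constants(hct = 1.2), "hct")
})

test_that("monoexp_fit recovers exact parameters and the flat limit", {
  t <- c(3, 10, 25)
  fit <- monoexp_fit(t, 1.0 * exp(-0.05 * t))
  expect_equal(fit$amplitude, 1.0, tolerance = 1e-12)
  expect_equal(fit$rate, 0.05, tolerance = 1e-12)
  expect_false(fit$clamped)
  flat <- monoexp_fit(t, rep(0.8, 3))
  expect_equal(flat$rate, 0)
  expect_equal(flat$amplitude, 0.8)
})

test_that("monoexp_fit matches a brute-force grid search on noisy points", {
  withr::with_seed(11, {
    t <- c(3, 10, 25)
    conc <- 1.2 * exp(-0.04 * t) * exp(rnorm(3, sd = 0.05))
    fit <- monoexp_fit(t, conc)
    # oracle: 2-parameter grid search over log-domain SSE
    sse <- function(loga, m) sum((log(conc) - (loga - m * t))^2)
    grid <- expand.grid(loga = seq(-0.5, 1, length.out = 601),
                        m = seq(0, 0.2, length.out = 601))
    best <- grid[which.min(mapply(sse, grid$loga, grid$m)), ]
    # refine around the grid winner
    opt <- optim(c(best$loga, best$m), function(p) sse(p[1], p[2]))
    expect_equal(log(fit$amplitude), opt$par[1], tolerance = 1e-4)
    expect_equal(fit$rate, opt$par[2], tolerance = 1e-4)
    expect_equal(sse(log(fit$amplitude), fit$rate), opt$value, tolerance = 1e-6)
  })
})

test_that("monoexp_fit rejects non-positive concentrations", {
  expect_error(monoexp_fit(c(1, 2), c(1, -0.1)), "positive")
  expect_error(monoexp_fit(3, 1), "at least 2")
})
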