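test_that("NMSE satisfies its identities", {
  set.seed(11)
  gt <- matrix(runif(60, 0.5, 2), 6, 10)
  expect_equal(nmse(gt, gt), 0)
  expect_equal(nmse(gt * 0, gt), 1)
  est <- gt + matrix(rnorm(60, 0, 0.1), 6, 10)
  # direct two-line oracle
  expect_equal(nmse(est, gt), mean((est - gt)^2) / mean(gt^2))
  # scale consistency
  expect_equal(nmse(3 * est, 3 * gt), nmse(est, gt), tolerance = 1e-12)
})

test_that("SSIM matches the reference implementation", {
  # expected values computed with scikit-image structural_similarity
  # (win_size = 7, uniform window, sample covariance, borders cropped)
  i <- matrix(0:19, 20, 30)
  j <- matrix(rep(0:29, each = 20), 20, 30)
  gt <- sin(i / 3) + 0.5 * cos(j / 4)
  est <- gt + 0.3 * ((i + j) %% 2) - 0.1
  dr <- max(gt) - min(gt)
  expect_equal(ssim_map(est, gt, dr), 0.88423042712943, tolerance = 1e-10)
  expect_equal(ssim_map(gt + 2, gt, dr), -0.13352004386630942,
               tolerance = 1e-10)
  cb <- (i + j) %% 2
  expect_equal(ssim_map(cb, matrix(0.5, 20, 30), 1),
               0.0035148648569731694, tolerance = 1e-10)
})

test_that("SSIM satisfies its identities", {
  set.seed(12)
  gt <- matrix(runif(200), 10, 20)
  expect_equal(ssim_map(gt, gt), 1)
  expect_lt(ssim_map(gt + 5, gt), 1)   # luminance term penalised
  expect_error(ssim_map(gt[1:5, 1:5], gt[1:5, 1:5], win = 7), "window")
})

test_that("perfect estimates give zero NMSE and unit SSIM", {
  d <- simulate_dro(dro_config(Fp_values = c(0.5, 1.5), vp_values = 0.05,
                               ve_values = 0.2, PS_values = c(0.5, 1.5),
                               block = c(5, 5, 1)))
  fake <- list(maps = d$gt, method = "oracle")
  class(fake) <- c("nlls_fit", "cxm_fit")
  fake$params <- gt_matrix(d)
  ev <- evaluate_fit(fake, d)
  expect_equal(ev$summary$nmse, rep(0, 5))
  expect_equal(ev$summary$ssim, rep(1, 5))
})

test_that("evaluation aggregates per slice", {
  d <- simulate_dro(dro_config(Fp_values = c(0.5, 1), vp_values = 0.05,
                               ve_values = 0.2, PS_values = c(1, 2),
                               block = c(5, 5, 2)))
  est <- lapply(d$gt, function(m) m * 1.1)   # 10% uniform inflation
  ev <- evaluate_fit(est, d)
  expect_equal(dim(ev$nmse_slices), c(4, 4))
  expect_equal(ev$summary$nmse[1], 0.01, tolerance = 1e-10)
})
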