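test_that("gamma-variate AIF has the advertised shape", {
  tt <- seq(0, 2, by = 1e-4)
  a <- gamma_variate_aif(tt, amplitude = 5, t0 = 0.1, alpha = 2.5,
                         beta = 0.08)
  expect_true(all(a[tt <= 0.1] == 0))
  # peak value equals the amplitude at t0 + alpha beta
  expect_equal(max(a), 5, tolerance = 1e-6)
  expect_lt(abs(tt[which.max(a)] - (0.1 + 2.5 * 0.08)), 1e-4 + 1e-12)
})

test_that("default parameter grid tiles 40 x 120 x 3 with 144 blocks", {
  cfg <- dro_config()
  maps <- build_parameter_maps(cfg)
  expect_equal(dim(maps$Fp), c(40, 120, 3))
  combos <- unique(cbind(as.vector(maps$Fp), as.vector(maps$vp),
                         as.vector(maps$ve), as.vector(maps$PS)))
  expect_equal(nrow(combos), 144)
  # every pixel of a block shares its tuple
  blk <- maps$Fp[1:10, 1:10, 1]
  expect_equal(length(unique(as.vector(blk))), 1)
  # PS is constant within a slice and varies only along z
  for (z in 1:3)
    expect_equal(length(unique(as.vector(maps$PS[, , z]))), 1)
  expect_equal(sort(unique(as.vector(maps$PS))), c(0.5, 1.5, 2.5))
})

test_that("single-value lists give one uniform block", {
  cfg <- dro_config(Fp_values = 1, vp_values = 0.1, ve_values = 0.2,
                    PS_values = 1, block = c(10, 10, 1))
  maps <- build_parameter_maps(cfg)
  expect_equal(dim(maps$Fp), c(10, 10, 1))
  expect_true(all(maps$Fp == 1) && all(maps$vp == 0.1))
})

test_that("simulation is seeded and clean curves come from the solver", {
  d1 <- tiny_dro()
  d2 <- tiny_dro()
  expect_identical(d1$curves_noisy, d2$curves_noisy)
  d3 <- tiny_dro(seed = 2)
  expect_false(identical(d1$curves_noisy, d3$curves_noisy))
  expect_identical(d1$curves_clean, d3$curves_clean)
  # a block's clean curve equals the direct forward solution
  p <- c(d1$gt$Fp[1, 1, 1], d1$gt$vp[1, 1, 1], d1$gt$ve[1, 1, 1],
         d1$gt$PS[1, 1, 1])
  sol <- solve_2cxm(p, d1$aif, d1$t)
  expect_equal(d1$curves_clean[1, 1, 1, ], sol$Cmyo, tolerance = 1e-12)
})

test_that("infinite SNR reproduces the clean curves", {
  d <- tiny_dro(snr = Inf)
  expect_identical(d$curves_noisy, d$curves_clean)
  expect_equal(d$noise_sigma, 0)
})

test_that("each noisy curve carries the configured noise level", {
  d <- simulate_dro(dro_config(Fp_values = c(1, 2), vp_values = 0.1,
                               ve_values = 0.2, PS_values = 1.5,
                               block = c(10, 10, 1)))
  clean <- matrix(d$curves_clean, nrow = 200)
  noisy <- matrix(d$curves_noisy, nrow = 200)
  z <- (noisy - clean) / d$noise_sigma   # standardised noise, per pixel
  expect_lt(abs(sd(as.vector(z)) - 1), 0.02)
  # per-curve SNR: peak / sigma equals the target
  peaks <- apply(clean, 1, max)
  expect_equal(unname(peaks / d$noise_sigma), rep(17.5, 200),
               tolerance = 1e-10)
})

test_that("renoise redraws noise but keeps the clean signal", {
  d <- tiny_dro()
  d2 <- renoise(d, 99)
  expect_identical(d$curves_clean, d2$curves_clean)
  expect_false(identical(d$curves_noisy, d2$curves_noisy))
  expect_equal(d$noise_sigma, d2$noise_sigma)
})

test_that("dro_subset restricts maps and curves consistently", {
  d <- simulate_dro(dro_config(Fp_values = c(0.5, 1), vp_values = 0.05,
                               ve_values = 0.2, PS_values = c(1, 2),
                               block = c(2, 2, 1)))
  s <- dro_subset(d, rows = 1:2, cols = 1:2, slices = 2)
  expect_equal(dim(s$curves_noisy), c(2, 2, 1, 100))
  expect_equal(s$gt$PS[1, 1, 1], 2)
  expect_equal(s$curves_clean[1, 1, 1, ], d$curves_clean[1, 1, 2, ])
})

test_that("time grid convention gives exactly 100 points in [0, 2)", {
  d <- tiny_dro()
  expect_equal(length(d$t), 100)
  expect_equal(d$t[1], 0)
  expect_equal(d$t[100], 1.98)
})
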