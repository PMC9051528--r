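test_that("noiseless curve initialised at the truth is a fixed point", {
  g <- default_grid()
  aif <- default_aif(g)
  truth <- c(Fp = 1.5, vp = 0.1, ve = 0.2, PS = 1.5)
  curve <- solve_2cxm(truth, aif, g)$Cmyo
  fit <- fit_pixel(curve, aif, g, nlls_config(init = truth,
                                              max_iter = 200))
  expect_equal(unname(fit$params), unname(truth), tolerance = 1e-3)
  expect_lt(fit$sse, 1e-8)
})

test_that("noiseless curve is recovered from a generic start", {
  g <- default_grid()
  aif <- default_aif(g)
  truth <- c(1.5, 0.1, 0.2, 1.5)
  curve <- solve_2cxm(truth, aif, g)$Cmyo
  fit <- fit_pixel(curve, aif, g, nlls_config(multi_start = 5,
                                              max_iter = 200))
  expect_lt(abs(fit$params[["Fp"]] - 1.5) / 1.5, 0.05)
  expect_lt(fit$sse, 1e-6)
})

test_that("an all-zero curve is explained by zero flow", {
  g <- default_grid()
  aif <- default_aif(g)
  fit <- fit_pixel(rep(0, 100), aif, g)
  expect_lt(fit$params[["Fp"]], 1e-3)
  expect_lt(fit$sse, 1e-6)
})

test_that("estimates respect bounds and never exceed the initial SSE", {
  d <- tiny_dro()
  cfg <- nlls_config()
  fit <- fit_nlls(d, cfg = cfg)
  expect_true(all(sweep(fit$params, 2, cfg$lower, ">=")))
  expect_true(all(sweep(fit$params, 2, cfg$upper, "<=")))
  curves <- matrix(d$curves_noisy, nrow = 16)
  sse0 <- sapply(seq_len(16), function(k)
    cxmpinn:::cxm_sse_cpp(cfg$init, d$t, d$aif, curves[k, ]))
  expect_true(all(fit$sse <= sse0 + 1e-12))
})

test_that("pixels are fitted independently and order-invariantly", {
  g <- default_grid()
  aif <- default_aif(g)
  curve <- solve_2cxm(c(1, 0.05, 0.2, 1), aif, g)$Cmyo
  curves <- rbind(curve, curve, curve)
  fit <- fit_nlls(curves, aif, g)
  expect_equal(fit$params[1, ], fit$params[2, ])
  expect_equal(fit$params[1, ], fit$params[3, ])
  # permuting pixels permutes results identically
  d <- tiny_dro()
  cm <- matrix(d$curves_noisy, nrow = 16)
  perm <- c(16:9, 1:8)
  f1 <- fit_nlls(cm, d$aif, d$t)
  f2 <- fit_nlls(cm[perm, ], d$aif, d$t)
  expect_equal(f2$params, f1$params[perm, ])
})

test_that("noiseless curves are fitted to solver tolerance almost everywhere", {
  # one converged fit per unique clean curve of the full reference grid;
  # a small fraction of genuine local-optimum failures (e.g. the
  # zero-flow solution) is expected of pixelwise NLLS
  g <- default_grid()
  aif <- default_aif(g)
  cfg <- dro_config()
  combos <- as.matrix(expand.grid(cfg$Fp_values, cfg$vp_values,
                                  cfg$ve_values, cfg$PS_values))
  curves <- cxmpinn:::cxm_cmyo_many_cpp(combos, g$t, aif)
  cfg_n <- nlls_config(max_iter = 200)
  rel <- sapply(seq_len(nrow(combos)), function(i)
    fit_pixel(curves[i, ], aif, g, cfg_n)$sse / sum(curves[i, ]^2))
  expect_gte(mean(rel < 1e-5), 0.95)
})

test_that("degenerate inputs are rejected", {
  g <- default_grid()
  aif <- default_aif(g)
  expect_error(fit_pixel(rep(NA_real_, 100), aif, g), "NA")
  expect_error(nlls_config(init = c(Fp = -1, vp = 0.05, ve = 0.2,
                                    PS = 1)), "bounds")
})
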