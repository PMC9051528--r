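test_that("forward pass honours the output-shape contract", {
  s <- random_pinn_setup(K = 4, B1 = 10, Nr = 5)
  tau <- s$tau_obs
  ev <- cxmpinn:::pinn_eval_cpp(s$net, tau, FALSE, list(), list())
  expect_equal(dim(ev$U), c(2 * 4 + 1, 10))
  expect_equal(dim(ev$V), c(2 * 4 + 1, 10))
  # seeded initialisation is reproducible
  s2 <- random_pinn_setup(K = 4, B1 = 10, Nr = 5)
  ev2 <- cxmpinn:::pinn_eval_cpp(s2$net, tau, FALSE, list(), list())
  expect_identical(ev$U, ev2$U)
})

test_that("forward-mode tangents match central finite differences", {
  s <- random_pinn_setup(K = 3, B1 = 20, Nr = 5)
  tau <- s$tau_obs
  ev <- cxmpinn:::pinn_eval_cpp(s$net, tau, FALSE, list(), list())
  bn <- list(mu = ev$bn_mu, sd = ev$bn_sd)
  h <- 1e-3
  up <- cxmpinn:::pinn_eval_cpp(s$net, tau + h, TRUE, bn$mu, bn$sd)$U
  dn <- cxmpinn:::pinn_eval_cpp(s$net, tau - h, TRUE, bn$mu, bn$sd)$U
  fd <- (up - dn) / (2 * h)
  expect_lt(max(abs(fd - ev$V)) / max(abs(ev$V)), 1e-3)
})

test_that("analytic gradients match finite differences for every variant", {
  # full batch-mode objective: the check covers the gradient flow through
  # the batch-normalisation statistics as well
  s <- random_pinn_setup()
  h <- 1e-6
  for (variant in c("2cxm", "reduced", "combined")) {
    st <- pinn_step(s, variant)
    total <- function(sx) pinn_step(sx, variant)$total
    errs <- c()
    for (l in 1:3) for (idx in seq(1, length(s$net$W[[l]]), by = 5)) {
      s2 <- s; s2$net$W[[l]][idx] <- s2$net$W[[l]][idx] + h
      up <- total(s2)
      s2$net$W[[l]][idx] <- s2$net$W[[l]][idx] - 2 * h
      dn <- total(s2)
      errs <- c(errs, abs((up - dn) / (2 * h) - st$gW[[l]][idx]) /
                  max(abs(st$gW[[l]][idx]), 1e-6))
    }
    for (l in 1:2) for (idx in c(1, 4)) {
      for (nm in c("gamma", "beta", "b")) {
        gn <- c(gamma = "ggamma", beta = "gbeta", b = "gb")[[nm]]
        s2 <- s; s2$net[[nm]][[l]][idx] <- s2$net[[nm]][[l]][idx] + h
        up <- total(s2)
        s2$net[[nm]][[l]][idx] <- s2$net[[nm]][[l]][idx] - 2 * h
        dn <- total(s2)
        errs <- c(errs, abs((up - dn) / (2 * h) - st[[gn]][[l]][idx]) /
                    max(abs(st[[gn]][[l]][idx]), 1e-6))
      }
    }
    for (j in 1:4) for (k in 1:s$K) {
      s2 <- s; s2$logk[k, j] <- s2$logk[k, j] + h
      up <- total(s2)
      s2$logk[k, j] <- s2$logk[k, j] - 2 * h
      dn <- total(s2)
      errs <- c(errs, abs((up - dn) / (2 * h) - st$glogk[k, j]) /
                  max(abs(st$glogk[k, j]), 1e-6))
    }
    expect_lt(max(errs), 1e-4, label = paste("gradients,", variant))
  }
})

test_that("engine loss terms agree with the reference implementations", {
  s <- random_pinn_setup(K = 5, B1 = 15, Nr = 9, seed = 3)
  tau_all <- c(s$tau_obs, s$tau_col, s$tau0)
  ev <- cxmpinn:::pinn_eval_cpp(s$net, tau_all, FALSE, list(), list())
  K <- s$K; B1 <- s$B1; Nr <- s$Nr
  U <- ev$U; V <- ev$V
  pars <- exp(s$logk)
  cp_o <- U[1:K, 1:B1]; ce_o <- U[K + 1:K, 1:B1]
  cmyo <- cp_o * pars[, 2] + ce_o * pars[, 3]
  ic <- B1 + seq_len(Nr)
  for (variant in c("2cxm", "reduced", "combined")) {
    st <- pinn_step(s, variant)
    expect_equal(st$LC, pinn_loss_data(cmyo, s$cobs)$value,
                 tolerance = 1e-10)
    expect_equal(st$LC_aif,
                 sum((U[2 * K + 1, 1:B1] - s$aifobs)^2),
                 tolerance = 1e-10)
    lr <- pinn_loss_residual(U[1:K, ic], U[K + 1:K, ic],
                             U[2 * K + 1, ic], V[1:K, ic],
                             V[K + 1:K, ic], pars, s$sigma_t, variant)
    expect_equal(st$Lr, lr$value, tolerance = 1e-10)
    ib <- B1 + Nr + 1
    expect_equal(st$Lb, mean(U[1:K, ib]^2 + U[K + 1:K, ib]^2),
                 tolerance = 1e-10)
    lreg <- mean(pinn_loss_nonneg(U[1:K, ic])$per_pixel +
                   pinn_loss_nonneg(U[K + 1:K, ic])$per_pixel)
    expect_equal(st$Lreg, lreg, tolerance = 1e-10)
  }
  # the combined residual loss is the sum of the other two by definition
  a <- pinn_step(s, "2cxm")$Lr
  b <- pinn_step(s, "reduced")$Lr
  cc <- pinn_step(s, "combined")$Lr
  expect_equal(cc, a + b, tolerance = 1e-10)
})

test_that("loss terms satisfy their closed-form special cases", {
  obs <- matrix(runif(30), 3, 10)
  expect_equal(pinn_loss_data(obs, obs)$value, 0)
  # constant offset on one pixel contributes N delta^2
  delta <- 0.3
  pred <- obs; pred[2, ] <- pred[2, ] + delta
  expect_equal(pinn_loss_data(pred, obs)$per_pixel[2], 10 * delta^2)
  # zero concentrations and AIF: all residual variants vanish
  z <- matrix(0, 2, 6)
  for (v in c("2cxm", "reduced", "combined"))
    expect_equal(pinn_loss_residual(z, z, rep(0, 6), z, z,
                                    matrix(c(1, 0.05, 0.2, 1), 2, 4,
                                           byrow = TRUE), 0.58,
                                    v)$value, 0)
  expect_equal(pinn_loss_boundary(c(0, 0))$value, 0)
  expect_equal(pinn_loss_nonneg(matrix(1, 2, 5))$value, 0)
  vals <- c(-0.1, rep(0.5, 9))
  expect_equal(pinn_loss_nonneg(vals)$per_pixel, 0.01 / 10)
})

test_that("the exact ODE solution annihilates the residual loss", {
  g <- default_grid()
  aif <- default_aif(g)
  p <- c(1.0, 0.05, 0.2, 1.5)
  sol <- solve_2cxm(p, aif, g)
  s <- max(aif)
  sigma_t <- sd(g$t)
  # derivatives from the governing equations themselves (exact)
  dCp <- (p[1] * (aif - sol$Cp) + p[4] * (sol$Ce - sol$Cp)) / p[2]
  dCe <- p[4] * (sol$Cp - sol$Ce) / p[3]
  cp_hat <- rbind(sol$Cp / s); ce_hat <- rbind(sol$Ce / s)
  dcp <- rbind(dCp * sigma_t / s); dce <- rbind(dCe * sigma_t / s)
  for (v in c("2cxm", "reduced", "combined")) {
    lr <- pinn_loss_residual(cp_hat, ce_hat, aif / s, dcp, dce,
                             rbind(p), sigma_t, v)
    expect_lt(lr$value, 1e-12, label = paste("residual loss,", v))
  }
})

test_that("short training decreases the data loss and keeps parameters positive", {
  d <- tiny_dro()
  fit <- fit_pinn(d, variant = "combined",
                  control = training_config(iterations = 1000,
                                            log_every = 100), seed = 1)
  lg <- fit$log
  expect_lt(lg$loss_data[lg$iter == 1000], lg$loss_data[lg$iter == 1])
  expect_true(all(fit$params > 0))
  expect_true(all(is.finite(as.matrix(lg[-1]))))
  expect_true(all(lg$loss_data >= 0 & lg$loss_residual >= 0 &
                    lg$loss_boundary >= 0 & lg$loss_nonneg >= 0))
  # descent on average: final total below the iteration-100 total
  expect_lte(lg$loss_total[lg$iter == 1000],
             lg$loss_total[lg$iter == 100])
})

test_that("training is reproducible under a fixed seed", {
  d <- tiny_dro()
  ctl <- training_config(iterations = 300, log_every = 100)
  f1 <- fit_pinn(d, variant = "2cxm", control = ctl, seed = 5)
  f2 <- fit_pinn(d, variant = "2cxm", control = ctl, seed = 5)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$params, f2$params)
  f3 <- fit_pinn(d, variant = "2cxm", control = ctl, seed = 6)
  expect_false(identical(f1$params, f3$params))
})

test_that("zero loss weights freeze the model", {
  d <- tiny_dro()
  fit <- fit_pinn(d, variant = "combined",
                  weights = loss_weights(0, 0, 0, 0),
                  control = training_config(iterations = 200,
                                            log_every = 50), seed = 1)
  expect_true(all(fit$log$loss_total == 0))
  # parameters stay at the initial values (single-precision round trip)
  expect_equal(unname(fit$params),
               matrix(c(1, 0.05, 0.2, 1), 16, 4, byrow = TRUE),
               tolerance = 1e-6)
})

test_that("prediction with frozen statistics is a function of time only", {
  d <- tiny_dro()
  fit <- fit_pinn(d, variant = "combined",
                  control = training_config(iterations = 200,
                                            log_every = 100), seed = 1)
  fw1 <- pinn_forward(fit, d$t[1:10])
  fw2 <- pinn_forward(fit, d$t[1:50])
  expect_equal(fw1$Cp_hat, fw2$Cp_hat[, 1:10], tolerance = 1e-12)
  pr <- predict(fit)
  expect_equal(dim(pr), c(16, 100))
})
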