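# Shared fixtures, all generated in code.

default_grid <- function() time_grid(2, 0.02)

default_aif <- function(grid = default_grid()) gamma_variate_aif(grid$t)

# Tiny DRO: 2 x 2 grid of 2 x 2 pixel blocks, 4 parameter combinations,
# K = 16 pixels in one slice.
tiny_dro_config <- function(snr = 17.5, seed = 1)
  dro_config(Fp_values = c(0.5, 1.5), vp_values = 0.05, ve_values = 0.2,
             PS_values = c(0.5, 1.5), block = c(2, 2, 1), snr = snr,
             seed = seed)

tiny_dro <- function(...) simulate_dro(tiny_dro_config(...))

gt_matrix <- function(dro)
  cbind(Fp = as.vector(dro$gt$Fp), vp = as.vector(dro$gt$vp),
        ve = as.vector(dro$gt$ve), PS = as.vector(dro$gt$PS))

# Reference 2CXM solution by an independent adaptive integrator (deSolve
# lsoda at tight tolerance), treating the AIF as piecewise linear exactly
# as the package solver does.
solve_2cxm_desolve <- function(params, aif, t) {
  p <- unname(unlist(params)[c(1, 2, 3, 4)])
  af <- stats::approxfun(t, aif, rule = 2)
  rhs <- function(tt, y, parms)
    list(c((p[1] * (af(tt) - y[1]) + p[4] * (y[2] - y[1])) / p[2],
           p[4] * (y[1] - y[2]) / p[3]))
  o <- deSolve::ode(c(0, 0), t, rhs, NULL, method = "lsoda",
                    rtol = 1e-10, atol = 1e-12)
  list(Cp = o[, 2], Ce = o[, 3], Cmyo = p[2] * o[, 2] + p[3] * o[, 3])
}

# Random small network + data batch for engine-level tests.
random_pinn_setup <- function(K = 3, B1 = 12, Nr = 7, units = 8,
                              seed = 42) {
  set.seed(seed)
  t <- seq(0, 1.98, length.out = B1)
  mu_t <- mean(t); sigma_t <- sd(t)
  list(
    K = K, B1 = B1, Nr = Nr,
    t = t, mu_t = mu_t, sigma_t = sigma_t,
    tau_obs = (t - mu_t) / sigma_t,
    tau0 = (0 - mu_t) / sigma_t,
    tau_col = sort(runif(Nr, (0 - mu_t) / sigma_t,
                         (max(t) - mu_t) / sigma_t)),
    cobs = matrix(runif(K * B1), K, B1),
    aifobs = runif(B1),
    net = cxmpinn:::init_network(network_config(2, units), K),
    logk = matrix(log(c(1, 0.05, 0.2, 1)), K, 4, byrow = TRUE) +
      matrix(rnorm(K * 4, 0, 0.1), K, 4),
    wts = c(10, 1, 1, 1))
}

pinn_step <- function(s, variant, use_stats = FALSE, bn = NULL) {
  if (is.null(bn)) bn <- list(mu = list(), sd = list())
  cxmpinn:::pinn_step_cpp(s$net, s$logk, s$tau_obs, s$cobs, s$aifobs,
                          s$tau_col, s$tau0, 1 / s$sigma_t, s$wts,
                          cxmpinn:::variant_code(variant), use_stats,
                          bn$mu, bn$sd)
}
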