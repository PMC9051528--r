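#' Loss-term weights for PINN training
#'
#' @param wC weight of the data-fidelity term (default 10).
#' @param wr weight of the ODE-residual term.
#' @param wb weight of the zero-concentration initial-condition term.
#' @param wreg weight of the non-negativity regulariser.
#' @return Object of class `loss_weights`.
#' @export
loss_weights <- function(wC = 10, wr = 1, wb = 1, wreg = 1) {
  w <- c(wC = wC, wr = wr, wb = wb, wreg = wreg)
  if (any(w < 0)) stop("loss weights must be non-negative")
  structure(as.list(w), class = "loss_weights")
}

#' Network architecture for the PINN
#'
#' A fully-connected network mapping standardised time to the normalised
#' plasma and interstitial concentrations of every pixel plus the AIF
#' (`2K + 1` outputs).  Each hidden layer is dense, tanh, then batch
#' normalisation; weights are Glorot-uniform initialised.
#'
#' @param hidden_layers number of hidden layers.
#' @param units units per hidden layer.
#' @return Object of class `network_config`.
#' @export
network_config <- function(hidden_layers = 2, units = 32) {
  if (hidden_layers < 1 || units < 1)
    stop("need at least one hidden layer and one unit")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 units = as.integer(units)), class = "network_config")
}

#' Training schedule and options for the PINN
#'
#' @param iterations Adam iterations (default 25000).
#' @param lr initial learning rate.
#' @param lr_decay_every iterations between learning-rate reductions.
#' @param lr_decay_factor division factor at each reduction.
#' @param n_collocation number of collocation points at which the ODE
#'   residuals are enforced, drawn uniformly over the observed time span.
#' @param resample_collocation redraw the collocation points every
#'   iteration (default `TRUE`).  With a fixed set the network can
#'   satisfy the residuals at the sampled times while violating the ODEs
#'   in between; resampling enforces the physics over the whole domain
#'   and measurably improves parameter recovery.  Set to `FALSE` for a
#'   fixed seeded set.
#' @param log_every record the loss terms and volume-mean parameters every
#'   this many iterations.
#' @param precision `"single"` (default, fast) or `"double"`.
#' @param train_kinetics update the log-parameterised kinetic parameters
#'   (disable to solve the forward problem with frozen parameters).
#' @param train_network update the network weights.
#' @param init_params initial kinetic parameter values (one set for all
#'   pixels, or a pixels-by-4 matrix), within the physiological range.
#' @return Object of class `training_config`.
#' @export
training_config <- function(iterations = 25000, lr = 0.01,
                            lr_decay_every = 10000, lr_decay_factor = 10,
                            n_collocation = 500,
                            resample_collocation = TRUE, log_every = 100,
                            precision = c("single", "double"),
                            train_kinetics = TRUE, train_network = TRUE,
                            init_params = c(Fp = 1, vp = 0.05, ve = 0.2,
                                            PS = 1)) {
  precision <- match.arg(precision)
  if (iterations < 1) stop("iterations must be positive")
  if (n_collocation < 1) stop("n_collocation must be positive")
  structure(list(iterations = as.integer(iterations), lr = lr,
                 lr_decay_every = as.integer(lr_decay_every),
                 lr_decay_factor = lr_decay_factor,
                 n_collocation = as.integer(n_collocation),
                 resample_collocation = resample_collocation,
                 log_every = as.integer(log_every), precision = precision,
                 train_kinetics = train_kinetics,
                 train_network = train_network,
                 init_params = init_params), class = "training_config")
}

# Glorot-uniform initialisation of the network parameter list.
init_network <- function(net_cfg, K) {
  sizes <- c(1, rep(net_cfg$units, net_cfg$hidden_layers), 2 * K + 1)
  L <- net_cfg$hidden_layers
  W <- vector("list", L + 1); b <- vector("list", L + 1)
  g <- vector("list", L); be <- vector("list", L)
  for (l in seq_len(L + 1)) {
    fin <- sizes[l]; fout <- sizes[l + 1]
    lim <- sqrt(6 / (fin + fout))
    W[[l]] <- matrix(runif(fin * fout, -lim, lim), fout, fin)
    b[[l]] <- numeric(fout)
  }
  for (l in seq_len(L)) {
    g[[l]] <- rep(1, sizes[l + 1])
    be[[l]] <- numeric(sizes[l + 1])
  }
  list(W = W, b = b, gamma = g, beta = be)
}

variant_code <- function(variant) {
  match(variant, c("2cxm", "reduced", "combined")) - 1L
}

#' Fit 2CXM parameters with a physics-informed neural network
#'
#' Trains a network that maps time to the plasma and interstitial
#' concentrations of every pixel plus the AIF, under a weighted loss with
#' four terms: squared misfit to the observed (normalised) tissue curves
#' and AIF, mean squared ODE residuals at collocation points, squared
#' predictions at `t = 0`, and the mean squared negative part of the
#' predicted concentrations.  The kinetic parameters enter the residuals
#' (and the tissue-curve assembly `Cmyo = vp Cp + ve Ce`) as per-pixel
#' trainables in log space, so the returned estimates are strictly
#' positive.  Inputs are standardised in time and concentrations are
#' scaled by the AIF peak; the residuals are evaluated in these rescaled
#' variables with the corresponding chain-rule factors.
#'
#' The residual `variant` selects which ODE residuals are enforced:
#' `"2cxm"` uses the plasma and interstitium compartment residuals,
#' `"reduced"` only the summed tissue conservation law (which weights
#' plasma flow most heavily), and `"combined"` (default) all three.
#'
#' @param x a `dro_volume` (use [dro_subset] to restrict it first), or a
#'   pixels-by-timepoints matrix of observed tissue curves (mM).
#' @param ... passed on to methods.
#' @return Object of class `c("pinn_fit", "cxm_fit")`: estimated `params`
#'   (pixels x 4) and `maps`, the training `log` (loss terms and
#'   volume-mean parameters per logging step), the trained network, the
#'   normalisation constants, and the configuration used.
#' @seealso [fit_nlls] for the conventional pixelwise baseline.
#' @export
fit_pinn <- function(x, ...) UseMethod("fit_pinn")

#' @rdname fit_pinn
#' @param aif AIF on the same grid, mM (noiseless or measured).
#' @param grid a [time_grid] or time vector, minutes.
#' @param variant residual variant: `"combined"` (default), `"2cxm"` or
#'   `"reduced"`.
#' @param weights a [loss_weights] object.
#' @param net a [network_config].
#' @param control a [training_config].
#' @param seed integer seed for initialisation and collocation sampling.
#' @param dims optional spatial dimensions used to shape parameter maps.
#' @export
fit_pinn.default <- function(x, aif, grid,
                             variant = c("combined", "2cxm", "reduced"),
                             weights = loss_weights(),
                             net = network_config(),
                             control = training_config(), seed = 1,
                             dims = NULL, ...) {
  variant <- match.arg(variant)
  t <- grid_times(grid)
  curves <- as.matrix(x)
  if (ncol(curves) != length(t))
    stop("curves must have one column per time point")
  if (length(aif) != length(t)) stop("aif length must match the grid")
  if (!all(is.finite(curves)) || !all(is.finite(aif)))
    stop("curves and AIF must be finite")
  K <- nrow(curves)

  # normalisation: standardised time, concentrations scaled by the AIF peak
  mu_t <- mean(t); sigma_t <- sd(t)
  c_scale <- max(aif)
  if (c_scale <= 0) stop("AIF peak must be positive")
  tau_obs <- (t - mu_t) / sigma_t
  tau0 <- (0 - mu_t) / sigma_t

  set.seed(seed)
  t_col <- runif(control$n_collocation, min(t), max(t))
  tau_col <- (t_col - mu_t) / sigma_t
  net0 <- init_network(net, K)

  ip <- control$init_params
  logk0 <- if (is.matrix(ip)) {
    if (nrow(ip) != K || ncol(ip) != 4)
      stop("init_params matrix must be pixels x 4")
    log(ip)
  } else matrix(log(as_param_vec(ip)), K, 4, byrow = TRUE)

  t0 <- proc.time()[["elapsed"]]
  res <- pinn_train_cpp(net0, logk0, tau_obs, curves / c_scale,
                        aif / c_scale, tau_col, tau0, 1 / sigma_t,
                        unlist(weights), variant_code(variant),
                        control$iterations, control$lr,
                        control$lr_decay_every, control$lr_decay_factor,
                        control$log_every, control$train_network,
                        control$train_kinetics,
                        control$resample_collocation,
                        min(tau_obs), max(tau_obs), seed,
                        control$precision == "single")
  runtime <- proc.time()[["elapsed"]] - t0

  params <- exp(res$logk)
  colnames(params) <- c("Fp", "vp", "ve", "PS")
  maps <- NULL
  if (!is.null(dims))
    maps <- lapply(setNames(1:4, colnames(params)),
                   function(j) array(params[, j], dim = dims))
  log_df <- as.data.frame(res$log)
  names(log_df) <- c("iter", "loss_data", "loss_residual",
                     "loss_boundary", "loss_nonneg", "loss_aif",
                     "loss_total", "mean_Fp", "mean_vp", "mean_ve",
                     "mean_PS")
  structure(list(params = params, maps = maps, dims = dims, log = log_df,
                 net = res$net, bn_mu = res$bn_mu, bn_sd = res$bn_sd,
                 norm = list(mu_t = mu_t, sigma_t = sigma_t,
                             c_scale = c_scale),
                 t = t, aif = aif, K = K, variant = variant,
                 weights = weights, net_config = net, control = control,
                 seed = seed, method = paste0("pinn_", variant),
                 runtime = runtime),
            class = c("pinn_fit", "cxm_fit"))
}

#' @rdname fit_pinn
#' @param which fit the `"noisy"` (default) or `"clean"` curves.
#' @export
fit_pinn.dro_volume <- function(x, variant = c("combined", "2cxm",
                                               "reduced"),
                                which = c("noisy", "clean"), ...) {
  variant <- match.arg(variant)
  which <- match.arg(which)
  curves <- dro_curve_matrix(x, which)
  fit_pinn.default(curves, x$aif, x$t, variant = variant,
                   dims = dim(x$curves_clean)[1:3], ...)
}

#' Evaluate a trained PINN at arbitrary times
#'
#' Returns the network outputs on the normalised scale together with their
#' time derivatives with respect to standardised time (forward-mode
#' tangents).  By default the batch-normalisation statistics stored from
#' the final training batch are reused (the prediction convention; the
#' network is fit per dataset, never deployed on new data), so the mapping
#' is a fixed deterministic function of time.
#'
#' @param fit a `pinn_fit`.
#' @param t times, minutes (default: the observed grid).
#' @param frozen_stats reuse training batch-norm statistics (default) or
#'   recompute them from this batch.
#' @return List with `Cp_hat`, `Ce_hat` (pixels x times), `Caif_hat`
#'   (times), the tangents `dCp_dtau`, `dCe_dtau`, `dCaif_dtau`, and the
#'   standardised times `tau`.
#' @export
pinn_forward <- function(fit, t = NULL, frozen_stats = TRUE) {
  stopifnot(inherits(fit, "pinn_fit"))
  if (is.null(t)) t <- fit$t
  tau <- (t - fit$norm$mu_t) / fit$norm$sigma_t
  ev <- pinn_eval_cpp(fit$net, tau, frozen_stats, fit$bn_mu, fit$bn_sd)
  K <- fit$K
  list(Cp_hat = ev$U[seq_len(K), , drop = FALSE],
       Ce_hat = ev$U[K + seq_len(K), , drop = FALSE],
       Caif_hat = ev$U[2 * K + 1, ],
       dCp_dtau = ev$V[seq_len(K), , drop = FALSE],
       dCe_dtau = ev$V[K + seq_len(K), , drop = FALSE],
       dCaif_dtau = ev$V[2 * K + 1, ], tau = tau)
}

#' Loss terms of the PINN objective
#'
#' Reference implementations of the four loss terms, exposed for
#' inspection and testing.  `pinn_loss_data` is the per-pixel sum of
#' squared differences between predicted and observed (normalised)
#' concentrations; `pinn_loss_residual` is the per-pixel mean over
#' collocation points of the squared ODE residuals of the chosen variant,
#' evaluated in the rescaled variables (`dC/dtau` tangents and the
#' `1/sigma_t` chain-rule factor); `pinn_loss_boundary` is the squared
#' prediction at `t = 0`; `pinn_loss_nonneg` the mean squared negative
#' part.  Each returns the per-pixel vector and its pixel mean `value` (the
#' form entering the total objective).
#'
#' @param pred,obs matrices (pixels x times) of predicted and observed
#'   normalised concentrations (or vectors for a single pixel / the AIF).
#' @return List with `value` (scalar) and `per_pixel` (vector).
#' @export
pinn_loss_data <- function(pred, obs) {
  pred <- rbind(pred); obs <- rbind(obs)
  if (!all(dim(pred) == dim(obs))) stop("prediction/observation mismatch")
  pp <- unname(rowSums((pred - obs)^2))
  list(value = mean(pp), per_pixel = pp)
}

#' @rdname pinn_loss_data
#' @param Cp_hat,Ce_hat,dCp_dtau,dCe_dtau network outputs and tangents at
#'   the collocation points (pixels x points).
#' @param Caif_hat AIF prediction at the collocation points.
#' @param params kinetic parameter matrix (pixels x 4) on the natural
#'   scale.
#' @param sigma_t time standardisation scale (minutes).
#' @param variant `"2cxm"`, `"reduced"` or `"combined"`.
#' @export
pinn_loss_residual <- function(Cp_hat, Ce_hat, Caif_hat, dCp_dtau,
                               dCe_dtau, params, sigma_t,
                               variant = c("combined", "2cxm",
                                           "reduced")) {
  variant <- match.arg(variant)
  Cp_hat <- rbind(Cp_hat); Ce_hat <- rbind(Ce_hat)
  dCp_dtau <- rbind(dCp_dtau); dCe_dtau <- rbind(dCe_dtau)
  params <- rbind(params)
  kappa <- 1 / sigma_t
  Fp <- params[, 1]; vp <- params[, 2]; ve <- params[, 3]; PS <- params[, 4]
  da <- sweep(-Cp_hat, 2, Caif_hat, "+")      # CAIF - Cp
  dpe <- Ce_hat - Cp_hat                      # Ce - Cp
  sq <- 0
  if (variant != "reduced") {
    rp <- dCp_dtau * (vp * kappa) - dpe * PS - da * Fp
    re <- dCe_dtau * (ve * kappa) + dpe * PS
    sq <- sq + rp^2 + re^2
  }
  if (variant != "2cxm") {
    rm <- dCp_dtau * (vp * kappa) + dCe_dtau * (ve * kappa) - da * Fp
    sq <- sq + rm^2
  }
  pp <- unname(rowMeans(rbind(sq)))
  list(value = mean(pp), per_pixel = pp)
}

#' @rdname pinn_loss_data
#' @param at_zero vector (or pixels x 1 matrix) of predicted normalised
#'   concentrations at `t = 0`.
#' @export
pinn_loss_boundary <- function(at_zero) {
  pp <- as.numeric(at_zero)^2
  list(value = mean(pp), per_pixel = pp)
}

#' @rdname pinn_loss_data
#' @param values predicted normalised concentrations at the collocation
#'   points (pixels x points).
#' @export
pinn_loss_nonneg <- function(values) {
  values <- rbind(values)
  pp <- unname(rowMeans(pmin(values, 0)^2))
  list(value = mean(pp), per_pixel = pp)
}
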