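#' Configuration for pixelwise NLLS fitting
#'
#' Bound-constrained quasi-Newton (L-BFGS-B) minimisation of the sum of
#' squared differences between the 2CXM tissue curve and the observed
#' curve.  All parameters are constrained positive with `vp, ve <= 1`; the
#' small lower bounds on `vp` and `ve` keep the ODE system regular.  With
#' `multi_start > 1`, additional random starting points are drawn
#' (log-uniform within physiological ranges, once per fit so results do not
#' depend on pixel order) and the best local optimum is kept.
#'
#' The default iteration budget is deliberately modest.  At typical
#' perfusion sampling rates the 2CXM likelihood has a nearly flat
#' `Fp`--`PS` ridge (the compartments equilibrate within a sampling
#' interval when `vp` is small, so only the extraction product
#' `Fp PS / (Fp + PS)` is sharply determined), and under noise the global
#' bounded optimum for low-`vp` pixels sits at implausibly high flow.  A
#' short quasi-Newton descent fits the curve and stays in the
#' physiological basin around the starting point, which is the behaviour
#' conventional pixelwise fitting exhibits in practice; raise `max_iter`
#' to optimise to convergence (useful with noiseless data or
#' `multi_start`).
#'
#' @param init starting point, named `Fp, vp, ve, PS`.
#' @param lower,upper box constraints in the same order.
#' @param max_iter L-BFGS-B iteration cap (see Details).
#' @param multi_start number of starting points (1 = single start).
#' @param seed seed for the random restarts.
#' @return Object of class `nlls_config`.
#' @export
nlls_config <- function(init = c(Fp = 1, vp = 0.05, ve = 0.2, PS = 1),
                        lower = c(Fp = 0, vp = 1e-3, ve = 1e-3, PS = 0),
                        upper = c(Fp = 10, vp = 1, ve = 1, PS = 10),
                        max_iter = 15, multi_start = 1, seed = 1) {
  if (any(lower < 0)) stop("lower bounds must be non-negative")
  if (any(upper[c(2, 3)] > 1)) stop("vp and ve upper bounds must be <= 1")
  if (any(init < lower | init > upper)) stop("init must satisfy the bounds")
  structure(list(init = init, lower = lower, upper = upper,
                 max_iter = max_iter, multi_start = multi_start,
                 seed = seed), class = "nlls_config")
}

# Multi-start points: log-uniform within broad physiological ranges.
nlls_starts <- function(cfg) {
  if (cfg$multi_start <= 1) return(matrix(cfg$init, nrow = 1))
  set.seed(cfg$seed)
  lo <- c(0.2, 0.01, 0.05, 0.2)
  hi <- c(4, 0.3, 0.6, 4)
  extra <- t(replicate(cfg$multi_start - 1,
                       exp(runif(4, log(lo), log(hi)))))
  rbind(matrix(cfg$init, nrow = 1), extra)
}

#' Fit the 2CXM to a single concentration curve
#'
#' @param curve observed tissue curve, mM.
#' @param aif AIF on the same grid, mM.
#' @param grid a [time_grid] or time vector, minutes.
#' @param cfg an [nlls_config].
#' @param starts optional pre-computed matrix of starting points (used by
#'   [fit_nlls] so the restart draw happens once per volume).
#' @return List with `params` (named vector), `sse`, and `convergence`
#'   (0 = converged; non-zero optimiser codes keep the best iterate found).
#' @export
fit_pixel <- function(curve, aif, grid, cfg = nlls_config(),
                      starts = NULL) {
  t <- grid_times(grid)
  curve <- as.numeric(curve)
  if (length(curve) != length(t)) stop("curve length must match the grid")
  if (all(is.na(curve))) stop("curve is all-NA")
  if (!all(is.finite(curve))) stop("curve contains non-finite values")
  if (is.null(starts)) starts <- nlls_starts(cfg)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    fit <- tryCatch(
      optim(starts[s, ], function(p) cxm_sse_cpp(p, t, aif, curve),
            gr = function(p) cxm_sse_grad_cpp(p, t, aif, curve, 1e-5),
            method = "L-BFGS-B", lower = cfg$lower, upper = cfg$upper,
            control = list(maxit = cfg$max_iter,
                           parscale = c(1, 0.05, 0.2, 1))),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    p0 <- starts[1, ]
    return(list(params = setNames(p0, c("Fp", "vp", "ve", "PS")),
                sse = cxm_sse_cpp(p0, t, aif, curve), convergence = 99L))
  }
  list(params = setNames(best$par, c("Fp", "vp", "ve", "PS")),
       sse = best$value, convergence = best$convergence)
}

#' Pixelwise NLLS estimation of 2CXM parameter maps
#'
#' Applies [fit_pixel] independently to every pixel.  Pixels are fitted in
#' storage order but share the same starting points, so results are
#' independent of ordering.  Optimiser failures are recorded per pixel and
#' never abort the volume.
#'
#' @param x a `dro_volume`, or a pixels-by-timepoints matrix of observed
#'   tissue curves (mM).
#' @param ... passed on to methods.
#' @return Object of class `c("nlls_fit", "cxm_fit")` with the estimated
#'   parameter matrix (`params`, pixels x 4), per-pixel `sse` and
#'   `convergence`, parameter `maps` when the spatial dimensions are known,
#'   and the fitting configuration.
#' @export
fit_nlls <- function(x, ...) UseMethod("fit_nlls")

#' @rdname fit_nlls
#' @param aif AIF on the same grid, mM.
#' @param grid a [time_grid] or time vector, minutes.
#' @param cfg an [nlls_config].
#' @param dims optional spatial dimensions used to shape parameter maps.
#' @param verbose print progress every 1000 pixels.
#' @export
fit_nlls.default <- function(x, aif, grid, cfg = nlls_config(),
                             dims = NULL, verbose = FALSE, ...) {
  t <- grid_times(grid)
  curves <- as.matrix(x)
  K <- nrow(curves)
  starts <- nlls_starts(cfg)
  params <- matrix(NA_real_, K, 4,
                   dimnames = list(NULL, c("Fp", "vp", "ve", "PS")))
  sse <- numeric(K)
  conv <- integer(K)
  t0 <- proc.time()[["elapsed"]]
  for (k in seq_len(K)) {
    fk <- fit_pixel(curves[k, ], aif, t, cfg, starts = starts)
    params[k, ] <- fk$params
    sse[k] <- fk$sse
    conv[k] <- fk$convergence
    if (verbose && k %% 1000 == 0)
      message(sprintf("  fitted %d / %d pixels", k, K))
  }
  maps <- NULL
  if (!is.null(dims))
    maps <- lapply(setNames(1:4, colnames(params)),
                   function(j) array(params[, j], dim = dims))
  structure(list(params = params, sse = sse, convergence = conv,
                 maps = maps, dims = dims, t = t, aif = aif, config = cfg,
                 method = "nlls",
                 runtime = proc.time()[["elapsed"]] - t0),
            class = c("nlls_fit", "cxm_fit"))
}

#' @rdname fit_nlls
#' @param which fit the `"noisy"` (default) or `"clean"` curves.
#' @export
fit_nlls.dro_volume <- function(x, cfg = nlls_config(),
                                which = c("noisy", "clean"),
                                verbose = FALSE, ...) {
  which <- match.arg(which)
  curves <- dro_curve_matrix(x, which)
  fit_nlls.default(curves, x$aif, x$t, cfg,
                   dims = dim(x$curves_clean)[1:3], verbose = verbose)
}
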