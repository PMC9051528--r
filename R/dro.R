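#' Gamma-variate arterial input function
#'
#' First-pass bolus model in the peak-normalised parameterisation
#' \deqn{C_{AIF}(t) = A \left(\frac{t - t_0}{\alpha\beta}\right)^{\alpha}
#'   \exp\!\left(\alpha - \frac{t - t_0}{\beta}\right)}
#' for `t > t0` and zero before arrival, so the curve peaks at
#' `t = t0 + alpha * beta` with value `amplitude`.  The defaults describe a
#' sharp first-pass bolus typical of stress myocardial perfusion imaging.
#'
#' @param t times, minutes.
#' @param amplitude peak concentration, mM.
#' @param t0 bolus arrival delay, minutes.
#' @param alpha dimensionless shape parameter.
#' @param beta timescale, minutes.
#' @return AIF values, mM.
#' @examples
#' g <- time_grid()
#' plot(g$t, gamma_variate_aif(g$t), type = "l")
#' @export
gamma_variate_aif <- function(t, amplitude = 5, t0 = 0.1, alpha = 2.5,
                              beta = 0.08) {
  if (amplitude <= 0 || alpha <= 0 || beta <= 0 || t0 < 0)
    stop("gamma-variate parameters must be positive (t0 non-negative)")
  u <- (t - t0) / beta
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- amplitude * (u[pos] / alpha)^alpha * exp(alpha - u[pos])
  out
}

#' Configuration of the digital reference object
#'
#' The DRO tiles a pixel volume with blocks of constant kinetic parameters,
#' one block per element of the Cartesian product of the four value lists.
#' With the default lists (4 x 4 x 3 x 3 = 144 combinations) and 10x10x1
#' blocks the volume is 40 x 120 x 3: `Fp` varies across the 4 row blocks,
#' the 12 column blocks run over `(vp, ve)` with `vp` fastest, and `PS` is
#' constant within each of the 3 slices.  Tissue curves are simulated on a
#' half-open grid `[0, T)` and corrupted by additive i.i.d. Gaussian noise
#' scaled to a target peak signal-to-noise ratio.
#'
#' @param Fp_values,vp_values,ve_values,PS_values parameter value lists.
#' @param block block shape (pixels) as an integer triple.
#' @param dt temporal resolution, minutes.
#' @param T time span, minutes.
#' @param snr target signal-to-noise ratio (peak tissue signal over noise
#'   standard deviation); `Inf` disables noise.
#' @param snr_mode `"per_pixel"` (default): each final curve has the
#'   stated SNR, i.e. sigma is set per pixel from that pixel's clean peak;
#'   `"global"`: one sigma for the whole volume, set from the volume-mean
#'   peak (under which low-amplitude blocks are effectively unfittable).
#' @param seed integer seed for the noise.
#' @param aif list of [gamma_variate_aif] parameters.
#' @return Object of class `dro_config`.
#' @export
dro_config <- function(Fp_values = c(0.5, 1.0, 1.5, 2.0),
                       vp_values = c(0.02, 0.05, 0.1, 0.2),
                       ve_values = c(0.1, 0.2, 0.5),
                       PS_values = c(0.5, 1.5, 2.5),
                       block = c(10, 10, 1),
                       dt = 0.02, T = 2, snr = 17.5,
                       snr_mode = c("per_pixel", "global"),
                       seed = 1,
                       aif = list(amplitude = 5, t0 = 0.1, alpha = 2.5,
                                  beta = 0.08)) {
  snr_mode <- match.arg(snr_mode)
  if (any(c(length(Fp_values), length(vp_values), length(ve_values),
            length(PS_values)) < 1))
    stop("parameter value lists must be non-empty")
  if (length(block) != 3 || any(block < 1))
    stop("block must be a positive integer triple")
  if (snr <= 0) stop("snr must be positive")
  structure(list(Fp_values = Fp_values, vp_values = vp_values,
                 ve_values = ve_values, PS_values = PS_values,
                 block = as.integer(block), dt = dt, T = T, snr = snr,
                 snr_mode = snr_mode, seed = seed, aif = aif),
            class = "dro_config")
}

dro_shape <- function(cfg) {
  c(cfg$block[1] * length(cfg$Fp_values),
    cfg$block[2] * length(cfg$vp_values) * length(cfg$ve_values),
    cfg$block[3] * length(cfg$PS_values))
}

#' Ground-truth parameter maps of the DRO
#'
#' Lays the Cartesian product of the configured parameter lists out
#' block-wise: `Fp` varies fastest (row blocks), then `vp`, then `ve`
#' (column blocks), with `PS` slowest (slices), so that `PS` is constant
#' within a slice.
#'
#' @param cfg a [dro_config].
#' @return Named list of four arrays (`Fp`, `vp`, `ve`, `PS`) with the
#'   volume dimensions.
#' @export
build_parameter_maps <- function(cfg) {
  shape <- dro_shape(cfg)
  if (any(shape %% cfg$block != 0))
    stop("volume shape is not divisible by the block shape")
  nF <- length(cfg$Fp_values); nv <- length(cfg$vp_values)
  ne <- length(cfg$ve_values); nP <- length(cfg$PS_values)
  maps <- lapply(1:4, function(i) array(NA_real_, dim = shape))
  names(maps) <- c("Fp", "vp", "ve", "PS")
  bx <- cfg$block[1]; by <- cfg$block[2]; bz <- cfg$block[3]
  for (iP in seq_len(nP)) for (ie in seq_len(ne)) for (iv in seq_len(nv))
    for (iF in seq_len(nF)) {
      xs <- (iF - 1) * bx + seq_len(bx)
      ys <- ((ie - 1) * nv + (iv - 1)) * by + seq_len(by)
      zs <- (iP - 1) * bz + seq_len(bz)
      maps$Fp[xs, ys, zs] <- cfg$Fp_values[iF]
      maps$vp[xs, ys, zs] <- cfg$vp_values[iv]
      maps$ve[xs, ys, zs] <- cfg$ve_values[ie]
      maps$PS[xs, ys, zs] <- cfg$PS_values[iP]
    }
  maps
}

#' Simulate the digital reference object
#'
#' Builds the ground-truth parameter maps, solves the 2CXM once per unique
#' parameter combination (pixels within a block share their clean curve),
#' and adds seeded Gaussian noise scaled so the peak tissue concentration
#' over the volume, divided by the noise standard deviation, equals the
#' configured SNR.
#'
#' @param cfg a [dro_config].
#' @return Object of class `dro_volume`: ground-truth maps `gt`, 4-d arrays
#'   `curves_clean` and `curves_noisy` (x, y, z, time; mM), the noiseless
#'   `aif`, time vector `t`, `noise_sigma`, and the configuration.
#' @examples
#' dro <- simulate_dro(dro_config(Fp_values = 1, vp_values = 0.05,
#'                                ve_values = 0.2, PS_values = 1,
#'                                block = c(2, 2, 1)))
#' @export
simulate_dro <- function(cfg = dro_config()) {
  stopifnot(inherits(cfg, "dro_config"))
  shape <- dro_shape(cfg)
  grid <- time_grid(cfg$T, cfg$dt)
  aif <- do.call(gamma_variate_aif, c(list(t = grid$t), cfg$aif))
  maps <- build_parameter_maps(cfg)
  P <- cbind(as.vector(maps$Fp), as.vector(maps$vp),
             as.vector(maps$ve), as.vector(maps$PS))
  combos <- unique(P)
  idx <- match(apply(P, 1, paste, collapse = "\r"),
               apply(combos, 1, paste, collapse = "\r"))
  curves_u <- cxm_cmyo_many_cpp(combos, grid$t, aif)
  clean <- curves_u[idx, , drop = FALSE]
  nt <- length(grid$t)
  peaks <- apply(clean, 1, max)
  if (is.finite(cfg$snr)) {
    sigma <- if (cfg$snr_mode == "global") mean(peaks) / cfg$snr
             else peaks / cfg$snr
    set.seed(cfg$seed)
    noise <- matrix(rnorm(length(clean)), nrow = nrow(clean)) * sigma
    noisy <- clean + noise
  } else {
    sigma <- 0
    noisy <- clean
  }
  structure(list(
    gt = maps,
    curves_clean = array(clean, dim = c(shape, nt)),
    curves_noisy = array(noisy, dim = c(shape, nt)),
    aif = aif, t = grid$t, dt = cfg$dt,
    noise_sigma = sigma, n_combinations = nrow(combos),
    seed = cfg$seed, config = cfg), class = "dro_volume")
}

#' Draw a new noise realisation of an existing DRO
#'
#' Reuses the clean curves and noise level; only the Gaussian noise is
#' redrawn under the given seed.
#'
#' @param dro a [simulate_dro] result.
#' @param seed integer seed.
#' @return A `dro_volume` with new `curves_noisy` and `seed`.
#' @export
renoise <- function(dro, seed) {
  stopifnot(inherits(dro, "dro_volume"))
  dm <- dim(dro$curves_clean)
  clean <- matrix(dro$curves_clean, nrow = prod(dm[1:3]))
  set.seed(seed)
  noisy <- clean + matrix(rnorm(length(clean)), nrow = nrow(clean)) *
    dro$noise_sigma
  dro$curves_noisy <- array(noisy, dim = dm)
  dro$seed <- seed
  dro
}

#' Extract a spatial subset of a DRO
#'
#' @param dro a `dro_volume`.
#' @param rows,cols,slices index vectors into the three spatial dimensions
#'   (default: all).
#' @return A `dro_volume` restricted to the selected pixels.
#' @export
dro_subset <- function(dro, rows = NULL, cols = NULL, slices = NULL) {
  stopifnot(inherits(dro, "dro_volume"))
  dm <- dim(dro$curves_clean)
  if (is.null(rows)) rows <- seq_len(dm[1])
  if (is.null(cols)) cols <- seq_len(dm[2])
  if (is.null(slices)) slices <- seq_len(dm[3])
  dro$gt <- lapply(dro$gt, function(m) m[rows, cols, slices, drop = FALSE])
  dro$curves_clean <- dro$curves_clean[rows, cols, slices, , drop = FALSE]
  dro$curves_noisy <- dro$curves_noisy[rows, cols, slices, , drop = FALSE]
  if (is.matrix(dro$noise_sigma) || length(dro$noise_sigma) > 1) {
    ns <- array(dro$noise_sigma, dim = dm[1:3])
    dro$noise_sigma <- as.vector(ns[rows, cols, slices])
  }
  dro
}

# Flatten the spatial dimensions of a DRO curve array to pixels x time.
dro_curve_matrix <- function(dro, which = c("noisy", "clean")) {
  which <- match.arg(which)
  a <- if (which == "noisy") dro$curves_noisy else dro$curves_clean
  dm <- dim(a)
  matrix(a, nrow = prod(dm[1:3]))
}

#' @export
print.dro_volume <- function(x, ...) {
  dm <- dim(x$curves_clean)
  cat("2CXM digital reference object\n")
  cat(sprintf("  volume: %d x %d x %d pixels, %d time points (dt = %g min)\n",
              dm[1], dm[2], dm[3], dm[4], x$dt))
  cat(sprintf("  unique parameter combinations: %d\n", x$n_combinations))
  cat(sprintf("  noise sigma: %s mM (seed %d)\n",
              format(mean(x$noise_sigma), digits = 4), x$seed))
  invisible(x)
}

#' @export
plot.dro_volume <- function(x, slice = 1, pixel = NULL, ...) {
  if (is.null(pixel)) {
    image(x$gt$Fp[, , slice], main = sprintf("Fp ground truth, slice %d",
                                             slice),
          col = hcl.colors(64, "viridis"), ...)
  } else {
    matplot(x$t, cbind(x$curves_noisy[pixel[1], pixel[2], slice, ],
                       x$curves_clean[pixel[1], pixel[2], slice, ]),
            type = "l", lty = c(1, 2), col = c("grey40", "red"),
            xlab = "time (min)", ylab = "Cmyo (mM)", ...)
    legend("topright", c("noisy", "clean"), lty = c(1, 2),
           col = c("grey40", "red"), bty = "n")
  }
  invisible(x)
}
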