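#' Normalised mean square error
#'
#' Mean squared error between estimate and ground truth, divided by the
#' mean squared ground truth, so an all-zero estimate scores 1 and the
#' metric is invariant to a common rescaling of both maps.
#'
#' @param est estimated values (vector, matrix or array).
#' @param gt ground-truth values of the same shape.
#' @return Scalar NMSE (>= 0).
#' @export
nmse <- function(est, gt) {
  if (length(est) != length(gt)) stop("est and gt must match in length")
  mean((as.numeric(est) - as.numeric(gt))^2) / mean(as.numeric(gt)^2)
}

# Moving-window mean over w x w windows, valid region only.
win_mean <- function(X, w) {
  m <- nrow(X); n <- ncol(X)
  cs <- matrix(0, m + 1, n + 1)
  cs[-1, -1] <- apply(apply(X, 2, cumsum), 1, cumsum) |> t()
  i <- seq_len(m - w + 1); j <- seq_len(n - w + 1)
  (cs[i + w, j + w, drop = FALSE] - cs[i, j + w, drop = FALSE] -
     cs[i + w, j, drop = FALSE] + cs[i, j, drop = FALSE]) / (w * w)
}

#' Structural similarity index between two 2-D maps
#'
#' Mean SSIM over a sliding uniform window (default 7x7) with the standard
#' stabilisation constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2` and
#' sample-covariance normalisation; border pixels without a full window
#' are excluded.  This follows the common reference-implementation
#' convention, so values are directly comparable with the image-processing
#' literature.
#'
#' @param est estimated 2-D map (matrix).
#' @param gt ground-truth 2-D map.
#' @param data_range dynamic range `L`; defaults to `max(gt) - min(gt)`.
#' @param win odd window width (default 7).
#' @return Scalar mean SSIM in \[-1, 1\].
#' @export
ssim_map <- function(est, gt, data_range = NULL, win = 7) {
  est <- as.matrix(est); gt <- as.matrix(gt)
  if (!all(dim(est) == dim(gt))) stop("maps must share dimensions")
  if (any(dim(est) < win)) stop("maps smaller than the SSIM window")
  if (is.null(data_range)) data_range <- max(gt) - min(gt)
  if (data_range <= 0) stop("data_range must be positive")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  NP <- win * win
  cov_norm <- NP / (NP - 1)
  ux <- win_mean(est, win); uy <- win_mean(gt, win)
  uxx <- win_mean(est * est, win); uyy <- win_mean(gt * gt, win)
  uxy <- win_mean(est * gt, win)
  vx <- cov_norm * (uxx - ux^2)
  vy <- cov_norm * (uyy - uy^2)
  vxy <- cov_norm * (uxy - ux * uy)
  S <- ((2 * ux * uy + C1) * (2 * vxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(S)
}

#' Evaluate estimated parameter maps against DRO ground truth
#'
#' Computes NMSE and SSIM per kinetic parameter and per 2-D slice, plus
#' the "Total" (unweighted mean over the four parameters).  The SSIM data
#' range is the ground-truth range of that parameter over the whole
#' evaluated volume (the per-slice range degenerates to zero for the
#' parameter that is constant within a slice); when the truth is constant
#' over the volume too, its magnitude is used as the range.
#'
#' @param fit a `cxm_fit` (from [fit_nlls] or [fit_pinn]) whose maps match
#'   the reference dimensions, or a named list of four parameter arrays.
#' @param reference a `dro_volume` (possibly a [dro_subset]) or a named
#'   list of ground-truth arrays `Fp, vp, ve, PS`.
#' @return Object of class `cxm_eval`: per-slice metric arrays and the
#'   slice-averaged summary table.
#' @export
evaluate_fit <- function(fit, reference) {
  est <- if (inherits(fit, "cxm_fit")) fit$maps else fit
  gt <- if (inherits(reference, "dro_volume")) reference$gt else reference
  pars <- c("Fp", "vp", "ve", "PS")
  if (is.null(est) || !all(pars %in% names(est)))
    stop("fit does not carry parameter maps; supply spatial dims when fitting")
  d <- dim(as.array(gt$Fp))
  if (length(d) == 2) d <- c(d, 1)
  nz <- d[3]
  nm <- ss <- matrix(NA_real_, nz, 4, dimnames = list(NULL, pars))
  # shrink the SSIM window for small maps; below 3 pixels SSIM is not
  # meaningful and is reported as NA
  win <- min(7, d[1], d[2])
  if (win %% 2 == 0) win <- win - 1
  if (win < 3)
    warning("maps too small for SSIM; reporting NA")
  for (p in pars) {
    e <- array(est[[p]], dim = d); g <- array(gt[[p]], dim = d)
    dr <- max(g) - min(g)
    if (dr <= 0) dr <- max(abs(g))
    for (z in seq_len(nz)) {
      nm[z, p] <- nmse(e[, , z], g[, , z])
      ss[z, p] <- if (win >= 3)
        ssim_map(e[, , z], g[, , z], data_range = dr, win = win)
      else NA_real_
    }
  }
  summary <- data.frame(
    parameter = c(pars, "Total"),
    nmse = c(colMeans(nm), mean(colMeans(nm))),
    ssim = c(colMeans(ss), mean(colMeans(ss))))
  structure(list(nmse_slices = nm, ssim_slices = ss, summary = summary,
                 method = if (inherits(fit, "cxm_fit")) fit$method else NA),
            class = "cxm_eval")
}

#' @export
print.cxm_eval <- function(x, digits = 3, ...) {
  cat("Parameter-map evaluation")
  if (!is.na(x$method)) cat(" (", x$method, ")", sep = "")
  cat("\n")
  s <- x$summary
  s$nmse <- signif(s$nmse, digits)
  s$ssim <- signif(s$ssim, digits)
  print(s, row.names = FALSE)
  invisible(x)
}
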