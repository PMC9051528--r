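#' @export
print.cxm_fit <- function(x, ...) {
  cat(sprintf("2CXM fit (%s): %d pixels\n", x$method, nrow(x$params)))
  cat("parameter medians:\n")
  print(signif(apply(x$params, 2, stats::median), 3))
  invisible(x)
}

#' @export
summary.cxm_fit <- function(object, ...) {
  s <- apply(object$params, 2, function(v)
    c(min = min(v), q25 = unname(stats::quantile(v, 0.25)),
      median = stats::median(v),
      q75 = unname(stats::quantile(v, 0.75)), max = max(v)))
  out <- list(method = object$method, params = s,
              runtime = object$runtime)
  if (inherits(object, "nlls_fit")) {
    out$sse <- summary(object$sse)
    out$non_converged <- sum(object$convergence != 0)
  }
  if (inherits(object, "pinn_fit"))
    out$final_loss <- tail(object$log, 1)
  class(out) <- "summary.cxm_fit"
  out
}

#' @export
print.summary.cxm_fit <- function(x, ...) {
  cat(sprintf("2CXM fit (%s), %.1f s\n", x$method, x$runtime))
  print(signif(x$params, 3))
  if (!is.null(x$non_converged))
    cat(sprintf("pixels flagged non-converged: %d\n", x$non_converged))
  if (!is.null(x$final_loss)) {
    cat("final loss terms:\n")
    print(x$final_loss, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.cxm_fit <- function(object, ...) object$params

#' Model tissue curves implied by a fit
#'
#' For an NLLS fit, solves the 2CXM forward problem for every pixel's
#' estimated parameters.  For a PINN fit, either does the same
#' (`type = "ode"`) or evaluates the trained network directly
#' (`type = "network"`, the fit's own continuous representation,
#' denormalised to mM).
#'
#' @param object a `cxm_fit`.
#' @param t times, minutes (default: the observed grid).
#' @param type for PINN fits: `"network"` (default) or `"ode"`.
#' @param ... unused.
#' @return Matrix of predicted tissue curves, pixels x times (mM).
#' @export
predict.cxm_fit <- function(object, t = NULL, ...) {
  if (is.null(t)) t <- object$t
  aif <- if (all(t %in% object$t)) object$aif[match(t, object$t)] else
    approx(object$t, object$aif, t, rule = 2)$y
  cxm_cmyo_many_cpp(object$params, t, aif)
}

#' @rdname predict.cxm_fit
#' @export
predict.pinn_fit <- function(object, t = NULL,
                             type = c("network", "ode"), ...) {
  type <- match.arg(type)
  if (type == "ode") return(NextMethod())
  if (is.null(t)) t <- object$t
  fw <- pinn_forward(object, t)
  cs <- object$norm$c_scale
  vp <- object$params[, "vp"]; ve <- object$params[, "ve"]
  (fw$Cp_hat * vp + fw$Ce_hat * ve) * cs
}

#' @export
residuals.cxm_fit <- function(object, data = NULL, ...) {
  if (is.null(data)) stop("supply the observed curves as 'data'")
  as.matrix(data) - predict(object)
}

#' @export
fitted.cxm_fit <- function(object, ...) predict(object)

#' Diagnostic plots for fits
#'
#' For a PINN fit, plots the training evolution of the loss terms and the
#' volume-mean kinetic parameters.  For any fit with maps, an `image` of a
#' parameter map can be drawn.
#'
#' @param x a `cxm_fit`.
#' @param what `"training"` (PINN only) or `"map"`.
#' @param parameter which map to draw.
#' @param slice slice index.
#' @param ... graphics arguments.
#' @export
plot.pinn_fit <- function(x, what = c("training", "map"),
                          parameter = "Fp", slice = 1, ...) {
  what <- match.arg(what)
  if (what == "map") return(plot_map(x, parameter, slice, ...))
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  lg <- x$log
  matplot(lg$iter, log10(cbind(lg$loss_data, lg$loss_residual,
                               lg$loss_boundary + 1e-12,
                               lg$loss_nonneg + 1e-12)),
          type = "l", lty = 1, xlab = "iteration",
          ylab = "log10 loss", ...)
  legend("topright", c("data", "residual", "boundary", "non-neg"),
         col = 1:4, lty = 1, bty = "n", cex = 0.8)
  matplot(lg$iter, cbind(lg$mean_Fp, lg$mean_vp, lg$mean_ve, lg$mean_PS),
          type = "l", lty = 1, xlab = "iteration",
          ylab = "mean parameter", ...)
  legend("topright", c("Fp", "vp", "ve", "PS"), col = 1:4, lty = 1,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' @export
plot.nlls_fit <- function(x, parameter = "Fp", slice = 1, ...)
  plot_map(x, parameter, slice, ...)

plot_map <- function(x, parameter, slice, ...) {
  if (is.null(x$maps)) stop("fit carries no spatial maps")
  image(x$maps[[parameter]][, , slice],
        main = sprintf("%s estimate, slice %d", parameter, slice),
        col = hcl.colors(64, "viridis"), ...)
  invisible(x)
}

#' @export
print.cxm_curves <- function(x, ...) {
  cat(sprintf("2CXM curves: %d time points over [%g, %g] min\n",
              length(x$t), min(x$t), max(x$t)))
  cat(sprintf("  peak Cmyo %.3g mM at t = %.3g min\n",
              max(x$Cmyo), x$t[which.max(x$Cmyo)]))
  invisible(x)
}

#' @export
plot.cxm_curves <- function(x, ...) {
  matplot(x$t, cbind(x$Cp, x$Ce, x$Cmyo), type = "l", lty = 1,
          xlab = "time (min)", ylab = "concentration (mM)", ...)
  legend("topright", c("Cp", "Ce", "Cmyo"), col = 1:3, lty = 1,
         bty = "n")
  invisible(x)
}
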