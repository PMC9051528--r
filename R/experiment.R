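#' Configure the DRO comparison experiment
#'
#' Bundles everything needed to reproduce the four-method comparison:
#' simulate the DRO, fit each method for each noise realisation, and
#' aggregate NMSE/SSIM per parameter as mean (sd) over slices and
#' realisations.  Realisation seeds are derived deterministically from the
#' global seed.
#'
#' The `"full"` profile runs the full volume for all methods at the full
#' iteration budget; the `"reduced"` profile (default) restricts the PINN
#' methods to a 20 x 60 sub-grid of one slice and 10,000 iterations so the
#' whole experiment runs at desk scale.
#'
#' @param dro a [dro_config].
#' @param methods character vector among `"nlls"`, `"2cxm"`, `"reduced"`,
#'   `"combined"` (the latter three are PINN residual variants).
#' @param realisations number of noise realisations (>= 1).
#' @param profile `"reduced"` or `"full"`.
#' @param pinn_subset list with `rows`, `cols`, `slices` defining the
#'   pixel subset used by the PINN methods (NULL = full volume).
#' @param nlls_subset like `pinn_subset`, for the NLLS baseline.
#' @param nlls an [nlls_config].
#' @param weights a [loss_weights].
#' @param net a [network_config].
#' @param control a [training_config] for the PINN methods.
#' @param seed global seed.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(dro = dro_config(),
                              methods = c("nlls", "2cxm", "reduced",
                                          "combined"),
                              realisations = 5,
                              profile = c("reduced", "full"),
                              pinn_subset = NULL, nlls_subset = NULL,
                              nlls = nlls_config(),
                              weights = loss_weights(),
                              net = network_config(),
                              control = NULL, seed = 1) {
  profile <- match.arg(profile)
  if (realisations < 1) stop("realisations must be at least 1")
  bad <- setdiff(methods, c("nlls", "2cxm", "reduced", "combined"))
  if (length(bad)) stop("unknown methods: ", paste(bad, collapse = ", "))
  if (is.null(pinn_subset) && profile == "reduced")
    pinn_subset <- list(rows = 11:30, cols = 31:90, slices = 2)
  if (is.null(control))
    control <- training_config(
      iterations = if (profile == "full") 25000L else 10000L)
  structure(list(dro = dro, methods = methods,
                 realisations = as.integer(realisations),
                 profile = profile, pinn_subset = pinn_subset,
                 nlls_subset = nlls_subset, nlls = nlls,
                 weights = weights, net = net, control = control,
                 seed = as.integer(seed)), class = "experiment_config")
}

apply_subset <- function(dro, subset) {
  if (is.null(subset)) return(dro)
  dro_subset(dro, subset$rows, subset$cols, subset$slices)
}

#' Run the DRO comparison experiment
#'
#' Simulates the DRO, then for every noise realisation fits each
#' configured method and evaluates its parameter maps against ground
#' truth.  Results are aggregated as mean and standard deviation over
#' slices x realisations, matching the summary-table convention of the
#' comparison study.  With a single realisation and slice, standard
#' deviations are reported as 0 with a warning.
#'
#' @param cfg an [experiment_config].
#' @param out_dir optional directory; when given, parameter maps (CSV),
#'   training logs and the summary table are written there, each tagged
#'   with the seed used.
#' @param verbose print progress.
#' @return Object of class `cxm_experiment` with the aggregated `table`
#'   (method x parameter x metric means and sds) and all per-realisation
#'   `evals` and `fits` metadata.
#' @export
run_experiment <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "experiment_config"))
  dro0 <- simulate_dro(cfg$dro)
  pars <- c("Fp", "vp", "ve", "PS", "Total")
  res <- list()
  for (r in seq_len(cfg$realisations)) {
    seed_r <- cfg$seed + 7919L * (r - 1L)
    dro_r <- if (r == 1) dro0 else renoise(dro0, seed_r)
    for (m in cfg$methods) {
      if (verbose)
        message(sprintf("realisation %d / %d: %s", r, cfg$realisations, m))
      if (m == "nlls") {
        d <- apply_subset(dro_r, cfg$nlls_subset)
        fit <- fit_nlls(d, cfg = cfg$nlls)
      } else {
        d <- apply_subset(dro_r, cfg$pinn_subset)
        fit <- fit_pinn(d, variant = m, weights = cfg$weights,
                        net = cfg$net, control = cfg$control,
                        seed = seed_r)
      }
      ev <- evaluate_fit(fit, d)
      res[[length(res) + 1]] <- list(method = m, realisation = r,
                                     seed = seed_r, eval = ev,
                                     runtime = fit$runtime)
      if (!is.null(out_dir)) {
        dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
        tag <- sprintf("%s_r%d_seed%d", m, r, seed_r)
        write.csv(data.frame(fit$params),
                  file.path(out_dir, paste0("maps_", tag, ".csv")),
                  row.names = FALSE)
        if (inherits(fit, "pinn_fit"))
          write.csv(fit$log,
                    file.path(out_dir, paste0("log_", tag, ".csv")),
                    row.names = FALSE)
      }
    }
  }
  # aggregate: per method, collect per-slice x realisation values
  tab <- list()
  for (m in cfg$methods) {
    sel <- Filter(function(e) e$method == m, res)
    nm_all <- do.call(rbind, lapply(sel, function(e) e$eval$nmse_slices))
    ss_all <- do.call(rbind, lapply(sel, function(e) e$eval$ssim_slices))
    nm_tot <- rowMeans(nm_all); ss_tot <- rowMeans(ss_all)
    single <- nrow(nm_all) == 1
    if (single)
      warning("single slice x realisation for method '", m,
              "'; standard deviations reported as 0")
    sdv <- function(v) if (length(v) > 1) sd(v) else 0
    for (p in pars) {
      nv <- if (p == "Total") nm_tot else nm_all[, p]
      sv <- if (p == "Total") ss_tot else ss_all[, p]
      tab[[length(tab) + 1]] <- data.frame(
        method = m, parameter = p,
        nmse_mean = mean(nv), nmse_sd = sdv(nv),
        ssim_mean = mean(sv), ssim_sd = sdv(sv))
    }
  }
  table <- do.call(rbind, tab)
  out <- structure(list(table = table, evals = res, config = cfg),
                   class = "cxm_experiment")
  if (!is.null(out_dir))
    write.csv(table, file.path(out_dir,
                               sprintf("summary_seed%d.csv", cfg$seed)),
              row.names = FALSE)
  out
}

#' @export
print.cxm_experiment <- function(x, digits = 2, ...) {
  cat("DRO comparison experiment (", x$config$profile, " profile, ",
      x$config$realisations, " realisation(s))\n\n", sep = "")
  t <- x$table
  fmt <- function(m, s) sprintf("%.*f (%.*f)", digits, m, digits, s)
  wide <- do.call(rbind, lapply(split(t, t$method), function(d) {
    d <- d[match(c("Total", "Fp", "vp", "ve", "PS"), d$parameter), ]
    data.frame(method = d$method[1],
               Total = fmt(d$nmse_mean[1], d$nmse_sd[1]),
               Total_SSIM = fmt(d$ssim_mean[1], d$ssim_sd[1]),
               Fp = fmt(d$nmse_mean[2], d$nmse_sd[2]),
               vp = fmt(d$nmse_mean[3], d$nmse_sd[3]),
               ve = fmt(d$nmse_mean[4], d$nmse_sd[4]),
               PS = fmt(d$nmse_mean[5], d$nmse_sd[5]))
  }))
  print(wide, row.names = FALSE)
  cat("\n(NMSE mean (sd); Total_SSIM is the four-parameter mean SSIM)\n")
  invisible(x)
}
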