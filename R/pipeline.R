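#' Configuration of a per-peptide analysis run
#'
#' Collects every input and tunable of the full pipeline. Either
#' `frames` + `labels` (in-memory trajectory) or trace file paths may
#' be supplied; a SASA trace (precomputed, nm^2) is optional and only
#' used for the free-energy landscape.
#'
#' @param frames Optional [md_frames] trajectory.
#' @param labels Optional [label_map]; required with `frames`.
#' @param ree_path,caca_path,sasa_path Optional delimited trace files
#'   (used when `frames` is absent; `sasa_path` optionally with
#'   either).
#' @param temperature Temperature (K), default 300.
#' @param eta_target,eta_model Viscosity pair (mPa s), defaults
#'   1.10 (heavy water) and 0.445 (SPC water).
#' @param t_exp Experimental MFCT (ns) for sink-radius optimization,
#'   or `NULL` to use `sink_radius` directly.
#' @param sink_radius Fixed sink radius (nm), default 0.45.
#' @param sg_window,sg_polyorder Savitzky-Golay smoothing parameters.
#' @param cluster_cutoff RMSD cutoff (nm) for Daura clustering.
#' @param cluster_stride Frame stride for clustering.
#' @param seed Integer seed for any stochastic stage.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(frames = NULL, labels = NULL,
                            ree_path = NULL, caca_path = NULL,
                            sasa_path = NULL,
                            temperature = 300,
                            eta_target = 1.10, eta_model = 0.445,
                            t_exp = NULL, sink_radius = 0.45,
                            sg_window = 51L, sg_polyorder = 3L,
                            cluster_cutoff = 0.25, cluster_stride = 1L,
                            seed = 1L) {
  if (eta_target <= 0 || eta_model <= 0) stop("viscosities must be positive")
  if (is.null(frames)) {
    for (p in c(ree_path, caca_path, sasa_path))
      if (!is.null(p) && !file.exists(p)) stop("missing input file: ", p)
    if (is.null(ree_path)) stop("need either frames+labels or ree_path")
  } else if (is.null(labels)) stop("frames require a label_map")
  structure(as.list(environment()), class = "analysis_config")
}

#' Run the full per-peptide analysis pipeline
#'
#' Orchestrates all stages on one peptide's data: geometric trace
#' extraction (if a trajectory is supplied), ensemble means with
#' block-averaged errors, mean kappa-squared, the skewed-Gaussian
#' distance-distribution fit, Daura clustering with the cumulative
#' cluster curve, contact kinetics (fixed sink radius, or optimized
#' when an experimental MFCT is given) with viscosity correction, and
#' the time-series indicator block for each observable. Deterministic
#' given the same config and seed.
#'
#' @param config An [analysis_config].
#' @return Object of class `peptide_report`: nested list with blocks
#'   `ensemble`, `kappa2`, `mixture`, `clusters`, `kinetics`,
#'   `timeseries`, `parameters`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (!is.null(config$frames)) {
    tr <- stage("traces", extract_traces(config$frames, config$labels))
    ree <- tr$ree; caca <- tr$caca; rg <- tr$rg; dip <- tr$dipoles
  } else {
    ree <- stage("traces", read_trace(config$ree_path, "Ree"))
    caca <- if (!is.null(config$caca_path))
      read_trace(config$caca_path, "RCaCa") else NULL
    rg <- NULL; dip <- NULL
  }
  sasa <- if (!is.null(config$sasa_path))
    read_trace(config$sasa_path, "SASA") else NULL

  ens <- stage("ensemble", {
    blk <- function(x) if (is.null(x)) NULL else {
      b <- block_average_error(x$values)
      list(mean = b$mean, error = b$error)
    }
    list(ree = blk(ree), caca = blk(caca), rg = blk(rg))
  })
  kap <- if (!is.null(dip)) stage("kappa2", {
    k <- kappa_squared_series(dip)
    b <- block_average_error(k)
    list(mean = b$mean, error = b$error)
  }) else NULL
  mix <- stage("mixture_fit", {
    m <- fit_ree_distribution(ree$values)
    list(components = m$components, residual = m$residual)
  })
  clus <- if (!is.null(config$frames)) stage("clustering", {
    cl <- daura_cluster(config$frames, config$cluster_cutoff,
                        atom_subset = config$labels$heavy_atoms,
                        stride = config$cluster_stride)
    list(n_clusters = length(cl$populations),
         populations = cl$populations,
         prc_top3 = 100 * sum(utils::head(cl$populations, 3L)) /
           cl$n_structures,
         cumulative = cumulative_cluster_curve(cl$assignments))
  }) else NULL
  kin <- stage("kinetics", {
    f <- config$eta_target / config$eta_model
    sm <- smooth_trace(ree, config$sg_window, config$sg_polyorder)
    if (!is.null(config$t_exp)) {
      opt <- optimize_sink_radius(sm, config$t_exp, f)
      r_use <- opt$r_opt
    } else {
      opt <- NULL
      r_use <- config$sink_radius
    }
    ms <- mfct_summary(ree, r_use, config$eta_target, config$eta_model,
                       config$sg_window, config$sg_polyorder)
    c(ms, list(r_opt = r_use,
               percent_error = if (!is.null(opt)) opt$percent_error else NA))
  })
  tsb <- stage("timeseries", {
    one <- function(x) if (is.null(x)) NULL else spectral_summary(x)
    out <- list(ree = one(ree), caca = one(caca))
    out$cross_corr <- if (!is.null(caca))
      zero_lag_crosscorr(ree, caca) else NA
    out
  })
  structure(list(ensemble = ens, kappa2 = kap, mixture = mix,
                 clusters = clus, kinetics = kin, timeseries = tsb,
                 parameters = list(
                   temperature = config$temperature,
                   eta_target = config$eta_target,
                   eta_model = config$eta_model,
                   sink_radius = config$sink_radius,
                   t_exp = config$t_exp,
                   sg_window = config$sg_window,
                   sg_polyorder = config$sg_polyorder,
                   cluster_cutoff = config$cluster_cutoff,
                   cluster_stride = config$cluster_stride,
                   seed = config$seed)),
            class = "peptide_report")
}

#' @export
print.peptide_report <- function(x, ...) {
  cat("<peptide_report>\n")
  if (!is.null(x$ensemble$ree))
    cat(sprintf("  <Ree>  = %.4g +/- %.2g nm\n",
                x$ensemble$ree$mean, x$ensemble$ree$error))
  if (!is.null(x$kappa2))
    cat(sprintf("  <k^2>  = %.4g +/- %.2g\n",
                x$kappa2$mean, x$kappa2$error))
  cat(sprintf("  MFCT   = %.4g ns (corr %.4g ns, f = %.3f, r = %.3f nm)\n",
              x$kinetics$t_sim, x$kinetics$t_corr, x$kinetics$f,
              x$kinetics$r_opt))
  if (!is.null(x$timeseries$ree))
    cat(sprintf("  Ree:   tau_corr = %.4g ps, H = %.3f, alpha = %.3f (%s)\n",
                x$timeseries$ree$tau_corr, x$timeseries$ree$H,
                x$timeseries$ree$alpha, x$timeseries$ree$noise_class))
  invisible(x)
}

#' Serialize a peptide report to JSON
#'
#' @param report A `peptide_report` from [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "peptide_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
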