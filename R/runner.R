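#' Run an end-to-end synthetic scenario
#'
#' Orchestrates simulate -> detect -> resample -> summarize on a synthetic
#' cohort, producing the standard outputs of a priming-agent sensitivity
#' study: (a) a burden-stratified sensitivity table over the threshold sweep,
#' (b) sensitivity-vs-panel-size curves from the bootstrap downsampler,
#' (c) sensitivity-vs-fraction curves from binomial downscaling, and (d) a
#' per-sample binomial model-check report — plus static plots of (b) and (c)
#' and a JSON run manifest with the config snapshot, seed, per-stage wall
#' times and MD5 checksums of every output file. Tables are the contract;
#' figures are conveniences. Re-running with the same config reproduces
#' identical table checksums.
#'
#' @param config a [scenario_config()].
#' @param plan a [resampling_plan()]; its `fractions` must be numeric for the
#'   downscaling stage.
#' @param outdir output directory (created if needed).
#' @param make_plots write PNG figures (default TRUE).
#' @return The manifest (a list), invisibly. All outputs land in `outdir`.
#' @export
run_scenario <- function(config, plan, outdir, make_plots = TRUE) {
  validate_scenario_config(config)
  if (identical(plan$fractions, "observed")) {
    stop("run_scenario requires numeric plan$fractions for the downscaling stage",
         call. = FALSE)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage_times <- list()
  outputs <- character()
  log_lines <- character()
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  run_stage <- function(name, expr) {
    logmsg("stage %s: start", name)
    tic <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s (partial outputs retained in %s)",
                   name, conditionMessage(e), outdir), call. = FALSE)
    })
    stage_times[[name]] <<- as.numeric(difftime(Sys.time(), tic,
                                                units = "secs"))
    logmsg("stage %s: done in %.1fs", name, stage_times[[name]])
    res
  }
  emit <- function(path) outputs <<- c(outputs, path)

  cohort <- run_stage("simulate", simulate_cohort(config))
  emit(write_panel(cohort$panel, file.path(outdir, "panel.bed")))
  emit(write_counts(cohort$counts, file.path(outdir, "counts.tsv")))
  emit(write_sample_metadata(cohort$metadata, file.path(outdir, "metadata.tsv")))

  detections <- run_stage("detect",
                          detect_samples(cohort$counts, cohort$panel,
                                         thresholds = plan$thresholds))
  det_path <- file.path(outdir, "detections.tsv")
  utils::write.table(as.data.frame(detections), det_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit(det_path)

  burden <- run_stage("burden_sensitivity",
                      sensitivity_by_burden(detections, cohort$metadata))
  burden_path <- file.path(outdir, "sensitivity_by_burden.tsv")
  utils::write.table(burden, burden_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  emit(burden_path)

  panel_grid <- run_stage("downsample_panel",
                          downsample_panel(cohort$counts, cohort$metadata,
                                           cohort$panel, plan))
  emit(write_sensitivity(panel_grid,
                         file.path(outdir, "sensitivity_vs_panel_size.tsv")))

  frac_grid <- run_stage("downscale_fraction",
                         downscale_fraction(cohort$counts, cohort$metadata,
                                            cohort$panel, plan))
  emit(write_sensitivity(frac_grid,
                         file.path(outdir, "sensitivity_vs_fraction.tsv")))

  check <- run_stage("model_check",
                     binomial_model_check(cohort$counts, cohort$panel,
                                          seed = plan$seed))
  check_path <- file.path(outdir, "model_check.tsv")
  utils::write.table(as.data.frame(check), check_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  emit(check_path)

  if (make_plots) {
    run_stage("plots", {
      plot_sensitivity_grid(panel_grid, "panel_size",
                            file.path(outdir, "sensitivity_vs_panel_size.png"))
      plot_sensitivity_grid(frac_grid, "fraction",
                            file.path(outdir, "sensitivity_vs_fraction.png"))
    })
    emit(file.path(outdir, "sensitivity_vs_panel_size.png"))
    emit(file.path(outdir, "sensitivity_vs_fraction.png"))
  }

  log_path <- file.path(outdir, "run.log")
  writeLines(log_lines, log_path)
  emit(log_path)

  manifest <- list(
    package = "duplexsens",
    version = as.character(utils::packageVersion("duplexsens")),
    r_version = as.character(getRversion()),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    scenario = unclass(config),
    resampling = unclass(plan),
    stage_seconds = stage_times,
    outputs = lapply(stats::setNames(outputs, basename(outputs)),
                     function(p) list(path = basename(p),
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# Base-graphics sensitivity curves: mean +/- SE per arm, one panel per
# threshold subset (headline threshold 2 highlighted by drawing it last).
plot_sensitivity_grid <- function(grid, xvar = c("panel_size", "fraction"),
                                  path) {
  xvar <- match.arg(xvar)
  grid <- grid[!is.na(grid[[xvar]]), , drop = FALSE]
  if (nrow(grid) == 0L) return(invisible(NULL))
  k0 <- if (2L %in% grid$threshold) 2L else min(grid$threshold)
  g <- grid[grid$threshold == k0, , drop = FALSE]
  grDevices::png(path, width = 900, height = 650, res = 120)
  on.exit(grDevices::dev.off())
  logx <- if (xvar == "fraction") "x" else ""
  arms <- sort(unique(g$arm))
  cols <- stats::setNames(c("#1f77b4", "#d62728")[seq_along(arms)], arms)
  plot(NA, xlim = range(g[[xvar]]), ylim = c(0, 1), log = logx,
       xlab = if (xvar == "fraction") "tumor fraction" else "panel size",
       ylab = "sensitivity",
       main = sprintf("Sensitivity vs %s (threshold >= %d SNVs)",
                      gsub("_", " ", xvar), k0))
  for (a in arms) {
    ga <- g[g$arm == a, , drop = FALSE]
    ga <- ga[order(ga[[xvar]]), , drop = FALSE]
    graphics::lines(ga[[xvar]], ga$mean, col = cols[[a]], lwd = 2, type = "b",
                    pch = 16)
    has_se <- ga$se > 0
    if (any(has_se)) {
      graphics::arrows(ga[[xvar]][has_se], pmax(0, ga$mean - ga$se)[has_se],
                       ga[[xvar]][has_se], pmin(1, ga$mean + ga$se)[has_se],
                       angle = 90, code = 3, length = 0.03, col = cols[[a]])
    }
  }
  graphics::legend("topleft", legend = arms, col = cols[arms], lwd = 2,
                   pch = 16, bty = "n")
  invisible(path)
}
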