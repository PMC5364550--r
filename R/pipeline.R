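#' Run the simulate -> gate -> transfer -> fit -> classify pipeline
#'
#' Orchestrates the full synthetic-experiment analysis for a set of
#' samples: events are simulated per sample from the titration model, gated
#' on the reference channel, reduced to transfer functions, fitted, and
#' classified into functional groups. If expression values with group
#' labels are supplied, the functional groups are additionally compared
#' with a Kruskal-Wallis/Dunn test. All outputs (event CSVs, transfer
#' functions, a fit report, an optional comparison table and a
#' machine-readable manifest) are written under \code{outdir};
#' rerunning the same configuration reproduces them byte-identically.
#'
#' The configuration is a list (or a YAML file with the same structure):
#' \preformatted{
#' seed: 7                      # required, expanded to per-stage substreams
#' gate: 100
#' bin_width: 0.05
#' min_events: 10
#' af_mean: 50                  # subtracted before binning
#' fit: {starts: 3}
#' classify: {low_cutoff: 0.75, high_cutoff: 0.5}
#' samples:
#'   - {id: weak,   theta: 30,  lam: 30, n_events: 20000}
#'   - {id: strong, theta: 400, lam: 5,  n_events: 20000}
#' }
#' Unlisted per-sample fields fall back to the [simulation_config()]
#' defaults. Each sample's simulation seed is \code{seed + 1000 + i} and
#' its fit seed \code{seed + 2000 + i}, so stages rerun in isolation
#' reproduce the pipeline exactly.
#'
#' @param config list or path to a YAML file.
#' @param outdir output directory (created if missing).
#' @param quiet suppress per-stage progress messages on stderr.
#' @return Invisibly, a report bundle: list with \code{report} (one row per
#'   sample: estimates, fit diagnostics, category), \code{tfs},
#'   \code{fits}, \code{comparison} (or NULL), \code{manifest} and
#'   \code{outdir}.
#' @export
run_pipeline <- function(config, outdir, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) {
    if (!quiet) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")),
                        sprintf(fmt, ...))
  }

  tfs <- list(); fits <- list(); rows <- list()
  for (i in seq_along(cfg$samples)) {
    s <- cfg$samples[[i]]
    say("sample %s: simulate %d events", s$id, s$n_events)
    sim_args <- s[setdiff(names(s), "id")]
    sim_args$seed <- cfg$seed + 1000L + i
    sim <- do.call(simulation_config, sim_args)
    ev <- simulate_events(sim, sample_id = s$id)
    write_events(ev, file.path(outdir, sprintf("events_%s.csv", s$id)))

    gated <- gate_ref_positive(ev, gate = cfg$gate)
    tf <- transfer_function(gated, bin_width = cfg$bin_width,
                            min_events = cfg$min_events,
                            af_mean = cfg$af_mean)
    write_transfer_function(tf, file.path(outdir, sprintf("tf_%s.csv", s$id)))
    say("sample %s: fit %d bins", s$id, nrow(tf))
    fit <- fit_transfer_function(tf, starts = cfg$fit$starts,
                                 seed = cfg$seed + 2000L + i)
    call <- classify_function(fit, low_cutoff = cfg$classify$low_cutoff,
                              high_cutoff = cfg$classify$high_cutoff)
    tfs[[s$id]] <- tf; fits[[s$id]] <- fit
    rows[[i]] <- data.frame(
      sample_id = s$id,
      theta_hat = fit$theta_hat, lam_hat = fit$lam_hat,
      gain_hat = fit$gain_hat, rss = fit$rss, n_bins = fit$n_bins,
      converged = fit$converged,
      flags = paste(fit$flags, collapse = ";"),
      category = as.character(call$category),
      min_rho = call$min_rho, crossing_p = call$crossing_p,
      stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  report_path <- file.path(outdir, "fit_report.csv")
  write_report_csv(report, report_path)

  comparison <- NULL
  if (!is.null(cfg$compare)) {
    say("comparing groups")
    comparison <- kruskal_dunn(cfg$compare$values, cfg$compare$groups,
                               p_adjust = cfg$compare$p_adjust)
    write_report_csv(comparison$pairwise,
                     file.path(outdir, "comparison.csv"))
  }

  manifest <- list(
    package = "uta",
    version = as.character(utils::packageVersion("uta")),
    seed = cfg$seed,
    config = config,
    config_hash = hash_config(config),
    outputs = sort(setdiff(list.files(outdir), "manifest.json")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done: %d sample(s) -> %s", nrow(report), outdir)

  invisible(list(report = report, tfs = tfs, fits = fits,
                 comparison = comparison, manifest = manifest,
                 outdir = outdir))
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  if (is.null(config$seed) || !is.finite(config$seed)) {
    stop("pipeline config requires an integer 'seed'")
  }
  if (is.null(config$samples) || length(config$samples) == 0) {
    stop("pipeline config requires a non-empty 'samples' list")
  }
  samples <- lapply(seq_along(config$samples), function(i) {
    s <- config$samples[[i]]
    if (is.null(s$id)) s$id <- sprintf("sample%d", i)
    s
  })
  ids <- vapply(samples, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in config")
  cfg <- list(seed = as.integer(config$seed), samples = samples,
              gate = config$gate %||% 100,
              bin_width = config$bin_width %||% 0.05,
              min_events = config$min_events %||% 10,
              af_mean = config$af_mean %||% 0,
              fit = list(starts = config$fit$starts %||% 3),
              classify = list(
                low_cutoff = config$classify$low_cutoff %||% 0.75,
                high_cutoff = config$classify$high_cutoff %||% 0.5))
  if (!is.null(config$compare)) {
    cmp <- config$compare
    if (is.null(cmp$values) || is.null(cmp$groups)) {
      stop("compare block needs 'values' and 'groups'")
    }
    cfg$compare <- list(values = as.numeric(cmp$values),
                        groups = as.character(cmp$groups),
                        p_adjust = cmp$p_adjust %||% "bonferroni")
  }
  # every sample block must build a valid simulation config
  for (s in cfg$samples) {
    args <- s[setdiff(names(s), "id")]
    args$seed <- 1L
    do.call(simulation_config, args)
  }
  if (cfg$gate <= 0) stop("gate must be positive")
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_report_csv <- function(d, path) {
  num <- vapply(d, is.double, TRUE)
  d[num] <- lapply(d[num], fmt_num)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Export figures from a pipeline report bundle
#'
#' Writes per-sample reference/reporter scatter plots and one overlay of
#' all transfer functions with their fitted curves as PNG files under
#' \code{file.path(dir, "figures")}. Plot failures warn and continue.
#'
#' @param bundle result of [run_pipeline()].
#' @param dir output directory; defaults to the bundle's outdir.
#' @param width,height,res PNG device settings.
#' @return Character vector of figure paths (empty, with a warning, for an
#'   empty bundle).
#' @export
plot_pipeline <- function(bundle, dir = bundle$outdir,
                          width = 900, height = 700, res = 120) {
  if (is.null(bundle$report) || nrow(bundle$report) == 0) {
    warning("empty report bundle; no figures written")
    return(character(0))
  }
  figdir <- file.path(dir, "figures")
  dir.create(figdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in names(bundle$fits)) {
    p <- file.path(figdir, sprintf("scatter_%s.png", id))
    ok <- tryCatch({
      ev <- read_events(file.path(bundle$outdir, sprintf("events_%s.csv", id)))
      grDevices::png(p, width, height, res = res)
      graphics::plot(ev$ref_intensity, ev$rep_intensity, log = "xy",
                     pch = ".", col = "#00000040",
                     xlab = "reference intensity", ylab = "reporter intensity",
                     main = id)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("scatter plot failed for ", id, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) paths <- c(paths, p)
  }
  p <- file.path(figdir, "tf_overlay.png")
  ok <- tryCatch({
    grDevices::png(p, width, height, res = res)
    xr <- range(unlist(lapply(bundle$tfs, `[[`, "bin_center")))
    yr <- range(unlist(lapply(bundle$tfs, `[[`, "mean_log_rep")))
    graphics::plot(NA, xlim = xr, ylim = yr,
                   xlab = "log10 relative reference intensity",
                   ylab = "mean log10 relative reporter intensity")
    cols <- grDevices::hcl.colors(max(3, length(bundle$tfs)), "Dark 3")
    for (i in seq_along(bundle$tfs)) {
      tf <- bundle$tfs[[i]]
      graphics::points(tf$bin_center, tf$mean_log_rep, col = cols[i], pch = 16)
      xx <- seq(xr[1], xr[2], length.out = 200)
      graphics::lines(xx, predict(bundle$fits[[i]], xx), col = cols[i])
    }
    graphics::legend("topleft", legend = names(bundle$tfs),
                     col = cols[seq_along(bundle$tfs)], pch = 16, bty = "n")
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("overlay plot failed: ", conditionMessage(e))
    FALSE
  })
  if (ok) paths <- c(paths, p)
  paths
}
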