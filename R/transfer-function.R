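#' Gate reference-positive events
#'
#' Keeps events whose reference-channel intensity exceeds a gate, mimicking
#' the selection of reporter-positive cells before analysis. The gate can be
#' given directly or derived from a control (untransfected) sample as a high
#' percentile of its reference intensities.
#'
#' @param t event table.
#' @param gate positive gate value, or \code{NULL} to derive it from
#'   \code{control}.
#' @param control optional event table of control cells used for the
#'   percentile rule.
#' @param percentile percentile of the control reference intensities used as
#'   gate (default 0.999, i.e. essentially above all background events).
#' @return The gated event table with the gate recorded in
#'   \code{attr(, "gate_value")}.
#' @export
gate_ref_positive <- function(t, gate = NULL, control = NULL,
                              percentile = 0.999) {
  check_event_table(t)
  if (is.null(gate)) {
    if (is.null(control)) stop("supply either a gate value or a control sample")
    check_event_table(control)
    gate <- unname(stats::quantile(control$ref_intensity, percentile,
                                   names = FALSE))
  }
  if (!is.finite(gate) || gate <= 0) stop("gate must be a positive number")
  out <- t[t$ref_intensity > gate, , drop = FALSE]
  if (nrow(out) == 0) {
    stop(sprintf("no events above the reference gate (gate = %g)", gate))
  }
  rownames(out) <- NULL
  attr(out, "gate_value") <- gate
  out
}

#' Compute a transfer function from gated events
#'
#' Log10-transformed relative reference intensities (intensity divided by
#' the gate value) are binned at fixed intervals and the average log10
#' relative reporter intensity is computed per bin, together with the event
#' count used later as fitting weight. Bins are half-open
#' \code{[k*w, (k+1)*w)} on the relative log scale and bins with fewer than
#' \code{min_events} events are dropped to stabilize the bin means.
#'
#' A constant autofluorescence estimate \code{af_mean} can be handled in
#' two ways. With \code{af_subtract = "ref"} (the default) it is subtracted
#' from the reference channel only: gated reference intensities sit well
#' above the background, so the subtraction is safe there and corrects the
#' binning coordinate, while the reporter channel - which does reach the
#' background floor in deeply repressed cells - is left intact and the
#' background is instead carried as a known additive term into the fit
#' (see [fit_transfer_function()]). Subtracting a background from
#' intensities that fluctuate around it produces near-zero or negative
#' values whose logarithms wreck the bin means; modelling it additively
#' does not. \code{af_subtract = "both"} subtracts from both channels
#' (floored at \code{1e-6 * gate} to keep logarithms finite) and
#' \code{"none"} disables the correction entirely.
#'
#' @param t gated event table (from [gate_ref_positive()]).
#' @param bin_width bin width on the log10 scale; default 0.05.
#' @param min_events minimum events per retained bin; default 10.
#' @param af_mean autofluorescence estimate in intensity units; default 0.
#' @param af_subtract where to subtract \code{af_mean}: \code{"ref"}
#'   (default), \code{"both"}, or \code{"none"}.
#' @param gate gate value; defaults to the one recorded by
#'   [gate_ref_positive()].
#' @return A data frame of class \code{uta_tf} with columns
#'   \code{bin_left, bin_center, mean_log_rep, n_events} and attributes
#'   \code{gate_value}, \code{bin_width}, \code{af_mean},
#'   \code{af_subtract}, \code{n_gated}.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 2, n_events = 20000, theta = 100, lam = 10)
#' ev <- gate_ref_positive(simulate_events(cfg), gate = 100)
#' tf <- transfer_function(ev, af_mean = 50)
#' head(tf)
transfer_function <- function(t, bin_width = 0.05, min_events = 10,
                              af_mean = 0,
                              af_subtract = c("ref", "both", "none"),
                              gate = attr(t, "gate_value")) {
  check_event_table(t)
  if (nrow(t) == 0) stop("gated event table is empty")
  if (is.null(gate) || !is.finite(gate) || gate <= 0) {
    stop("a positive gate value is required (gate the table first or pass gate=)")
  }
  if (bin_width <= 0) stop("bin_width must be positive")
  if (min_events < 1) stop("min_events must be >= 1")
  af_subtract <- match.arg(af_subtract)
  if (af_mean < 0) stop("af_mean must be >= 0")
  if (af_mean == 0) af_subtract <- "none"
  floor_at <- 1e-6 * gate
  sub_ref <- if (af_subtract %in% c("ref", "both")) af_mean else 0
  sub_rep <- if (af_subtract == "both") af_mean else 0
  ref <- pmax(t$ref_intensity - sub_ref, floor_at)
  rep <- pmax(t$rep_intensity - sub_rep, floor_at)
  x <- log10(ref / gate)
  y <- log10(rep / gate)

  k <- floor(x / bin_width)
  agg <- vapply(split(y, k), function(v) c(mean(v), length(v)), numeric(2))
  kk <- as.numeric(colnames(agg))
  ord <- order(kk)
  out <- data.frame(bin_left = kk[ord] * bin_width,
                    bin_center = (kk[ord] + 0.5) * bin_width,
                    mean_log_rep = agg[1, ord],
                    n_events = as.integer(agg[2, ord]))
  out <- out[out$n_events >= min_events, , drop = FALSE]
  if (nrow(out) == 0) {
    stop("every bin has fewer than min_events events; ",
         "use more events or wider bins")
  }
  rownames(out) <- NULL
  structure(out, class = c("uta_tf", "data.frame"),
            gate_value = gate, bin_width = bin_width, af_mean = af_mean,
            af_subtract = af_subtract, min_events = min_events,
            n_gated = nrow(t))
}

#' @export
print.uta_tf <- function(x, ...) {
  cat(sprintf(
    "Transfer function: %d bins (width %g), gate = %g, %d gated events\n",
    nrow(x), attr(x, "bin_width"), attr(x, "gate_value"), attr(x, "n_gated")))
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.uta_tf <- function(x, ...,
                        xlab = "log10 relative reference intensity",
                        ylab = "mean log10 relative reporter intensity") {
  graphics::plot(x$bin_center, x$mean_log_rep, xlab = xlab, ylab = ylab,
                 pch = 16, ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(x)
}

#' Write a transfer function as CSV
#'
#' Columns \code{bin_left,bin_center,mean_log_rep,n_events} preceded by a
#' comment line \code{# gate=<value> bin_width=<w>} carrying the gating
#' metadata.
#'
#' @param tf a [transfer_function()] object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_transfer_function <- function(tf, path) {
  stopifnot(inherits(tf, "uta_tf"))
  lines <- c(sprintf("# gate=%s bin_width=%s",
                     fmt_num(attr(tf, "gate_value")),
                     fmt_num(attr(tf, "bin_width"))),
             "bin_left,bin_center,mean_log_rep,n_events",
             paste(fmt_num(tf$bin_left), fmt_num(tf$bin_center),
                   fmt_num(tf$mean_log_rep), tf$n_events, sep = ","))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a transfer function written by [write_transfer_function()]
#' @param path input path.
#' @return A \code{uta_tf} object.
#' @export
read_transfer_function <- function(path) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^# gate=([-0-9.eE+]+) bin_width=([-0-9.eE+]+)", header))[[1]]
  if (length(m) != 3) stop("missing '# gate=... bin_width=...' header in ", path)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  structure(d, class = c("uta_tf", "data.frame"),
            gate_value = as.numeric(m[2]), bin_width = as.numeric(m[3]),
            af_mean = 0, af_subtract = "none", min_events = NA_integer_,
            n_gated = NA_integer_)
}
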