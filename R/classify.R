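#' Classify the functional behavior of a fitted repression curve
#'
#' Assigns the ordinal functional category - \code{low}, \code{mid} or
#' \code{high} - from the shape of the fitted repression curve over the
#' observed intensity range. The repression ratio
#' \code{rho(x) = r(10^x)/10^x} is evaluated on a dense grid over
#' \code{[L, U]} (log10 relative reference units); \code{rho} is increasing
#' in \code{x}, so its minimum sits at \code{L}.
#'
#' \itemize{
#'   \item \code{low}: no detectable threshold - \code{min rho >= low_cutoff}
#'     (the curve is a near-parallel shift of the unrepressed line);
#'   \item otherwise the crossing position \code{p = (x_cross - L)/(U - L)}
#'     where \code{rho} first reaches 0.5 (clipped to the unit interval)
#'     splits
#'   \item \code{mid} (\code{p < high_cutoff}: threshold at intermediate
#'     intensities) from
#'   \item \code{high} (\code{p >= high_cutoff}: repression maintained up to
#'     high intensities).
#' }
#'
#' The cutoffs are operational definitions of curve-shape groups that are
#' otherwise only described qualitatively; both are exposed as arguments.
#'
#' @param fit a converged [fit_transfer_function()] result, or a list with
#'   elements \code{theta} and \code{lam} (relative units) for classifying a
#'   noise-free model curve directly.
#' @param x_range range \code{c(L, U)} in log10 relative reference units;
#'   defaults to the fitted transfer function's bin span.
#' @param low_cutoff minimum repression ratio defining "no detectable
#'   threshold"; default 0.75.
#' @param high_cutoff crossing-position fraction splitting mid from high;
#'   default 0.5.
#' @param n_grid grid resolution.
#' @return A list of class \code{uta_call}: \code{category} (ordered factor
#'   low < mid < high), \code{min_rho}, \code{crossing_p} (NA for low),
#'   \code{x_range} and the cutoffs used.
#' @export
#' @examples
#' classify_function(list(theta = 0, lam = 1), x_range = c(0, 3))    # low
#' classify_function(list(theta = 800, lam = 0.01), x_range = c(0, 3)) # high
classify_function <- function(fit, x_range = NULL, low_cutoff = 0.75,
                              high_cutoff = 0.5, n_grid = 512) {
  if (inherits(fit, "uta_fit")) {
    if (!isTRUE(fit$converged)) {
      stop("cannot classify a non-converged fit")
    }
    theta <- fit$theta_hat
    lam <- fit$lam_hat
    if (is.null(x_range)) x_range <- fit$x_range
  } else {
    theta <- fit$theta
    lam <- fit$lam
    if (is.null(x_range)) stop("x_range is required when classifying raw parameters")
  }
  check_nonneg(theta, "theta")
  L <- x_range[1]; U <- x_range[2]
  if (!(U > L)) stop("x_range must satisfy U > L")

  xx <- seq(L, U, length.out = n_grid)
  r0 <- 10^xx
  rho <- steady_state_r(r0, theta, lam) / r0
  min_rho <- rho[1]  # rho is increasing in x

  if (min_rho >= low_cutoff) {
    category <- "low"
    p <- NA_real_
  } else {
    if (rho[1] >= 0.5) {
      x_cross <- L            # crossing below the observed range
    } else if (rho[n_grid] < 0.5) {
      x_cross <- U            # never de-represses within the range
    } else {
      x_cross <- stats::uniroot(function(x) {
        steady_state_r(10^x, theta, lam) / 10^x - 0.5
      }, lower = L, upper = U, tol = 1e-10)$root
    }
    p <- min(max((x_cross - L) / (U - L), 0), 1)
    category <- if (p >= high_cutoff) "high" else "mid"
  }
  structure(list(category = factor(category, levels = c("low", "mid", "high"),
                                   ordered = TRUE),
                 min_rho = min_rho, crossing_p = p,
                 x_range = c(L, U),
                 low_cutoff = low_cutoff, high_cutoff = high_cutoff),
            class = "uta_call")
}

#' @export
print.uta_call <- function(x, ...) {
  cat(sprintf(
    "Functional category: %s (min r/r0 = %.3f%s over log10 range [%.2f, %.2f])\n",
    as.character(x$category), x$min_rho,
    if (is.na(x$crossing_p)) "" else sprintf(", crossing at p = %.2f",
                                             x$crossing_p),
    x$x_range[1], x$x_range[2]))
  invisible(x)
}
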