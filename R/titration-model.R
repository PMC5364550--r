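#' Kinetic parameters of the miRNA titration model
#'
#' Bundles the full rate-constant parameterization of the two-species model
#' of miRNA-mediated repression: a target mRNA is transcribed at rate
#' \code{k_R}, decays at rate \code{gamma_r}, and reversibly binds a miRNA
#' pool of fixed total size \code{m_total} (association \code{k_on},
#' dissociation \code{k_off}); the bound complex is degraded at rate
#' \code{gamma_star}.
#'
#' @param k_R transcription rate of the target mRNA (molecules/time).
#' @param gamma_r decay rate of free mRNA (1/time); must be positive.
#' @param k_on miRNA-mRNA association rate (1/(concentration x time)).
#' @param k_off complex dissociation rate (1/time).
#' @param gamma_star complex degradation rate (1/time).
#' @param m_total total miRNA concentration (free plus bound), held constant.
#'
#' @return An object of class \code{kinetic_params} (a named list).
#' @seealso [reduce_params()], [integrate_titration_ode()]
#' @export
#' @examples
#' kp <- kinetic_params(k_R = 10, gamma_r = 1, k_on = 1, k_off = 1,
#'                      gamma_star = 1, m_total = 5)
#' reduce_params(kp)
kinetic_params <- function(k_R, gamma_r, k_on, k_off, gamma_star, m_total) {
  vals <- c(k_R = k_R, gamma_r = gamma_r, k_on = k_on, k_off = k_off,
            gamma_star = gamma_star, m_total = m_total)
  if (!all(is.finite(vals))) {
    stop("all kinetic parameters must be finite numbers")
  }
  if (any(vals < 0)) {
    stop("kinetic parameters must be non-negative; got negative ",
         paste(names(vals)[vals < 0], collapse = ", "))
  }
  if (gamma_r <= 0) {
    stop("gamma_r must be positive: the unrepressed steady state k_R/gamma_r ",
         "is undefined at gamma_r = 0")
  }
  if (m_total > 0 && k_on <= 0) {
    stop("k_on must be positive when m_total > 0: ",
         "the effective dissociation parameter lambda is undefined at k_on = 0")
  }
  structure(as.list(vals), class = "kinetic_params")
}

#' Reduce kinetic rate constants to the two-parameter steady-state form
#'
#' The steady state of the two-species model depends on the six rate
#' constants only through three combinations: the unrepressed mRNA level
#' \code{r0 = k_R/gamma_r}, the effective dissociation parameter
#' \code{lambda = (k_off + gamma_star)/k_on}, and the effective miRNA
#' abundance \code{theta = (gamma_star/gamma_r) * m_total}. \code{theta}
#' sets where the repression threshold sits and \code{lambda} how sharp it
#' is (\code{1/lambda} is the binding capability).
#'
#' @param kp a [kinetic_params()] object.
#' @return A list with components \code{theta}, \code{lam} and \code{r0},
#'   of class \code{reduced_params}.
#' @export
#' @examples
#' reduce_params(kinetic_params(10, 1, 1, 1, 1, 5)) # theta = 5, lam = 2, r0 = 10
reduce_params <- function(kp) {
  if (!inherits(kp, "kinetic_params")) kp <- do.call(kinetic_params, as.list(kp))
  lam <- if (kp$k_on > 0) (kp$k_off + kp$gamma_star) / kp$k_on else Inf
  structure(list(theta = kp$gamma_star / kp$gamma_r * kp$m_total,
                 lam = lam,
                 r0 = kp$k_R / kp$gamma_r),
            class = "reduced_params")
}

#' @export
print.reduced_params <- function(x, ...) {
  cat(sprintf("Reduced titration parameters: theta = %g, lambda = %g, r0 = %g\n",
              x$theta, x$lam, x$r0))
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(name, " must be finite and non-negative")
  }
  invisible(x)
}

#' Steady-state free mRNA under miRNA titration
#'
#' Closed-form steady state of the titration model: the free (translatable)
#' mRNA level \code{r} is the unique non-negative root of
#' \code{r^2 + r*(lam + theta - r0) - lam*r0 = 0}, i.e.
#' \code{r = ((r0 - theta - lam) + sqrt((r0 - theta - lam)^2 + 4*lam*r0))/2}.
#' At \code{lam = 0} the exact threshold-linear branch
#' \code{max(r0 - theta, 0)} is used: below the threshold \code{r0 = theta}
#' a perfectly binding miRNA silences the target completely, above it the
#' response grows linearly.
#'
#' In the deeply repressed regime (\code{r0 < theta + lam}) the equivalent
#' form \code{2*lam*r0 / ((theta + lam - r0) + sqrt(...))} is used to avoid
#' catastrophic cancellation between the two quadratic-formula terms.
#'
#' @param r0 unrepressed steady-state mRNA level(s), \code{k_R/gamma_r};
#'   vectorized.
#' @param theta effective miRNA abundance (same units as \code{r0}).
#' @param lam effective dissociation parameter (same units as \code{r0}).
#' @return Free mRNA level(s), same length as the recycled inputs.
#' @export
#' @examples
#' steady_state_r(10, theta = 5, lam = 1)  # 2 + sqrt(14)
#' steady_state_r(c(25, 50, 75), theta = 50, lam = 0)  # 0, 0, 25
steady_state_r <- function(r0, theta, lam) {
  check_nonneg(r0, "r0")
  check_nonneg(theta, "theta")
  if (!is.numeric(lam) || any(is.na(lam)) || any(lam < 0)) {
    stop("lam must be non-negative")
  }
  n <- max(length(r0), length(theta), length(lam))
  r0 <- rep_len(r0, n); theta <- rep_len(theta, n); lam <- rep_len(lam, n)
  r <- numeric(n)

  zero <- lam == 0
  r[zero] <- pmax(r0[zero] - theta[zero], 0)
  inf <- is.infinite(lam)
  r[inf] <- r0[inf]

  i <- which(!zero & !inf)
  if (length(i)) {
    a <- r0[i] - theta[i] - lam[i]
    disc <- sqrt(a * a + 4 * lam[i] * r0[i])
    # stable branch: avoid a + disc cancellation when a < 0
    r[i] <- ifelse(a >= 0, (a + disc) / 2, 2 * lam[i] * r0[i] / (disc - a))
  }
  r
}

#' Steady-state miRNA-bound mRNA
#'
#' The bound complex at steady state in reduced units, \code{r0 - r}; always
#' bounded above by the effective miRNA abundance \code{theta}.
#'
#' @inheritParams steady_state_r
#' @return Bound mRNA level(s).
#' @export
steady_state_complex <- function(r0, theta, lam) {
  r0 - steady_state_r(r0, theta, lam)
}

#' Integrate the two-species titration ODEs to steady state
#'
#' Numerically integrates the kinetic system
#' \deqn{dr/dt = k_R - \gamma_r r - k_{on} r (m_{tot} - r^*) + k_{off} r^*}
#' \deqn{dr^*/dt = k_{on} r (m_{tot} - r^*) - (k_{off} + \gamma^*) r^*}
#' from an empty cell to its long-time limit. This is the reference against
#' which the closed-form [steady_state_r()] is validated; the two routes are
#' independent (quadratic root vs. stiff integration).
#'
#' @param kp a [kinetic_params()] object.
#' @param t_start initial integration horizon; defaults to 100 over the
#'   slowest first-order rate in the system. The horizon is doubled until
#'   the net production rates fall below 1e-10 of the gross fluxes, so slow
#'   modes (e.g. weak association at low miRNA levels) are integrated out.
#' @param rtol,atol solver tolerances passed to [deSolve::lsoda()].
#' @return A list with steady-state \code{r}, \code{r_star} and free miRNA
#'   \code{m_free}.
#' @export
integrate_titration_ode <- function(kp, t_start = NULL, rtol = 1e-10,
                                    atol = 1e-12) {
  if (!inherits(kp, "kinetic_params")) kp <- do.call(kinetic_params, as.list(kp))
  derivs <- function(t, y, p) {
    r <- y[1]; rs <- y[2]
    m <- p$m_total - rs
    bind <- p$k_on * r * m
    list(c(p$k_R - p$gamma_r * r - bind + p$k_off * rs,
           bind - (p$k_off + p$gamma_star) * rs))
  }
  if (is.null(t_start)) {
    rates <- c(kp$gamma_r,
               if (kp$gamma_star > 0) kp$gamma_star,
               if (kp$m_total > 0 && kp$k_on > 0)
                 kp$k_on * kp$m_total + kp$k_off + kp$gamma_star)
    t_start <- 100 / min(rates)
  }
  y <- c(r = 0, r_star = 0)
  horizon <- t_start
  for (i in 1:60) {
    out <- deSolve::lsoda(y = y, times = seq(0, horizon, length.out = 11),
                          func = derivs, parms = kp, rtol = rtol,
                          atol = atol, maxsteps = 50000)
    y <- out[nrow(out), c("r", "r_star")]
    # steady when net rates are negligible against the one-way fluxes
    r <- y[["r"]]; rs <- y[["r_star"]]
    bind <- kp$k_on * r * (kp$m_total - rs)
    gross_r <- kp$k_R + kp$gamma_r * r + bind + kp$k_off * rs
    gross_rs <- bind + (kp$k_off + kp$gamma_star) * rs
    d <- unlist(derivs(0, y, kp))
    if (abs(d[1]) <= 1e-10 * gross_r + atol &&
        abs(d[2]) <= 1e-10 * max(gross_rs, atol) + atol) {
      break
    }
    horizon <- horizon * 2
  }
  list(r = unname(y[["r"]]),
       r_star = unname(y[["r_star"]]),
       m_free = kp$m_total - unname(y[["r_star"]]))
}

#' Simulate a dose-response curve of the titration model
#'
#' Evaluates the steady-state free mRNA over a grid of unrepressed levels
#' \code{r0}, the in-silico analogue of scanning reference-channel intensity
#' across transfected cells.
#'
#' @param theta,lam reduced model parameters.
#' @param r0 strictly increasing grid of positive unrepressed levels. See
#'   [r0_log_grid()] for the default log-spaced construction.
#' @return A data frame with columns \code{r0, r, theta, lam}.
#' @export
#' @examples
#' simulate_dose_response(theta = 100, lam = 1, r0 = r0_log_grid(1, 1000, 50))
simulate_dose_response <- function(theta, lam, r0) {
  if (length(r0) == 0) stop("r0 grid must be non-empty")
  if (any(!is.finite(r0)) || any(r0 <= 0)) stop("r0 grid must be positive")
  if (is.unsorted(r0, strictly = TRUE)) {
    stop("r0 grid must be strictly increasing")
  }
  data.frame(r0 = r0, r = steady_state_r(r0, theta, lam),
             theta = theta, lam = lam)
}

#' Log-spaced r0 grid
#'
#' Transfection intensities span decades (lognormal copy-number spread), so
#' dose-response grids default to log spacing.
#'
#' @param from,to positive range endpoints.
#' @param n number of points.
#' @return Strictly increasing numeric vector of length \code{n}.
#' @export
r0_log_grid <- function(from = 1, to = 1000, n = 100) {
  if (from <= 0 || to <= from) stop("need 0 < from < to")
  10^seq(log10(from), log10(to), length.out = n)
}

#' Simulate a grid of titration curves over theta and binding capability
#'
#' Crosses effective miRNA abundances \code{thetas} with binding
#' capabilities \code{inv_lams} (\code{1/lambda}; use \code{Inf} for a
#' perfectly binding miRNA, \code{lambda = 0}) and returns one labeled
#' dose-response curve per combination. Across such a grid the threshold
#' position shifts with \code{theta} while its sharpness is governed by
#' \code{1/lambda}.
#'
#' @param thetas non-empty vector of effective abundances.
#' @param inv_lams non-empty vector of positive binding capabilities
#'   (\code{Inf} allowed as the perfect-binding sentinel).
#' @param r0 grid as in [simulate_dose_response()].
#' @return A data frame of stacked curves with columns
#'   \code{curve_id, theta, inv_lam, lam, r0, r}.
#' @export
#' @examples
#' g <- simulate_titration_grid(c(10, 50, 250), c(0.1, 1, 10),
#'                              r0_log_grid(1, 1000, 25))
#' length(unique(g$curve_id))  # 9
simulate_titration_grid <- function(thetas, inv_lams, r0) {
  if (length(thetas) == 0 || length(inv_lams) == 0) {
    stop("thetas and inv_lams must be non-empty")
  }
  check_nonneg(thetas, "thetas")
  if (any(is.na(inv_lams)) || any(inv_lams <= 0)) {
    stop("inv_lams must be positive (use Inf for lambda = 0)")
  }
  combos <- expand.grid(theta = thetas, inv_lam = inv_lams,
                        KEEP.OUT.ATTRS = FALSE)
  curves <- lapply(seq_len(nrow(combos)), function(k) {
    theta <- combos$theta[k]
    inv_lam <- combos$inv_lam[k]
    lam <- if (is.infinite(inv_lam)) 0 else 1 / inv_lam
    cv <- simulate_dose_response(theta, lam, r0)
    cbind(curve_id = sprintf("theta=%g_invlam=%g", theta, inv_lam),
          cv[, c("theta", "lam", "r0", "r")],
          inv_lam = inv_lam)
  })
  out <- do.call(rbind, curves)
  out[, c("curve_id", "theta", "inv_lam", "lam", "r0", "r")]
}

#' Export simulated curves as CSV
#'
#' Writes a dose-response curve (`r0,r,theta,lam`) or a grid of curves
#' (additionally `curve_id,inv_lam`) in a plain CSV dialect.
#'
#' @param curves data frame from [simulate_dose_response()] or
#'   [simulate_titration_grid()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_curves <- function(curves, path) {
  cols <- c("r0", "r", "theta", "lam")
  if ("curve_id" %in% names(curves)) cols <- c("curve_id", cols, "inv_lam")
  utils::write.csv(curves[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
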