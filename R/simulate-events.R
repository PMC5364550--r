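#' Configuration for the synthetic dual-fluorescence cytometry generator
#'
#' Describes one in-silico transfection experiment with a dual-fluorescence
#' reporter: per-cell plasmid copy numbers are lognormal (with an
#' untransfected zero-copy fraction), the reference channel reads out the
#' unrepressed level r0 and the reporter channel the titration-model steady
#' state, both subject to multiplicative measurement noise and an additive
#' autofluorescence floor.
#'
#' Defaults emulate a transient transfection spanning roughly three decades
#' of reference intensity: median 100 copies with a 1-log (natural)
#' spread, 20% untransfected carrier cells, 15% multiplicative
#' measurement noise and an autofluorescence background of 50 +/- 10
#' intensity units per channel. The seed has no default: every simulated
#' dataset is explicitly reproducible.
#'
#' @param seed integer RNG seed (required).
#' @param n_events number of cells to simulate.
#' @param theta,lam reduced titration parameters of the simulated miRNA, in
#'   copy-number (reference-intensity) units.
#' @param copy_log_mean,copy_log_sd natural-log mean and sd of the per-cell
#'   plasmid copy number.
#' @param untransfected_fraction proportion of cells with zero copies.
#' @param gain_ref,gain_rep proportionality constants mapping r0 and r to
#'   reference and reporter channel intensities.
#' @param meas_log_sd sd of the per-channel multiplicative (natural-log)
#'   measurement noise.
#' @param af_mean,af_sd mean and sd of the additive autofluorescence per
#'   channel (normal truncated at zero).
#' @return A validated list of class \code{uta_sim_config}.
#' @export
#' @examples
#' cfg <- simulation_config(seed = 1, n_events = 1000, theta = 100, lam = 10)
#' ev <- simulate_events(cfg)
#' head(ev)
simulation_config <- function(seed,
                              n_events = 50000,
                              theta = 0,
                              lam = 0,
                              copy_log_mean = log(100),
                              copy_log_sd = 1.0,
                              untransfected_fraction = 0.2,
                              gain_ref = 1,
                              gain_rep = 1,
                              meas_log_sd = 0.15,
                              af_mean = 50,
                              af_sd = 10) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a seed is required: simulated experiments must be reproducible")
  }
  cfg <- list(seed = as.integer(seed), n_events = as.integer(n_events),
              theta = theta, lam = lam,
              copy_log_mean = copy_log_mean, copy_log_sd = copy_log_sd,
              untransfected_fraction = untransfected_fraction,
              gain_ref = gain_ref, gain_rep = gain_rep,
              meas_log_sd = meas_log_sd, af_mean = af_mean, af_sd = af_sd)
  if (cfg$n_events < 0) stop("n_events must be >= 0")
  check_nonneg(cfg$theta, "theta"); check_nonneg(cfg$lam, "lam")
  if (cfg$copy_log_sd < 0 || cfg$meas_log_sd < 0 || cfg$af_sd < 0) {
    stop("standard deviations must be >= 0")
  }
  if (cfg$untransfected_fraction < 0 || cfg$untransfected_fraction > 1) {
    stop("untransfected_fraction must lie in [0, 1]")
  }
  if (cfg$gain_ref <= 0 || cfg$gain_rep <= 0) stop("gains must be positive")
  if (cfg$af_mean < 0) stop("af_mean must be >= 0")
  structure(cfg, class = "uta_sim_config")
}

#' Simulate per-cell two-channel fluorescence events
#'
#' Draws one event table according to a [simulation_config()]: per cell a
#' plasmid copy number C (zero with probability
#' \code{untransfected_fraction}, else lognormal) sets the unrepressed
#' level r0 = C; the observed intensities are
#' \code{ref = gain_ref * r0 * exp(e1) + AF} and
#' \code{rep = gain_rep * steady_state_r(r0, theta, lam) * exp(e2) + AF}
#' with independent Normal(0, meas_log_sd) log-noise per channel and
#' autofluorescence AF ~ Normal(af_mean, af_sd) truncated at zero.
#' Deterministic given the config seed.
#'
#' @param cfg a [simulation_config()].
#' @param sample_id label stored in the \code{sample_id} column.
#' @return A data frame (event table) with columns
#'   \code{event_id, sample_id, ref_intensity, rep_intensity}.
#' @export
simulate_events <- function(cfg, sample_id = "sample1") {
  stopifnot(inherits(cfg, "uta_sim_config"))
  n <- cfg$n_events
  if (n == 0) {
    return(data.frame(event_id = integer(0), sample_id = character(0),
                      ref_intensity = numeric(0), rep_intensity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cfg$seed)

  transfected <- stats::runif(n) >= cfg$untransfected_fraction
  copies <- numeric(n)
  copies[transfected] <- stats::rlnorm(sum(transfected),
                                       cfg$copy_log_mean, cfg$copy_log_sd)
  r0 <- copies
  r <- steady_state_r(r0, cfg$theta, cfg$lam)
  eps_ref <- stats::rnorm(n, 0, cfg$meas_log_sd)
  eps_rep <- stats::rnorm(n, 0, cfg$meas_log_sd)
  af_ref <- pmax(stats::rnorm(n, cfg$af_mean, cfg$af_sd), 0)
  af_rep <- pmax(stats::rnorm(n, cfg$af_mean, cfg$af_sd), 0)

  data.frame(event_id = seq_len(n),
             sample_id = sample_id,
             ref_intensity = cfg$gain_ref * r0 * exp(eps_ref) + af_ref,
             rep_intensity = cfg$gain_rep * r * exp(eps_rep) + af_rep,
             stringsAsFactors = FALSE)
}

#' Effective dissociation parameter for multi-copy target sites
#'
#' Binding capability 1/lambda is taken proportional to the number of
#' miRNA target-site copies in the reporter 3'UTR, so
#' \code{lambda_eff = lam_single / copies}. A bulged (imperfectly paired)
#' site is modelled as 0.2 copy equivalents, weakening binding fivefold.
#'
#' @param lam_single lambda of a single perfect site; positive.
#' @param copies copy-number equivalents; positive (0.2 for a bulged site).
#' @return The effective lambda.
#' @export
#' @examples
#' effective_lambda(10, copies = 2)          # 5
#' effective_lambda(10, copies = bulged_site_copies())  # 50
effective_lambda <- function(lam_single, copies) {
  if (any(!is.finite(lam_single)) || any(lam_single <= 0)) {
    stop("lam_single must be positive")
  }
  if (any(!is.finite(copies)) || any(copies <= 0)) {
    stop("copies must be positive")
  }
  lam_single / copies
}

#' Copy-number equivalent of a bulged target site
#' @return The constant 0.2.
#' @export
bulged_site_copies <- function() 0.2

#' Effective miRNA abundance under siRNA competition
#'
#' An excess of co-transfected siRNA outcompetes the endogenous miRNA for
#' the silencing machinery, reducing the number of effective miRNA
#' molecules. Modelled as hyperbolic saturation:
#' \code{theta_eff = theta / (1 + sirna_dose/half_dose)} - a shift of the
#' transfer function with no change of its sharpness.
#'
#' @param theta uncompeted effective abundance.
#' @param sirna_dose competing siRNA dose (arbitrary units, >= 0).
#' @param half_dose dose at which theta is halved; positive.
#' @return The effective theta.
#' @export
effective_theta_competition <- function(theta, sirna_dose, half_dose) {
  check_nonneg(theta, "theta")
  check_nonneg(sirna_dose, "sirna_dose")
  if (any(!is.finite(half_dose)) || any(half_dose <= 0)) {
    stop("half_dose must be positive")
  }
  theta / (1 + sirna_dose / half_dose)
}
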