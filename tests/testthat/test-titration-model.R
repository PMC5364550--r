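test_that("kinetic reduction matches the closed formulas and the ODE limit", {
  kp <- kinetic_params(k_R = 10, gamma_r = 1, k_on = 1, k_off = 1,
                       gamma_star = 1, m_total = 5)
  rp <- reduce_params(kp)
  expect_equal(rp$r0, 10)
  expect_equal(rp$lam, 2)
  expect_equal(rp$theta, 5)
  ode <- integrate_titration_ode(kp)
  expect_equal(steady_state_r(rp$r0, rp$theta, rp$lam), ode$r,
               tolerance = 1e-6)

  kp2 <- kinetic_params(k_R = 7, gamma_r = 1, k_on = 2, k_off = 4,
                        gamma_star = 2, m_total = 3)
  rp2 <- reduce_params(kp2)
  expect_equal(rp2$lam, 3)
  expect_equal(rp2$theta, 6)
  expect_equal(steady_state_r(rp2$r0, rp2$theta, rp2$lam),
               integrate_titration_ode(kp2)$r, tolerance = 1e-6)

  # no miRNA at all: theta is zero whatever the kinetics
  expect_equal(reduce_params(kinetic_params(5, 2, 1, 1, 1, 0))$theta, 0)
})

test_that("degenerate kinetic parameterizations are rejected by name", {
  expect_error(kinetic_params(10, 0, 1, 1, 1, 5), "gamma_r")
  expect_error(kinetic_params(10, 1, 0, 1, 1, 5), "k_on")
  expect_error(kinetic_params(-1, 1, 1, 1, 1, 5), "k_R")
})

test_that("closed-form steady state reproduces hand-derived values", {
  # no miRNA: no repression
  expect_equal(steady_state_r(5, theta = 0, lam = 3), 5)
  # perfect binding: threshold-linear
  expect_equal(steady_state_r(4, theta = 10, lam = 0), 0)
  expect_equal(steady_state_r(15, theta = 10, lam = 0), 5)
  # quadratic root (10 - 5 - 1 + sqrt(16 + 40))/2 = 2 + sqrt(14)
  expect_equal(steady_state_r(10, theta = 5, lam = 1), 2 + sqrt(14))
  # bound complex is the complement
  expect_equal(steady_state_complex(10, theta = 5, lam = 1), 8 - sqrt(14))
  expect_equal(steady_state_complex(7, theta = 0, lam = 2), 0)
  # binding abolished at huge lambda
  expect_lt(steady_state_complex(10, theta = 5, lam = 1e9), 1e-6)
  expect_error(steady_state_r(-1, 1, 1), "non-negative")
})

test_that("steady state satisfies quadratic, monotonicity, limit and conservation properties", {
  set.seed(7)
  for (i in 1:100) {
    r0 <- 10^runif(1, -2, 3)
    theta <- 10^runif(1, -2, 3)
    lam <- 10^runif(1, -2, 3)
    r <- steady_state_r(r0, theta, lam)
    # quadratic residual, relative to the largest term
    resid <- r^2 + r * (lam + theta - r0) - lam * r0
    scale <- max(r^2, lam * r0, abs(r * (lam + theta - r0)))
    expect_lt(abs(resid) / scale, 1e-9)
    # conservation: repressed amount within [0, theta]
    expect_gte(r0 - r, -1e-12 * r0)
    expect_lte(r0 - r, theta * (1 + 1e-9))
    # perfect-binding limit is the exact branch
    expect_identical(steady_state_r(r0, theta, 0), max(r0 - theta, 0))
    # weak-binding limit recovers the unrepressed level
    big <- 1e6 * max(r0, theta)
    expect_lt(abs(steady_state_r(r0, theta, big) - r0) / r0, 1e-5)
  }

  # monotone in each argument
  r0s <- 10^seq(-2, 3, length.out = 40)
  lams <- 10^seq(-2, 3, length.out = 40)
  thetas <- 10^seq(-2, 3, length.out = 40)
  expect_true(all(diff(steady_state_r(r0s, 50, 3)) > 0))
  expect_true(all(diff(steady_state_r(20, 50, lams)) > 0))
  expect_true(all(diff(steady_state_r(20, thetas, 3)) < 0))
})

test_that("dose-response simulation is the pointwise steady state on a valid grid", {
  expect_equal(simulate_dose_response(theta = 0, lam = 1, r0 = c(1, 2, 3))$r,
               c(1, 2, 3))
  one <- simulate_dose_response(theta = 5, lam = 1, r0 = 10)
  expect_equal(one$r, 2 + sqrt(14))

  grid <- r0_log_grid(1, 1000, 60)
  cv <- simulate_dose_response(theta = 100, lam = 1, r0 = grid)
  expect_true(all(diff(cv$r) > 0))
  # strongly repressed far below the threshold, linear far above it
  expect_lt(cv$r[1] / cv$r0[1], 0.05)
  expect_equal(cv$r[60], cv$r0[60] - 100, tolerance = 1e-2)

  expect_error(simulate_dose_response(1, 1, numeric(0)), "non-empty")
  expect_error(simulate_dose_response(1, 1, c(2, 1, 3)), "increasing")
  expect_error(simulate_dose_response(1, 1, c(-1, 2)), "positive")
})

test_that("grid simulation crosses theta with binding capability into labeled curves", {
  grid <- r0_log_grid(1, 1000, 25)
  g <- simulate_titration_grid(c(10, 50, 250), c(0.1, 1, 10), grid)
  expect_equal(length(unique(g$curve_id)), 9)
  expect_equal(nrow(g), 9 * 25)
  expect_setequal(unique(g$theta), c(10, 50, 250))
  expect_setequal(unique(g$inv_lam), c(0.1, 1, 10))

  # 1 x 1 grid degenerates to a single dose-response curve
  g1 <- simulate_titration_grid(50, 2, grid)
  expect_equal(g1$r, simulate_dose_response(50, 0.5, grid)$r)

  # theta = 0 gives the identity curve for every binding capability
  g0 <- simulate_titration_grid(0, c(0.1, 10, Inf), grid)
  expect_equal(g0$r, rep(grid, 3))

  # Inf binding capability is the perfect-binding (lambda = 0) sentinel
  gp <- simulate_titration_grid(100, Inf, grid)
  expect_equal(gp$r, pmax(grid - 100, 0))

  expect_error(simulate_titration_grid(numeric(0), 1, grid), "non-empty")
  expect_error(simulate_titration_grid(10, -1, grid), "positive")
})

test_that("curve CSV export carries the documented columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_curves(simulate_dose_response(5, 1, c(1, 10)), path)
  d <- read.csv(path)
  expect_named(d, c("r0", "r", "theta", "lam"))
  write_curves(simulate_titration_grid(c(1, 2), 1, c(1, 10)), path)
  d <- read.csv(path)
  expect_named(d, c("curve_id", "r0", "r", "theta", "lam", "inv_lam"))
})
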