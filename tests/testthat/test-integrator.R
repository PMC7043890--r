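test_that("the continuous leaky integrator solves its ODE exactly", {
  tau <- 435
  # pure decay from 1 with zero input
  y <- integrate_continuous(times = tau, x = 0, tau_leak = tau, y0 = 1,
                            dt_out = tau / 10)
  expect_equal(y$y[nrow(y)], exp(-1), tolerance = 1e-12)
  # constant input relaxes to the fixed point x * tau
  y2 <- integrate_continuous(times = 20 * tau, x = 0.001, tau_leak = tau,
                             dt_out = tau)
  expect_equal(y2$y[nrow(y2)], 0.001 * tau, tolerance = 1e-8)

  # the discrete recursion converges to the continuous solution as dt -> 0
  err <- sapply(c(0.5, 0.05), function(dt) {
    t_end <- 200
    xs <- rep(0.002, t_end / dt)
    yd <- integrate_discrete(xs, dt, tau)
    yc <- integrate_continuous(t_end, 0.002, tau, dt_out = dt)$y[-1]
    max(abs(yd - yc))
  })
  expect_lt(err[2], err[1] / 5)   # first-order in dt
})

test_that("the discrete recursion has the published limiting behaviours", {
  dt <- 0.05
  x <- as.numeric(stats::runif(400) > 0.8)
  # infinite leak: a running sum (event counter for digital input)
  y_sum <- integrate_discrete(x, dt, tau_leak = 1e12)
  expect_equal(y_sum, cumsum(x * dt), tolerance = 1e-9)
  # vanishing leak: a scaled copy of the input
  y_copy <- integrate_discrete(x, dt, tau_leak = 1e-9)
  expect_equal(y_copy, x * dt)
  # a unit impulse decays exponentially afterwards
  imp <- c(1, rep(0, 99))
  y_imp <- integrate_discrete(imp, dt, tau_leak = 3)
  n <- seq_along(y_imp)
  expect_equal(y_imp, dt * exp(-(n - 1) * dt / 3), tolerance = 1e-12)

  # linearity: superposition holds exactly
  x1 <- as.numeric(stats::runif(200) > 0.5)
  x2 <- as.numeric(stats::runif(200) > 0.5)
  expect_equal(integrate_discrete(x1 + x2, dt, 100),
               integrate_discrete(x1, dt, 100) +
                 integrate_discrete(x2, dt, 100),
               tolerance = 1e-12)
})

test_that("the saturating form is bounded, nonlinear, and loads y_inc per pulse", {
  p <- leaky_integrator_params(tau_leak = 435, dt = 0.05, y_inc = 0.2,
                               t_p = 5)
  # bounded in [0, 1] for adversarial digital inputs
  set.seed(11)
  for (i in 1:5) {
    x <- as.numeric(stats::runif(4000) > stats::runif(1, 0.05, 0.95))
    y <- integrate_saturating(x, p, y0 = stats::runif(1))
    expect_gte(min(y), 0)
    expect_lte(max(y), 1)
  }
  # sustained input saturates monotonically onto the recursion's fixed
  # point g / (1 - e + g e), with g = y_inc dt / t_p and e the per-step
  # leak factor (the leak keeps the plateau just below 1)
  y_on <- integrate_saturating(rep(1, 60000), p)
  expect_true(all(diff(y_on) >= -1e-15))
  e <- exp(-p$dt / p$tau_leak); g <- p$y_inc * p$dt / p$t_p
  expect_equal(y_on[length(y_on)], g / (1 - e + g * e), tolerance = 1e-8)

  # single step spanning the whole pulse gives exactly y_inc from rest
  p1 <- leaky_integrator_params(tau_leak = 435, dt = 5, y_inc = 0.2, t_p = 5)
  expect_equal(integrate_saturating(1, p1), 0.2, tolerance = 1e-12)

  # a full pulse from rest loads ~y_inc (within the compounding error)
  pslow <- leaky_integrator_params(tau_leak = 1e7, dt = 0.05, y_inc = 0.2,
                                   t_p = 5)
  y_pulse <- integrate_saturating(rep(1, 100), pslow)
  expect_lt(abs(y_pulse[100] - 0.2), 0.025)

  # superposition must fail for the saturating form
  x1 <- pulse_train_input(10, 5, 500, 0.05)
  x2 <- pulse_train_input(20, 5, 500, 0.05)
  y12 <- integrate_saturating(pmin(x1 + x2, 1), p)
  expect_gt(max(abs(y12 - (integrate_saturating(x1, p) +
                             integrate_saturating(x2, p)))), 0.05)

  expect_error(integrate_saturating(c(0, 0.5), p), "digital")
  expect_error(leaky_integrator_params(dt = 6, t_p = 5), "t_p")
})

test_that("steady integrator output increases with pulse frequency", {
  p <- leaky_integrator_params()
  steady <- sapply(c(2, 10, 50, 100), function(f) {
    x <- pulse_train_input(f, 5, 6000, p$dt)
    mean(utils::tail(integrate_saturating(x, p), round(1000 / max(f, 1) / p$dt)))
  })
  expect_true(all(diff(steady) > 0))
})

test_that("model and integrator agree at low rates and part ways under constant input", {
  freqs <- c(2, 100)
  fr <- frequency_response(fix_lti(), freqs, duration = 6000)
  fr_const <- frequency_response(fix_lti(), 200, pulse_ms = 5,
                                 duration = 1000)  # pulse = period
  fr_const$freq_hz <- 200
  model_resp <- rbind(fr, fr_const)
  p <- leaky_integrator_params(tau_leak = 435, dt = 0.05, y_inc = 0.2,
                               t_p = 5)
  cmp <- compare_ps_vs_integrator(model_resp, p, pulse_ms = 5)
  expect_equal(nrow(cmp), 3)
  # close at 2 Hz
  expect_lt(abs(cmp$mean_diff[1]), 0.05)
  # under constant input the integrator saturates near its upper plateau
  # while the model relaxes to its equilibrium S occupancy ~0.7
  expect_gt(cmp$integ_mean[3], 0.9)
  expect_lt(cmp$model_mean[3], 0.75)
  expect_gt(abs(cmp$mean_diff[3]), abs(cmp$mean_diff[1]))

  # identical steady statistics give zero deviation
  self <- model_resp
  cmp0 <- compare_ps_vs_integrator(self, p, pulse_ms = 5)
  self2 <- self
  self2$ps_min <- cmp0$integ_min; self2$ps_max <- cmp0$integ_max
  self2$ps_mean <- cmp0$integ_mean
  cmp_self <- compare_ps_vs_integrator(self2, p, pulse_ms = 5)
  expect_equal(cmp_self$mean_diff, rep(0, 3), tolerance = 1e-12)
})
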