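test_that("voltage-dependent rates follow the exponential barrier form", {
  expect_equal(eval_rate(rate_constant(400.8, -0.011), 0), 400.8)
  expect_equal(eval_rate(rate_constant(0.207, -0.031), 0), 0.207)
  # voltage-independent rate is constant at any potential
  rc <- rate_constant(3.7, 0)
  expect_equal(eval_rate(rc, c(-120, 0, 55)), rep(3.7, 3))
  # explicit value off zero
  expect_equal(eval_rate(rate_constant(2, -0.05), -80), 2 * exp(4))
  expect_error(eval_rate(rate_constant(1, 10), -100), "out of range")
  expect_error(rate_constant(-1, 0), "positive")
  expect_error(rate_constant(1, Inf), "finite")
})

test_that("generator matrices have the row-vector convention and validate", {
  Q <- build_generator(two_state_scheme(1.5, 0.5), 0)
  expect_equal(matrix(Q, 2, 2), matrix(c(-1.5, 0.5, 1.5, -0.5), 2, 2))
  expect_equal(rowSums(Q), c(S1 = 0, S2 = 0))

  Q13 <- build_generator(fix_lti()$scheme, 0)
  expect_equal(dim(Q13), c(13, 13))
  expect_equal(max(abs(rowSums(Q13))), 0, tolerance = 1e-12)
  expect_true(all(Q13[upper.tri(Q13) | lower.tri(Q13)] >= 0))

  dup <- data.frame(from = c("A", "A"), to = c("B", "B"),
                    k0 = c(1, 2), k1 = 0)
  expect_error(kinetic_scheme(c("A", "B"), c(FALSE, FALSE), dup),
               "duplicate")
  orphan <- data.frame(from = "A", to = "B", k0 = 1, k1 = 0)
  expect_error(kinetic_scheme(c("A", "B", "C"), rep(FALSE, 3), orphan),
               "not connected")
})

test_that("propagation matches the two-state closed form and conserves mass", {
  a <- 2.3; b <- 0.7
  Q <- build_generator(two_state_scheme(a, b), 0)
  P0 <- c(1, 0)
  expect_equal(propagate(P0, Q, 0), c(S1 = 1, S2 = 0))
  for (dt in c(0.1, 0.5, 2, 10)) {
    P <- propagate(P0, Q, dt)
    expected <- b / (a + b) + a / (a + b) * exp(-(a + b) * dt)
    expect_equal(unname(P[1]), expected, tolerance = 1e-10)
    expect_equal(sum(P), 1, tolerance = 1e-12)
  }
  Qbad <- Q; Qbad[1, 2] <- NaN
  expect_error(propagate(P0, Qbad, 1), "non-finite")
  expect_error(propagate(c(0.7, 0.7), Q, 1), "sum to 1")
})

test_that("stationary distributions solve P Q = 0 and reject reducibility", {
  a <- 1.2; b <- 3.4
  P <- stationary_distribution(build_generator(two_state_scheme(a, b), 0))
  expect_equal(unname(P), c(b, a) / (a + b), tolerance = 1e-10)
  Psym <- stationary_distribution(build_generator(two_state_scheme(2, 2), 0))
  expect_equal(unname(Psym), c(0.5, 0.5), tolerance = 1e-10)

  P13 <- stationary_distribution(build_generator(fix_lti()$scheme, -80))
  expect_equal(max(abs(P13 %*% build_generator(fix_lti()$scheme, -80))), 0,
               tolerance = 1e-10)
  expect_equal(sum(P13), 1, tolerance = 1e-12)

  # two absorbing pairs bridged by a transient state: stationary not unique
  red <- kinetic_scheme(
    c("A", "B", "C", "D", "E"), rep(FALSE, 5),
    data.frame(from = c("A", "B", "C", "C", "D", "E"),
               to = c("B", "A", "B", "D", "E", "D"),
               k0 = 1, k1 = 0))
  expect_error(stationary_distribution(build_generator(red, 0)),
               "reducible")
})

test_that("protocol propagation is exact: fixed point, step invariance, Euler oracle", {
  lti <- fix_lti()
  # constant voltage from the stationary state stays put
  P0 <- rested(lti, -80)
  traj <- run_protocol(lti, voltage_protocol(50, -80), P0 = P0, dt_out = 1)
  expect_lt(max(abs(sweep(traj$P, 2, P0))), 1e-9)

  # sampling-interval invariance at shared time points
  prot <- voltage_protocol(c(5, 10), c(0, -80))
  t1 <- run_protocol(lti, prot, P0 = P0, dt_out = 0.1)
  t2 <- run_protocol(lti, prot, P0 = P0, dt_out = 0.01)
  shared <- match(round(t1$times, 9), round(t2$times, 9))
  expect_false(anyNA(shared))
  expect_lt(max(abs(t1$P - t2$P[shared, ])), 1e-9)

  # independent fine-step forward-Euler oracle on random small schemes
  for (seed in 1:3) {
    sch <- random_scheme(3, seed)
    Q <- build_generator(sch, -20)
    P0r <- rep(1 / 3, 3)
    ref <- euler_propagate(P0r, Q, t_end = 1, dt = 1e-4)
    got <- run_protocol(sch, voltage_protocol(1, -20), P0 = P0r,
                        dt_out = 0.5)
    expect_lt(max(abs(got$P[nrow(got$P), ] - ref)), 1e-6)
  }
})

test_that("trajectories conserve probability and stay non-negative", {
  lti <- fix_lti()
  prot <- pulse_train_protocol(-80, 0, 5, 20, 10)
  traj <- run_protocol(lti, prot, dt_out = 0.05)
  expect_lt(max(abs(rowSums(traj$P) - 1)), 1e-9)
  expect_gt(min(traj$P), -1e-12)

  # long constant depolarisation converges to the stationary distribution
  Pinf <- stationary_distribution(build_generator(lti$scheme, 0))
  tr <- run_protocol(lti, voltage_protocol(20000, 0), dt_out = 500)
  expect_lt(max(abs(tr$P[nrow(tr$P), ] - Pinf)), 1e-6)
})

test_that("a brief depolarisation splits channels ~80/20 between I and S", {
  lti <- fix_lti()
  traj <- run_protocol(lti, voltage_protocol(5, 0), P0 = rested(lti),
                       dt_out = 0.01)
  n <- length(traj$times)
  expect_equal(p_inactivated(traj)[n], 0.8, tolerance = 0.05)
  expect_equal(p_lti(traj)[n], 0.2, tolerance = 0.05)
  # the fast phase is essentially complete within a couple of milliseconds
  i2 <- which.min(abs(traj$times - 2))
  expect_equal(p_lti(traj)[i2], 0.2, tolerance = 0.05)
  expect_lt(open_probability(traj)[n], 0.01)
})

test_that("the rate-table reader handles units and the bundled table is sound", {
  tab <- nav_rate_table()
  expect_equal(attr(tab, "units_declared"), "per_s")
  expect_setequal(unique(c(tab$from, tab$to)),
                  c(paste0("C", 1:5), "O6", paste0("I", 7:12), "S13"))
  os <- tab[tab$from == "O6" & tab$to == "S13", ]
  so <- tab[tab$from == "S13" & tab$to == "O6", ]
  expect_equal(os$k0, 400.8e-3, tolerance = 1e-9)  # per-ms scale
  expect_equal(os$k1, -0.011)
  expect_equal(so$k0, 0.207e-3, tolerance = 1e-9)
  expect_equal(so$k1, -0.031)

  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: per_ms", "from,to,k0,k1", "A,B,2,0", "B,A,1,0"),
             tmp)
  expect_equal(read_rate_table(tmp)$k0, c(2, 1))
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# units: per_s", "from,to,k0,k1", "A,B,2000,0", "B,A,1,0"),
             tmp2)
  expect_equal(read_rate_table(tmp2)$k0, c(2, 0.001))
  tmp3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("from,to,k0", "A,B,1"), tmp3)
  expect_error(read_rate_table(tmp3), "columns")
})
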