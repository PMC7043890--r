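test_that("spike detection, instantaneous and steady frequency behave", {
  t <- seq(0, 2000, by = 0.5)
  expect_length(detect_spikes(t, rep(-60, length(t))), 0)

  # synthetic 4 Hz spike train over 2 s -> 8 spikes
  v <- rep(-60, length(t))
  centres <- seq(125, 1875, by = 250)
  for (ct in centres) v <- pmax(v, 20 - 80 * abs(t - ct))
  sp <- detect_spikes(t, v)
  expect_length(sp, 8)
  expect_equal(sp, centres, tolerance = 1e-6)

  # a double crossing within the refractory interval counts once
  v2 <- rep(-60, length(t))
  v2[t >= 100 & t < 101] <- 0
  v2[t >= 102 & t < 103] <- 0
  expect_length(detect_spikes(t, v2, min_isi = 5), 1)

  inst <- instantaneous_frequency(centres)
  expect_equal(inst$freq_hz, rep(4, 7))
  expect_equal(nrow(instantaneous_frequency(100)), 0)
  accel <- cumsum(seq(100, 10, length.out = 10))
  expect_true(all(diff(instantaneous_frequency(accel)$freq_hz) > 0))

  expect_equal(steady_frequency(centres, c(0, 2000)), 4)
  expect_equal(steady_frequency(numeric(0), c(0, 2000)), 0)
  # an adapting train is slower in the second half than the first
  adapt <- cumsum(seq(50, 400, length.out = 20))
  f_steady <- steady_frequency(adapt, c(0, max(adapt)))
  f_first <- mean(instantaneous_frequency(
    adapt[adapt <= max(adapt) / 2])$freq_hz)
  expect_lt(f_steady, f_first)
})

test_that("the hybrid loop conserves occupancy and is step-size robust", {
  host <- host_neuron()
  lti <- fix_lti()
  s <- simulate_hybrid(host, lti, g_na_density = 10, duration = 6000,
                       grid = fix_grid(lti))
  expect_lt(s$conservation_err, 1e-8)
  expect_true(all(diff(s$spikes) > 0))
  expect_true(all(s$V >= -120 & s$V <= 60))

  s_half <- simulate_hybrid(host, lti, g_na_density = 10, duration = 6000,
                            dt = 0.01, grid = fix_grid(lti, 0.01))
  f1 <- steady_frequency(s$spikes, c(0, 6000))
  f2 <- steady_frequency(s_half$spikes, c(0, 6000))
  expect_lt(abs(f1 - f2) / f1, 0.02)
})

test_that("the surrogate host shows the calibrated pacemaker phenotype", {
  host <- host_neuron()
  non <- fix_non_lti()
  s <- simulate_hybrid(host, non, g_na_density = 10, duration = 10000,
                       grid = fix_grid(non))
  f <- steady_frequency(s$spikes, c(0, 10000))
  expect_gt(f, 3); expect_lt(f, 8)
  w <- spike_width(s)
  expect_gt(w, 3); expect_lt(w, 6)
  isi <- diff(s$spikes[s$spikes > 5000])
  expect_lt(stats::sd(isi) / mean(isi), 0.1)   # regular pacemaking

  # without any regenerative current there are no spikes
  passive <- host_neuron(g_shoulder = 0)
  s0 <- simulate_hybrid(passive, non, g_na_density = 1e-9,
                        duration = 3000, grid = fix_grid(non))
  expect_length(s0$spikes, 0)
})

test_that("long-term inactivation lowers the firing rate at equal conductance", {
  host <- host_neuron()
  res <- frequency_vs_gna(host, list(lti = fix_lti(), non_lti = fix_non_lti()),
                          gna_list = c(5, 10, 20), duration = 10000)
  cv <- res$curve
  f_l <- cv$freq_hz[cv$variant == "lti"]
  f_n <- cv$freq_hz[cv$variant == "non_lti"]
  expect_true(all(f_l > 0))
  expect_true(all(f_l < f_n))                    # LTI strictly slower
  expect_gt(res$fits$lti[["slope"]], 0)          # both curves rise with G_Na
  expect_gt(res$fits$non_lti[["slope"]], 0)
})

test_that("the S occupancy tracks firing frequency during free firing", {
  host <- host_neuron()
  lti <- fix_lti()
  out <- sapply(c(5, 15), function(g) {
    s <- simulate_hybrid(host, lti, g_na_density = g, duration = 10000,
                         grid = fix_grid(lti))
    n <- length(s$ps1)
    c(f = steady_frequency(s$spikes, c(0, 10000)),
      ps = mean(s$ps1[(n - n %/% 3):n]))
  })
  expect_gt(out["ps", 1], 0.05)          # nonzero steady level
  expect_gt(out["f", 2], out["f", 1])
  expect_gt(out["ps", 2], out["ps", 1])  # higher rate, higher occupancy
})

test_that("depolarising bias reveals the flatter, adapting LTI response", {
  host <- host_neuron()
  navs <- list(lti = fix_lti(), non_lti = fix_non_lti())
  r <- frequency_vs_iinj(host, navs, iinj_steps = c(0, 40),
                         g_na_density = 10, mode = "rest", step_ms = 8000)
  rl <- r[r$variant == "lti", ]; rn <- r[r$variant == "non_lti", ]
  expect_true(all(rl$freq_steady < rn$freq_steady))
  # smaller total rise over the input range: the stationary response is flatter
  expect_lt(diff(rl$freq_steady), diff(rn$freq_steady))
  # the initial frequency transient decays (adaptation) at the largest step
  expect_gt(rl$adapt_depth[rl$i_inj == 40], 0)
  expect_warning(current_steps(100, 60), "40 pA")
})

test_that("swapping the active model from LTI to non-LTI raises the rate", {
  host <- host_neuron()
  navs <- list(lti = fix_lti(), non_lti = fix_non_lti())
  r <- frequency_vs_iinj(host, navs, iinj_steps = 20, g_na_density = 10,
                         mode = "alternate", step_ms = 8000)
  expect_gt(r$freq_steady[r$variant == "non_lti"],
            r$freq_steady[r$variant == "lti"])
})
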