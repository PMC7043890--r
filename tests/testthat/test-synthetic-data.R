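test_that("the built-in recovery parameter sets carry the published values", {
  sets <- builtin_param_sets()
  expect_equal(nrow(sets), 4)
  neo80 <- recovery_ground_truth("neonatal", -80)
  expect_equal(unlist(neo80[c("a_fast", "tau_fast_ms", "a_slow",
                              "tau_slow_ms")], use.names = FALSE),
               c(0.786, 3.14, 0.212, 612))
  expect_equal(neo80$n_cells, 18)
  expect_equal(neo80$se_tau_slow, 76)
  mat100 <- recovery_ground_truth("mature", -100)
  expect_equal(unlist(mat100[c("a_fast", "tau_fast_ms", "a_slow",
                               "tau_slow_ms")], use.names = FALSE),
               c(0.74, 5.25, 0.252, 247))
  # amplitude pairs sum to ~1 in every set
  expect_true(all(sets$a_fast + sets$a_slow >= 0.95 &
                    sets$a_fast + sets$a_slow <= 1.05))
  expect_error(recovery_ground_truth("neonatal", -60), "no built-in")
})

test_that("the recovery generator is seed-reproducible and noise-faithful", {
  truth <- recovery_ground_truth("neonatal", -80)
  d <- log_spaced_delays(1, 6000, 12)

  clean <- synth_recovery_dataset(truth, d, n_cells = 2,
                                  noise = noise_model(availability_sd = 0,
                                                      seed = 3),
                                  cell_jitter = FALSE)
  expect_equal(clean$availability,
               rep(biexp_availability(d, 0.786, 3.14, 0.212, 612), 2),
               tolerance = 1e-12)

  a <- synth_recovery_dataset(truth, d, n_cells = 5,
                              noise = noise_model(seed = 42))
  b <- synth_recovery_dataset(truth, d, n_cells = 5,
                              noise = noise_model(seed = 42))
  c2 <- synth_recovery_dataset(truth, d, n_cells = 5,
                               noise = noise_model(seed = 43))
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a$availability, c2$availability)))
  expect_true(all(a$availability >= 0 & a$availability <= 1.05))

  # the generator leaves the session RNG stream untouched
  set.seed(99); before <- .Random.seed
  invisible(synth_recovery_dataset(truth, d, 2, noise_model(seed = 7)))
  expect_identical(.Random.seed, before)

  expect_warning(synth_recovery_dataset(truth, delays = c(50, 100), n_cells = 1),
                 "span")
})

test_that("the cohort mean converges to the ground-truth curve", {
  truth <- recovery_ground_truth("neonatal", -80)
  d <- log_spaced_delays(1, 6000, 20)
  big <- synth_recovery_dataset(truth, d, n_cells = 100,
                                noise = noise_model(availability_sd = 0.02,
                                                    seed = 1),
                                cell_jitter = FALSE)
  m <- tapply(big$availability, big$delay_ms, mean)
  expected <- biexp_availability(as.numeric(names(m)), 0.786, 3.14,
                                 0.212, 612)
  expect_lt(max(abs(m - expected)), 3 * 0.02 / sqrt(100))
})

test_that("an 18-cell noisy cohort refits to the generating time constants", {
  truth <- recovery_ground_truth("neonatal", -80)
  ds <- synth_recovery_dataset(truth, log_spaced_delays(1, 6000, 20),
                               n_cells = 18,
                               noise = noise_model(availability_sd = 0.02,
                                                   seed = 5),
                               cell_jitter = FALSE)
  fits <- fit_recovery_cells(ds)
  expect_equal(nrow(fits), 18)
  expect_equal(mean(fits$tau_slow), 612, tolerance = 0.15)
  expect_equal(mean(fits$tau_fast), 3.14, tolerance = 0.15)
})

test_that("noisy pulse-train traces reduce to the clean simulation", {
  lti <- fix_lti()
  clean <- synth_pulse_train_trace(lti, freq = 10, n_pulses = 4,
                                   noise = noise_model(peak_sd_pA = 0))
  ref <- simulate_current(lti, attr(clean, "protocol"),
                          current_sim_settings(g_na = 100), dt_out = 0.02)
  expect_equal(clean$I, ref$I)

  noisy <- synth_pulse_train_trace(lti, freq = 10, n_pulses = 4,
                                   noise = noise_model(peak_sd_pA = 5,
                                                       seed = 2))
  pk_clean <- peaks_from_train(clean, attr(clean, "protocol"))
  pk_noisy <- peaks_from_train(noisy, attr(noisy, "protocol"))
  expect_equal(pk_noisy$availability[1], 1)
  # peaks on the noisy trace stay within a few noise SDs of the clean ones
  expect_lt(max(abs(pk_noisy$peak_I - pk_clean$peak_I)), 4 * 5)
})
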