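test_that("generation is a pure function of the seed", {
  sp <- mi_synth_spec(n_trials_per_class = 3, seed = 42)
  a <- simulate_mi_eeg(sp)
  b <- simulate_mi_eeg(sp)
  expect_identical(a$data, b$data)
  expect_identical(a$labels, b$labels)
  cc <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 3, seed = 43))
  expect_false(identical(a$data, cc$data))
  expect_equal(as.vector(table(a$labels)), c(3, 3))
  expect_equal(n_samples(a), 1000L)
})

test_that("spec invariants are validated", {
  expect_error(mi_synth_spec(n_classes = 3), "2 or 4")
  expect_error(mi_synth_spec(snr = -1), "snr")
  expect_error(mi_synth_spec(erd_channels = list("Oz", "C4")), "subset")
  expect_error(mi_synth_spec(fs = 250, duration = 4.0001), "integer")
})

test_that("background spectra follow the configured 1/f slope", {
  for (alpha in c(0.5, 1, 1.5)) {
    sp <- mi_synth_spec(n_trials_per_class = 4, snr = 0,
                        noise_exponent = alpha, seed = 7)
    x <- simulate_mi_eeg(sp)
    T <- n_samples(x)
    freqs <- (0:(T - 1)) * x$fs / T
    sel <- freqs >= 2 & freqs <= 60
    psd <- rep(0, sum(sel))
    for (i in seq_len(n_trials(x))) for (c in seq_len(n_channels(x)))
      psd <- psd + (Mod(stats::fft(x$data[i, c, ]))^2 / T)[sel]
    fit <- stats::lm(log(psd) ~ log(freqs[sel]))
    expect_lt(abs(stats::coef(fit)[2] + alpha), 0.3)
  }
})

test_that("the class effect is confined to its channels and band", {
  # identical seeds isolate the effect as the difference of the two runs
  base <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 6, snr = 0,
                                        seed = 19))
  on <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 6, snr = 3,
                                      seed = 19))
  eff <- on$data - base$data
  # class 0 rides on C3 (channel 1), class 1 on C4 (channel 3)
  for (cl in 0:1) {
    rows <- which(on$labels == cl)
    target <- if (cl == 0) 1 else 3
    others <- setdiff(1:3, target)
    e_target <- sum(eff[rows, target, ]^2)
    e_others <- sum(eff[rows, others, ]^2)
    expect_lt(e_others, 0.05 * e_target)      # < 5% leakage
    # band confinement: effect power concentrates at the class rhythm
    T <- n_samples(on)
    freqs <- (0:(T - 1)) * on$fs / T
    pw <- rep(0, T)
    for (i in rows) pw <- pw + Mod(stats::fft(eff[i, target, ]))^2
    f_peak <- freqs[which.max(pw[freqs <= 125])]
    expected <- if (cl == 0) 10 else 22
    expect_lt(abs(f_peak - expected), 1)
  }
})

test_that("the band-power baseline brackets the difficulty regimes", {
  # fully separable: disjoint channels, strong rhythms
  sep <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 20, snr = 6,
                                       seed = 3))
  expect_equal(bandpower_baseline(sep, seed = 1), 1.0)

  # no class information at all: chance within 3 SE over repeated draws
  accs <- vapply(1:20, function(s) {
    chance <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 10,
                                            snr = 0, erd_depth = 0,
                                            seed = 100 + s))
    bandpower_baseline(chance, seed = s)
  }, 0)
  n_eval <- 20 * round(0.2 * 20)               # held-out trials pooled
  se <- sqrt(0.25 / n_eval)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)

  # intermediate snr sits between the regimes, nondecreasing in snr
  grid <- c(0.05, 0.2, 2, 6)
  acc_grid <- vapply(grid, function(s) {
    mean(vapply(1:4, function(r) {
      x <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 15, snr = s,
                                         seed = 200 + r))
      bandpower_baseline(x, seed = r)
    }, 0))
  }, 0)
  expect_gt(acc_grid[4], acc_grid[1])
  expect_true(all(diff(acc_grid) > -0.05))     # monotone up to noise
  expect_gt(acc_grid[2], 0.5)
  expect_lt(acc_grid[2], 1)
})

test_that("erd_depth scales the effect like snr does", {
  a <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 2, snr = 2,
                                     erd_depth = 0.5, seed = 5))
  b <- simulate_mi_eeg(mi_synth_spec(n_trials_per_class = 2, snr = 1,
                                     erd_depth = 1, seed = 5))
  expect_equal(a$data, b$data, tolerance = 1e-12)
})
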