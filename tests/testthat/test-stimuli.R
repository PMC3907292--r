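# Forcing functions, spike trains and synthetic fitting fixtures.

test_that("transient waveforms start at baseline, peak at Cmax and decay", {
  cap <- ca_transient_params()
  expect_equal(ca_spike_waveform(0, cap), 0.06)
  expect_equal(ca_spike_waveform(1e4, cap), 0.06, tolerance = 1e-6)
  dap <- da_transient_params()
  expect_equal(da_transient(0, dap), 0.01)
  expect_equal(da_transient(1e7, dap), 0.01, tolerance = 1e-6)
  # peak equals Cmax at the analytic peak time; dense-grid numeric oracle
  tt <- seq(0, 2, by = 1e-4)
  peak_num <- max(ca_spike_waveform(tt, cap))
  expect_equal(peak_num, cap$Cmax, tolerance = 1e-5)
  tp <- log(cap$k1 / cap$k2) / (cap$k1 - cap$k2)
  expect_equal(tt[which.max(ca_spike_waveform(tt, cap))], tp, tolerance = 1e-3)
  tda <- seq(0, 36000, by = 1)
  expect_equal(max(da_transient(tda, dap)), dap$Cmax, tolerance = 1e-5)
})

test_that("the degenerate k1 == k2 transient uses the alpha-function limit", {
  p <- transient_params(0, 1, 2, 2)
  tt <- seq(0, 10, by = 1e-3)
  v <- ca_spike_waveform(tt, p)
  expect_equal(max(v), 1, tolerance = 1e-4)  # still unit peak
  # continuous limit: nearby k1 gives nearly the same curve
  p2 <- transient_params(0, 1, 2 + 1e-9, 2)
  expect_lt(max(abs(v - ca_spike_waveform(tt, p2))), 1e-6)
  expect_error(transient_params(0, 1, 1, 2), "k1")
})

test_that("spike trains are reproducible, correctly spaced and counted", {
  tr <- spike_train(0.1, 1e4, "poisson", seed = 42)
  tr2 <- spike_train(0.1, 1e4, "poisson", seed = 42)
  expect_identical(tr$times, tr2$times)
  expect_lt(abs(length(tr$times) - 1000), 3 * sqrt(1000))
  expect_true(all(diff(tr$times) > 0))
  reg <- spike_train(0.1, 100, "regular")
  expect_equal(reg$times, seq(10, 100, by = 10))
  empty <- spike_train(0, 100, "poisson", seed = 1)
  expect_length(empty$times, 0)
  expect_error(spike_train(-1, 10), "non-negative")
})

test_that("inter-spike intervals are exponential (KS at alpha = 0.01)", {
  tr <- spike_train(0.1, 1.2e5, "poisson", seed = 7)
  gaps <- diff(tr$times)
  expect_gt(length(gaps), 1e4 * 0.9)
  ks <- stats::ks.test(gaps, "pexp", rate = 0.1)
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(gaps), 10, tolerance = 0.05)
})

test_that("the superposed train waveform stays at or above baseline", {
  tr <- spike_train(0.1, 300, "poisson", seed = 3)
  tt <- seq(0, 300, by = 0.05)
  w <- spike_train_waveform(tr, tt)
  expect_true(all(w >= 0.06 - 1e-12))
  # amplitude scaling multiplies only the spike term
  w2 <- spike_train_waveform(tr, tt, amps = rep(2, length(tr$times)))
  expect_true(all(w2 - 0.06 >= 2 * (w - 0.06) - 1e-9))
})

test_that("protocols are fully specified and serialise to JSON", {
  apa <- protocol("APA")
  expect_equal(apa$readout, 900)
  expect_equal(apa$da$type, 2L)
  expect_equal(apa$train$rate, 0.1)
  das <- protocol("DAslice")
  expect_equal(das$da$base, 10)
  expect_equal(das$readout, 300)
  nmda <- protocol("NMDAslice")
  expect_equal(nmda$ca$base, 10)
  pp2b <- protocol("PP2B_inhibition")
  expect_true(pp2b$pp2b_inhibited)
  expect_error(protocol("mystery"), "unknown protocol")

  dir <- withr::local_tempdir()
  f <- write_protocol_json(apa, file.path(dir, "apa.json"))
  apa2 <- read_protocol_json(f)
  expect_equal(apa2$train$times, apa$train$times)
  expect_equal(apa2$da$amp, apa$da$amp)
  f2 <- write_spike_train_csv(apa$train, file.path(dir, "train.csv"))
  tr <- utils::read.csv(f2)
  expect_equal(tr$time, apa$train$times)
})

test_that("synthetic fixtures reproduce their generating curves", {
  d <- synthetic_fit_fixtures("hill", list(Cmin = 0, Cmax = 1, K = 0.8, h = 4.1),
                              noise_sd = 0)
  expect_equal(d$y, d$y_true)
  f <- fit_hill(d$x, d$y)
  expect_equal(f$h, 4.1, tolerance = 1e-5)
  expect_equal(f$K, 0.8, tolerance = 1e-5)

  d2 <- synthetic_fit_fixtures("monoexp", list(A = 1, k = 0.15), noise_sd = 0)
  f2 <- fit_monoexp(d2$x, d2$y)
  expect_equal(f2$k, 0.15, tolerance = 1e-6)

  # seeded noise is reproducible
  n1 <- synthetic_fit_fixtures("hill", list(Cmin = 0, Cmax = 1, K = 1, h = 2),
                               noise_sd = 0.05, seed = 5)
  n2 <- synthetic_fit_fixtures("hill", list(Cmin = 0, Cmax = 1, K = 1, h = 2),
                               noise_sd = 0.05, seed = 5)
  expect_identical(n1$y, n2$y)
  expect_error(synthetic_fit_fixtures("hill", list(), noise_sd = -1),
               "non-negative")
})

test_that("noisy Hill estimates agree with a grid-search oracle", {
  true <- list(Cmin = 0, Cmax = 1, K = 0.8, h = 4.1)
  hs <- Ks <- numeric(10)
  for (s in 1:10) {
    d <- synthetic_fit_fixtures("hill", true, n_points = 15, noise_sd = 0.02,
                                seed = s)
    f <- fit_hill(d$x, d$y)
    # coarse grid-search oracle over (K, h) with analytic Cmin/Cmax fixed
    grid <- expand.grid(K = seq(0.4, 1.6, by = 0.02),
                        h = seq(2, 7, by = 0.05))
    sse <- mapply(function(K, h) {
      yy <- true$Cmin + (true$Cmax - true$Cmin) * d$x^h / (K^h + d$x^h)
      sum((d$y - yy)^2)
    }, grid$K, grid$h)
    best <- grid[which.min(sse), ]
    expect_equal(f$K, best$K, tolerance = 0.1)
    expect_equal(f$h, best$h, tolerance = 0.15)
    hs[s] <- f$h; Ks[s] <- f$K
  }
  # estimator is unbiased within the Monte-Carlo spread at this noise level
  expect_equal(mean(hs), 4.1, tolerance = 0.1)
  expect_equal(mean(Ks), 0.8, tolerance = 0.05)
})
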