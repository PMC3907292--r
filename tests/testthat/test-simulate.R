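# Equilibration, trajectory integration, conservation and scaling factors.

test_that("a closed two-state system equilibrates to the closed form", {
  net <- toy_two_state_network(kf = 0.2, kr = 0.2, total = 1)
  eq <- equilibrate(net, tol = 1e-8, horizon = 1e4)
  expect_true(eq$ok)
  expect_equal(unname(eq$state["A"]), 0.5, tolerance = 1e-6)
  expect_equal(unname(eq$state["B"]), 0.5, tolerance = 1e-6)
  # asymmetric rates: A/B = kr/kf
  net2 <- toy_two_state_network(kf = 0.3, kr = 0.1, total = 1)
  eq2 <- equilibrate(net2, horizon = 1e4)
  expect_equal(unname(eq2$state["A"]), 0.25, tolerance = 1e-6)
})

test_that("zero-stimulus simulation from equilibrium stays at the fixed point", {
  m <- wt_model(); y <- wt_basal()
  tr <- simulate_protocol(m, y, protocol("basal", duration = 600), dt_out = 60)
  drift <- apply(tr$conc, 2, function(col) max(abs(col - col[1])))
  expect_lt(max(drift / pmax(abs(y), 1e-6)), 1e-4)
})

test_that("moiety totals are conserved and concentrations stay non-negative", {
  m <- wt_model(); y <- wt_basal()
  tr <- simulate_protocol(m, y, protocol("APA", duration = 300),
                          mechanism = "yTrf", F = 4)
  expect_true(all(tr$conc > -1e-9))
  md <- moiety_drift(m, tr)
  expect_lt(max(md$max_rel_drift[md$total > 0]), 1e-6)
  # slice protocol as well
  tr2 <- simulate_protocol(m, y, protocol("DAslice"))
  md2 <- moiety_drift(m, tr2)
  expect_lt(max(md2$max_rel_drift[md2$total > 0]), 1e-6)
})

test_that("scaling factors are normalised, capped and ratio-based", {
  m <- wt_model(); y <- wt_basal()
  for (mech in c("sSCh", "yTrf", "ySCh")) {
    R0 <- scaling_ratio(m, y, mech)
    expect_equal(scaling_factor(m, y, mech, F = 8, R0 = R0), 1)
    expect_equal(scaling_factor(m, y, mech, F = 0, R0 = 0.9 * R0), 1)
  }
  # doubling every NMDAR species leaves all ratios (hence the factor) unchanged
  y2 <- y
  nm <- grepl("NMDARm|NMDARi", names(y2))
  y2[nm] <- 2 * y2[nm]
  for (mech in c("sSCh", "yTrf", "ySCh")) {
    expect_equal(scaling_ratio(m, y2, mech), scaling_ratio(m, y, mech),
                 tolerance = 1e-12)
  }
  # factor saturates at the common maximum amplitude
  R0 <- scaling_ratio(m, y, "yTrf")
  ybig <- y; ybig[grepl("NMDARm", names(ybig))] <- 100 * ybig[grepl("NMDARm", names(ybig))]
  expect_equal(scaling_factor(m, ybig, "yTrf", F = 1e3, R0 = R0), 2.5)
  # no membrane NMDAR: undefined
  y0 <- y; y0[grepl("NMDARm", names(y0))] <- 0
  expect_error(scaling_ratio(m, y0, "ySCh"), "undefined")
})

test_that("halving solver tolerances leaves basal markers unchanged (<0.5%)", {
  m <- wt_model()
  eq1 <- suppressWarnings(equilibrate(m, horizon = 3e5, rtol = 1e-7, atol = 1e-10))
  eq2 <- suppressWarnings(equilibrate(m, horizon = 3e5, rtol = 5e-8, atol = 5e-11))
  for (mk in c("cAMP", "D32p34", "D32p75", "STEPact", "GluR1p845")) {
    v1 <- state_marker(eq1$state, mk); v2 <- state_marker(eq2$state, mk)
    expect_lt(abs(v1 - v2) / abs(v1), 0.005)
  }
})

test_that("trajectory accessors, tidiers and plots work", {
  m <- wt_model(); y <- wt_basal()
  tr <- simulate_protocol(m, y, protocol("DAslice"), dt_out = 60)
  expect_s3_class(tr, "msn_traj")
  expect_error(readout(tr, "cAMP", 1e6), "outside")
  st <- traj_state(tr, 150)
  expect_length(st, nrow(m$species))
  d <- tidy(tr, markers = c("cAMP", "D32p34"))
  expect_setequal(unique(d$marker), c("cAMP", "D32p34"))
  g <- glance(tr)
  expect_equal(g$protocol, "DAslice")
  p <- autoplot(tr, markers = c("cAMP", "D32p34"))
  expect_s3_class(p, "ggplot")
  dir <- withr::local_tempdir()
  write_trajectory_csv(tr, file.path(dir, "tr.csv"))
  write_run_metadata(tr, file.path(dir, "tr.json"))
  expect_true(file.exists(file.path(dir, "tr.csv")))
})
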