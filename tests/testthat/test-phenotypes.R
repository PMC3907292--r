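# Marker readouts, the immunoblot correction, curve fits and panel scoring.

test_that("marker readouts sum the right species", {
  m <- wt_model()
  y <- stats::setNames(numeric(nrow(m$species)), m$species$id)
  y["STEP"] <- 0.3
  expect_equal(state_marker(y, "STEPact"), 1)      # nothing phosphorylated
  y["STEPp@S"] <- 0.1; y["STEP"] <- 0.2
  expect_equal(state_marker(y, "STEPact"), 1 - 0.1 / 0.3)
  y2 <- stats::setNames(numeric(nrow(m$species)), m$species$id)
  y2["RASgtp.RAF"] <- 0.5                          # all RAS in the complex
  expect_equal(state_marker(y2, "RASRAF_fraction"), 1)
  y2["RASgdp"] <- 0.5
  expect_equal(state_marker(y2, "RASRAF_fraction"), 0.5)
  expect_error(state_marker(y2, "mystery"), "unknown marker")
})

test_that("the immunoblot correction inverts the forward mixture", {
  # property: ib_correction(ib_mixture(FC)) == FC over a grid
  for (FC in c(1.5, 3, 11, 30)) {
    for (f_c in c(0, 0.05, 0.2)) {
      for (f_t in c(0.5, 0.8, 1)) {
        W <- ib_mixture(FC, f_c, f_t)
        if (f_t > W * f_c)
          expect_equal(ib_correction(W, f_c, f_t), FC, tolerance = 1e-10)
      }
    }
  }
  # no change measured maps to no cell-specific change
  expect_equal(ib_correction(1, 0.3, 0.3), 1)
  # homogeneous fully-responding sample: correction vanishes
  expect_equal(ib_correction(6, 0, 1), 6)
  expect_error(ib_correction(2, 0.9, 0.9), "not invertible")
  expect_error(ib_correction(2, 0, 1.5), "fractions")
})

test_that("the shipped correction examples reproduce the reported pairs", {
  ex <- ib_correction_examples()
  for (i in seq_len(nrow(ex))) {
    expect_equal(ib_correction(ex$W[i], ex$f_c[i], ex$f_t[i]),
                 ex$FC_corrected[i], tolerance = 0.02)
  }
})

test_that("degenerate fit inputs are flagged", {
  expect_error(fit_hill(1:10, rep(1, 10)), "flat")
  expect_warning(f <- fit_monoexp(1:10, rep(2, 10)), "constant")
  expect_equal(f$k, 0)
  expect_warning(fit_monoexp(1:10, c(1:5, 4:0) / 5), "non-monotone")
})

test_that("wt_ratio is 1 for identical genotypes and errors on zero WT fold", {
  mk_traj <- function(v) {
    structure(list(times = c(0, 900),
                   conc = matrix(v, 2, 1,
                                 dimnames = list(NULL, "ERKp@Tp@Y")),
                   scale = c(1, 1)), class = "msn_traj")
  }
  a <- mk_traj(0.4); s <- mk_traj(0.1)
  expect_equal(wt_ratio(a, s, a, s, "ERKpp", 900), 1)
  z <- mk_traj(0.1)
  expect_error(wt_ratio(a, s, z, z, "ERKpp", 900), NA)  # fold 1 is fine
  zero <- mk_traj(0)
  expect_error(wt_ratio(a, s, zero, s, "ERKpp", 900), "zero WT fold")
})

test_that("panel evaluation scores divergences and r2 as documented", {
  panel <- phenotype_panel()
  expect_equal(nrow(panel), 17)
  # perfect agreement
  sim <- stats::setNames(panel$target, panel$variable)
  ev <- evaluate_panel(sim, panel)
  expect_true(all(ev$divergence == 0))
  expect_equal(attr(ev, "r2"), 1)
  # range target scores zero anywhere inside the interval
  sim2 <- sim; sim2["basal-D32p34"] <- 0.42
  ev2 <- evaluate_panel(sim2, panel)
  expect_equal(ev2$divergence[ev2$variable == "basal-D32p34"], 0)
  sim3 <- sim; sim3["basal-D32p34"] <- 0.6
  ev3 <- evaluate_panel(sim3, panel)
  expect_equal(ev3$divergence[ev3$variable == "basal-D32p34"], 0.1 / 0.5)
  # a +50% perturbed value lands beyond the 20% band and is flagged
  sim4 <- sim; sim4["basal-cAMP"] <- sim4["basal-cAMP"] * 1.5
  ev4 <- evaluate_panel(sim4, panel)
  expect_gt(ev4$divergence[ev4$variable == "basal-cAMP"], 0.2)
  expect_lt(attr(ev4, "r2"), 1)
  # r2 is invariant to the ordering of panel variables
  perm <- sample(names(sim4))
  ev5 <- evaluate_panel(sim4[perm], panel[match(perm, panel$variable), ])
  expect_equal(attr(ev5, "r2"), attr(ev4, "r2"))
  expect_error(evaluate_panel(sim[-1], panel), "missing simulated")
  g <- glance(ev4)
  expect_equal(g$n, 17)
})

test_that("fit recovery improves as noise shrinks", {
  true <- list(Cmin = 0, Cmax = 1, K = 0.8, h = 4.1)
  err <- vapply(c(0.05, 0.01, 0), function(sd) {
    d <- synthetic_fit_fixtures("hill", true, n_points = 15, noise_sd = sd,
                                seed = 11)
    abs(fit_hill(d$x, d$y)$h - 4.1)
  }, numeric(1))
  expect_true(all(diff(err) <= 1e-8 + 0.05))  # non-increasing within noise
  expect_lt(err[3], 1e-6)
})
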