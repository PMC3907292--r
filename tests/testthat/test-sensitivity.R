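# Perturbation conventions, analytic sensitivity toys, sensitive sets,
# overlap and ranking.

test_that("perturbation conventions match the K_M / k_cat bookkeeping", {
  m <- wt_model()
  d0 <- derived_constants(m)
  # k_cat perturbation leaves K_M unchanged to 1e-12 relative
  up <- perturb(m, "pp2b3.kcat", +1)
  d1 <- derived_constants(up)
  expect_equal(d1$KM[d1$id == "pp2b3"], d0$KM[d0$id == "pp2b3"],
               tolerance = 1e-12)
  expect_equal(up$params[["pp2b3.kcat"]], m$params[["pp2b3.kcat"]] * 1.005)
  expect_equal(up$params[["pp2b3.kf"]], m$params[["pp2b3.kf"]] * 1.005)
  expect_equal(up$params[["pp2b3.kr"]], m$params[["pp2b3.kr"]] * 1.005)
  # K_M perturbation scales K_M by exactly the factor, k_cat untouched
  km <- perturb(m, "pp2b3.KM", +1)
  d2 <- derived_constants(km)
  expect_equal(d2$KM[d2$id == "pp2b3"], d0$KM[d0$id == "pp2b3"] * 1.005,
               tolerance = 1e-12)
  expect_equal(km$params[["pp2b3.kcat"]], m$params[["pp2b3.kcat"]])
  # totals leave every rate constant unchanged
  tt <- perturb(m, "total.CaM", +1)
  expect_equal(tt$params, m$params)
  expect_equal(tt$totals$total[tt$totals$moiety == "CaM"],
               m$totals$total[m$totals$moiety == "CaM"] * 1.005)
  expect_error(perturb(m, "nope.kf"), "unknown target")
})

test_that("parameter enumeration covers kinetics plus the 40 totals", {
  m <- wt_model()
  pp <- perturbable_parameters(m)
  expect_equal(sum(pp$type == "total"), 40)
  rx <- m$reactions
  n_expected <- 2 * sum(rx$class == "enzymatic") +
    2 * sum(rx$class == "reversible") + sum(rx$class == "irreversible") + 40
  expect_equal(nrow(pp), n_expected)
  expect_false(anyDuplicated(pp$target) > 0)
})

test_that("the sensitivity operator is exact on analytic toys", {
  # a fake 'network' whose outputs are closed forms of two parameters
  fake <- list(params = c(a.kf = 2, b.kf = 3),
               totals = tibble::tibble(moiety = "M", total = 5),
               reactions = tibble::tibble(id = c("a", "b"),
                                          class = "irreversible"))
  outputs <- function(net) {
    p <- net$params[["a.kf"]]; tot <- net$totals$total[1]
    c(linear = 7 * p,          # S = 1 for any c, p > 0
      quadratic = p^2,         # S = 2
      constant = 42,           # S = 0
      total_linear = 3 * tot)  # S = 1 in the total
  }
  S <- sensitivity_matrix(fake, outputs,
                          targets = c("a.kf", "b.kf", "total.M"))
  expect_equal(S["a.kf", "linear"], 1, tolerance = 1e-4)
  expect_equal(S["a.kf", "quadratic"], 2, tolerance = 1e-4)
  expect_equal(S["a.kf", "constant"], 0, tolerance = 1e-12)
  expect_equal(S["b.kf", "linear"], 0, tolerance = 1e-12)
  expect_equal(S["total.M", "total_linear"], 1, tolerance = 1e-4)
  d <- tidy(S)
  expect_equal(nrow(d), 12)
})

test_that("failed perturbed runs are flagged missing, not fatal", {
  fake <- list(params = c(a.kf = 2, bad.kf = 1),
               totals = tibble::tibble(moiety = "M", total = 5),
               reactions = tibble::tibble(id = c("a", "bad"),
                                          class = "irreversible"))
  outputs <- function(net) {
    if (net$params[["bad.kf"]] != 1) stop("boom")
    c(o = net$params[["a.kf"]])
  }
  expect_warning(S <- sensitivity_matrix(fake, outputs,
                                         targets = c("a.kf", "bad.kf")),
                 "failed")
  expect_true(is.na(S["bad.kf", "o"]))
  expect_equal(S["a.kf", "o"], 1, tolerance = 1e-4)
})

test_that("sensitive sets, threshold and summary fractions behave", {
  S <- structure(matrix(c(0.5, 0.1, 0.02,
                          0.4, 0.05, 0.01,
                          0.3, 0.3, 0.001), 3, 3, byrow = TRUE,
                        dimnames = list(c("p1", "p2", "p3"),
                                        c("o1", "o2", "o3"))),
                 class = c("msn_sensitivity", "matrix"))
  ss <- sensitive_sets(S)
  expect_equal(ss$threshold, stats::median(c(0.5, 0.4, 0.3)))
  expect_setequal(ss$sets$o1, c("p1"))          # only p1 exceeds 0.4
  expect_equal(unname(ss$n_sensitive["o3"]), 0L)
  # an all-zero matrix gives empty sets and threshold 0
  Z <- structure(matrix(0, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))),
                 class = c("msn_sensitivity", "matrix"))
  zz <- sensitive_sets(Z)
  expect_equal(zz$threshold, 0)
  expect_true(all(vapply(zz$sets, length, 1L) == 0))
  expect_equal(zz$frac_pairs_sensitive, 0)
})

test_that("overlap follows the larger-set normalisation", {
  expect_equal(overlap(c("a", "b"), c("a", "b")), 1)
  expect_equal(overlap(c("a"), c("b")), 0)
  expect_equal(overlap(c("a"), c("a", "b", "c")), 1 / 3)  # A subset of B
  expect_equal(overlap(character(0), character(0)), 0)
  r <- rank_parameters(S = structure(
    matrix(c(1, 0.1, 0.2, 0.3), 2, 2,
           dimnames = list(c("total.X", "r1.kf"), c("o1", "o2"))),
    class = c("msn_sensitivity", "matrix")))
  expect_equal(r$target[1], "total.X")
  expect_true(r$is_total[1])
})

test_that("a structurally decoupled parameter has zero sensitivity", {
  # in the toy three-reaction network the binding branch cannot influence
  # the enzymatic product and vice versa
  net <- toy_three_reaction_network()
  outputs <- function(n) {
    eq <- equilibrate(n, horizon = 1e4)
    c(D = unname(eq$state["D"]), P = unname(eq$state["P"]))
  }
  S <- sensitivity_matrix(net, outputs,
                          targets = c("b1.kf", "e1.kcat", "total.A"))
  expect_equal(S["b1.kf", "P"], 0, tolerance = 1e-6)
  expect_equal(S["e1.kcat", "D"], 0, tolerance = 1e-6)
  # the drained pool equals the conserved total at steady state: S = 1
  expect_equal(S["total.A", "D"], 1, tolerance = 1e-3)
})
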