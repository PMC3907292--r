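# Network assembly, validation, conserved moieties and table IO.

test_that("a toy network assembles with hand-checkable mass-action terms", {
  net <- toy_three_reaction_network()
  expect_setequal(net$species$id,
                  c("A", "B", "C", "D", "E", "S", "E.S", "P"))
  y <- c(A = 0.4, B = 0.7, C = 0.2, D = 0, E = 0.3, S = 1.5, E.S = 0.1, P = 0.05)
  ptr <- msnsig:::model_pointer(net)
  dy <- rhs_eval(ptr, 0, unname(y[net$species$id]))
  names(dy) <- net$species$id
  # hand-written mass action
  v1 <- 2 * y["A"] * y["B"] - 1 * y["C"]
  v2 <- 0.3 * y["C"]
  vb <- 1 * y["E"] * y["S"] - 0.5 * y["E.S"]
  vc <- 0.2 * y["E.S"]
  expect_equal(dy[["A"]], unname(-v1))
  expect_equal(dy[["C"]], unname(v1 - v2))
  expect_equal(dy[["D"]], unname(v2))
  expect_equal(dy[["E.S"]], unname(vb - vc))
  expect_equal(dy[["P"]], unname(vc))
})

test_that("malformed tables are rejected with informative errors", {
  totals <- tibble::tibble(moiety = c("A", "B"), total = c(1, 1),
                           seed = c("A", "B"))
  reg <- moiety_registry(list(C = c(A = 1, B = 1)))
  expect_error(build_network(rxn_rev("x", "A + B", "C", -1, 1), totals, reg),
               "negative rate constant")
  bad <- rxn_rev("x", "A + B", "C", 1, 1)
  bad$class <- "weird"
  expect_error(build_network(bad, totals, reg), "malformed")
  # unbalanced moieties: A + B -> A would destroy the B pool
  expect_error(build_network(rxn_irr("x", "A + B", "A", 1), totals, reg),
               "mass balance")
  # unknown species reference (moiety not declared in totals)
  expect_error(build_network(rxn_rev("x", "A + Z", "C", 1, 1), totals, reg),
               "unknown moieties")
})

test_that("conserved moieties match the textbook answer and the null space", {
  net <- toy_enzyme_network()
  cm <- conserved_moieties(net)
  expect_equal(nrow(cm), 2)
  e <- cm[cm$moiety == "E", ]
  expect_setequal(e$species[[1]], c("E", "E.S"))
  s <- cm[cm$moiety == "S", ]
  expect_setequal(s$species[[1]], c("S", "E.S", "P"))

  # oracle: moiety vectors lie in the left null space of the stoichiometric
  # matrix computed independently
  skip_if_not_installed("pracma")
  st <- net$steps
  nspec <- nrow(net$species); nsteps <- length(st$par)
  N <- matrix(0, nspec, nsteps)
  for (sdx in seq_len(nsteps)) {
    ix <- if (st$stptr[sdx] < st$stptr[sdx + 1])
      (st$stptr[sdx] + 1):st$stptr[sdx + 1] else integer(0)
    N[st$stspec[ix] + 1, sdx] <- st$stdelta[ix]
  }
  null_basis <- pracma::nullspace(t(N))
  for (i in seq_len(nrow(cm))) {
    w <- numeric(nspec)
    w[match(cm$species[[i]], net$species$id)] <- cm$mult[[i]]
    # projection onto the null space reproduces w
    proj <- null_basis %*% solve(crossprod(null_basis), crossprod(null_basis, w))
    expect_lt(max(abs(proj - w)), 1e-9)
  }
})

test_that("the standard model assembles with its documented structure", {
  m <- wt_model()
  expect_s3_class(m, "msn_network")
  expect_equal(nrow(m$totals), 40)
  cm <- conserved_moieties(m)   # errors if any pool is not conserved
  expect_equal(nrow(cm), 40)
  counts <- table(m$reactions$class)
  expect_true(all(c("enzymatic", "reversible", "irreversible") %in%
                    names(counts)))
  # every reaction references species whose moieties are declared
  expect_true(all(m$species$moiety %in% c(m$totals$moiety, NA)))
  # documented subsystems are present
  for (sp in c("AC5", "PDE1", "PDE4", "PDE10", "PP2A72", "PP2A56", "STEP",
               "Fynp@420p@527", "NMDARmp@Yp@S", "RASgtp.RAF", "MEKp@1p@2",
               "ERKp@Tp@Y", "DUSP", "Gbg.AncGN", "D1R.AncRA"))
    expect_true(sp %in% m$species$id, label = paste("species", sp))
})

test_that("anchor capacities respect the compartment inequalities", {
  tot <- stats::setNames(standard_totals()$total, standard_totals()$moiety)
  expect_lte(tot[["AncRA"]], 0.2 * tot[["D1R"]])
  expect_lte(tot[["AncGN"]], 0.4 * tot[["Gaolf"]])
  p <- wt_model()$params
  # AC5 compartment binds D1R with higher capacity/affinity ratio than the
  # NMDAR compartment, and the reverse for Golf
  kd_ra <- p[["r1.kr"]] / p[["r1.kf"]]; kd_rn <- p[["r2.kr"]] / p[["r2.kf"]]
  kd_ga <- p[["r5.kr"]] / p[["r5.kf"]]; kd_gn <- p[["r6.kr"]] / p[["r6.kf"]]
  expect_gt(tot[["AncRA"]] / kd_ra, tot[["AncRN"]] / kd_rn)
  expect_gt(tot[["AncGN"]] / kd_gn, tot[["AncGA"]] / kd_ga)
})

test_that("reaction and totals tables round-trip through the TSV dialect", {
  dir <- withr::local_tempdir()
  rx <- standard_reactions()
  tt <- standard_totals()
  write_reaction_table(rx, file.path(dir, "rx.tsv"))
  write_totals_table(tt, file.path(dir, "tot.tsv"))
  rx2 <- read_reaction_table(file.path(dir, "rx.tsv"))
  tt2 <- read_totals_table(file.path(dir, "tot.tsv"))
  expect_equal(as.data.frame(rx2), as.data.frame(rx))
  expect_equal(as.data.frame(tt2), as.data.frame(tt))
  # a network built from the round-tripped tables is identical to one built
  # from the in-memory tables (before any crosstalk scheme is applied)
  m1 <- build_network(rx, tt)
  m2 <- build_network(rx2, tt2)
  expect_equal(m2$params, m1$params)
})

test_that("per-parameter overrides correct a loaded table", {
  rx <- standard_reactions(); tt <- standard_totals()
  m <- build_network(rx, tt, param_overrides = c("cam1.kf" = 99))
  expect_equal(unname(m$params["cam1.kf"]), 99)
  expect_error(build_network(rx, tt, param_overrides = c("nope.kf" = 1)),
               "unknown parameter override")
})

test_that("genotype scaling touches only the targeted totals", {
  m <- wt_model()
  het <- apply_genotype(m, "Drd1a_het")
  expect_equal(het$totals$total[het$totals$moiety == "D1R"],
               0.2 * m$totals$total[m$totals$moiety == "D1R"])
  same <- het$totals$moiety != "D1R"
  expect_equal(het$totals$total[same], m$totals$total[same])
  expect_equal(het$params, m$params)

  gnal <- apply_genotype(m, "Gnal_het")
  expect_equal(gnal$totals$total[gnal$totals$moiety %in% c("Gaolf", "Gbg")],
               0.4 * m$totals$total[m$totals$moiety %in% c("Gaolf", "Gbg")])
  ko <- apply_genotype(m, "D32KO")
  expect_equal(ko$totals$total[ko$totals$moiety == "D32"], 0)
  wt <- apply_genotype(m, "WT")
  expect_equal(wt$totals, m$totals)
  expect_error(apply_genotype(m, "mystery"), "unknown genotype")
})

test_that("network JSON dump writes species, reactions and totals", {
  dir <- withr::local_tempdir()
  f <- write_network_json(toy_enzyme_network(), file.path(dir, "net.json"))
  x <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_setequal(names(x), c("species", "reactions", "totals"))
  expect_equal(nrow(x$species), 4)
})
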