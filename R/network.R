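# Reaction-network representation: species grammar, reaction classes,
# assembly into a mass-action ODE system, conserved-moiety analysis and
# table input/output.

#' Reaction table row constructors
#'
#' Three non-overlapping reaction classes are supported.  `rxn_enz()` encodes a
#' full Michaelis scheme with an explicit enzyme-substrate complex (no
#' steady-state shortcut): the first name in `reactants` is the enzyme, the
#' second the substrate, and the complex species `<enzyme>.<substrate>` is
#' created automatically.  `rxn_rev()` is a reversible mass-action reaction and
#' `rxn_irr()` an irreversible one (transport steps included).
#'
#' Rate constant units are s^-1 for first-order and uM^-1 s^-1 for
#' second-order steps; concentrations are uM throughout.
#'
#' @param id unique reaction identifier.
#' @param reactants,products reaction sides, e.g. `"CaM + 2 Ca"`.
#' @param kf,kr,kcat rate constants for the class.
#' @param notes free-text annotation.
#' @return A one-row tibble in the reaction-table dialect.
#' @export
rxn_enz <- function(id, reactants, products, kf, kr, kcat, notes = "") {
  tibble::tibble(id = id, class = "enzymatic", reactants = reactants,
                 products = products, kf = kf, kr = kr, kcat = kcat,
                 notes = notes)
}

#' @rdname rxn_enz
#' @export
rxn_rev <- function(id, reactants, products, kf, kr, notes = "") {
  tibble::tibble(id = id, class = "reversible", reactants = reactants,
                 products = products, kf = kf, kr = kr, kcat = NA_real_,
                 notes = notes)
}

#' @rdname rxn_enz
#' @export
rxn_irr <- function(id, reactants, products, kf, notes = "") {
  tibble::tibble(id = id, class = "irreversible", reactants = reactants,
                 products = products, kf = kf, kr = NA_real_, kcat = NA_real_,
                 notes = notes)
}

# parse "A + 2 B" into a named multiplicity vector
parse_side <- function(x) {
  if (is.na(x) || !nzchar(trimws(x))) return(stats::setNames(numeric(0), character(0)))
  parts <- trimws(strsplit(x, "+", fixed = TRUE)[[1]])
  out <- numeric(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)\\s+(.*)$", p))[[1]]
    if (length(m) == 3) {
      n <- as.numeric(m[2]); sp <- m[3]
    } else {
      n <- 1; sp <- p
    }
    out[sp] <- ifelse(is.na(out[sp]), 0, out[sp]) + n
  }
  out[is.na(out)] <- 0
  out
}

format_side <- function(v) {
  if (!length(v)) return("")
  paste(ifelse(v == 1, names(v), paste(v, names(v))), collapse = " + ")
}

# split a complex species id into its components
species_components <- function(id) strsplit(id, ".", fixed = TRUE)[[1]]

# strip phospho-site tags ("p@34", "p@Y", ...) from a component name;
# sites are numeric residue positions or single capital letters
component_base <- function(x) gsub("p@([0-9]+|[A-Z])", "", x)

#' Moiety composition registry of the standard species grammar
#'
#' Maps a component base name to the conserved pools (moieties) it carries.
#' Identity entries are implicit; only irregular components are listed here
#' (ligand-bound forms, the PKA holoenzyme which carries one regulatory dimer
#' and two catalytic subunits, nucleotide-state forms, and the non-conserved
#' small molecules).
#'
#' @param extra optional named list of additional entries, each a named
#'   numeric vector of moiety counts (used by toy networks in examples and
#'   tests, e.g. `list(P = c(S = 1))` for a product species).
#' @return Named list of named numeric vectors.
#' @export
moiety_registry <- function(extra = list()) {
  base <- list(
    PKA        = c(PKAr = 1, PKAc = 2),
    PKAcamp2   = c(PKAr = 1, PKAc = 2),
    PKAcamp4   = c(PKAr = 1, PKAc = 2),
    PKAcamp4c1 = c(PKAr = 1, PKAc = 1),
    CaMCa2     = c(CaM = 1),
    CaMCa4     = c(CaM = 1),
    Golf       = c(Gaolf = 1, Gbg = 1),
    Gaolf_A    = c(Gaolf = 1), Gaolf_N = c(Gaolf = 1),
    GaolfGDP_A = c(Gaolf = 1), GaolfGDP_N = c(Gaolf = 1),
    Gbg_A      = c(Gbg = 1), Gbg_N = c(Gbg = 1),
    D1Rda      = c(D1R = 1),
    PP2A72ca   = c(PP2A72 = 1),
    AC5ca      = c(AC5 = 1),
    PKAc2      = c(PKAc = 2),
    DUSPi      = c(DUSP = 1),
    NMDARm     = c(NMDAR = 1), NMDARi = c(NMDAR = 1),
    PDE10a     = c(PDE10 = 1),
    RASgdp     = c(RAS = 1), RASgtp = c(RAS = 1),
    cAMP       = c(), AMP = c(),
    Ca         = c(), DA = c()
  )
  utils::modifyList(base, extra)
}

species_composition <- function(id, registry) {
  comps <- component_base(species_components(id))
  out <- numeric(0)
  for (cc in comps) {
    entry <- if (cc %in% names(registry)) registry[[cc]] else stats::setNames(1, cc)
    for (m in names(entry)) out[m] <- ifelse(is.na(out[m]), 0, out[m]) + entry[[m]]
  }
  out[is.na(out)] <- 0
  out
}

#' Compartment tag of a species
#'
#' Species are indexed into a closed set of reaction compartments: the spine
#' cytosol, the PSD/synaptic membrane, the intracellular NMDAR reservoir, the
#' two D1R/Golf signalling compartments (AC5-linked and NMDAR-linked) and the
#' non-signalling D1R/Golf reservoir.
#'
#' @param id species identifier(s).
#' @return Character vector of compartment tags.
#' @export
species_compartment <- function(id) {
  vapply(id, function(x) {
    if (grepl("_A(\\.|$)", x) || grepl("AncRA|AncGA", x)) return("d1r_ac5")
    if (grepl("_N(\\.|$)", x) || grepl("AncRN|AncGN", x)) return("d1r_nmdar")
    if (grepl("NMDARm", x)) return("psd")
    if (grepl("NMDARi", x)) return("nmdar_res")
    if (x %in% c("D1R", "Golf")) return("reservoir")
    "cyt"
  }, character(1), USE.NAMES = FALSE)
}

boundary_species <- function() c("Ca", "DA")

validate_reactions <- function(reactions) {
  stopifnot(is.data.frame(reactions))
  need <- c("id", "class", "reactants", "products", "kf", "kr", "kcat")
  missing <- setdiff(need, names(reactions))
  if (length(missing)) stop("reaction table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(reactions$id)) stop("duplicate reaction ids")
  bad <- setdiff(unique(reactions$class), c("enzymatic", "reversible", "irreversible"))
  if (length(bad)) stop("malformed reaction class: ", paste(bad, collapse = ", "))
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    ks <- switch(r$class,
                 enzymatic = c(r$kf, r$kr, r$kcat),
                 reversible = c(r$kf, r$kr),
                 irreversible = r$kf)
    if (anyNA(ks)) stop("reaction ", r$id, ": missing rate constant for class ", r$class)
    if (any(ks < 0)) stop("reaction ", r$id, ": negative rate constant")
    rng <- ks[ks > 0]
    if (length(rng) && (any(rng < 1e-6) || any(rng > 1e6)))
      warning("reaction ", r$id, ": rate constant far outside the usual 1e-3..1e3 range")
  }
  invisible(reactions)
}

# expand classed reactions into elementary mass-action steps
expand_steps <- function(reactions) {
  rows <- list()
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    re <- parse_side(r$reactants); pr <- parse_side(r$products)
    if (r$class == "irreversible") {
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kf"),
                                       sub = re, from = re, to = pr)
    } else if (r$class == "reversible") {
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kf"),
                                       sub = re, from = re, to = pr)
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kr"),
                                       sub = pr, from = pr, to = re)
    } else {
      if (length(re) != 2 || any(re != 1))
        stop("reaction ", r$id, ": enzymatic reactions need 'E + S' reactants")
      enz <- names(re)[1]; sub <- names(re)[2]
      cx <- paste(enz, sub, sep = ".")
      es <- stats::setNames(c(1, 1), c(enz, sub))
      cs <- stats::setNames(1, cx)
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kf"),
                                       sub = es, from = es, to = cs)
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kr"),
                                       sub = cs, from = cs, to = es)
      rows[[length(rows) + 1]] <- list(rxn = r$id, par = paste0(r$id, ".kcat"),
                                       sub = cs, from = cs, to = parse_side(r$products))
    }
  }
  rows
}

#' Assemble a reaction network into a mass-action ODE model
#'
#' Expands the classed reaction table into elementary steps, derives the
#' species list (including the explicit enzyme-substrate complexes), checks
#' moiety mass balance of every reaction, and builds the stoichiometric
#' machinery used by the simulator.
#'
#' @param reactions reaction table (see [rxn_enz()]).
#' @param totals totals table: tibble with columns `moiety`, `total` (uM) and
#'   optionally `seed` (species receiving the pool at initialisation; defaults
#'   to the moiety name itself).
#' @param registry moiety composition registry, see [moiety_registry()].
#' @param param_overrides optional named numeric vector of rate-constant
#'   overrides keyed `"<reaction id>.<kf|kr|kcat>"`, applied after assembly
#'   (supports per-parameter correction of a loaded table).
#' @return An object of class `msn_network`.
#' @export
build_network <- function(reactions, totals, registry = moiety_registry(),
                          param_overrides = NULL) {
  reactions <- validate_reactions(reactions)
  steps <- expand_steps(reactions)

  sp <- unique(unlist(lapply(steps, function(s) c(names(s$from), names(s$to)))))
  bnd <- intersect(boundary_species(), sp)
  states <- setdiff(sp, boundary_species())

  comp <- lapply(stats::setNames(states, states), species_composition, registry = registry)
  moieties <- sort(unique(unlist(lapply(comp, names))))

  unknown <- setdiff(moieties, totals$moiety)
  if (length(unknown)) stop("species reference unknown moieties: ",
                            paste(unknown, collapse = ", "))

  # mass balance of conserved moieties for every reaction
  side_comp <- function(v) {
    out <- stats::setNames(numeric(length(moieties)), moieties)
    for (s in names(v)) {
      if (s %in% boundary_species()) next
      cc <- species_composition(s, registry)
      for (m in names(cc)) out[m] <- out[m] + v[s] * cc[[m]]
    }
    out
  }
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    lhs <- side_comp(parse_side(r$reactants)); rhs <- side_comp(parse_side(r$products))
    if (r$class == "enzymatic") {
      # catalytic step must conserve as well; binding conserves by construction
      if (max(abs(lhs - rhs)) > 1e-9)
        stop("reaction ", r$id, ": moiety mass balance violated")
    } else if (max(abs(lhs - rhs)) > 1e-9) {
      stop("reaction ", r$id, ": moiety mass balance violated")
    }
  }

  # parameter vector
  params <- numeric(0)
  for (i in seq_len(nrow(reactions))) {
    r <- reactions[i, ]
    params[paste0(r$id, ".kf")] <- r$kf
    if (r$class != "irreversible") params[paste0(r$id, ".kr")] <- r$kr
    if (r$class == "enzymatic") params[paste0(r$id, ".kcat")] <- r$kcat
  }
  if (!is.null(param_overrides)) {
    bad <- setdiff(names(param_overrides), names(params))
    if (length(bad)) stop("unknown parameter override: ", paste(bad, collapse = ", "))
    params[names(param_overrides)] <- param_overrides
  }

  # flat step arrays for the compiled right-hand side
  idx_of <- stats::setNames(seq_along(states) - 1L, states)
  nst <- length(states)
  ext_idx <- c(Ca = nst, DA = nst + 1L)
  subptr <- integer(1); subidx <- integer(0)
  stptr <- integer(1); stspec <- integer(0); stdelta <- numeric(0)
  par_of_step <- character(0)
  for (s in steps) {
    subs <- integer(0)
    for (nm in names(s$sub)) {
      ii <- if (nm %in% states) idx_of[[nm]] else ext_idx[[nm]]
      subs <- c(subs, rep(ii, s$sub[[nm]]))
    }
    subidx <- c(subidx, subs); subptr <- c(subptr, length(subidx))
    delta <- stats::setNames(numeric(0), character(0))
    for (nm in names(s$from)) if (!nm %in% boundary_species())
      delta[nm] <- ifelse(is.na(delta[nm]), 0, delta[nm]) - s$from[[nm]]
    for (nm in names(s$to)) if (!nm %in% boundary_species())
      delta[nm] <- ifelse(is.na(delta[nm]), 0, delta[nm]) + s$to[[nm]]
    delta <- delta[delta != 0]
    stspec <- c(stspec, unname(idx_of[names(delta)]))
    stdelta <- c(stdelta, unname(delta))
    stptr <- c(stptr, length(stspec))
    par_of_step <- c(par_of_step, s$par)
  }

  species <- tibble::tibble(
    id = states,
    compartment = species_compartment(states),
    moiety = vapply(comp, function(x) if (length(x)) names(x)[1] else NA_character_, character(1))
  )

  structure(list(
    reactions = reactions,
    species = species,
    composition = comp,
    totals = totals,
    params = params,
    registry = registry,
    steps = list(subptr = subptr, subidx = subidx, stptr = stptr,
                 stspec = stspec, stdelta = stdelta, par = par_of_step),
    state_index = idx_of
  ), class = "msn_network")
}

#' @export
print.msn_network <- function(x, ...) {
  cat("<msn_network> ", nrow(x$reactions), " reactions, ",
      nrow(x$species), " species, ", nrow(x$totals), " conserved totals, ",
      length(x$params), " rate constants\n", sep = "")
  tab <- table(x$reactions$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Conserved moieties of an assembled network
#'
#' Returns the conserved pools (one per declared total) with their member
#' species and stoichiometric multiplicities, after verifying structurally
#' that each pool's weighted species sum is invariant under every elementary
#' step (i.e. that each moiety vector lies in the left null space of the
#' stoichiometric matrix).
#'
#' @param network an `msn_network`.
#' @return Tibble with one row per moiety: `moiety`, `total`, `species`
#'   (list-column of member ids) and `mult` (list-column of multiplicities).
#' @export
conserved_moieties <- function(network) {
  states <- network$species$id
  n <- length(states)
  st <- network$steps
  nsteps <- length(st$par)
  rows <- purrr::map(seq_len(nrow(network$totals)), function(i) {
    m <- network$totals$moiety[i]
    w <- vapply(network$composition, function(cc) ifelse(m %in% names(cc), cc[[m]], 0),
                numeric(1))
    # structural invariance: sum_j w_j * delta_js == 0 for every step s
    for (s in seq_len(nsteps)) {
      ix <- (st$stptr[s] + 1):st$stptr[s + 1]
      if (st$stptr[s] == st$stptr[s + 1]) next
      drift <- sum(w[st$stspec[ix] + 1] * st$stdelta[ix])
      if (abs(drift) > 1e-9)
        stop("moiety ", m, " is not conserved by step of parameter ", st$par[s])
    }
    tibble::tibble(moiety = m, total = network$totals$total[i],
                   species = list(states[w != 0]), mult = list(unname(w[w != 0])))
  })
  dplyr::bind_rows(rows)
}

#' Initial state consistent with the declared totals
#'
#' Each conserved pool is seeded into its designated seed species (the free,
#' unmodified form by default); residuals arising from seeds shared between
#' pools (e.g. the PKA holoenzyme carrying both the regulatory and catalytic
#' pools) are placed in the pool's free species.
#'
#' @param network an `msn_network`.
#' @param totals optional named numeric vector overriding declared totals.
#' @return Named numeric state vector (uM).
#' @export
initial_state <- function(network, totals = NULL) {
  tt <- stats::setNames(network$totals$total, network$totals$moiety)
  if (!is.null(totals)) tt[names(totals)] <- totals
  seeds <- if ("seed" %in% names(network$totals)) {
    stats::setNames(network$totals$seed, network$totals$moiety)
  } else stats::setNames(network$totals$moiety, network$totals$moiety)
  y <- stats::setNames(numeric(nrow(network$species)), network$species$id)
  for (m in network$totals$moiety) {
    w <- vapply(network$composition, function(cc) ifelse(m %in% names(cc), cc[[m]], 0), numeric(1))
    current <- sum(w * y)
    resid <- tt[[m]] - current
    seed <- seeds[[m]]
    if (is.na(seed) || !seed %in% names(y)) next
    if (resid < 0 && y[seed] + resid < -1e-12) {
      # shared seed over-filled this pool; trim proportionally
      scale <- tt[[m]] / current
      y[w != 0] <- y[w != 0] * scale
    } else {
      mult <- network$composition[[seed]][[m]]
      y[seed] <- y[seed] + resid / mult
    }
  }
  y
}

#' Read / write reaction and totals tables
#'
#' The frozen table dialect is tab-separated with columns
#' `id, class, reactants, products, kf, kr, kcat, notes` for reactions and
#' `moiety, total, seed` for conserved totals.  The loader validates classes
#' and rate constants; `param_overrides` in [build_network()] supports
#' per-parameter correction of a loaded table.
#'
#' @param file path to a TSV file.
#' @return A tibble.
#' @export
read_reaction_table <- function(file) {
  x <- utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE,
                         na.strings = "NA")
  x$notes[is.na(x$notes)] <- ""
  x$products[is.na(x$products)] <- ""
  validate_reactions(tibble::as_tibble(x))
}

#' @rdname read_reaction_table
#' @export
read_totals_table <- function(file) {
  tibble::as_tibble(utils::read.delim(file, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname read_reaction_table
#' @param x reaction or totals tibble.
#' @export
write_reaction_table <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_reaction_table
#' @export
write_totals_table <- function(x, file) {
  utils::write.table(x, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Dump the network graph as JSON
#'
#' Writes species (with compartment tags and moiety membership) and reactions
#' (with class and rate constants) for inspection in external graph tools.
#'
#' @param network an `msn_network`.
#' @param file output path.
#' @export
write_network_json <- function(network, file) {
  obj <- list(
    species = network$species,
    reactions = network$reactions,
    totals = network$totals
  )
  jsonlite::write_json(obj, file, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(file)
}
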