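# Built-in study models: the enzyme kinetics motif and the yeast glucose
# transport model (shipped with their printed structure), the three-species
# complex-formation example with its closed-form back-translation, and a
# seeded random generator of fast-cluster networks for property testing.

.fixture <- function(network, fast, exact, apparent, schemes, notes) {
  structure(list(network = network, fast = fast, exact = exact,
                 apparent = apparent, schemes = schemes, notes = notes),
            class = "FixtureModel")
}

#' @export
print.FixtureModel <- function(x, ...) {
  print(x$network)
  cat("fast reactions:", paste(x$fast, collapse = ", "), "\n")
  cat("notes:", x$notes, "\n")
  invisible(x)
}

#' Enzyme kinetics model (5 species, 3 reactions)
#'
#' The classical catalytic motif S + E <-> CS -> CP <-> P + E with rate
#' constants k1 = 1000, km1 = 2000, k2 = 1, k3 = 3000, km3 = 1000 and
#' initial amounts S(0) = E(0) = 1, all others 0. k1 and k3 are the
#' association rates of the two binding equilibria (S+E -> CS and
#' P+E -> CP), km1 and km3 the dissociations; the net rate of the product
#' binding step is written on the CP -> P+E column as km3*CP - k3*P*E so the
#' stoichiometric matrix keeps its conventional column orientation. The
#' binding steps r1 and r3 dominate the conversion r2, so all five species
#' are in quasi-steady state. The derived ratio parameters are
#' M1 = k1/km1 = 0.5 and M3 = k3/km3 = 3, and the total enzyme
#' LE = E + CS + CP = 1.
#'
#' @return a `FixtureModel` with the network, the recommended fast set
#'   (`r1`, `r3`), canonical exact (`LE`, `LT`) and apparent
#'   (`LS`, `LP`, `LE`) conservation bases, and the two-state lumping scheme
#'   (lumps S, P, LE with LE constant).
#' @export
enzyme_kinetics <- function() {
  net <- reaction_network(
    species = c(S = 1, E = 1, P = 0, CS = 0, CP = 0),
    parameters = c(k1 = 1000, km1 = 2000, k2 = 1, k3 = 3000, km3 = 1000),
    reactions = list(
      rxn("r1", c(S = 1, E = 1), c(CS = 1), "k1*S*E - km1*CS"),
      rxn("r2", c(CS = 1), c(CP = 1), "k2*CS"),
      rxn("r3", c(CP = 1), c(P = 1, E = 1), "km3*CP - k3*P*E")))
  S <- stoichiometric_matrix(net)
  part <- fs_partition(net, fast = c("r1", "r3"))
  exact <- conservation_basis(
    rbind(LE = c(S = 0, E = 1, P = 0, CS = 1, CP = 1),
          LT = c(S = 1, E = 0, P = 1, CS = 1, CP = 1)), S, "S")
  apparent <- conservation_basis(
    rbind(LS = c(S = 1, E = 0, P = 0, CS = 1, CP = 0),
          LP = c(S = 0, E = 0, P = 1, CS = 0, CP = 1),
          LE = c(S = 0, E = 1, P = 0, CS = 1, CP = 1)), part$Sf, "Sf")
  scheme <- build_scheme(apparent, exact, keep = "LE")
  .fixture(net, c("r1", "r3"), exact, apparent,
           list(two_state = scheme),
           "nominal parameter values; exact further reduction to one state uses LT")
}

#' Glucose transport model of baker's yeast (9 species)
#'
#' Facilitated diffusion of glucose across the cell membrane by a carrier
#' enzyme E, with glucose 6-phosphate (G6P) inhibiting transport by binding
#' the carrier on the inner face. Species: external/internal glucose (Glce,
#' Glci), internal G6P (G6Pi), the free carrier on each face (Ee, Ei) and its
#' complexes (EGlce, EGlci, EG6Pi, EGlcG6Pi). The four binding reactions at
#' the membrane faces are fast; the translocation steps (rates alpha, beta)
#' are slow.
#'
#' The model structure (reactions and conservation relations) is as
#' published; the default parameter values are synthetic placeholders (the
#' original study's fitted values are not printed anywhere reproducible) and
#' are chosen so the binding reactions are >= 1000x faster than
#' translocation, with total carrier LE = 0.01: all on-rates 1e5, all
#' off-rates 1e3, alpha = beta = 1, Glce(0) = 0.1, G6Pi(0) = 0.05,
#' Ee(0) = Ei(0) = 0.005.
#'
#' @param params optional named overrides of the placeholder parameters.
#' @return a `FixtureModel` with canonical exact (`LE`, `LGlc`, `LG6P`) and
#'   apparent (`LGlc1`, `LE1`, `LGlc2`, `LG6P`, `LE2`) bases and three
#'   shipped schemes: `four_state` (keep LE1, LG6P; extra lump LE3 =
#'   {EGlci, Ei}), `five_state` (keep LE1, LE2), and `three_state`
#'   (keep the full carrier lump LE against a reduced 4-row apparent list;
#'   to be used with the constant-regional-transporter constraint).
#' @export
glucose_transport <- function(params = NULL) {
  p <- c(k1 = 1e5, km1 = 1e3, k2 = 1e5, km2 = 1e3,
         k3 = 1e5, km3 = 1e3, k4 = 1e5, km4 = 1e3,
         alpha = 1, beta = 1)
  if (!is.null(params)) p[names(params)] <- params
  sp <- c(Glce = 0.1, Glci = 0, EG6Pi = 0, EGlcG6Pi = 0, G6Pi = 0.05,
          EGlce = 0, EGlci = 0, Ee = 0.005, Ei = 0.005)
  net <- reaction_network(
    species = sp, parameters = p,
    reactions = list(
      rxn("r1", c(Ee = 1, Glce = 1), c(EGlce = 1), "k1*Ee*Glce"),
      rxn("r1_rev", c(EGlce = 1), c(Ee = 1, Glce = 1), "km1*EGlce",
          group = "r1"),
      rxn("r2", c(Ei = 1, Glci = 1), c(EGlci = 1), "k2*Ei*Glci"),
      rxn("r2_rev", c(EGlci = 1), c(Ei = 1, Glci = 1), "km2*EGlci",
          group = "r2"),
      rxn("r3", c(EGlci = 1, G6Pi = 1), c(EGlcG6Pi = 1), "k3*EGlci*G6Pi"),
      rxn("r3_rev", c(EGlcG6Pi = 1), c(EGlci = 1, G6Pi = 1), "km3*EGlcG6Pi",
          group = "r3"),
      rxn("r4", c(Ei = 1, G6Pi = 1), c(EG6Pi = 1), "k4*Ei*G6Pi"),
      rxn("r4_rev", c(EG6Pi = 1), c(Ei = 1, G6Pi = 1), "km4*EG6Pi",
          group = "r4"),
      rxn("ra", c(EGlci = 1), c(EGlce = 1), "alpha*(EGlci - EGlce)"),
      rxn("rb", c(Ei = 1), c(Ee = 1), "beta*(Ei - Ee)")))
  S <- stoichiometric_matrix(net)
  part <- fs_partition(net, fast = c("r1", "r2", "r3", "r4"))
  z <- stats::setNames(rep(0L, length(sp)), names(sp))
  row <- function(...) { v <- z; sel <- c(...); v[sel] <- 1L; v }
  exact <- conservation_basis(
    rbind(LE = row("EG6Pi", "EGlcG6Pi", "EGlce", "EGlci", "Ee", "Ei"),
          LGlc = row("Glce", "Glci", "EGlcG6Pi", "EGlce", "EGlci"),
          LG6P = row("G6Pi", "EG6Pi", "EGlcG6Pi")), S, "S")
  apparent <- conservation_basis(
    rbind(LGlc1 = row("Glce", "EGlce"),
          LE1 = row("EGlce", "Ee"),
          LGlc2 = row("Glci", "EGlcG6Pi", "EGlci"),
          LG6P = row("G6Pi", "EG6Pi", "EGlcG6Pi"),
          LE2 = row("EG6Pi", "EGlcG6Pi", "EGlci", "Ei")), part$Sf, "Sf")
  four <- build_scheme(apparent, exact, keep = c("LE1", "LG6P"),
                       assignment = c(EGlci = "LE3", Ei = "LE3"))
  five <- build_scheme(apparent, exact, keep = c("LE1", "LE2"))
  # the three-state reduction pairs the full carrier lump with a deliberately
  # non-maximal 4-row apparent list (the carrier relation spans both membrane
  # faces)
  apparent4 <- conservation_basis(
    rbind(LGlc1 = row("Glce", "EGlce"),
          LGlc2 = row("Glci", "EGlcG6Pi", "EGlci"),
          LG6P = row("G6Pi", "EG6Pi", "EGlcG6Pi"),
          LE = row("EG6Pi", "EGlcG6Pi", "EGlce", "EGlci", "Ee", "Ei")),
    part$Sf, "Sf", check_basis = FALSE)
  three <- build_scheme(apparent4, exact, keep = "LE")
  .fixture(net, c("r1", "r2", "r3", "r4"), exact, apparent,
           list(four_state = four, five_state = five, three_state = three,
               apparent4 = apparent4),
           paste("structure as published; parameter values are synthetic",
                 "placeholders (>=1e3 timescale separation, LE = 0.01)"))
}

#' Three-species complex formation example
#'
#' Reversible formation of a complex C from substrate A and enzyme B
#' (A + B <-> C, a single fast cluster with two apparent conserved moieties
#' A + C and B + C), surrounded by configurable slow flows. Defaults: a
#' constant slow inflow to A (rate `vin`) and a linear slow outflow from C
#' (rate `kout*C`).
#'
#' @param k1,km1 fast association/dissociation rate constants.
#' @param slow_flows list of slow flows, each
#'   `list(species=, rate=, direction="in"|"out")`; the rate is an expression
#'   string and any new symbols it uses must be supplied via `extra_params`.
#' @param extra_params named numeric vector of parameters used by the slow
#'   flow rates (defaults provide `vin = 1`, `kout = 1`).
#' @param x0 initial amounts.
#' @return a `FixtureModel`; the scheme lumps A and C into L1 and keeps B,
#'   so the reduced states are (L1, B).
#' @export
small_example <- function(k1 = 1000, km1 = 2000,
                          slow_flows = list(
                            list(species = "A", rate = "vin",
                                 direction = "in"),
                            list(species = "C", rate = "kout*C",
                                 direction = "out")),
                          extra_params = c(vin = 1, kout = 1),
                          x0 = c(A = 1, B = 1, C = 0)) {
  reactions <- list(rxn("rf", c(A = 1, B = 1), c(C = 1), "k1*A*B - km1*C"))
  for (i in seq_along(slow_flows)) {
    fl <- slow_flows[[i]]
    id <- paste0("s", i)
    if (fl$direction == "in") {
      reactions[[length(reactions) + 1]] <-
        rxn(id, stats::setNames(integer(0), character(0)),
            stats::setNames(1L, fl$species), fl$rate)
    } else {
      reactions[[length(reactions) + 1]] <-
        rxn(id, stats::setNames(1L, fl$species),
            stats::setNames(integer(0), character(0)), fl$rate)
    }
  }
  net <- reaction_network(species = x0,
                          parameters = c(k1 = k1, km1 = km1, extra_params),
                          reactions = reactions)
  part <- fs_partition(net, fast = "rf")
  apparent <- conservation_basis(
    rbind(L1 = c(A = 1, B = 0, C = 1), L2 = c(A = 0, B = 1, C = 1)),
    part$Sf, "Sf")
  exact <- exact_conservations(net)
  scheme <- build_scheme(apparent, exact, keep = "L1")
  .fixture(net, "rf", exact, apparent, list(two_state = scheme),
           "closed-form back-translation available via oracle_backtranslate")
}

#' Closed-form back-translation for the complex-formation example
#'
#' The nonnegative solution of the fast equilibrium k1*A*B = km1*C under the
#' two apparent conservations A + C = L1 and B + C = L2, with
#' K1 = km1/k1:
#' A = (L1 - L2 - K1 + sqrt((L1 + L2 + K1)^2 - 4*L1*L2)) / 2, and
#' symmetrically for B; C = L1 - A. Used as an independent oracle for the
#' fraction-parameter pipeline and for analytic reduced initial conditions.
#'
#' @param L1,L2 lump values (may be vectors).
#' @param K1 dissociation constant km1/k1.
#' @return data.frame with columns A, B, C.
#' @export
oracle_backtranslate <- function(L1, L2, K1) {
  disc <- sqrt((L1 + L2 + K1)^2 - 4 * L1 * L2)
  A <- 0.5 * (L1 - L2 - K1 + disc)
  B <- 0.5 * (-L1 + L2 - K1 + disc)
  data.frame(A = A, B = B, C = L1 - A)
}

#' Random fast-cluster network generator
#'
#' Builds a seeded, reproducible closed mass-action network containing one or
#' more fast reversible binding clusters (A_k + B_k <-> C_k at rates scaled
#' by `separation`) connected by slow first-order conversions among the
#' A-type species and optional extra slow species. By construction every
#' cluster has two apparent conserved moieties (A_k + C_k and B_k + C_k) and
#' the closed network retains at least one exact conservation row
#' (each B_k + C_k).
#'
#' @param seed integer seed (the generator restores the caller's RNG state).
#' @param n_clusters number of fast binding clusters.
#' @param n_slow number of extra slow species in the conversion chain.
#' @param separation ratio of fast to slow rate scales (>= 1).
#' @return a `FixtureModel`; schemes keep each cluster's B-moiety lump.
#' @export
random_fast_cluster <- function(seed, n_clusters = 1, n_slow = 2,
                                separation = 1e4) {
  stopifnot(separation >= 1)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  species <- numeric(0)
  reactions <- list()
  params <- numeric(0)
  a_names <- character(0)
  for (k in seq_len(n_clusters)) {
    A <- paste0("A", k); B <- paste0("B", k); C <- paste0("C", k)
    a_names <- c(a_names, A)
    species[A] <- round(stats::runif(1, 0.5, 2), 3)
    species[B] <- round(stats::runif(1, 0.5, 2), 3)
    species[C] <- 0
    kf <- paste0("kf", k); kr <- paste0("kr", k)
    params[kf] <- separation * round(stats::runif(1, 0.5, 2), 3)
    params[kr] <- separation * round(stats::runif(1, 0.5, 2), 3)
    reactions[[length(reactions) + 1]] <-
      rxn(paste0("bind", k), stats::setNames(c(1L, 1L), c(A, B)),
          stats::setNames(1L, C),
          sprintf("%s*%s*%s - %s*%s", kf, A, B, kr, C))
  }
  slow_sp <- if (n_slow > 0) paste0("X", seq_len(n_slow)) else character(0)
  for (s in slow_sp) species[s] <- round(stats::runif(1, 0.1, 1), 3)
  chain <- c(a_names, slow_sp)
  if (length(chain) > 1) {
    for (i in seq_len(length(chain) - 1)) {
      kc <- paste0("kc", i)
      params[kc] <- round(stats::runif(1, 0.3, 1.5), 3)
      reactions[[length(reactions) + 1]] <-
        rxn(paste0("conv", i), stats::setNames(1L, chain[i]),
            stats::setNames(1L, chain[i + 1]),
            sprintf("%s*%s - %s*%s", kc, chain[i], kc, chain[i + 1]))
    }
  }
  net <- reaction_network(species, params, reactions)
  part <- fs_partition(net, fast = paste0("bind", seq_len(n_clusters)))
  apparent <- apparent_conservations(part)
  exact <- exact_conservations(net)
  .fixture(net, paste0("bind", seq_len(n_clusters)), exact, apparent,
           list(), "seeded random fast-cluster network (synthetic)")
}
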