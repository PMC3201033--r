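# Conserved moieties, apparent conservations, the vanishing-row transform,
# and fast clusters -- all in exact integer arithmetic.

test_that("enzyme exact basis spans total enzyme and total substrate", {
  fx <- enzyme_setup()
  B <- exact_conservations(fx$network)$matrix
  ref <- rbind(c(S = 0, E = 1, P = 0, CS = 1, CP = 1),   # E + CS + CP
               c(S = 1, E = 0, P = 1, CS = 1, CP = 1))   # S + P + CS + CP
  expect_true(same_row_span(B, ref))
  expect_true(all(B %*% stoichiometric_matrix(fx$network) == 0))
  expect_true(all(B >= 0))
})

test_that("glucose exact basis spans the three published moiety relations", {
  fx <- glucose_setup()
  B <- exact_conservations(fx$network)$matrix
  expect_equal(nrow(B), 3)
  expect_true(same_row_span(B, fx$exact$matrix))
  expect_true(all(B %*% stoichiometric_matrix(fx$network) == 0))
})

test_that("full-row-rank stoichiometry has an empty basis", {
  net <- reaction_network(c(A = 1), c(kin = 1, kout = 2),
                          list(rxn("in", setNames(integer(0), character(0)),
                                   c(A = 1), "kin"),
                               rxn("out", c(A = 1),
                                   setNames(integer(0), character(0)),
                                   "kout*A")))
  expect_equal(nrow(exact_conservations(net)$matrix), 0)
})

test_that("fast/slow partition isolates the published slow column", {
  fx <- enzyme_setup()
  part <- fx$part
  expect_equal(part$fast_species, c("S", "E", "P", "CS", "CP"))
  expect_equal(unname(part$Ss[, "r2"]), c(0, 0, 0, -1, 1))
  expect_equal(colnames(part$Sf), c("r1", "r3"))
  # small example: one fast column (-1,-1,1)
  sm <- small_setup()
  expect_equal(unname(sm$part$Sf[, "rf"]), c(-1, -1, 1))
  # empty fast set
  p0 <- fs_partition(fx$network, fast = character(0))
  expect_equal(ncol(p0$Sf), 0)
  expect_equal(length(p0$fast_species), 0)
})

test_that("partition validates its inputs", {
  fx <- enzyme_setup()
  expect_error(fs_partition(fx$network, fast = c("r1", "nope")),
               "unknown fast reaction")
  expect_error(fs_partition(fx$network, fast = "r1",
                            fast_species = c("S", "E", "CS", "P")),
               "touched by no fast reaction")
  # species may be given as indices
  p_idx <- fs_partition(fx$network, fast = "r1", fast_species = c(1, 2, 4))
  expect_equal(p_idx$fast_species, c("S", "E", "CS"))
})

test_that("apparent bases span the published relations", {
  fx <- enzyme_setup()
  A <- apparent_conservations(fx$part)$matrix
  expect_true(same_row_span(A, fx$apparent$matrix))
  expect_true(all(A %*% fx$part$Sf == 0))
  gx <- glucose_setup()
  Ag <- apparent_conservations(gx$part)$matrix
  expect_equal(nrow(Ag), 5)
  expect_true(same_row_span(Ag, gx$apparent$matrix))
  sm <- small_setup()
  As <- apparent_conservations(sm$part)$matrix
  expect_true(same_row_span(As, rbind(c(A = 1, B = 0, C = 1),
                                      c(A = 0, B = 1, C = 1))))
})

test_that("row counts match the n - rank dimension formula (qr oracle)", {
  for (seed in 1:10) {
    fx <- random_fast_cluster(seed, n_clusters = 1 + seed %% 2, n_slow = 2)
    S <- stoichiometric_matrix(fx$network)
    B <- exact_conservations(fx$network)$matrix
    expect_equal(nrow(B), nrow(S) - qr(S)$rank)
    part <- fs_partition(fx$network, fast = fx$fast)
    A <- apparent_conservations(part)$matrix
    expect_equal(nrow(A), nrow(part$Sf) - qr(part$Sf)$rank)
  }
})

test_that("vanishing-row transform finds the maximal constant set", {
  fx <- enzyme_setup()
  # Mf Ss = (-1, 1, 0)^T for rows (LS, LP, LE): two combinations vanish
  P <- fx$apparent$matrix %*% fx$part$Ss
  expect_equal(unname(P[, 1]), c(-1, 1, 0))
  tr <- maximize_vanishing_rows(fx$apparent, fx$part$Ss)
  v <- attr(tr, "vanishing")
  expect_equal(sum(v), 2)
  expect_true(all(tr$matrix[v, , drop = FALSE] %*% fx$part$Ss == 0))
  # the vanishing rows span {LE, LT = LS + LP}
  expect_true(same_row_span(tr$matrix[v, , drop = FALSE],
                            rbind(c(S = 0, E = 1, P = 0, CS = 1, CP = 1),
                                  c(S = 1, E = 0, P = 1, CS = 1, CP = 1))))
  # the non-vanishing row stays in the span of the original basis
  expect_equal(rat_rank(rbind(fx$apparent$matrix, tr$matrix)), 3)
})

test_that("Ss = 0 makes every row vanish; generic Ss leaves the basis alone", {
  fx <- enzyme_setup()
  tr0 <- maximize_vanishing_rows(fx$apparent,
                                 matrix(0L, 5, 1,
                                        dimnames = list(rownames(fx$part$Ss),
                                                        "z")))
  expect_true(all(attr(tr0, "vanishing")))
  expect_true(same_row_span(tr0$matrix, fx$apparent$matrix))
  sm <- small_setup()
  trs <- maximize_vanishing_rows(sm$apparent, sm$part$Ss)
  expect_equal(sum(attr(trs, "vanishing")),
               2 - qr(sm$apparent$matrix %*% sm$part$Ss)$rank)
})

test_that("fast clusters partition the fast species", {
  gx <- glucose_setup()
  cl <- fast_clusters(gx$part)
  expect_length(cl, 2)
  sp <- lapply(cl, `[[`, "species")
  outer_idx <- which(vapply(sp, function(s) "Glce" %in% s, logical(1)))
  expect_setequal(sp[[outer_idx]], c("Glce", "EGlce", "Ee"))
  expect_setequal(sp[[3 - outer_idx]],
                  c("Glci", "EG6Pi", "EGlcG6Pi", "G6Pi", "EGlci", "Ei"))
  expect_setequal(unlist(sp), gx$part$fast_species)
  fx <- enzyme_setup()
  expect_length(fast_clusters(fx$part), 1)
  expect_length(fast_clusters(fs_partition(fx$network,
                                           fast = character(0))), 0)
})

test_that("exact conservations hold along simulated trajectories", {
  fx <- enzyme_setup()
  traj <- simulate_model(fx$network, seq(0.5, 10, 0.5))
  M <- fx$exact$matrix
  vals <- as.matrix(traj[, colnames(M)]) %*% t(M)
  for (j in 1:ncol(vals)) {
    expect_lt(max(abs(vals[, j] - vals[1, j])) / vals[1, j], 1e-6)
  }
})

test_that("flux-balance heuristic flags the fast-equilibrated species", {
  gx <- glucose_setup()
  sug <- suggest_qss_species(gx$network, t_end = 5, threshold = 0.05)
  # every species sits on a fast binding equilibrium in this model
  expect_true(all(sug$qss))
  # a model with no separation is not flagged
  slow <- reaction_network(c(A = 1, B = 0), c(k = 1, kb = 2),
                           list(rxn("r", c(A = 1), c(B = 1), "k*A - kb*B")))
  sug2 <- suggest_qss_species(slow, t_end = 0.3, threshold = 1e-3)
  expect_false(any(sug2$qss))
})
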