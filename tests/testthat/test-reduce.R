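# Reduced-model derivation: the Jacobian correction, the assembled ODEs,
# the naive baseline, initial conditions, and simulation.

test_that("overlapping apparent rows cannot both be kept as lumps", {
  sm <- small_setup()
  expect_error(build_scheme(sm$apparent, sm$exact, keep = c("L1", "L2")),
               "share species C")
})

test_that("lumping exactly along an apparent row yields J = 0 and plain balances", {
  # mono-molecular fast isomerization: the single apparent row A + B is a
  # proper lump on its own, so no Jacobian correction is needed and the lump
  # rate is the bare slow balance
  net <- reaction_network(c(A = 1, B = 0, X = 1),
                          c(kf = 1000, kr = 500, ks = 1),
                          list(rxn("iso", c(A = 1), c(B = 1), "kf*A - kr*B"),
                               rxn("ex", c(X = 1), c(A = 1), "ks*X - ks*A")))
  part <- fs_partition(net, fast = "iso")
  ap <- apparent_conservations(part)
  ex <- exact_conservations(net)
  sch <- build_scheme(ap, ex, keep = rownames(ap$matrix))
  fr <- derive_fractions(net, part, sch, exact = ex)
  J <- jacobian_correction(sch, ap, fr,
                           states = setdiff(rownames(sch$Mm), sch$constants))
  for (row in J) for (e in row) expect_true(rf_is_zero(e))
  red <- derive_reduced(net, part, sch, fr, ap, exact = ex)
  lump <- rownames(ap$matrix)[1]
  # d(lump)/dt = ks*X - ks*A with A replaced by its share of the lump
  expect_true(sym_equiv(red$rhs[[lump]],
    str2lang(paste0("ks*X - ks*(kr/(kf+kr))*", lump))))
})

test_that("the scalar correction matches the closed-form factor", {
  sm <- small_setup()
  # dB/dt = (1 + K1 L1/(B+K1)^2)^-1 (ldot_2 - B/(B+K1) ldot_1)
  gC <- "(B*L1/(B + (km1/k1)))"
  l1dot <- paste0("(vin - kout*", gC, ")")
  l2dot <- paste0("(-kout*", gC, ")")
  expected <- paste0("(", l2dot, " - (B/(B + (km1/k1)))*", l1dot,
                     ") / (1 + (km1/k1)*L1/(B + (km1/k1))^2)")
  expect_true(sym_equiv(sm$reduced$rhs$B, str2lang(expected)))
  expect_true(sym_equiv(sm$reduced$rhs$L1, str2lang(l1dot)))
})

test_that("enzyme reduced ODEs match the published two-state system", {
  fx <- enzyme_setup()
  den <- "(1 + (k1/km1)*S + (k3/km3)*P)"
  phi <- paste0("(", den, "^3 + ((k1/km1) + (k3/km3) + (k1/km1)*(k3/km3)*(P+S))*",
                den, "*LE + (k1/km1)*(k3/km3)*LE^2)")
  expect_true(sym_equiv(fx$reduced$rhs$S,
    str2lang(paste0("-k2*(k1/km1)*S*LE*(", den, "^2 + (k3/km3)*LE)/", phi))))
  expect_true(sym_equiv(fx$reduced$rhs$P,
    str2lang(paste0("k2*(k1/km1)*S*LE*(", den, "^2 + (k1/km1)*LE)/", phi))))
  expect_equal(fx$reduced$constants, c(LE = 1))
})

test_that("the inner-membrane correction block has the published structure", {
  gx <- glucose_setup()
  sch <- gx$schemes$five_state
  J <- jacobian_correction(sch, gx$apparent, gx$fr5,
                           states = setdiff(rownames(sch$Mm), sch$constants))
  # carrier lump LE2 equals its apparent row: its J row vanishes
  for (e in J$LE2) expect_true(rf_is_zero(e))
  # outer-face states do not enter the inner block and vice versa
  expect_true(rf_is_zero(J$Glci$Glce))
  expect_true(rf_is_zero(J$Glce$Glci))
  expect_true(rf_is_zero(J$Glce$G6Pi))
  # inner block entries present: Glci row depends on Glci, G6Pi, LE2
  expect_false(rf_is_zero(J$Glci$Glci))
  expect_false(rf_is_zero(J$Glci$G6Pi))
  expect_false(rf_is_zero(J$Glci$LE2))
})

test_that("naive substitution reproduces the published glucose baseline", {
  gx <- glucose_setup()
  part <- fs_partition(gx$network, fast = gx$fast)
  nai <- naive_reduce(gx$network, part,
                      qss_species = c("Glce", "Glci", "EG6Pi", "EGlcG6Pi",
                                      "G6Pi"),
                      exact = gx$exact)
  expect_setequal(nai$states, c("EGlce", "EGlci", "Ee", "Ei"))
  # the four retained ODEs are the bare exchange terms
  expect_true(sym_equiv(nai$rhs$EGlce, quote(alpha * (EGlci - EGlce))))
  expect_true(sym_equiv(nai$rhs$EGlci, quote(alpha * (EGlce - EGlci))))
  expect_true(sym_equiv(nai$rhs$Ee, quote(beta * (Ei - Ee))))
  expect_true(sym_equiv(nai$rhs$Ei, quote(beta * (Ee - Ei))))
  # the complexed pair is decoupled from the free pair
  expect_false(any(c("Ee", "Ei") %in% all.vars(nai$rhs$EGlce)))
  # back-translation solves the QSS system with the inhibitor conservation
  den <- "((km4/k4)*EGlci + (km3/k3)*Ei + (km3/k3)*(km4/k4))"
  expect_true(rf_equal(nai$fractions$g$G6Pi,
    expr_to_rf(str2lang(paste0("(km3/k3)*(km4/k4)*LG6P/", den)))))
  expect_true(rf_equal(nai$fractions$g$Glce,
    expr_to_rf(quote((km1 / k1) * EGlce / Ee))))
  # documented failure mode: raw initial conditions pin the complexes at zero
  traj <- simulate_model(nai, seq(1, 20, 1), x0 = gx$network$species[nai$states])
  expect_true(all(traj$EGlce == 0))
  expect_true(all(traj$EGlci == 0))
  expect_true(all(traj$Ee > 0))
})

test_that("a model with no slow reactions reduces to all-constant states", {
  net <- reaction_network(c(A = 1, B = 1, C = 0), c(k1 = 10, km1 = 5),
                          list(rxn("r", c(A = 1, B = 1), c(C = 1),
                                   "k1*A*B - km1*C")))
  part <- fs_partition(net, fast = "r")
  nai <- naive_reduce(net, part, qss_species = "C",
                      exact = exact_conservations(net))
  for (s in nai$states) expect_true(sym_equiv(nai$rhs[[s]], 0))
})

test_that("equilibrated reduced initial conditions match the closed form", {
  fx <- enzyme_setup()
  l0 <- reduced_initial_conditions(fx$network, fx$reduced, method = "fast_eq")
  # analytic route: S(0) from the quadratic with LS = LE = 1, K1 = 2
  expect_equal(unname(l0["S"]), sqrt(3) - 1, tolerance = 1e-6)
  expect_equal(unname(l0["P"]), 0, tolerance = 1e-9)
  expect_equal(unname(l0["S"]), oracle_backtranslate(1, 1, 2)$A,
               tolerance = 1e-6)
  # burn-in lands nearby (it additionally picks up slow drift)
  l0b <- suppressWarnings(
    reduced_initial_conditions(fx$network, fx$reduced, method = "burnin",
                               t_burn = 0.005))
  expect_equal(unname(l0b["S"]), sqrt(3) - 1, tolerance = 1e-2)
})

test_that("a model already at QSS maps through the lumping exactly", {
  fx <- enzyme_setup()
  net <- fx$network
  eq <- oracle_backtranslate(1, 1, 2)
  net$species <- c(S = eq$A, E = eq$B, P = 0, CS = eq$C, CP = 0)
  part <- fs_partition(net, fast = fx$fast)
  fr <- derive_fractions(net, part, fx$schemes$two_state, exact = fx$exact)
  red <- derive_reduced(net, part, fx$schemes$two_state, fr, fx$apparent,
                        exact = fx$exact)
  l0 <- reduced_initial_conditions(net, red, method = "fast_eq")
  expect_equal(unname(l0["S"]), eq$A, tolerance = 1e-7)
  expect_equal(unname(l0["P"]), 0, tolerance = 1e-10)
})

test_that("simulation preserves conservation and handles degenerate models", {
  fx <- enzyme_setup()
  traj <- simulate_model(fx$network, seq(0.2, 10, 0.2))
  LT <- traj$S + traj$P + traj$CS + traj$CP
  expect_lt(max(abs(LT - 1)), 1e-6)
  # reduced model conserves the back-translated total substrate
  l0 <- reduced_initial_conditions(fx$network, fx$reduced, method = "fast_eq")
  rt <- simulate_model(fx$reduced, seq(0.2, 10, 0.2), x0 = l0)
  bt <- back_translate(rt, fx$reduced)
  LTr <- bt$S + bt$P + bt$CS + bt$CP
  expect_lt(max(abs(LTr - LTr[1])), 1e-4)
  # zero-rate model stays put
  net0 <- reaction_network(c(A = 2), c(k = 0),
                           list(rxn("r", c(A = 1),
                                    setNames(integer(0), character(0)),
                                    "k*A")))
  expect_equal(simulate_model(net0, c(1, 5))$A, c(2, 2))
})

test_that("reduced dynamics match finite differences of the lump balances", {
  # d(lm)/dt from the reduced rhs equals (I+J)^-1 d(l)/dt measured on the
  # original trajectory while QSS holds
  fx <- enzyme_setup()
  h <- 1e-4
  for (t0 in c(1, 3, 6)) {
    tr <- simulate_model(fx$network, c(t0 - h, t0, t0 + h))
    x <- unlist(tr[2, names(fx$network$species)])
    lm <- drop(fx$schemes$two_state$Mm %*% x)
    # finite-difference lump derivatives on the original trajectory
    Mf <- fx$apparent$matrix
    lall <- as.matrix(tr[, colnames(Mf)]) %*% t(Mf)
    ldot_fd <- (lall[3, ] - lall[1, ]) / (2 * h)
    env <- c(as.list(lm[c("S", "P")]), as.list(fx$reduced$constants),
             as.list(fx$network$parameters))
    IpJ <- sapply(fx$reduced$IpJ_expr, function(row)
      sapply(row, eval, envir = env))
    pred <- solve(t(IpJ), ldot_fd[c("LS", "LP")])
    rhs <- netzoom:::.reduced_rhs_num(fx$reduced, lm[c("S", "P")],
                                      fx$network$parameters)
    expect_equal(unname(rhs), unname(pred), tolerance = 5e-3)
  }
})

test_that("det(I+J) stays positive along shipped-model trajectories", {
  fx <- enzyme_setup()
  l0 <- reduced_initial_conditions(fx$network, fx$reduced, method = "fast_eq")
  rt <- simulate_model(fx$reduced, seq(0.5, 10, 0.5), x0 = l0)
  for (i in seq_len(nrow(rt))) {
    x <- unlist(rt[i, fx$reduced$states])
    expect_gt(netzoom:::det_IpJ(fx$reduced, x), 0)
  }
  gx <- glucose_setup()
  g0 <- reduced_initial_conditions(gx$network, gx$red5, method = "fast_eq")
  expect_gt(netzoom:::det_IpJ(gx$red5, g0), 0)
})

test_that("missing back-translation in the difference support is an error", {
  fx <- enzyme_setup()
  fr <- fx$fractions
  fr$g$CS <- NULL
  expect_error(jacobian_correction(fx$schemes$two_state, fx$apparent, fr),
               "no back-translation")
})
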