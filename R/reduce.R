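# Reduced-model derivation: pairing of modified lumps with apparent
# conservation rows, the Jacobian correction (I+J)^-1, assembly of the
# reduced right-hand sides, the naive direct-substitution baseline, reduced
# initial conditions, and numeric simulation of both model classes.

# perfect matching of lumps to apparent rows such that each lump's members
# are a subset of its row's support; exact-support matches are fixed first.
.pair_lumps_rows <- function(scheme, apparent) {
  Mm <- scheme$Mm
  A <- apparent$matrix
  if (nrow(Mm) != nrow(A)) {
    stop("need as many apparent conservation rows (", nrow(A),
         ") as lumps (", nrow(Mm), ") to pair them")
  }
  sup <- lapply(seq_len(nrow(A)), function(k) colnames(A)[A[k, ] != 0])
  mem <- lapply(seq_len(nrow(Mm)), function(i) colnames(Mm)[Mm[i, ] != 0])
  n <- nrow(Mm)
  allowed <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (k in seq_len(n)) allowed[i, k] <- all(mem[[i]] %in% sup[[k]])
  }
  pair <- rep(NA_integer_, n)
  taken <- rep(FALSE, n)
  # fix exact matches first
  for (i in seq_len(n)) {
    for (k in seq_len(n)) {
      if (!taken[k] && setequal(mem[[i]], sup[[k]])) {
        pair[i] <- k; taken[k] <- TRUE; break
      }
    }
  }
  # backtracking for the rest
  rest <- which(is.na(pair))
  assign_rest <- function(idx, taken) {
    if (!length(idx)) return(list(ok = TRUE, pair = integer(0)))
    i <- idx[1]
    for (k in which(allowed[i, ] & !taken)) {
      taken2 <- taken; taken2[k] <- TRUE
      res <- assign_rest(idx[-1], taken2)
      if (res$ok) return(list(ok = TRUE, pair = c(k, res$pair)))
    }
    list(ok = FALSE)
  }
  res <- assign_rest(rest, taken)
  if (!res$ok) {
    stop("no proper pairing of lumps to apparent conservation rows exists")
  }
  pair[rest] <- res$pair
  pair
}

# symbolic ldot for one apparent row: row %*% Ss %*% rs with fast species
# replaced by their back-translation
.ldot_rf <- function(row, partition, gsubs) {
  acc <- rf_zero()
  rs <- lapply(partition$rs, expr_to_rf)
  coef <- drop(row %*% partition$Ss)
  for (j in seq_along(coef)) {
    if (coef[j] == 0) next
    acc <- rf_add(acc, rf_mul(rf_const(coef[j]), rs[[j]]))
  }
  rf_subs(acc, gsubs)
}

#' Jacobian correction matrix for a lumping scheme
#'
#' The correction `J` accounts for lumps being strict sub-pools of their
#' apparent conservation relations: row i is the gradient (w.r.t. the
#' modified lumped variables) of the back-translated difference between
#' apparent relation i and lump i. The reduced dynamics is
#' `(I + J)^-1` times the apparent-lump balance rates.
#'
#' @param scheme a `LumpingScheme`.
#' @param apparent the apparent `ConservationBasis` paired with the scheme
#'   (same number of rows as lumps).
#' @param fractions a `FractionParameterSet` providing the composed
#'   back-translation map `g`.
#' @param states which lump names to differentiate against (defaults to all
#'   non-constant lumps).
#' @return matrix (list of rows) of symbolic entries, with dimnames attribute;
#'   use [derive_reduced()] for the full pipeline.
#' @export
jacobian_correction <- function(scheme, apparent, fractions, states = NULL) {
  pair <- .pair_lumps_rows(scheme, apparent)
  lumps <- rownames(scheme$Mm)
  if (is.null(states)) states <- setdiff(lumps, scheme$constants)
  A <- apparent$matrix
  sp <- colnames(scheme$Mm)
  J <- list()
  for (i in seq_along(lumps)) {
    diffrow <- A[pair[i], sp] - scheme$Mm[i, sp]
    rowJ <- stats::setNames(vector("list", length(states)), states)
    # accumulated difference (Mf - Mm) g for this row
    acc <- rf_zero()
    for (k in sp[diffrow != 0]) {
      gk <- fractions$g[[k]]
      if (is.null(gk)) {
        stop("cannot derive reduced dynamics: species '", k,
             "' in the lump/apparent difference has no back-translation")
      }
      acc <- rf_add(acc, rf_mul(rf_const(diffrow[[k]]), gk))
    }
    for (j in seq_along(states)) rowJ[[j]] <- rf_deriv(acc, states[j])
    J[[i]] <- rowJ
  }
  names(J) <- lumps
  attr(J, "pair") <- pair
  J
}

#' Derive the reduced (zoomed-out) model
#'
#' Builds the reduced ODE system for the modified lumped state variables:
#' pairs each lump with an apparent conservation row, drops lumps retained as
#' exact constants (verifying their balance rate vanishes symbolically),
#' forms the Jacobian correction, and assembles
#' `d(lm)/dt = (I + J)^-1 %*% Mf %*% Ss %*% rs` with every original species
#' replaced by its back-translation. The `(I+J)` matrix is inverted
#' symbolically per sparsity block of dimension at most `sym_threshold`;
#' larger blocks are solved numerically at each evaluation. Species outside
#' the fast set pass through with their own (substituted) ODEs.
#'
#' @param network a [reaction_network()].
#' @param partition a [fs_partition()].
#' @param scheme a `LumpingScheme`.
#' @param fractions a `FractionParameterSet` from [derive_fractions()].
#' @param apparent the apparent basis used to build the scheme.
#' @param exact optional exact `ConservationBasis`; required to value any
#'   conservation constants appearing in the expressions.
#' @param sym_threshold largest block dimension inverted symbolically.
#' @return an object of class `ReducedModel`.
#' @export
derive_reduced <- function(network, partition, scheme, fractions,
                           apparent, exact = NULL, sym_threshold = 4) {
  lumps <- rownames(scheme$Mm)
  constants <- scheme$constants
  states <- setdiff(lumps, constants)
  gsubs <- fractions$g
  J <- jacobian_correction(scheme, apparent, fractions, states = states)
  pair <- attr(J, "pair")
  A <- apparent$matrix
  sp <- colnames(scheme$Mm)
  # ldot per lump (via its paired apparent row)
  ldot <- stats::setNames(vector("list", length(lumps)), lumps)
  for (i in seq_along(lumps)) {
    ldot[[i]] <- .ldot_rf(A[pair[i], sp, drop = FALSE], partition, gsubs)
  }
  # constants must have vanishing balance rates
  for (k in constants) {
    if (!rf_is_zero(ldot[[k]])) {
      stop("lump '", k, "' is flagged constant but its balance rate ",
           "does not vanish symbolically")
    }
  }
  # dynamic system: rows/cols over `states`
  n <- length(states)
  IpJ <- lapply(states, function(i) {
    row <- J[[i]]
    lapply(states, function(j) {
      e <- row[[j]]
      if (i == j) rf_add(e, rf_const(1)) else e
    })
  })
  names(IpJ) <- states
  # block decomposition by sparsity (symmetrized)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (!rf_is_zero(IpJ[[i]][[j]]) && i != j) {
        adj[i, j] <- TRUE; adj[j, i] <- TRUE
      }
    }
  }
  blocks <- list(); seen <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (seen[i]) next
    comp <- i
    repeat {
      grow <- unique(c(comp, which(rowSums(adj[, comp, drop = FALSE]) > 0)))
      if (length(grow) == length(comp)) break
      comp <- grow
    }
    seen[comp] <- TRUE
    blocks[[length(blocks) + 1]] <- sort(comp)
  }
  # assemble rhs per block
  rhs <- stats::setNames(vector("list", n), states)
  numeric_blocks <- list()
  for (b in blocks) {
    sub <- lapply(b, function(i) IpJ[[i]][b])
    bl <- lapply(states[b], function(s) ldot[[s]])
    if (length(b) <= sym_threshold) {
      x <- rf_linsolve(sub, bl)
      if (is.null(x)) stop("(I+J) block is symbolically singular")
      for (r in seq_along(b)) {
        rhs[[states[b[r]]]] <- rf_to_expr(x[[r]])
      }
    } else {
      numeric_blocks[[length(numeric_blocks) + 1]] <- list(
        states = states[b],
        IpJ = lapply(sub, function(row) lapply(row, rf_to_expr)),
        ldot = lapply(bl, rf_to_expr))
      for (s in states[b]) rhs[[s]] <- NA
    }
  }
  # pass-through species (outside the fast set): own ODEs, substituted
  other <- setdiff(names(network$species), partition$fast_species)
  if (length(other)) {
    full_rhs <- rhs_rf(network)
    for (s in other) {
      rhs[[s]] <- rf_to_expr(rf_subs(full_rhs[[s]], gsubs))
    }
    states <- c(states, other)
  }
  # constants: retained lumps + any exact-row symbols referenced
  x0 <- network$species
  const_vals <- stats::setNames(numeric(0), character(0))
  for (k in constants) {
    const_vals[k] <- sum(x0[sp[scheme$Mm[k, ] != 0]])
  }
  syms <- unique(unlist(lapply(rhs[!is.na(rhs)], all.vars)))
  for (nb in numeric_blocks) {
    syms <- unique(c(syms, unlist(lapply(nb$IpJ, function(r)
      lapply(r, all.vars))), unlist(lapply(nb$ldot, all.vars))))
  }
  gvars <- unique(unlist(lapply(fractions$g, rf_vars)))
  syms <- unique(c(syms, gvars))
  known <- c(states, names(const_vals), names(network$parameters), "t")
  unknown <- setdiff(syms, known)
  if (length(unknown) && !is.null(exact)) {
    E <- exact$matrix
    for (u in intersect(unknown, rownames(E))) {
      const_vals[u] <- sum(E[u, ] * x0[colnames(E)])
    }
    unknown <- setdiff(unknown, rownames(E))
  }
  if (length(unknown)) {
    stop("reduced model references unknown symbol(s): ",
         paste(unknown, collapse = ", "))
  }
  IpJ_expr <- lapply(IpJ, function(row) lapply(row, rf_to_expr))
  structure(list(states = states,
                 lump_states = setdiff(lumps, constants),
                 constants = const_vals,
                 params = network$parameters,
                 rhs = rhs,
                 IpJ_expr = IpJ_expr,
                 numeric_blocks = numeric_blocks,
                 fractions = fractions, scheme = scheme,
                 partition = partition, apparent = apparent,
                 method = "lumping"),
            class = "ReducedModel")
}

#' @export
print.ReducedModel <- function(x, ...) {
  cat("ReducedModel (", x$method, "): ", length(x$states),
      " dynamic state(s): ", paste(x$states, collapse = ", "), "\n", sep = "")
  if (length(x$constants)) {
    cat("  constants:", paste(sprintf("%s = %g", names(x$constants),
                                      x$constants), collapse = ", "), "\n")
  }
  for (s in x$states) {
    if (!is.language(x$rhs[[s]]) && is.na(x$rhs[[s]])) {
      cat(sprintf("  d%s/dt : [numeric block solve]\n", s))
    } else {
      cat(sprintf("  d%s/dt = %s\n", s, deparse1(x$rhs[[s]])))
    }
  }
  invisible(x)
}

#' Naive reduction by direct QSS substitution
#'
#' The baseline approach: species assumed in QSS are removed and the fast
#' reaction balances are substituted into the remaining ODEs (equivalently,
#' retained fast species keep only their slow-reaction terms). The QSS
#' equation system plus exact conservations is solved symbolically for the
#' eliminated species to give a back-translation map. This approach is known
#' to fail structurally on some models (eliminated complexes can stay pinned
#' at their initial values when the retained states start at zero), which is
#' why the lumping-based reduction exists.
#'
#' @param network a [reaction_network()].
#' @param partition a [fs_partition()].
#' @param qss_species species to eliminate.
#' @param exact optional exact `ConservationBasis` contributing relations for
#'   the back-translation solve.
#' @return a `ReducedModel` with `method = "naive"`.
#' @export
naive_reduce <- function(network, partition, qss_species, exact = NULL) {
  sp <- names(network$species)
  bad <- setdiff(qss_species, sp)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  retained <- setdiff(sp, qss_species)
  S <- stoichiometric_matrix(network)
  slow <- partition$slow_reactions
  rs <- lapply(rate_expressions(network)[slow], expr_to_rf)
  # back-translation: solve QSS rows + conservations for the QSS species
  cand <- list()
  rfs <- lapply(partition$rf, expr_to_rf)
  for (i in seq_len(nrow(partition$Sf))) {
    acc <- rf_zero()
    for (j in seq_len(ncol(partition$Sf))) {
      cij <- partition$Sf[i, j]
      if (cij == 0) next
      acc <- rf_add(acc, rf_mul(rf_const(cij), rfs[[j]]))
    }
    if (!rf_is_zero(acc)) cand[[length(cand) + 1]] <- acc
  }
  if (!is.null(exact)) {
    E <- exact$matrix
    # prefer relations whose support lies entirely in the eliminated set
    # (they close the system without dragging in retained states)
    ord <- order(!vapply(seq_len(nrow(E)), function(k) {
      all(colnames(E)[E[k, ] != 0] %in% qss_species)
    }, logical(1)))
    for (k in ord) {
      acc <- rf_neg(rf_var(rownames(E)[k]))
      for (s2 in colnames(E)[E[k, ] != 0]) {
        acc <- rf_add(acc, rf_mul(rf_const(E[k, s2]), rf_var(s2)))
      }
      cand[[length(cand) + 1]] <- acc
    }
  }
  rows <- list(); consts <- list()
  for (r in cand) {
    if (mvp_deg(r$den, qss_species) > 0) next
    spl <- mvp_split_linear(r$num, qss_species)
    if (is.null(spl)) next
    den <- rf_new(r$den)
    row <- lapply(qss_species, function(m) rf_div(rf_new(spl$coef[[m]]), den))
    if (all(vapply(row, rf_is_zero, logical(1)))) next
    if (rf_rank(c(rows, list(row))) > length(rows)) {
      rows <- c(rows, list(row))
      consts[[length(consts) + 1]] <- rf_neg(rf_div(rf_new(spl$const), den))
    }
    if (length(rows) == length(qss_species)) break
  }
  if (length(rows) < length(qss_species)) {
    stop("QSS equation system cannot be solved symbolically for: ",
         paste(qss_species, collapse = ", "))
  }
  x <- rf_solve(rows, consts)
  if (is.null(x)) stop("QSS equation system is singular")
  g <- stats::setNames(x, qss_species)
  # compose (a solution may reference another eliminated species)
  for (iter in seq_len(length(g) + 1)) {
    changed <- FALSE
    for (m in names(g)) {
      pending <- setdiff(intersect(rf_vars(g[[m]]), qss_species), m)
      if (length(pending)) {
        g[[m]] <- rf_subs(g[[m]], g[pending])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (s2 in retained) g[[s2]] <- rf_var(s2)
  # retained rhs: slow columns only, eliminated species substituted
  rhs <- stats::setNames(vector("list", length(retained)), retained)
  for (s2 in retained) {
    acc <- rf_zero()
    for (j in seq_along(slow)) {
      cij <- S[s2, slow[j]]
      if (cij == 0) next
      acc <- rf_add(acc, rf_mul(rf_const(cij), rs[[j]]))
    }
    rhs[[s2]] <- rf_to_expr(rf_subs(acc, g[qss_species]))
  }
  const_vals <- stats::setNames(numeric(0), character(0))
  syms <- unique(c(unlist(lapply(rhs, all.vars)),
                   unlist(lapply(g, rf_vars))))
  known <- c(retained, qss_species, names(network$parameters), "t")
  unknown <- setdiff(syms, known)
  if (length(unknown) && !is.null(exact)) {
    E <- exact$matrix
    for (u in intersect(unknown, rownames(E))) {
      const_vals[u] <- sum(E[u, ] * network$species[colnames(E)])
    }
    unknown <- setdiff(unknown, rownames(E))
  }
  if (length(unknown)) {
    stop("naive reduction references unknown symbol(s): ",
         paste(unknown, collapse = ", "))
  }
  fractions <- structure(list(lumps = list(), g = g[qss_species],
                              non_back_translatable = character(0)),
                         class = "FractionParameterSet")
  structure(list(states = retained, lump_states = retained,
                 constants = const_vals, params = network$parameters,
                 rhs = rhs, numeric_blocks = list(),
                 fractions = fractions, scheme = NULL,
                 partition = partition, apparent = NULL,
                 method = "naive"),
            class = "ReducedModel")
}

## ---- numeric evaluation and simulation -------------------------------------

.reduced_rhs_num <- function(reduced, x, p, t = 0) {
  env <- c(as.list(x), as.list(reduced$constants), as.list(p), list(t = t))
  out <- stats::setNames(numeric(length(reduced$states)), reduced$states)
  for (s in reduced$states) {
    e <- reduced$rhs[[s]]
    if (is.language(e) || is.numeric(e)) {
      if (!is.language(e) && is.na(e)) next
      out[s] <- eval(e, env)
    }
  }
  for (nb in reduced$numeric_blocks) {
    m <- length(nb$states)
    M <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) M[i, j] <- eval(nb$IpJ[[i]][[j]], env)
    }
    b <- vapply(nb$ldot, eval, numeric(1), envir = env)
    out[nb$states] <- solve(M, b)
  }
  out
}

# determinant of (I+J) evaluated numerically at a state (positivity check)
det_IpJ <- function(reduced, x, p = reduced$params, t = 0) {
  env <- c(as.list(x), as.list(reduced$constants), as.list(p), list(t = t))
  dets <- numeric(0)
  if (!is.null(reduced$IpJ_expr)) {
    m <- length(reduced$IpJ_expr)
    M <- matrix(0, m, m)
    for (i in seq_len(m)) {
      for (j in seq_len(m)) M[i, j] <- eval(reduced$IpJ_expr[[i]][[j]], env)
    }
    dets <- c(dets, det(M))
  } else {
    for (nb in reduced$numeric_blocks) {
      m <- length(nb$states)
      M <- matrix(0, m, m)
      for (i in seq_len(m)) {
        for (j in seq_len(m)) M[i, j] <- eval(nb$IpJ[[i]][[j]], env)
      }
      dets <- c(dets, det(M))
    }
  }
  if (!length(dets)) 1 else prod(dets)
}

#' Simulate a model
#'
#' Stiff-capable integration (deSolve, `lsoda`) of either an original
#' reaction network or a reduced model, at tight tolerances so that
#' reduction error dominates integration error in comparisons.
#'
#' @param model a [reaction_network()] or `ReducedModel`.
#' @param times strictly increasing time grid (output reported exactly there).
#' @param params optional parameter overrides (full named vector or a subset).
#' @param x0 optional initial state (defaults to the model's own initial
#'   amounts; for a reduced model use [reduced_initial_conditions()]).
#' @param rtol,atol integrator tolerances.
#' @return a `Trajectory`: data.frame with `time` plus one column per state,
#'   carrying the parameter snapshot as attributes.
#' @export
simulate_model <- function(model, times, params = NULL, x0 = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(diff(times) > 0) || length(times) == 1)
  if (inherits(model, "ReactionNetwork")) {
    p <- model$parameters
    if (!is.null(params)) p[names(params)] <- params
    if (is.null(x0)) x0 <- model$species
    S <- stoichiometric_matrix(model)
    rates <- rate_expressions(model)
    pl <- as.list(p)
    fun <- function(t, y, parms) {
      env <- c(as.list(y), pl, list(t = t))
      r <- vapply(rates, eval, numeric(1), envir = env)
      list(drop(S %*% r))
    }
    id <- "original"
  } else if (inherits(model, "ReducedModel")) {
    p <- model$params
    if (!is.null(params)) p[names(params)] <- params
    if (is.null(x0)) {
      stop("supply reduced initial conditions (see reduced_initial_conditions)")
    }
    d0 <- det_IpJ(model, x0, p, t = min(times))
    if (!is.finite(d0) || abs(d0) < 1e-12) {
      stop("(I+J) is singular at the initial state (det = ", d0, ")")
    }
    fun <- function(t, y, parms) list(unname(.reduced_rhs_num(model, y, p, t)))
    id <- paste0("reduced-", model$method)
  } else {
    stop("unsupported model class")
  }
  t0 <- times
  if (t0[1] > 0) t0 <- c(0, t0)
  sol <- deSolve::ode(y = x0, times = t0, func = fun, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integration failed (istate = ", attr(sol, "istate")[1], ")")
  }
  df <- as.data.frame(sol)
  names(df)[1] <- "time"
  df <- df[df$time %in% times, , drop = FALSE]
  rownames(df) <- NULL
  if (!all(is.finite(as.matrix(df)))) stop("non-finite values in trajectory")
  structure(df, params = p, model_id = id,
            constants = if (inherits(model, "ReducedModel"))
              model$constants else NULL,
            class = c("Trajectory", "data.frame"))
}

#' Initial conditions for a reduced model
#'
#' The original initial state is generally off the fast subsystem's
#' quasi-steady state, so reduced initial conditions are obtained by
#' equilibrating first and then applying the lumping map. Two routes:
#' `"fast_eq"` integrates the fast subsystem alone (no slow leak, so
#' apparent lumps are preserved exactly) until the fast balance residual
#' drops below `tol`; `"burnin"` integrates the full original model for a
#' short window (`t_burn`, default one thousandth of `horizon`) and warns if
#' the residual has not settled.
#'
#' @param network the original [reaction_network()].
#' @param reduced the `ReducedModel`.
#' @param method `"fast_eq"` or `"burnin"`.
#' @param horizon comparison horizon (used for the default burn-in window).
#' @param t_burn explicit burn-in time (overrides `horizon`).
#' @param params optional parameter overrides.
#' @param tol fast-balance residual tolerance.
#' @return named numeric vector over the reduced states.
#' @export
reduced_initial_conditions <- function(network, reduced,
                                       method = c("fast_eq", "burnin"),
                                       horizon = NULL, t_burn = NULL,
                                       params = NULL, tol = 1e-6) {
  method <- match.arg(method)
  p <- network$parameters
  if (!is.null(params)) p[names(params)] <- params
  part <- reduced$partition
  residual <- function(x) {
    env <- c(as.list(x), as.list(p), list(t = 0))
    rfv <- vapply(part$rf, eval, numeric(1), envir = env)
    net <- drop(part$Sf %*% rfv)
    gross <- drop(abs(part$Sf) %*% abs(rfv))
    max(ifelse(gross > 0, abs(net) / gross, 0))
  }
  x0 <- network$species
  if (method == "fast_eq") {
    fast_net <- network
    fast_net$reactions <- network$reactions[
      vapply(network$reactions, function(rx) rx$id %in% part$fast_reactions,
             logical(1))]
    tb <- 1e-6
    x <- x0
    for (i in 1:40) {
      traj <- simulate_model(fast_net, c(0, tb), params = p, x0 = x)
      x <- unlist(traj[nrow(traj), names(x0)])
      if (residual(x) < tol) break
      tb <- tb * 2
    }
    if (residual(x) >= tol) {
      warning("fast equilibration residual still ", signif(residual(x), 3))
    }
  } else {
    if (is.null(t_burn)) {
      if (is.null(horizon)) stop("supply horizon or t_burn for burn-in")
      t_burn <- 1e-3 * horizon
    }
    traj <- simulate_model(network, c(0, t_burn), params = p, x0 = x0)
    x <- unlist(traj[nrow(traj), names(x0)])
    r <- residual(x)
    if (r >= tol) {
      warning("burn-in did not settle: fast balance residual ", signif(r, 3))
    }
  }
  out <- stats::setNames(numeric(length(reduced$states)), reduced$states)
  if (reduced$method == "naive") {
    out[reduced$states] <- x[reduced$states]
    return(out)
  }
  Mm <- reduced$scheme$Mm
  for (s in reduced$states) {
    if (s %in% rownames(Mm)) {
      out[s] <- sum(Mm[s, ] * x[colnames(Mm)])
    } else {
      out[s] <- x[[s]]
    }
  }
  out
}
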