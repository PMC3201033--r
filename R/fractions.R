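# Fraction parameters: the state- and parameter-dependent share of a lumped
# variable attributed to each of its member species. They are solved
# symbolically from relations that are jointly linear in the lump's members:
# quasi-steady-state balances of the fast reactions, conservation relations,
# the lump's own definition, and any user-supplied constraints. Symbols
# belonging to other lumps are frozen as parameters during the linearity
# check and the solve -- that freezing is what turns the nonlinear
# mass-action balances into linear systems.

.relation <- function(rf, provenance, label) {
  list(rf = rf, provenance = provenance, label = label)
}

#' Collect candidate linear relations for one lump
#'
#' Gathers, in deterministic provenance order (lump definition, QSS balances,
#' extra constraints, exact conservations), all relations that are jointly
#' linear in the lump's member species. QSS balances are the per-fast-species
#' rows of `Sf %*% rf ~ 0`, which covers both encodings of reversible fast
#' steps. Relations that fail the joint-linearity check (total degree > 1 in
#' the members, or members in a denominator) are dropped.
#'
#' @param network a [reaction_network()].
#' @param partition a [fs_partition()].
#' @param scheme a `LumpingScheme`.
#' @param lump name of the lump to collect relations for.
#' @param exact optional exact `ConservationBasis`; each row contributes a
#'   relation `sum(m_i x_i) = <row name>` with the row name acting as the
#'   constant symbol.
#' @param extra optional character/expression vector of additional constraint
#'   expressions understood as `expr = 0`.
#' @return an object of class `LinearRelationSet`.
#' @export
collect_relations <- function(network, partition, scheme, lump,
                              exact = NULL, extra = NULL) {
  members <- scheme$members[[lump]]
  if (is.null(members)) stop("unknown lump: ", lump)
  cand <- list()
  # 1. lump definition: sum of members = lump symbol
  if (!(length(members) == 1 && members == lump)) {
    def <- Reduce(rf_add, lapply(members, rf_var))
    cand[[length(cand) + 1]] <-
      .relation(rf_sub(def, rf_var(lump)), "lump definition",
                paste0(paste(members, collapse = "+"), " = ", lump))
  }
  # 2. QSS: rows of Sf %*% rf ~ 0, one per fast species
  rfs <- lapply(partition$rf, expr_to_rf)
  for (i in seq_len(nrow(partition$Sf))) {
    acc <- rf_zero()
    for (j in seq_len(ncol(partition$Sf))) {
      cij <- partition$Sf[i, j]
      if (cij == 0) next
      acc <- rf_add(acc, rf_mul(rf_const(cij), rfs[[j]]))
    }
    if (!rf_is_zero(acc)) {
      cand[[length(cand) + 1]] <-
        .relation(acc, "QSS",
                  paste0("fast balance of ", rownames(partition$Sf)[i]))
    }
  }
  # 3. extra constraints (tried before generic conservation rows: a supplied
  # constraint is the point of supplying it)
  if (!is.null(extra)) {
    for (e in extra) {
      if (is.character(e)) e <- str2lang(e)
      cand[[length(cand) + 1]] <-
        .relation(expr_to_rf(e), "extra", deparse1(e))
    }
  }
  # 4. exact conservations: sum(m_i x_i) = <row name>
  if (!is.null(exact)) {
    E <- exact$matrix
    for (k in seq_len(nrow(E))) {
      acc <- rf_neg(rf_var(rownames(E)[k]))
      for (s in colnames(E)[E[k, ] != 0]) {
        acc <- rf_add(acc, rf_mul(rf_const(E[k, s]), rf_var(s)))
      }
      cand[[length(cand) + 1]] <-
        .relation(acc, "conservation", rownames(E)[k])
    }
  }
  # joint-linearity filter w.r.t. this lump's members
  keep <- list()
  for (rel in cand) {
    if (mvp_deg(rel$rf$den, members) > 0) next
    if (is.null(mvp_split_linear(rel$rf$num, members))) next
    keep[[length(keep) + 1]] <- rel
  }
  structure(list(lump = lump, members = members, relations = keep),
            class = "LinearRelationSet")
}

#' @export
print.LinearRelationSet <- function(x, ...) {
  cat("LinearRelationSet for lump", x$lump, "(", length(x$members),
      "member(s) )\n")
  for (r in x$relations) {
    cat(sprintf("  [%s] %s = 0\n", r$provenance, format_rf(r$rf)))
  }
  invisible(x)
}

#' Solve a relation set for the fraction parameters of one lump
#'
#' Selects, in provenance order, the first subset of `n_m` relations whose
#' coefficient matrix is symbolically nonsingular (each added relation must
#' increase the symbolic rank), solves the linear system exactly, and forms
#' the fraction parameters `eta_i = x_i / sum(x)`. The normalization
#' `sum(eta) = 1` is verified symbolically.
#'
#' @param relations a [collect_relations()] result.
#' @param use optional integer indices selecting an explicit relation subset
#'   instead of the default first-found nonsingular one.
#' @return list with `members`, `eta` (named list of symbolic expressions),
#'   `g` (named list: member -> eta * lump, the back-translation map), and
#'   the selected relation labels; or an object of class
#'   `non_back_translatable` when no nonsingular subset exists (the lump can
#'   still be used in the reduced model, but cannot be back-translated).
#' @export
solve_fractions <- function(relations, use = NULL) {
  members <- relations$members
  lump <- relations$lump
  n_m <- length(members)
  if (n_m == 1) {
    eta <- stats::setNames(list(rf_const(1)), members)
    g <- stats::setNames(list(rf_var(lump)), members)
    return(list(lump = lump, members = members, eta = eta, g = g,
                selected = "identity (singleton lump)"))
  }
  rels <- relations$relations
  if (!is.null(use)) rels <- rels[use]
  rows <- list(); consts <- list(); labels <- character(0)
  for (rel in rels) {
    sp <- mvp_split_linear(rel$rf$num, members)
    den <- rf_new(rel$rf$den)
    row <- lapply(members, function(m) rf_div(rf_new(sp$coef[[m]]), den))
    if (all(vapply(row, rf_is_zero, logical(1)))) next
    cand_rows <- c(rows, list(row))
    if (rf_rank(cand_rows) > length(rows)) {
      rows <- cand_rows
      consts[[length(consts) + 1]] <- rf_neg(rf_div(rf_new(sp$const), den))
      labels <- c(labels, paste0(rel$provenance, ": ", rel$label))
    }
    if (length(rows) == n_m) break
  }
  if (length(rows) < n_m) {
    return(structure(list(lump = lump, members = members,
                          reason = sprintf(
                            "only %d independent linear relation(s) for %d members",
                            length(rows), n_m)),
                     class = "non_back_translatable"))
  }
  # Cramer's rule: x_i = det(A_i)/det(A). The common det(A) cancels in the
  # fractions, leaving each eta as a single polynomial ratio (the form the
  # method's worked reductions are written in).
  detA <- rf_det(rows)
  if (rf_is_zero(detA)) {
    return(structure(list(lump = lump, members = members,
                          reason = "selected relation system is singular"),
                     class = "non_back_translatable"))
  }
  x <- vector("list", n_m)
  for (i in seq_len(n_m)) {
    Ai <- lapply(seq_len(n_m), function(r) {
      row <- rows[[r]]
      row[[i]] <- consts[[r]]
      row
    })
    x[[i]] <- rf_div(rf_det(Ai), detA)
  }
  total <- Reduce(rf_add, x)
  if (rf_is_zero(total)) {
    return(structure(list(lump = lump, members = members,
                          reason = "member sum is identically zero"),
                     class = "non_back_translatable"))
  }
  eta <- stats::setNames(lapply(x, function(xi) rf_div(xi, total)), members)
  sum_eta <- Reduce(rf_add, eta)
  if (!rf_equal(sum_eta, rf_const(1))) {
    stop("internal error: fraction parameters do not sum to one for lump ",
         lump)
  }
  g <- stats::setNames(lapply(eta, function(e) rf_mul(e, rf_var(lump))),
                       members)
  list(lump = lump, members = members, eta = eta, g = g, selected = labels)
}

#' Derive fraction parameters for every lump of a scheme
#'
#' Runs [collect_relations()] and [solve_fractions()] for each lump and
#' composes the resulting back-translation maps so that every `g` is a
#' function of reduced-model states, constants and parameters only (a lump's
#' share may initially reference members of another lump; those are
#' substituted by their own back-translation).
#'
#' @inheritParams collect_relations
#' @param extra optional extra constraints (see [collect_relations()]),
#'   applied when collecting relations for every multi-member lump.
#' @return an object of class `FractionParameterSet`: per-lump solutions
#'   (`lumps`), the composed per-species back-translation map (`g`, named
#'   list of expressions), and the names of any non-back-translatable lumps.
#' @export
derive_fractions <- function(network, partition, scheme, exact = NULL,
                             extra = NULL) {
  sols <- list()
  nbt <- character(0)
  for (lump in rownames(scheme$Mm)) {
    rel <- collect_relations(network, partition, scheme, lump,
                             exact = exact, extra = extra)
    sol <- solve_fractions(rel)
    if (inherits(sol, "non_back_translatable")) {
      nbt <- c(nbt, lump)
      sols[[lump]] <- sol
    } else {
      sols[[lump]] <- sol
    }
  }
  # composed per-species map
  g <- list()
  for (lump in names(sols)) {
    sol <- sols[[lump]]
    if (inherits(sol, "non_back_translatable")) next
    for (m in sol$members) g[[m]] <- sol$g[[m]]
  }
  # substitute member symbols appearing inside other g's by their own g
  fast_sp <- partition$fast_species
  for (iter in seq_len(length(g) + 2)) {
    changed <- FALSE
    for (m in names(g)) {
      vars <- rf_vars(g[[m]])
      # species symbols that are not themselves lump names (a singleton lump
      # shares its species' name; substituting it would be the identity)
      pending <- intersect(vars, setdiff(fast_sp, rownames(scheme$Mm)))
      pending <- intersect(pending, names(g))
      pending <- pending[pending != m]
      if (length(pending)) {
        g[[m]] <- rf_subs(g[[m]], g[pending])
        changed <- TRUE
      }
    }
    if (!changed) break
    if (iter > length(g) + 1) {
      stop("cyclic dependency while composing back-translation maps")
    }
  }
  structure(list(lumps = sols, g = g, non_back_translatable = nbt),
            class = "FractionParameterSet")
}

#' Fraction parameters under additional linear constraints
#'
#' Convenience wrapper around [derive_fractions()] for reductions that assume
#' extra linear relations among the lump members (for instance a constant
#' regional distribution of a transporter between two membrane faces).
#'
#' @inheritParams derive_fractions
#' @param extra constraint expressions (strings or language), read as
#'   `expr = 0`.
#' @export
fractions_with_constraint <- function(network, partition, scheme,
                                      extra, exact = NULL) {
  derive_fractions(network, partition, scheme, exact = exact, extra = extra)
}

#' @export
print.FractionParameterSet <- function(x, ...) {
  for (lump in names(x$lumps)) {
    sol <- x$lumps[[lump]]
    if (inherits(sol, "non_back_translatable")) {
      cat(lump, ": non-back-translatable (", sol$reason, ")\n", sep = "")
      next
    }
    if (length(sol$members) == 1) next
    cat(lump, ":\n", sep = "")
    for (m in sol$members) {
      cat(sprintf("  eta[%s] = %s\n", m, format_rf(sol$eta[[m]])))
    }
  }
  invisible(x)
}
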