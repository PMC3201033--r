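# Conserved moiety analysis: exact left null spaces of stoichiometric
# matrices (conserved moieties), apparent conservation relations of the fast
# subnetwork, the maximal-vanishing-row change of basis, and detection of
# disjoint fast clusters.

#' @export
print.ConservationBasis <- function(x, ...) {
  cat("ConservationBasis (target: ", x$target, "), ",
      nrow(x$matrix), " relation(s)\n", sep = "")
  if (nrow(x$matrix)) print(x$matrix)
  invisible(x)
}

.conservation_basis <- function(M, target, names = NULL) {
  if (is.null(names)) names <- .auto_lump_names(M)
  rownames(M) <- names
  structure(list(matrix = M, target = target), class = "ConservationBasis")
}

# name a row after the shared moiety if one species name is a substring of
# every other name in the support; otherwise L1, L2, ... (deterministic)
.auto_lump_names <- function(M) {
  nm <- character(nrow(M))
  for (i in seq_len(nrow(M))) {
    sup <- colnames(M)[M[i, ] != 0]
    cand <- sup[vapply(sup, function(s) all(grepl(s, sup, fixed = TRUE)),
                       logical(1))]
    nm[i] <- if (length(cand) == 1) paste0("L", cand[1]) else paste0("L", i)
  }
  if (anyDuplicated(nm)) nm <- paste0("L", seq_len(nrow(M)))
  nm
}

#' Exact conserved moieties of a network
#'
#' Computes an integer basis of the left null space of the stoichiometric
#' matrix (rows m with `m %*% S == 0` in exact integer arithmetic). The basis
#' has `n - rank(S)` rows; a greedy repair attempts a nonnegative basis,
#' falling back to a signed integer basis with a warning.
#'
#' @param S a stoichiometric matrix (from [stoichiometric_matrix()]) or a
#'   [reaction_network()].
#' @param names optional row names for the relations.
#' @return a `ConservationBasis` (possibly with zero rows).
#' @export
exact_conservations <- function(S, names = NULL) {
  if (inherits(S, "ReactionNetwork")) S <- stoichiometric_matrix(S)
  M <- nonnegative_basis(rat_left_nullspace(S))
  .conservation_basis(M, target = "S", names = names)
}

#' Split a network into fast and slow reaction parts
#'
#' Restricts the model ODEs of the fast species to the form
#' `Ss %*% rs + Sf %*% rf`, where the fast columns are those named in
#' `fast` and the fast species default to all species touched by a fast
#' reaction.
#'
#' @param network a [reaction_network()].
#' @param fast character vector of reaction ids or group labels (a reversible
#'   step expanded into two columns is selected as one group), or integer
#'   column indices.
#' @param fast_species `"auto"` (species touched by fast reactions) or a
#'   character vector; a declared fast species touched by no fast reaction is
#'   an error.
#' @param window optional validity window `c(T0, T1)` (metadata only).
#' @return an object of class `FastSlowPartition` with components `Sf`, `Ss`
#'   (both restricted to the fast species), the rate expression lists
#'   `rf`/`rs`, and bookkeeping fields.
#' @export
fs_partition <- function(network, fast, fast_species = "auto",
                         window = c(0, Inf)) {
  S <- stoichiometric_matrix(network)
  ids <- colnames(S)
  groups <- vapply(network$reactions, `[[`, character(1), "group")
  if (is.numeric(fast)) {
    if (any(fast < 1 | fast > ncol(S))) stop("fast reaction index out of range")
    fast_cols <- ids[fast]
  } else {
    fast_cols <- ids[ids %in% fast | groups %in% fast]
    missing <- setdiff(fast, c(ids, groups))
    if (length(missing)) {
      stop("unknown fast reaction id(s): ", paste(missing, collapse = ", "))
    }
  }
  if (identical(fast_species, "auto")) {
    xf <- rownames(S)[rowSums(abs(S[, fast_cols, drop = FALSE])) > 0]
    # keep species order
    xf <- rownames(S)[rownames(S) %in% xf]
  } else if (is.numeric(fast_species)) {
    if (any(fast_species < 1 | fast_species > nrow(S))) {
      stop("fast species index out of range")
    }
    return(fs_partition(network, fast, rownames(S)[fast_species], window))
  } else {
    xf <- fast_species
    bad <- setdiff(xf, rownames(S))
    if (length(bad)) stop("unknown fast species: ", paste(bad, collapse = ", "))
    untouched <- xf[colSums(abs(t(S[xf, fast_cols, drop = FALSE]))) == 0]
    if (length(untouched)) {
      stop("declared fast species touched by no fast reaction: ",
           paste(untouched, collapse = ", "))
    }
    xf <- rownames(S)[rownames(S) %in% xf]
  }
  if (length(fast_cols)) {
    touch <- colSums(abs(S[xf, fast_cols, drop = FALSE])) > 0
    if (!all(touch)) {
      stop("fast reaction(s) touching no fast species: ",
           paste(fast_cols[!touch], collapse = ", "))
    }
  }
  slow_cols <- setdiff(ids, fast_cols)
  rates <- rate_expressions(network)
  rf <- rates[fast_cols]
  nonfast_syms <- setdiff(unique(unlist(lapply(rf, all.vars))),
                          c(xf, names(network$parameters), "t"))
  if (length(nonfast_syms)) {
    warning("fast rate expressions reference non-fast species: ",
            paste(nonfast_syms, collapse = ", "))
  }
  structure(list(network = network,
                 fast_reactions = fast_cols, slow_reactions = slow_cols,
                 fast_species = xf,
                 Sf = S[xf, fast_cols, drop = FALSE],
                 Ss = S[xf, slow_cols, drop = FALSE],
                 rf = rf, rs = rates[slow_cols],
                 window = window),
            class = "FastSlowPartition")
}

#' @export
print.FastSlowPartition <- function(x, ...) {
  cat("FastSlowPartition:", length(x$fast_species), "fast species,",
      length(x$fast_reactions), "fast /", length(x$slow_reactions),
      "slow reaction column(s)\n")
  cat("  fast species:", paste(x$fast_species, collapse = ", "), "\n")
  cat("  fast columns:", paste(x$fast_reactions, collapse = ", "), "\n")
  invisible(x)
}

#' Apparent conservation relations of the fast subnetwork
#'
#' An apparent conservation is a left null vector of the fast stoichiometric
#' matrix `Sf`: a quantity conserved by the fast reactions alone and hence
#' slowly varying in the full model. The basis has
#' `n_f - rank(Sf)` integer rows.
#'
#' @param partition a [fs_partition()].
#' @param names optional row names.
#' @return a `ConservationBasis` with target `"Sf"`.
#' @export
apparent_conservations <- function(partition, names = NULL) {
  M <- nonnegative_basis(rat_left_nullspace(partition$Sf))
  .conservation_basis(M, target = "Sf", names = names)
}

#' Change of basis maximizing vanishing rows of M Ss
#'
#' Any nonsingular recombination `N %*% Mf` of an apparent conservation basis
#' is again a valid basis. This picks one for which a maximal number of rows
#' of `M %*% Ss` vanish (those rows are then exactly conserved, not just
#' apparently), namely `a - rank(Mf %*% Ss)` rows.
#'
#' @param Mf a `ConservationBasis` (target `"Sf"`).
#' @param Ss slow stoichiometric matrix restricted to the fast species
#'   (from the partition).
#' @return a `ConservationBasis` with a logical attribute `vanishing` marking
#'   the transformed rows whose product with `Ss` is zero; untransformed rows
#'   keep their names.
#' @export
maximize_vanishing_rows <- function(Mf, Ss) {
  M <- Mf$matrix
  a <- nrow(M)
  if (a == 0) return(Mf)
  P <- M %*% Ss
  W <- rat_left_nullspace(P)            # rows w with w %*% P == 0
  nz <- nrow(W)
  # complete W to a nonsingular N with unit rows (exact rank tests)
  N <- W
  for (i in seq_len(a)) {
    if (nrow(N) == a) break
    e <- matrix(0, 1, a); e[1, i] <- 1
    if (rat_rank(rbind(N, e)) > nrow(N)) N <- rbind(N, e)
  }
  # prefer presenting unit rows untransformed and putting vanishing rows first
  Mhat <- N %*% M
  # integer rescale each row
  for (i in seq_len(nrow(Mhat))) {
    v <- Mhat[i, ]
    if (any(v != 0)) {
      g <- Reduce(.gcd_pair, abs(v[v != 0]))
      Mhat[i, ] <- v / g
    }
  }
  vanishing <- c(rep(TRUE, nz), rep(FALSE, a - nz))
  nm <- character(a)
  for (i in seq_len(a)) {
    coefs <- N[i, ]
    used <- which(coefs != 0)
    nm[i] <- if (length(used) == 1 && coefs[used] == 1) rownames(M)[used] else
      paste(ifelse(coefs[used] == 1, rownames(M)[used],
                   paste0(coefs[used], "*", rownames(M)[used])),
            collapse = "+")
  }
  out <- .conservation_basis(Mhat, target = Mf$target, names = nm)
  attr(out, "vanishing") <- vanishing
  out
}

#' Disjoint clusters of fast reactions
#'
#' Connected components of the bipartite graph on fast species and fast
#' reaction columns (an edge where the fast stoichiometry is nonzero). Each
#' cluster is an internally equilibrated unit treated separately by the
#' reduction.
#'
#' @param partition a [fs_partition()].
#' @return list of clusters, each `list(species=, reactions=)`; every fast
#'   species belongs to exactly one cluster.
#' @export
fast_clusters <- function(partition) {
  Sf <- partition$Sf
  if (ncol(Sf) == 0) return(list())
  sp <- rownames(Sf); rx <- colnames(Sf)
  edges <- which(Sf != 0, arr.ind = TRUE)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(c(paste0("s:", sp), paste0("r:", rx)))
  g <- igraph::add_edges(g, rbind(paste0("s:", sp[edges[, 1]]),
                                  paste0("r:", rx[edges[, 2]])))
  comp <- igraph::components(g)
  out <- list()
  for (k in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == k]
    cl_sp <- sub("^s:", "", vs[startsWith(vs, "s:")])
    cl_rx <- sub("^r:", "", vs[startsWith(vs, "r:")])
    if (!length(cl_sp)) next
    out[[length(out) + 1]] <- list(species = sp[sp %in% cl_sp],
                                   reactions = rx[rx %in% cl_rx])
  }
  out
}

#' Heuristic screen for quasi-steady-state species
#'
#' Simulates the model and flags species whose net production stays small
#' relative to their gross in/out fluxes (flux balance). This is a screening
#' aid only; the choice of fast reactions is always the user's (there is no
#' consensus criterion for automatic QSS detection) and nothing in the
#' reduction pipeline applies this heuristic implicitly.
#'
#' @param network a [reaction_network()].
#' @param t_end pilot-simulation horizon.
#' @param threshold maximum |net|/gross flux ratio for the QSS flag.
#' @param n_points samples along the trajectory (the first 5% of the horizon
#'   is ignored to let fast transients settle).
#' @return data.frame with species, the worst residual, and the flag.
#' @export
suggest_qss_species <- function(network, t_end, threshold = 0.05,
                                n_points = 60) {
  times <- seq(0, t_end, length.out = n_points + 1)
  traj <- simulate_model(network, times)
  S <- stoichiometric_matrix(network)
  rates <- rate_expressions(network)
  keep <- traj$time >= 0.05 * t_end
  res <- stats::setNames(numeric(nrow(S)), rownames(S))
  for (i in which(keep)) {
    env <- c(as.list(traj[i, rownames(S)]), as.list(network$parameters),
             list(t = traj$time[i]))
    r <- vapply(rates, eval, numeric(1), envir = env)
    flux <- S * rep(r, each = nrow(S))
    gross <- rowSums(pmax(flux, 0)) + rowSums(pmax(-flux, 0))
    net <- abs(rowSums(flux))
    ratio <- ifelse(gross > 0, 2 * net / gross, 0)
    res <- pmax(res, ratio)
  }
  data.frame(species = rownames(S), max_residual = unname(res),
             qss = unname(res < threshold), row.names = NULL)
}

#' Construct a conservation basis from an explicit matrix
#'
#' For declaring a canonical, named basis (e.g. the interpretable moiety
#' relations of a published model). Each row is verified to annihilate the
#' target matrix in exact integer arithmetic, and the row count must equal
#' the null-space dimension (so the rows really are a basis).
#'
#' @param M integer matrix, rows = relations, columns named by species.
#' @param target the stoichiometric matrix the rows must annihilate
#'   (full `S` for exact relations, `Sf` for apparent ones).
#' @param target_tag `"S"` or `"Sf"`.
#' @param check_basis verify the rows span the full left null space (set to
#'   `FALSE` to allow a deliberate non-maximal list of relations).
#' @return a `ConservationBasis`.
#' @export
conservation_basis <- function(M, target, target_tag = "S",
                               check_basis = TRUE) {
  M <- M[, rownames(target), drop = FALSE]
  Z <- M %*% target
  if (any(Z != 0)) {
    bad <- rownames(M)[rowSums(Z != 0) > 0]
    stop("row(s) do not annihilate the target matrix: ",
         paste(bad, collapse = ", "))
  }
  if (rat_rank(M) != nrow(M)) stop("rows are not linearly independent")
  if (check_basis) {
    expected <- nrow(target) - rat_rank(target)
    if (nrow(M) != expected) {
      stop("expected ", expected, " basis rows, got ", nrow(M))
    }
  }
  .conservation_basis(M, target = target_tag, names = rownames(M))
}
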