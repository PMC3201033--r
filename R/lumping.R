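# Proper lumping schemes: binary lumping matrices whose rows define the
# modified lumped state variables of the reduced model. A scheme is proper
# when every original (fast) species contributes to exactly one lump, and
# each lump is a sub-pool of one apparent conservation relation.

#' Validate a proper lumping scheme
#'
#' Checks the three defining conditions: binary entries, unit column sums
#' (each species in exactly one lump), and each lump's member set contained
#' in the support of a single apparent conservation row.
#'
#' @param Mm binary lumping matrix (lumps x fast species, dimnames required)
#'   or a `LumpingScheme`.
#' @param apparent the apparent `ConservationBasis` the scheme refines.
#' @return list with `ok` flag and a data.frame `violations`
#'   (one row per problem, naming the offending row/column).
#' @export
validate_proper <- function(Mm, apparent) {
  if (inherits(Mm, "LumpingScheme")) Mm <- Mm$Mm
  viol <- data.frame(kind = character(0), where = character(0),
                     detail = character(0))
  add <- function(kind, where, detail) {
    viol[nrow(viol) + 1, ] <<- list(kind, where, detail)
  }
  if (!all(Mm %in% c(0, 1))) {
    bad <- which(!(Mm %in% c(0, 1)))[1]
    add("non-binary entry", paste0("entry ", bad), as.character(Mm[bad]))
  }
  cs <- colSums(Mm)
  for (j in which(cs != 1)) {
    add("column sum != 1", colnames(Mm)[j], as.character(cs[j]))
  }
  A <- apparent$matrix
  for (i in seq_len(nrow(Mm))) {
    members <- colnames(Mm)[Mm[i, ] != 0]
    if (!length(members)) {
      add("empty lump", rownames(Mm)[i], "")
      next
    }
    contained <- vapply(seq_len(nrow(A)), function(k) {
      all(members %in% colnames(A)[A[k, ] != 0])
    }, logical(1))
    if (!any(contained)) {
      add("lump not inside any apparent conservation", rownames(Mm)[i],
          paste(members, collapse = "+"))
    }
  }
  list(ok = nrow(viol) == 0, violations = viol)
}

#' Build a proper lumping scheme from conservation bases
#'
#' Retained lumps (named in `keep`) take the full member set of the matching
#' apparent conservation row; every other fast species becomes its own
#' singleton lump (or is attached per `assignment`). Lumps whose relation is
#' also an exact conservation of the full model are flagged as retained
#' constants. Kept lumps with overlapping members make the scheme improper
#' and raise an error naming the shared species.
#'
#' @param apparent apparent `ConservationBasis` (target `"Sf"`).
#' @param exact exact `ConservationBasis` of the full model (target `"S"`).
#' @param keep character vector of apparent row names to retain as lumps.
#' @param assignment optional named character vector mapping a non-kept fast
#'   species to the name of the lump it should join (default: singleton).
#' @param names_from optional named list `lump -> members` overriding the
#'   kept rows' member sets with a strict subset (must stay proper).
#' @return a `LumpingScheme` with the binary matrix `Mm`, the member map,
#'   and the retained-constant set.
#' @export
build_scheme <- function(apparent, exact, keep = character(0),
                         assignment = NULL, names_from = NULL) {
  A <- apparent$matrix
  sp <- colnames(A)
  missing <- setdiff(keep, rownames(A))
  if (length(missing)) {
    stop("kept lump(s) not among the apparent conservation rows: ",
         paste(missing, collapse = ", "))
  }
  members <- list()
  for (k in keep) {
    mem <- sp[A[k, ] != 0]
    if (!is.null(names_from) && k %in% names(names_from)) {
      mem <- names_from[[k]]
    }
    members[[k]] <- mem
  }
  # overlap check among kept lumps
  if (length(keep) > 1) {
    for (i in seq_along(keep)[-1]) {
      for (j in seq_len(i - 1)) {
        shared <- intersect(members[[keep[i]]], members[[keep[j]]])
        if (length(shared)) {
          stop("improper scheme: lumps '", keep[i], "' and '", keep[j],
               "' share species ", paste(shared, collapse = ", "))
        }
      }
    }
  }
  assigned <- unlist(members, use.names = FALSE)
  rest <- setdiff(sp, assigned)
  for (s in rest) {
    tgt <- if (!is.null(assignment) && s %in% names(assignment))
      assignment[[s]] else s
    members[[tgt]] <- c(members[[tgt]], s)
  }
  # deterministic lump order: file order of the first member
  first_pos <- vapply(members, function(m) min(match(m, sp)), numeric(1))
  members <- members[order(first_pos)]
  Mm <- matrix(0L, length(members), length(sp),
               dimnames = list(names(members), sp))
  for (i in seq_along(members)) Mm[i, members[[i]]] <- 1L
  chk <- validate_proper(Mm, apparent)
  if (!chk$ok) {
    stop("improper scheme: ", paste(chk$violations$kind, "at",
                                    chk$violations$where, collapse = "; "))
  }
  # retained constants: kept lumps whose relation annihilates the full S
  S <- NULL
  constants <- character(0)
  if (!is.null(exact)) {
    E <- exact$matrix
    for (k in keep) {
      row <- Mm[k, , drop = FALSE]
      full <- matrix(0, 1, ncol(E), dimnames = list(k, colnames(E)))
      full[1, colnames(row)] <- row
      # constant iff the row lies in the row space of the exact basis
      if (nrow(E) && rat_rank(rbind(E, full)) == rat_rank(E)) {
        constants <- c(constants, k)
      }
    }
  }
  structure(list(Mm = Mm, members = members, constants = constants,
                 keep = keep),
            class = "LumpingScheme")
}

#' @export
print.LumpingScheme <- function(x, ...) {
  cat("LumpingScheme:", nrow(x$Mm), "lump(s) over", ncol(x$Mm),
      "fast species\n")
  for (i in seq_len(nrow(x$Mm))) {
    nm <- rownames(x$Mm)[i]
    cat(sprintf("  %s = %s%s\n", nm,
                paste(colnames(x$Mm)[x$Mm[i, ] != 0], collapse = " + "),
                if (nm %in% x$constants) "  [constant]" else ""))
  }
  invisible(x)
}

#' Summary counts for a reduction
#'
#' Reports the number of dynamic states, retained constants, and the number
#' of independent parameter combinations of a reduced model. The dynamic
#' state count is the number of lumps (plus pass-through species) minus the
#' retained constants and minus any additionally exploited exact conservation
#' relations; the parameter count is the rank of the reduced right-hand
#' side's sensitivity to log-parameters on a fixed deterministic state grid,
#' i.e. the number of parameter combinations the reduced dynamics actually
#' depends on (ratio parameters such as binding constants count once).
#'
#' @param reduced a `ReducedModel` from [derive_reduced()].
#' @param exploit names of additional exact conservation rows (from the
#'   exact basis used when building the scheme) to exploit for state
#'   elimination; each must be expressible through back-translatable lumps.
#' @param exact optional exact `ConservationBasis` (needed when `exploit`
#'   is nonempty).
#' @param count_parameters set `FALSE` to skip the (potentially costly)
#'   sensitivity-rank parameter count.
#' @return list with `dynamic_states`, `constants`, `parameters`.
#' @export
reduction_summary <- function(reduced, exploit = character(0), exact = NULL,
                              count_parameters = TRUE) {
  n_dyn <- length(reduced$states)
  n_const <- length(reduced$scheme$constants)
  if (length(exploit)) {
    if (is.null(exact)) stop("supply the exact basis to exploit relations")
    E <- exact$matrix
    bt <- names(reduced$fractions$g)
    used <- E[reduced$scheme$constants[reduced$scheme$constants %in%
                                         rownames(E)], , drop = FALSE]
    for (k in exploit) {
      if (!k %in% rownames(E)) stop("unknown exact relation: ", k)
      sup <- colnames(E)[E[k, ] != 0]
      if (!all(sup %in% bt)) {
        stop("relation '", k, "' involves species without back-translation: ",
             paste(setdiff(sup, bt), collapse = ", "))
      }
      if (rat_rank(rbind(used, E[k, , drop = FALSE])) > rat_rank(used)) {
        used <- rbind(used, E[k, , drop = FALSE])
        n_dyn <- n_dyn - 1L
      }
    }
  }
  list(dynamic_states = n_dyn,
       constants = n_const + length(exploit),
       parameters = if (count_parameters) .parameter_count(reduced) else NA)
}

# rank of d(rhs)/d(log p) stacked over a fixed deterministic grid of states
.parameter_count <- function(reduced) {
  pnames <- names(reduced$params)
  if (!length(pnames)) return(0L)
  states <- reduced$states
  rows <- list()
  # fixed, seedless probe states: positive, incommensurate values
  probes <- lapply(1:6, function(k) {
    stats::setNames(0.2 + 0.37 * ((k * seq_along(states) + 1) %% 7), states)
  })
  h <- 1e-5
  Jmat <- matrix(0, length(probes) * length(states), length(pnames))
  for (k in seq_along(probes)) {
    x <- probes[[k]]
    for (j in seq_along(pnames)) {
      pu <- reduced$params; pu[j] <- pu[j] * exp(h)
      pd <- reduced$params; pd[j] <- pd[j] * exp(-h)
      sens <- (.reduced_rhs_num(reduced, x, pu) -
                 .reduced_rhs_num(reduced, x, pd)) / (2 * h)
      Jmat[(k - 1) * length(states) + seq_along(states), j] <- sens
    }
  }
  # scale out the overall magnitude per column block, then SVD rank
  s <- svd(Jmat)$d
  sum(s > max(s) * 1e-6)
}
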