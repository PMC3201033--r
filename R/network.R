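# Reaction network representation: species, parameters, reactions with
# stoichiometry and (possibly signed) rate expressions. The model ODEs are
# always x' = S %*% r(x, p), with S the integer stoichiometric matrix and r
# the vector of rate expressions, one per stored column.

#' Construct a single reaction
#'
#' @param id reaction identifier (unique within a network).
#' @param reactants,products named integer vectors of stoichiometric
#'   coefficients (may be empty for exchange reactions).
#' @param rate rate expression as a string or unevaluated R expression over
#'   species, parameters and time `t`. A signed expression (e.g.
#'   `"k1*A*B - km1*C"`) denotes the net rate of a reversible step stored as
#'   a single column.
#' @param group optional label tying together columns that arose from one
#'   written reaction (e.g. the two irreversible columns of a reversible
#'   step); defaults to `id`.
#' @return a list describing one stoichiometric column.
#' @export
rxn <- function(id, reactants, products, rate, group = id) {
  if (is.character(rate)) rate <- str2lang(rate)
  r <- as.integer(reactants); names(r) <- names(reactants)
  p <- as.integer(products); names(p) <- names(products)
  list(id = id, reactants = r, products = p, rate = rate, group = group)
}

#' Construct a reaction network model
#'
#' @param species named numeric vector of nonnegative initial amounts, in
#'   model order (all matrices produced from the network use this order).
#' @param parameters named numeric vector of positive parameter values.
#' @param reactions list of reactions built with [rxn()].
#' @return an object of class `ReactionNetwork`.
#' @export
reaction_network <- function(species, parameters, reactions) {
  stopifnot(length(species) >= 1)
  if (anyDuplicated(names(species))) stop("duplicate species names")
  if (anyDuplicated(names(parameters))) stop("duplicate parameter names")
  if (length(intersect(names(species), names(parameters)))) {
    stop("species and parameter names must be disjoint: ",
         paste(intersect(names(species), names(parameters)), collapse = ", "))
  }
  if (any(species < 0)) stop("initial amounts must be nonnegative")
  ids <- vapply(reactions, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate reaction ids")
  known <- c(names(species), names(parameters), "t")
  for (rx in reactions) {
    bad <- setdiff(all.vars(rx$rate), known)
    if (length(bad)) {
      stop("undeclared symbol(s) in rate of reaction '", rx$id, "': ",
           paste(bad, collapse = ", "))
    }
    badsp <- setdiff(c(names(rx$reactants), names(rx$products)), names(species))
    if (length(badsp)) {
      stop("undeclared species in reaction '", rx$id, "': ",
           paste(badsp, collapse = ", "))
    }
  }
  closed <- all(vapply(reactions, function(rx) {
    length(rx$reactants) > 0 && length(rx$products) > 0
  }, logical(1)))
  structure(list(species = species, parameters = parameters,
                 reactions = reactions, closed = closed),
            class = "ReactionNetwork")
}

#' @export
print.ReactionNetwork <- function(x, ...) {
  cat("ReactionNetwork:", length(x$species), "species,",
      length(x$reactions), "reaction column(s),",
      length(x$parameters), "parameter(s)",
      if (x$closed) "(closed)" else "(open)", "\n")
  for (rx in x$reactions) {
    side <- function(s) if (!length(s)) "0" else
      paste(ifelse(s > 1, paste(s, names(s)), names(s)), collapse = " + ")
    cat(sprintf("  %s: %s -> %s : %s\n", rx$id, side(rx$reactants),
                side(rx$products), deparse1(rx$rate)))
  }
  invisible(x)
}

#' Stoichiometric matrix of a network
#'
#' Column j holds product-minus-reactant stoichiometry of the j:th stored
#' reaction column, so that the model ODEs are exactly `S %*% r(x, p)`.
#'
#' @param network a [reaction_network()].
#' @return integer matrix (species x reactions) with dimnames.
#' @export
stoichiometric_matrix <- function(network) {
  sp <- names(network$species)
  q <- length(network$reactions)
  S <- matrix(0L, length(sp), q,
              dimnames = list(sp, vapply(network$reactions, `[[`,
                                         character(1), "id")))
  for (j in seq_len(q)) {
    rx <- network$reactions[[j]]
    for (s in names(rx$reactants)) S[s, j] <- S[s, j] - rx$reactants[[s]]
    for (s in names(rx$products)) S[s, j] <- S[s, j] + rx$products[[s]]
  }
  S
}

rate_expressions <- function(network) {
  stats::setNames(lapply(network$reactions, `[[`, "rate"),
                  vapply(network$reactions, `[[`, character(1), "id"))
}

# symbolic rhs per species, as kernel rational functions
rhs_rf <- function(network) {
  S <- stoichiometric_matrix(network)
  rates <- lapply(rate_expressions(network), expr_to_rf)
  out <- stats::setNames(vector("list", nrow(S)), rownames(S))
  for (i in seq_len(nrow(S))) {
    acc <- rf_zero()
    for (j in seq_len(ncol(S))) {
      if (S[i, j] == 0) next
      acc <- rf_add(acc, rf_mul(rf_const(S[i, j]), rates[[j]]))
    }
    out[[i]] <- acc
  }
  out
}

#' Evaluate the network right-hand side S r(x, p) at a state
#'
#' @param network a [reaction_network()].
#' @param x numeric state vector of length `n` (named or in species order).
#' @param p parameter values; defaults to the network's parameters.
#' @param t time (rate expressions may reference `t`).
#' @return named numeric vector of state derivatives.
#' @export
network_rhs <- function(network, x, p = network$parameters, t = 0) {
  sp <- names(network$species)
  if (length(x) != length(sp)) stop("state vector has wrong length")
  if (is.null(names(x))) names(x) <- sp else x <- x[sp]
  if (any(x < -1e-8)) {
    warning("state has negative entries beyond solver tolerance")
  }
  bad <- setdiff(names(p), names(network$parameters))
  if (length(bad)) stop("unknown parameter name(s): ", paste(bad, collapse = ", "))
  env <- c(as.list(x), as.list(p), list(t = t))
  S <- stoichiometric_matrix(network)
  r <- vapply(rate_expressions(network), eval, numeric(1), envir = env)
  drop(S %*% r) |> stats::setNames(sp)
}

## ---- native model file format --------------------------------------------

.parse_side <- function(txt) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") return(stats::setNames(integer(0), character(0)))
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  out <- integer(0)
  for (p in parts) {
    m <- regmatches(p, regexec("^([0-9]+)\\s+(\\S+)$", p))[[1]]
    if (length(m)) {
      out[m[3]] <- as.integer(m[2])
    } else {
      out[p] <- 1L
    }
  }
  out
}

#' Read a reaction network from a model file
#'
#' The native format is a declarative text file with `[species]`,
#' `[parameters]` and `[reactions]` sections. Species and parameters are
#' `name = value` lines; reactions are written as reaction schemes:
#' \preformatted{
#' r1: S + E <-> CS : k1, km1        # two irreversible mass-action columns
#' r2: CS -> CP : k2                 # one mass-action column (rate k2*CS)
#' r3: CP <-> P + E : k3*CP - km3*P*E  # one signed net-rate column
#' }
#' A reversible arrow with two rate constants expands into two irreversible
#' columns (grouped under the written id); a reaction with an explicit rate
#' expression is stored as a single (possibly signed) column. Both encodings
#' of a reversible step yield identical right-hand sides.
#'
#' @param path file path.
#' @param format `"native"` or `"sbml"` (a Level 2/3 core subset; events,
#'   rules and other constructs raise an "unsupported feature" error).
#' @return a validated [reaction_network()]; species and reaction order equal
#'   file order.
#' @export
load_network <- function(path, format = c("native", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("model file not found: ", path)
  if (format == "sbml") return(.load_sbml(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  section <- NA_character_
  species <- numeric(0); params <- numeric(0); reactions <- list()
  for (ln in lines) {
    if (grepl("^\\[", ln)) {
      section <- tolower(gsub("\\[|\\]", "", ln))
      if (!section %in% c("species", "parameters", "reactions")) {
        stop("unknown section in model file: [", section, "]")
      }
      next
    }
    if (is.na(section)) stop("content before first section in model file: ", ln)
    if (section %in% c("species", "parameters")) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("cannot parse line: ", ln)
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (is.na(val)) stop("non-numeric value in line: ", ln)
      if (section == "species") species[trimws(kv[1])] <- val
      else params[trimws(kv[1])] <- val
    } else {
      parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
      if (length(parts) < 3) stop("cannot parse reaction line: ", ln)
      id <- trimws(parts[1])
      scheme <- trimws(parts[2])
      ratespec <- trimws(paste(parts[-(1:2)], collapse = ":"))
      rev <- grepl("<->", scheme, fixed = TRUE)
      arrow <- if (rev) "<->" else "->"
      if (!grepl(arrow, scheme, fixed = TRUE)) {
        stop("reaction line has no arrow: ", ln)
      }
      sides <- strsplit(scheme, arrow, fixed = TRUE)[[1]]
      lhs <- .parse_side(sides[1]); rhs <- .parse_side(sides[2])
      mass_action <- function(k, st) {
        e <- str2lang(k)
        for (s in names(st)) {
          f <- if (st[[s]] == 1) as.name(s) else call("^", as.name(s), st[[s]])
          e <- call("*", e, f)
        }
        e
      }
      if (grepl(",", ratespec, fixed = TRUE)) {
        ks <- trimws(strsplit(ratespec, ",", fixed = TRUE)[[1]])
        if (!rev || length(ks) != 2) {
          stop("two rate constants require a reversible arrow: ", ln)
        }
        reactions[[length(reactions) + 1]] <-
          rxn(id, lhs, rhs, mass_action(ks[1], lhs), group = id)
        reactions[[length(reactions) + 1]] <-
          rxn(paste0(id, "_rev"), rhs, lhs, mass_action(ks[2], rhs), group = id)
      } else if (grepl("^[A-Za-z][A-Za-z0-9_.]*$", ratespec) && !rev) {
        reactions[[length(reactions) + 1]] <-
          rxn(id, lhs, rhs, mass_action(ratespec, lhs), group = id)
      } else {
        reactions[[length(reactions) + 1]] <-
          rxn(id, lhs, rhs, str2lang(ratespec), group = id)
      }
    }
  }
  reaction_network(species, params, reactions)
}

#' Write a network in the native model format
#'
#' Each stored column is written with its explicit rate expression, so a
#' reloaded file reproduces the right-hand side symbolically.
#'
#' @param network a [reaction_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  side <- function(s) if (!length(s)) "0" else
    paste(ifelse(s > 1, paste(s, names(s)), names(s)), collapse = " + ")
  lines <- c("[species]",
             sprintf("%s = %.17g", names(network$species), network$species),
             "", "[parameters]",
             sprintf("%s = %.17g", names(network$parameters), network$parameters),
             "", "[reactions]",
             vapply(network$reactions, function(rx) {
               sprintf("%s: %s -> %s : %s", rx$id, side(rx$reactants),
                       side(rx$products), deparse1(rx$rate))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

## ---- SBML subset importer -------------------------------------------------

.mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  if (name == "math") {
    kids <- xml2::xml_children(node)
    if (length(kids) != 1) stop("unsupported feature: multi-child math element")
    return(.mathml_to_expr(kids[[1]]))
  }
  if (name == "ci") return(as.name(trimws(xml2::xml_text(node))))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && !type %in% c("integer", "real")) {
      stop("unsupported feature: cn type '", type, "'")
    }
    return(as.numeric(trimws(xml2::xml_text(node))))
  }
  if (name == "apply") {
    kids <- xml2::xml_children(node)
    op <- xml2::xml_name(kids[[1]])
    args <- lapply(kids[-1], .mathml_to_expr)
    sym <- switch(op, plus = "+", minus = "-", times = "*",
                  divide = "/", power = "^",
                  stop("unsupported feature: MathML operator <", op, ">"))
    if (op == "minus" && length(args) == 1) return(call("-", args[[1]]))
    if (length(args) < 2) stop("unsupported feature: unary <", op, ">")
    return(Reduce(function(a, b) call(sym, a, b), args))
  }
  stop("unsupported feature: MathML element <", name, ">")
}

.load_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  model <- xml2::xml_find_first(doc, ".//model")
  if (inherits(model, "xml_missing")) stop("no <model> element in SBML file")
  for (forb in c("listOfEvents", "listOfRules", "listOfConstraints",
                 "listOfFunctionDefinitions", "listOfInitialAssignments")) {
    if (!inherits(xml2::xml_find_first(model, paste0("./", forb)),
                  "xml_missing")) {
      stop("unsupported feature: ", forb)
    }
  }
  sp_nodes <- xml2::xml_find_all(model, "./listOfSpecies/species")
  if (!length(sp_nodes)) stop("no species in SBML model")
  species <- stats::setNames(vapply(sp_nodes, function(n) {
    v <- xml2::xml_attr(n, "initialAmount")
    if (is.na(v)) v <- xml2::xml_attr(n, "initialConcentration")
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1)), vapply(sp_nodes, xml2::xml_attr, character(1), "id"))
  par_nodes <- xml2::xml_find_all(model, "./listOfParameters/parameter")
  params <- stats::setNames(
    vapply(par_nodes, function(n) as.numeric(xml2::xml_attr(n, "value")),
           numeric(1)),
    vapply(par_nodes, xml2::xml_attr, character(1), "id"))
  rx_nodes <- xml2::xml_find_all(model, "./listOfReactions/reaction")
  reactions <- list()
  for (n in rx_nodes) {
    id <- xml2::xml_attr(n, "id")
    if (!inherits(xml2::xml_find_first(
      n, "./kineticLaw/listOfParameters|./kineticLaw/listOfLocalParameters"),
      "xml_missing")) {
      stop("unsupported feature: local kineticLaw parameters in reaction ", id)
    }
    refs <- function(xp) {
      nodes <- xml2::xml_find_all(n, xp)
      st <- vapply(nodes, function(x) {
        v <- xml2::xml_attr(x, "stoichiometry")
        if (is.na(v)) 1 else as.numeric(v)
      }, numeric(1))
      stats::setNames(as.integer(st),
                      vapply(nodes, xml2::xml_attr, character(1), "species"))
    }
    math <- xml2::xml_find_first(n, "./kineticLaw/math")
    if (inherits(math, "xml_missing")) {
      stop("unsupported feature: reaction ", id, " has no kineticLaw")
    }
    reactions[[length(reactions) + 1]] <-
      rxn(id, refs("./listOfReactants/speciesReference"),
          refs("./listOfProducts/speciesReference"),
          .mathml_to_expr(math))
  }
  reaction_network(species, params, reactions)
}
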