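# Exact symbolic kernel: multivariate polynomials with rational coefficients
# and rational functions (ratios of polynomials) built on top of them.
#
# All symbolic derivations in the package (null spaces aside, which use the
# rational matrix routines in ratmat.R) run through this kernel: fraction
# parameters are solved from linear systems whose coefficients are rational
# functions, reduced right-hand sides are assembled by exact arithmetic, and
# algebraic equivalence is decided by "difference reduces to the zero
# polynomial" after cross-multiplication -- never by string comparison and
# never by floating-point simplification.
#
# Coefficients are rationals stored as numerator/denominator pairs of doubles;
# exact as long as intermediates stay below 2^53, which the moderate-size
# models this package targets do not approach.

## ---- rational coefficient helpers -------------------------------------

.gcd_pair <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b > 0)) {
    t <- b
    b <- ifelse(b > 0, a %% b, 0)
    a <- t
  }
  ifelse(a == 0, 1, a)
}

# normalize rational vectors: den > 0, gcd(|num|, den) == 1
.rat_norm <- function(num, den) {
  stopifnot(all(den != 0))
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- .gcd_pair(num, den)
  list(num = num / g, den = den / g)
}

.rat_add <- function(n1, d1, n2, d2) .rat_norm(n1 * d2 + n2 * d1, d1 * d2)
.rat_mul <- function(n1, d1, n2, d2) .rat_norm(n1 * n2, d1 * d2)

# decimal -> exact rational via continued fractions
.as_rat <- function(x) {
  if (!is.finite(x)) stop("non-finite numeric in symbolic expression")
  if (x == round(x)) return(list(num = x, den = 1))
  num <- c(1, 0); den <- c(0, 1); r <- x
  for (i in 1:50) {
    a <- floor(r)
    num <- c(a * num[1] + num[2], num[1])
    den <- c(a * den[1] + den[2], den[1])
    if (abs(num[1] / den[1] - x) <= 1e-14 * abs(x)) {
      return(.rat_norm(num[1], den[1]))
    }
    if (den[1] > 1e12) break
    r <- 1 / (r - a)
    if (!is.finite(r)) break
  }
  stop("numeric constant ", x, " is not representable as an exact rational")
}

## ---- multivariate polynomials ------------------------------------------

# p$vars: character; p$expo: integer matrix (terms x vars); p$num/p$den:
# rational coefficients. Zero polynomial has 0 rows.
.mvp <- function(vars, expo, num, den) {
  structure(list(vars = vars, expo = expo, num = num, den = den),
            class = "mvp")
}

mvp_zero <- function() .mvp(character(0), matrix(0L, 0, 0), numeric(0), numeric(0))

mvp_const <- function(num, den = 1) {
  if (num == 0) return(mvp_zero())
  r <- .rat_norm(num, den)
  .mvp(character(0), matrix(0L, 1, 0), r$num, r$den)
}

mvp_var <- function(name) {
  .mvp(name, matrix(1L, 1, 1), 1, 1)
}

.mvp_canon <- function(p, keep_vars = FALSE) {
  if (nrow(p$expo) == 0L) {
    if (keep_vars) return(.mvp(p$vars, matrix(0L, 0, length(p$vars)),
                               numeric(0), numeric(0)))
    return(mvp_zero())
  }
  # drop unused variables
  if (ncol(p$expo) > 0L && !keep_vars) {
    used <- colSums(p$expo != 0L) > 0L
    p$vars <- p$vars[used]
    p$expo <- p$expo[, used, drop = FALSE]
  }
  # merge duplicate monomials
  key <- if (ncol(p$expo)) apply(p$expo, 1, paste, collapse = ",") else
    rep("", nrow(p$expo))
  if (anyDuplicated(key)) {
    idx <- split(seq_along(key), key)
    rows <- vapply(idx, `[`, integer(1), 1L)
    num <- den <- numeric(length(idx))
    for (i in seq_along(idx)) {
      n <- 0; d <- 1
      for (j in idx[[i]]) {
        r <- .rat_add(n, d, p$num[j], p$den[j])
        n <- r$num; d <- r$den
      }
      num[i] <- n; den[i] <- d
    }
    p$expo <- p$expo[rows, , drop = FALSE]
    p$num <- num; p$den <- den
  }
  keep <- p$num != 0
  p$expo <- p$expo[keep, , drop = FALSE]
  p$num <- p$num[keep]; p$den <- p$den[keep]
  if (nrow(p$expo) == 0L) {
    if (keep_vars) return(.mvp(p$vars, matrix(0L, 0, length(p$vars)),
                               numeric(0), numeric(0)))
    return(mvp_zero())
  }
  # canonical variable and term order
  ov <- order(p$vars)
  p$vars <- p$vars[ov]
  p$expo <- p$expo[, ov, drop = FALSE]
  ot <- do.call(order, c(lapply(seq_len(ncol(p$expo)), function(j) -p$expo[, j]),
                         list(method = "radix")))
  if (length(ot)) {
    p$expo <- p$expo[ot, , drop = FALSE]
    p$num <- p$num[ot]; p$den <- p$den[ot]
  }
  p
}

.mvp_align <- function(p, q) {
  if (identical(p$vars, q$vars)) return(list(p, q))
  vars <- sort(union(p$vars, q$vars))
  expand <- function(x) {
    e <- matrix(0L, nrow(x$expo), length(vars), dimnames = NULL)
    if (length(x$vars)) e[, match(x$vars, vars)] <- x$expo
    .mvp(vars, e, x$num, x$den)
  }
  list(expand(p), expand(q))
}

mvp_is_zero <- function(p) nrow(p$expo) == 0L

mvp_add <- function(p, q) {
  a <- .mvp_align(p, q)
  .mvp_canon(.mvp(a[[1]]$vars, rbind(a[[1]]$expo, a[[2]]$expo),
                  c(a[[1]]$num, a[[2]]$num), c(a[[1]]$den, a[[2]]$den)))
}

mvp_neg <- function(p) { p$num <- -p$num; p }
mvp_sub <- function(p, q) mvp_add(p, mvp_neg(q))

mvp_mul <- function(p, q) {
  if (mvp_is_zero(p) || mvp_is_zero(q)) return(mvp_zero())
  a <- .mvp_align(p, q)
  p <- a[[1]]; q <- a[[2]]
  np <- nrow(p$expo); nq <- nrow(q$expo)
  i <- rep(seq_len(np), times = nq); j <- rep(seq_len(nq), each = np)
  expo <- p$expo[i, , drop = FALSE] + q$expo[j, , drop = FALSE]
  r <- .rat_mul(p$num[i], p$den[i], q$num[j], q$den[j])
  .mvp_canon(.mvp(p$vars, expo, r$num, r$den))
}

mvp_pow <- function(p, k) {
  stopifnot(k == round(k), k >= 0)
  out <- mvp_const(1)
  base <- p
  while (k > 0) {
    if (k %% 2 == 1) out <- mvp_mul(out, base)
    k <- k %/% 2
    if (k > 0) base <- mvp_mul(base, base)
  }
  out
}

mvp_equal <- function(p, q) mvp_is_zero(mvp_sub(p, q))

# total degree restricted to a set of variables (all by default)
mvp_deg <- function(p, vars = NULL) {
  if (mvp_is_zero(p)) return(-Inf)
  cols <- if (is.null(vars)) seq_along(p$vars) else which(p$vars %in% vars)
  if (!length(cols)) return(0L)
  max(rowSums(p$expo[, cols, drop = FALSE]))
}

mvp_vars <- function(p) p$vars

mvp_deriv <- function(p, var) {
  j <- match(var, p$vars)
  if (is.na(j)) return(mvp_zero())
  keep <- p$expo[, j] > 0L
  expo <- p$expo[keep, , drop = FALSE]
  num <- p$num[keep] * expo[, j]
  den <- p$den[keep]
  expo[, j] <- expo[, j] - 1L
  .mvp_canon(.mvp(p$vars, expo, num, den))
}

mvp_eval <- function(p, env) {
  if (mvp_is_zero(p)) return(0)
  vals <- unlist(env[p$vars])
  if (length(vals) != length(p$vars) || anyNA(vals)) {
    stop("missing value for symbol(s): ",
         paste(setdiff(p$vars, names(env)), collapse = ", "))
  }
  sum((p$num / p$den) *
        apply(p$expo, 1, function(e) prod(vals^e)))
}

# leading term under the canonical (graded-ish lex) term order
.mvp_lead <- function(p) list(expo = p$expo[1, ], num = p$num[1], den = p$den[1])

# exact multivariate division: returns quotient mvp or NULL if not divisible
mvp_divexact <- function(a, b) {
  if (mvp_is_zero(b)) stop("division by zero polynomial")
  if (mvp_is_zero(a)) return(mvp_zero())
  al <- .mvp_align(a, b); a <- al[[1]]; b <- al[[2]]
  lb_expo <- b$expo[1, ]; lb_num <- b$num[1]; lb_den <- b$den[1]
  q_expo <- list(); q_num <- numeric(0); q_den <- numeric(0)
  guard <- 0L
  while (!mvp_is_zero(a)) {
    guard <- guard + 1L
    if (guard > 20000L) return(NULL)
    d <- a$expo[1, ] - lb_expo
    if (any(d < 0)) return(NULL)
    r <- .rat_norm(a$num[1] * lb_den, a$den[1] * lb_num)
    q_expo[[length(q_expo) + 1]] <- d
    q_num <- c(q_num, r$num); q_den <- c(q_den, r$den)
    # subtract (monomial * b) from a without re-aligning
    shift_expo <- b$expo + matrix(d, nrow(b$expo), length(d), byrow = TRUE)
    cr <- .rat_mul(b$num, b$den, -r$num, r$den)
    a <- .mvp_canon(.mvp(a$vars, rbind(a$expo, shift_expo),
                         c(a$num, cr$num), c(a$den, cr$den)),
                    keep_vars = TRUE)
  }
  .mvp_canon(.mvp(b$vars, do.call(rbind, q_expo), q_num, q_den))
}

# scale so coefficients are coprime integers with positive leading coefficient
mvp_primitive <- function(p) {
  if (mvp_is_zero(p)) return(list(p = p, scale_num = 1, scale_den = 1))
  l <- Reduce(function(a, b) a * b / .gcd_pair(a, b), p$den, accumulate = FALSE)
  num <- p$num * (l / p$den)
  g <- Reduce(.gcd_pair, abs(num))
  s <- if (num[1] < 0) -1 else 1
  list(p = .mvp(p$vars, p$expo, num / g * s, rep(1, length(num))),
       scale_num = l * s, scale_den = g)
}

format_mvp <- function(p) {
  if (mvp_is_zero(p)) return("0")
  terms <- vapply(seq_len(nrow(p$expo)), function(i) {
    co <- p$num[i] / p$den[i]
    mono <- p$vars[p$expo[i, ] > 0]
    pow <- p$expo[i, p$expo[i, ] > 0]
    ms <- paste(ifelse(pow > 1, paste0(mono, "^", pow), mono), collapse = "*")
    if (ms == "") return(format(co, digits = 15))
    if (co == 1) ms else if (co == -1) paste0("-", ms) else
      paste0(format(co, digits = 15), "*", ms)
  }, character(1))
  out <- terms[1]
  for (t in terms[-1]) {
    out <- if (startsWith(t, "-")) paste0(out, " - ", substring(t, 2)) else
      paste0(out, " + ", t)
  }
  out
}

## ---- rational functions --------------------------------------------------

rf_new <- function(num, den = mvp_const(1)) {
  if (mvp_is_zero(den)) stop("zero denominator in rational function")
  if (mvp_is_zero(num)) return(structure(list(num = mvp_zero(),
                                              den = mvp_const(1)), class = "rf"))
  # cancel common monomial content
  if (length(den$vars) && length(num$vars)) {
    vars <- intersect(num$vars, den$vars)
    for (v in vars) {
      en <- min(num$expo[, match(v, num$vars)])
      ed <- min(den$expo[, match(v, den$vars)])
      k <- min(en, ed)
      if (k > 0) {
        num$expo[, match(v, num$vars)] <- num$expo[, match(v, num$vars)] - k
        den$expo[, match(v, den$vars)] <- den$expo[, match(v, den$vars)] - k
      }
    }
    num <- .mvp_canon(num); den <- .mvp_canon(den)
  }
  # exact cancellation of the full denominator
  q <- mvp_divexact(num, den)
  if (!is.null(q)) { num <- q; den <- mvp_const(1) }
  # normalize scale: primitive integer denominator, positive leading coeff
  pd <- mvp_primitive(den)
  num <- mvp_mul(num, mvp_const(pd$scale_num, pd$scale_den))
  structure(list(num = num, den = pd$p), class = "rf")
}

rf_zero <- function() rf_new(mvp_zero())
rf_const <- function(num, den = 1) rf_new(mvp_const(num, den))
rf_var <- function(name) rf_new(mvp_var(name))

rf_is_zero <- function(x) mvp_is_zero(x$num)
rf_is_const <- function(x) length(x$num$vars) == 0 && length(x$den$vars) == 0

rf_add <- function(x, y) {
  if (rf_is_zero(x)) return(y)
  if (rf_is_zero(y)) return(x)
  if (mvp_equal(x$den, y$den)) return(rf_new(mvp_add(x$num, y$num), x$den))
  q <- mvp_divexact(x$den, y$den)
  if (!is.null(q)) return(rf_new(mvp_add(x$num, mvp_mul(y$num, q)), x$den))
  q <- mvp_divexact(y$den, x$den)
  if (!is.null(q)) return(rf_new(mvp_add(mvp_mul(x$num, q), y$num), y$den))
  rf_new(mvp_add(mvp_mul(x$num, y$den), mvp_mul(y$num, x$den)),
         mvp_mul(x$den, y$den))
}
rf_neg <- function(x) { x$num <- mvp_neg(x$num); x }
rf_sub <- function(x, y) rf_add(x, rf_neg(y))
rf_mul <- function(x, y) {
  if (rf_is_zero(x) || rf_is_zero(y)) return(rf_zero())
  # cross-cancel before multiplying to keep intermediates small
  q <- mvp_divexact(x$num, y$den)
  if (!is.null(q)) { x$num <- q; y$den <- mvp_const(1) }
  q <- mvp_divexact(y$num, x$den)
  if (!is.null(q)) { y$num <- q; x$den <- mvp_const(1) }
  rf_new(mvp_mul(x$num, y$num), mvp_mul(x$den, y$den))
}
rf_div <- function(x, y) {
  if (rf_is_zero(y)) stop("division by zero rational function")
  if (rf_is_zero(x)) return(rf_zero())
  # x/y = (x$num * y$den) / (x$den * y$num); cancel shared denominators first
  if (mvp_equal(x$den, y$den)) return(rf_new(x$num, y$num))
  q <- mvp_divexact(y$den, x$den)
  if (!is.null(q)) return(rf_new(mvp_mul(x$num, q), y$num))
  q <- mvp_divexact(x$den, y$den)
  if (!is.null(q)) return(rf_new(x$num, mvp_mul(y$num, q)))
  rf_new(mvp_mul(x$num, y$den), mvp_mul(x$den, y$num))
}
rf_pow <- function(x, k) {
  stopifnot(k == round(k))
  if (k < 0) return(rf_div(rf_const(1), rf_pow(x, -k)))
  rf_new(mvp_pow(x$num, k), mvp_pow(x$den, k))
}

rf_equal <- function(x, y) rf_is_zero(rf_sub(x, y))

rf_deriv <- function(x, var) {
  dn <- mvp_deriv(x$num, var)
  dd <- mvp_deriv(x$den, var)
  num <- mvp_sub(mvp_mul(dn, x$den), mvp_mul(x$num, dd))
  q <- mvp_divexact(num, x$den)
  if (!is.null(q)) rf_new(q, x$den) else rf_new(num, mvp_mul(x$den, x$den))
}

rf_eval <- function(x, env) mvp_eval(x$num, env) / mvp_eval(x$den, env)

rf_vars <- function(x) union(x$num$vars, x$den$vars)

# substitute named rf values for variables (composition)
mvp_subs <- function(p, subs) {
  if (mvp_is_zero(p)) return(rf_zero())
  out <- rf_zero()
  for (i in seq_len(nrow(p$expo))) {
    term <- rf_const(p$num[i], p$den[i])
    for (j in seq_along(p$vars)) {
      e <- p$expo[i, j]
      if (e == 0) next
      v <- p$vars[j]
      base <- if (v %in% names(subs)) subs[[v]] else rf_var(v)
      term <- rf_mul(term, rf_pow(base, e))
    }
    out <- rf_add(out, term)
  }
  out
}

rf_subs <- function(x, subs) {
  if (!length(intersect(rf_vars(x), names(subs)))) return(x)
  rf_div(mvp_subs(x$num, subs), mvp_subs(x$den, subs))
}

format_rf <- function(x) {
  if (mvp_is_zero(x$num)) return("0")
  if (mvp_equal(x$den, mvp_const(1))) return(format_mvp(x$num))
  paste0("(", format_mvp(x$num), ") / (", format_mvp(x$den), ")")
}

#' @export
print.rf <- function(x, ...) {
  cat(format_rf(x), "\n")
  invisible(x)
}

## ---- bridge to R expressions --------------------------------------------

#' Convert an R expression to the kernel's rational-function form
#'
#' Supports `+`, `-`, `*`, `/`, integer `^`, parentheses, numeric constants
#' (converted to exact rationals) and symbols. Anything else (e.g. `sqrt`)
#' is rejected: the exact kernel only covers rational expressions.
#'
#' @param e a call, symbol, or numeric scalar (e.g. from [str2lang()]).
#' @return an object of internal class `rf`.
#' @keywords internal
expr_to_rf <- function(e) {
  if (is.numeric(e)) {
    r <- .as_rat(e)
    return(rf_const(r$num, r$den))
  }
  if (is.symbol(e)) return(rf_var(as.character(e)))
  if (is.call(e)) {
    op <- as.character(e[[1]])
    args <- as.list(e)[-1]
    if (op == "(") return(expr_to_rf(args[[1]]))
    if (op == "+" && length(args) == 1) return(expr_to_rf(args[[1]]))
    if (op == "-" && length(args) == 1) return(rf_neg(expr_to_rf(args[[1]])))
    if (length(args) == 2) {
      if (op == "^") {
        k <- args[[2]]
        if (!is.numeric(k) || k != round(k)) {
          stop("only integer powers are supported in symbolic expressions")
        }
        return(rf_pow(expr_to_rf(args[[1]]), k))
      }
      a <- expr_to_rf(args[[1]]); b <- expr_to_rf(args[[2]])
      return(switch(op,
                    "+" = rf_add(a, b), "-" = rf_sub(a, b),
                    "*" = rf_mul(a, b), "/" = rf_div(a, b),
                    stop("unsupported operator in symbolic expression: ", op)))
    }
  }
  stop("unsupported construct in symbolic expression: ", deparse(e))
}

.mvp_to_expr <- function(p) {
  if (mvp_is_zero(p)) return(0)
  terms <- lapply(seq_len(nrow(p$expo)), function(i) {
    co <- p$num[i] / p$den[i]
    parts <- list()
    for (j in seq_along(p$vars)) {
      e <- p$expo[i, j]
      if (e == 0) next
      parts <- c(parts, list(if (e == 1) as.name(p$vars[j]) else
        call("^", as.name(p$vars[j]), e)))
    }
    mono <- if (!length(parts)) NULL else Reduce(function(a, b) call("*", a, b), parts)
    if (is.null(mono)) co
    else if (co == 1) mono
    else if (co == -1) call("-", mono)
    else call("*", co, mono)
  })
  # balanced fold keeps the call tree shallow for very long sums
  while (length(terms) > 1) {
    nxt <- vector("list", ceiling(length(terms) / 2))
    for (i in seq_along(nxt)) {
      a <- terms[[2 * i - 1]]
      nxt[[i]] <- if (2 * i <= length(terms)) call("+", a, terms[[2 * i]]) else a
    }
    terms <- nxt
  }
  terms[[1]]
}

#' Convert a kernel rational function back to an R expression
#' @param x an `rf` object.
#' @return a call or numeric scalar.
#' @keywords internal
rf_to_expr <- function(x) {
  num <- .mvp_to_expr(x$num)
  if (mvp_equal(x$den, mvp_const(1))) return(num)
  call("/", num, .mvp_to_expr(x$den))
}

#' Test two expressions for exact algebraic equivalence
#'
#' Decides whether two rational expressions are identical as functions by
#' forming their difference, cross-multiplying, and checking that the
#' resulting polynomial is identically zero. This is an exact decision for
#' rational expressions: no numeric sampling is involved.
#'
#' @param e1,e2 R expressions (calls/symbols, or strings parsed with
#'   [str2lang()]) built from `+`, `-`, `*`, `/`, integer `^`, numbers and
#'   symbols.
#' @return `TRUE` if equivalent, `FALSE` otherwise.
#' @examples
#' sym_equiv("(a + b)^2", "a^2 + 2*a*b + b^2")
#' sym_equiv("k1/(k1 + k2)", "1/(1 + k2/k1)")
#' @export
sym_equiv <- function(e1, e2) {
  if (is.character(e1)) e1 <- str2lang(e1)
  if (is.character(e2)) e2 <- str2lang(e2)
  rf_equal(expr_to_rf(e1), expr_to_rf(e2))
}

## ---- linear algebra over rational functions ------------------------------

# A: list of rows, each a list of rf; b: list of rf.
# Gaussian elimination with symbolic pivoting; returns list of rf or NULL if
# the system is singular.
rf_solve <- function(A, b) {
  n <- length(A)
  stopifnot(all(lengths(A) == n), length(b) == n)
  A <- lapply(A, function(r) r) # copy
  x <- vector("list", n)
  perm <- seq_len(n)
  for (k in seq_len(n)) {
    piv <- NULL
    for (i in k:n) if (!rf_is_zero(A[[i]][[k]])) { piv <- i; break }
    if (is.null(piv)) return(NULL)
    if (piv != k) {
      tmp <- A[[k]]; A[[k]] <- A[[piv]]; A[[piv]] <- tmp
      tmp <- b[[k]]; b[[k]] <- b[[piv]]; b[[piv]] <- tmp
    }
    for (i in setdiff(seq_len(n), k)) {
      if (rf_is_zero(A[[i]][[k]])) next
      f <- rf_div(A[[i]][[k]], A[[k]][[k]])
      for (j in k:n) A[[i]][[j]] <- rf_sub(A[[i]][[j]], rf_mul(f, A[[k]][[j]]))
      b[[i]] <- rf_sub(b[[i]], rf_mul(f, b[[k]]))
    }
  }
  for (k in seq_len(n)) x[[k]] <- rf_div(b[[k]], A[[k]][[k]])
  x
}

# symbolic rank of a list-of-rows matrix of rf
rf_rank <- function(A) {
  if (!length(A)) return(0L)
  m <- length(A); n <- length(A[[1]])
  A <- lapply(A, function(r) r)
  rank <- 0L
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- NULL
    for (i in row:m) if (!rf_is_zero(A[[i]][[col]])) { piv <- i; break }
    if (is.null(piv)) next
    tmp <- A[[row]]; A[[row]] <- A[[piv]]; A[[piv]] <- tmp
    for (i in seq_len(m)) {
      if (i == row || rf_is_zero(A[[i]][[col]])) next
      f <- rf_div(A[[i]][[col]], A[[row]][[col]])
      for (j in col:n) A[[i]][[j]] <- rf_sub(A[[i]][[j]], rf_mul(f, A[[row]][[j]]))
    }
    rank <- rank + 1L
    row <- row + 1L
  }
  rank
}

rf_det <- function(A) {
  n <- length(A)
  A <- lapply(A, function(r) r)
  det <- rf_const(1)
  for (k in seq_len(n)) {
    piv <- NULL
    for (i in k:n) if (!rf_is_zero(A[[i]][[k]])) { piv <- i; break }
    if (is.null(piv)) return(rf_const(0))
    if (piv != k) {
      tmp <- A[[k]]; A[[k]] <- A[[piv]]; A[[piv]] <- tmp
      det <- rf_neg(det)
    }
    det <- rf_mul(det, A[[k]][[k]])
    for (i in seq_len(n)) {
      if (i <= k || rf_is_zero(A[[i]][[k]])) next
      f <- rf_div(A[[i]][[k]], A[[k]][[k]])
      for (j in k:n) A[[i]][[j]] <- rf_sub(A[[i]][[j]], rf_mul(f, A[[k]][[j]]))
    }
  }
  det
}

# split a polynomial that is jointly linear in `unknowns` into coefficient
# polynomials and the constant part: p = sum_j coef[[j]] * unknowns[j] + const.
# Returns NULL if p is not jointly linear in the unknowns.
mvp_split_linear <- function(p, unknowns) {
  if (mvp_is_zero(p)) {
    return(list(coef = stats::setNames(replicate(length(unknowns), mvp_zero(),
                                                 simplify = FALSE), unknowns),
                const = mvp_zero()))
  }
  cols <- match(unknowns, p$vars)
  udeg <- rowSums(p$expo[, cols[!is.na(cols)], drop = FALSE])
  if (any(udeg > 1)) return(NULL)
  coef <- stats::setNames(vector("list", length(unknowns)), unknowns)
  for (j in seq_along(unknowns)) {
    cj <- cols[j]
    if (is.na(cj)) { coef[[j]] <- mvp_zero(); next }
    sel <- p$expo[, cj] == 1L
    if (!any(sel)) { coef[[j]] <- mvp_zero(); next }
    e <- p$expo[sel, , drop = FALSE]
    e[, cj] <- 0L
    coef[[j]] <- .mvp_canon(.mvp(p$vars, e, p$num[sel], p$den[sel]))
  }
  sel0 <- udeg == 0
  const <- if (any(sel0)) {
    .mvp_canon(.mvp(p$vars, p$expo[sel0, , drop = FALSE], p$num[sel0], p$den[sel0]))
  } else mvp_zero()
  list(coef = coef, const = const)
}

# cofactor-expansion determinant over rational functions: division-free, so
# shared denominators combine instead of piling up (used for the small
# blocks the reduction inverts symbolically)
rf_det_cof <- function(A) {
  n <- length(A)
  if (n == 1) return(A[[1]][[1]])
  acc <- rf_zero()
  for (j in seq_len(n)) {
    a <- A[[1]][[j]]
    if (rf_is_zero(a)) next
    minor <- lapply(A[-1], function(row) row[-j])
    term <- rf_mul(a, rf_det_cof(minor))
    if (j %% 2 == 0) term <- rf_neg(term)
    acc <- rf_add(acc, term)
  }
  acc
}

# solve A x = b over rational functions by Cramer's rule with cofactor
# determinants: each solution component is a single ratio of determinants
rf_linsolve <- function(A, b) {
  detA <- rf_det_cof(A)
  if (rf_is_zero(detA)) return(NULL)
  lapply(seq_along(A), function(j) {
    Aj <- lapply(seq_along(A), function(i) {
      r <- A[[i]]; r[[j]] <- b[[i]]; r
    })
    rf_div(rf_det_cof(Aj), detA)
  })
}
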