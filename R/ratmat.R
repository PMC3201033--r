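# Exact linear algebra over the rationals for integer matrices
# (stoichiometric matrices and conservation bases). Floating-point rank is
# never used for these structural computations: matrices are carried as
# numerator/denominator pairs and reduced by exact Gauss-Jordan elimination.

.ratmat <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  list(num = num, den = den)
}

# exact reduced row echelon form; returns rref matrix, pivot columns, rank
rat_rref <- function(M) {
  num <- M$num; den <- M$den
  m <- nrow(num); n <- ncol(num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    piv <- which(num[row:m, col] != 0)
    if (!length(piv)) next
    piv <- piv[1] + row - 1L
    if (piv != row) {
      num[c(row, piv), ] <- num[c(piv, row), ]
      den[c(row, piv), ] <- den[c(piv, row), ]
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- .rat_norm(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    for (i in seq_len(m)) {
      if (i == row || num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      # row_i <- row_i - f * row_row
      sn <- fn * num[row, ]; sd <- fd * den[row, ]
      rn <- num[i, ] * sd - sn * den[i, ]
      rd <- den[i, ] * sd
      r <- .rat_norm(rn, rd)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = pivots, rank = length(pivots))
}

# exact rank of an integer/rational matrix
rat_rank <- function(M) {
  if (is.matrix(M)) M <- .ratmat(M)
  rat_rref(M)$rank
}

# exact (right) null space of an integer matrix, returned as a matrix whose
# rows are basis vectors scaled to coprime integers
rat_nullspace <- function(A) {
  n <- ncol(A)
  rr <- rat_rref(.ratmat(A))
  free <- setdiff(seq_len(n), rr$pivots)
  if (!length(free)) {
    return(matrix(0, 0, n, dimnames = list(NULL, colnames(A))))
  }
  basis <- matrix(0, length(free), n)
  for (k in seq_along(free)) {
    fc <- free[k]
    # x[fc] = 1, pivot variables from rref rows
    xn <- numeric(n); xd <- rep(1, n)
    xn[fc] <- 1
    for (i in seq_along(rr$pivots)) {
      pc <- rr$pivots[i]
      xn[pc] <- -rr$num[i, fc]
      xd[pc] <- rr$den[i, fc]
    }
    # scale to coprime integers
    l <- Reduce(function(a, b) a * b / .gcd_pair(a, b), xd)
    v <- xn * (l / xd)
    g <- Reduce(.gcd_pair, abs(v[v != 0]))
    basis[k, ] <- v / g
  }
  colnames(basis) <- colnames(A)
  basis
}

# left null space of A: rows m with m %*% A == 0, coprime integer rows
rat_left_nullspace <- function(A) {
  B <- rat_nullspace(t(A))
  colnames(B) <- rownames(A)
  B
}

# Try to make all basis rows nonnegative by adding integer multiples of other
# rows (the models targeted here always admit a nonnegative basis, but no
# general algorithm is attempted: if the greedy repair fails a signed basis is
# returned with a warning).
nonnegative_basis <- function(B, max_mult = 6L, quiet = FALSE) {
  if (!nrow(B)) return(B)
  for (pass in 1:4) {
    for (i in seq_len(nrow(B))) {
      if (all(B[i, ] >= 0)) next
      if (all(B[i, ] <= 0)) { B[i, ] <- -B[i, ]; next }
      improved <- TRUE
      while (improved && any(B[i, ] < 0)) {
        improved <- FALSE
        negcount <- sum(B[i, ] < 0)
        for (j in seq_len(nrow(B))) {
          if (j == i) next
          for (c_ in seq_len(max_mult)) {
            for (s in c(1, -1)) {
              cand <- B[i, ] + s * c_ * B[j, ]
              if (sum(cand < 0) < negcount && any(cand != 0)) {
                B[i, ] <- cand
                g <- Reduce(.gcd_pair, abs(cand[cand != 0]))
                B[i, ] <- B[i, ] / g
                improved <- TRUE
                negcount <- sum(B[i, ] < 0)
              }
            }
          }
        }
      }
    }
    if (all(B >= 0)) break
  }
  if (any(B < 0) && !quiet) {
    warning("no nonnegative conservation basis found; returning a signed integer basis")
  }
  B
}
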