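# Dense two-phase primal simplex for the small linear programs that flux
# balance analysis and gap-filling produce (tens of reactions/metabolites).
# Bland's rule is used throughout, which guarantees termination on the
# degenerate steady-state systems typical of metabolic networks.

# Maximize cost'z subject to A z = b (b >= 0), z >= 0, starting from a basis
# whose columns already form an identity in A. Returns list(status, z, basis,
# A, b) with the tableau in reduced form.
simplex_run <- function(A, b, cost, basis, tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A)
  for (it in seq_len(max_iter)) {
    # reduced costs r_j = cost_j - cost_B' B^-1 A_j (A is already reduced)
    cb <- cost[basis]
    r <- cost - as.vector(crossprod(A, cb))
    r[basis] <- 0
    enter <- which(r > tol)
    if (length(enter) == 0L) {
      return(list(status = "optimal", A = A, b = b, basis = basis))
    }
    j <- enter[1L]                       # Bland: smallest eligible index
    col <- A[, j]
    pos <- which(col > tol)
    if (length(pos) == 0L) {
      return(list(status = "unbounded", A = A, b = b, basis = basis))
    }
    ratios <- b[pos] / col[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + tol]
    leave <- cand[which.min(basis[cand])] # Bland on leaving variable
    piv <- A[leave, j]
    A[leave, ] <- A[leave, ] / piv
    b[leave] <- b[leave] / piv
    other <- setdiff(seq_len(m), leave)
    fac <- A[other, j]
    A[other, ] <- A[other, , drop = FALSE] - outer(fac, A[leave, ])
    b[other] <- b[other] - fac * b[leave]
    b[b < 0 & b > -tol] <- 0
    basis[leave] <- j
  }
  list(status = "maxiter", A = A, b = b, basis = basis)
}

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) `obj' v` subject to `Aeq v = beq` and
#' `lb <= v <= ub`, with finite bounds, via a dense two-phase primal simplex.
#' Sized for the desk-scale programs of flux balance analysis; not a
#' general-purpose large-scale solver.
#'
#' @param obj Numeric objective coefficients (length n).
#' @param Aeq Numeric equality-constraint matrix (m x n).
#' @param beq Numeric right-hand side (length m).
#' @param lb,ub Finite variable bounds (length n).
#' @param maximize Maximize (default) or minimize.
#' @param tol Numerical tolerance.
#' @return List with `status` ("optimal", "infeasible", or "unbounded"),
#'   `value` (objective at optimum), and `x` (solution vector).
#' @export
lp_solve <- function(obj, Aeq, beq, lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  Aeq <- matrix(as.numeric(Aeq), nrow = length(beq), ncol = n)
  stopifnot(length(lb) == n, length(ub) == n, all(is.finite(lb)), all(is.finite(ub)))
  if (any(ub - lb < -tol)) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n)))
  }
  u <- pmax(ub - lb, 0)
  cc <- if (maximize) obj else -obj
  m <- length(beq)

  b0 <- beq - as.vector(Aeq %*% lb)
  flip <- b0 < 0
  Aeq[flip, ] <- -Aeq[flip, , drop = FALSE]
  b0[flip] <- -b0[flip]

  # columns: x (n) | bound slacks s (n) | artificials a (m)
  A <- rbind(
    cbind(Aeq, matrix(0, m, n), diag(m)),
    cbind(diag(n), diag(n), matrix(0, n, m))
  )
  b <- c(b0, u)
  basis <- c(2L * n + seq_len(m), n + seq_len(n))

  # phase 1: drive artificials to zero
  cost1 <- c(rep(0, 2L * n), rep(-1, m))
  ph1 <- simplex_run(A, b, cost1, basis, tol = tol)
  if (ph1$status != "optimal" || sum(ph1$b[ph1$basis > 2L * n]) > 1e-7) {
    return(list(status = "infeasible", value = NA_real_, x = rep(NA_real_, n)))
  }
  A <- ph1$A; b <- ph1$b; basis <- ph1$basis

  # pivot out any degenerate basic artificial; drop redundant rows
  art_rows <- which(basis > 2L * n)
  drop_rows <- integer(0)
  for (i in art_rows) {
    piv_col <- which(abs(A[i, seq_len(2L * n)]) > tol)[1L]
    if (is.na(piv_col)) {
      drop_rows <- c(drop_rows, i)
      next
    }
    piv <- A[i, piv_col]
    A[i, ] <- A[i, ] / piv
    b[i] <- b[i] / piv
    other <- setdiff(seq_len(nrow(A)), i)
    fac <- A[other, piv_col]
    A[other, ] <- A[other, , drop = FALSE] - outer(fac, A[i, ])
    b[other] <- b[other] - fac * b[i]
    basis[i] <- piv_col
  }
  if (length(drop_rows)) {
    keep <- setdiff(seq_len(nrow(A)), drop_rows)
    A <- A[keep, , drop = FALSE]
    b <- b[keep]
    basis <- basis[keep]
  }
  A <- A[, seq_len(2L * n), drop = FALSE]

  # phase 2
  cost2 <- c(cc, rep(0, n))
  ph2 <- simplex_run(A, b, cost2, basis, tol = tol)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", value = NA_real_, x = rep(NA_real_, n)))
  }
  z <- numeric(2L * n)
  z[ph2$basis] <- ph2$b
  x <- z[seq_len(n)] + lb
  list(status = "optimal", value = sum(obj * x), x = x)
}
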