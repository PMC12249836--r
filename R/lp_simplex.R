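# Dense bounded-variable two-phase simplex.
#
# Solves   min/max  c'x   s.t.  A x = b,  lb <= x <= ub
# with finite lower bounds and possibly infinite upper bounds. Intended for
# the desk-scale networks this package works with (tens to a few hundred
# variables); the basis system is re-solved densely at every iteration, which
# favours numerical accuracy over speed. Bland's rule is used throughout, so
# the method terminates on degenerate problems.

#' Solve a bounded linear program
#'
#' Minimizes or maximizes `obj %*% x` subject to `A %*% x == b` and
#' `lb <= x <= ub`, using a two-phase primal simplex with bounded variables.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A constraint matrix (m x n); may have zero rows.
#' @param b right-hand side (length m).
#' @param lb,ub variable bounds; `lb` must be finite, `ub` may be `Inf`.
#' @param sense `"max"` or `"min"`.
#' @param tol feasibility/optimality tolerance (default 1e-9).
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x` (primal solution, `NULL` unless optimal) and `objval`.
#' @keywords internal
lp_solve <- function(obj, A, b, lb, ub, sense = c("max", "min"), tol = 1e-9) {
  sense <- match.arg(sense)
  n <- length(obj)
  A <- as.matrix(A)
  if (n == 0L) {
    return(list(status = "optimal", x = numeric(0), objval = 0))
  }
  stopifnot(ncol(A) == n, length(b) == nrow(A), length(lb) == n,
            length(ub) == n)
  if (any(!is.finite(lb))) stop("lp_solve: lower bounds must be finite")
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  cvec <- if (sense == "max") -as.numeric(obj) else as.numeric(obj)

  # shift to y = x - lb >= 0
  u <- ub - lb
  u[u < 0] <- 0
  m <- nrow(A)
  b2 <- as.numeric(b) - as.numeric(A %*% lb)

  if (m == 0L) {
    # pure bound problem
    y <- ifelse(cvec < -tol, u, 0)
    if (any(!is.finite(y))) {
      return(list(status = "unbounded", x = NULL, objval = NA_real_))
    }
    x <- y + lb
    val <- sum(obj * x)
    return(list(status = "optimal", x = x, objval = val))
  }

  # make rhs nonnegative, append artificial columns
  neg <- b2 < 0
  A2 <- A
  A2[neg, ] <- -A2[neg, , drop = FALSE]
  b2[neg] <- -b2[neg]
  Afull <- cbind(A2, diag(m))
  ufull <- c(u, rep(Inf, m))
  ntot <- n + m
  art <- seq.int(n + 1L, ntot)

  basis <- art
  at_upper <- rep(FALSE, ntot)     # status of nonbasic variables

  run_phase <- function(cost, basis, at_upper, allow_enter, phase1) {
    maxit <- 20000L
    for (it in seq_len(maxit)) {
      Bmat <- Afull[, basis, drop = FALSE]
      nonbasic <- setdiff(seq_len(ntot), basis)
      # current basic values
      rhs <- b2
      upn <- nonbasic[at_upper[nonbasic]]
      if (length(upn)) {
        rhs <- rhs - Afull[, upn, drop = FALSE] %*% ufull[upn]
      }
      xB <- tryCatch(solve(Bmat, rhs), error = function(e) NULL)
      if (is.null(xB)) stop("lp_solve: singular basis encountered")
      xB <- as.numeric(xB)
      # reduced costs
      piv <- tryCatch(solve(t(Bmat), cost[basis]), error = function(e) NULL)
      if (is.null(piv)) stop("lp_solve: singular basis encountered")
      d <- cost[nonbasic] - as.numeric(t(Afull[, nonbasic, drop = FALSE]) %*% piv)
      elig <- nonbasic %in% allow_enter &
        ((!at_upper[nonbasic] & d < -tol) | (at_upper[nonbasic] & d > tol))
      if (!any(elig)) {
        return(list(code = "optimal", basis = basis, at_upper = at_upper,
                    xB = xB))
      }
      j <- min(nonbasic[elig])            # Bland: smallest index
      sigma <- if (at_upper[j]) -1 else 1 # direction of movement of x_j
      w <- as.numeric(solve(Bmat, Afull[, j]))
      # ratio test: x_B moves to xB - sigma * w * t as x_j moves by t >= 0
      nb <- length(basis)
      ratio <- rep(Inf, nb)
      to_upper <- rep(FALSE, nb)
      for (i in seq_len(nb)) {
        swi <- sigma * w[i]
        if (swi > tol) {
          ratio[i] <- max(xB[i], 0) / swi
        } else if (swi < -tol && is.finite(ufull[basis[i]])) {
          ratio[i] <- max(ufull[basis[i]] - xB[i], 0) / (-swi)
          to_upper[i] <- TRUE
        }
      }
      tstar <- min(ratio, ufull[j])
      if (!is.finite(tstar)) {
        return(list(code = "unbounded", basis = basis, at_upper = at_upper,
                    xB = xB))
      }
      if (ufull[j] < min(ratio) - tol) {
        # entering variable hits its opposite bound: flip, no basis change
        at_upper[j] <- !at_upper[j]
      } else {
        blocking <- which(ratio <= tstar + tol)
        k <- blocking[which.min(basis[blocking])]  # Bland on leaving variable
        leave <- basis[k]
        basis[k] <- j
        at_upper[j] <- FALSE
        at_upper[leave] <- to_upper[k]
      }
    }
    stop("lp_solve: iteration limit exceeded")
  }

  # ---- phase 1: minimize sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  r1 <- run_phase(c1, basis, at_upper, allow_enter = seq_len(n), phase1 = TRUE)
  if (r1$code != "optimal") stop("lp_solve: phase 1 failed unexpectedly")
  basis <- r1$basis; at_upper <- r1$at_upper
  # phase-1 objective value
  art_val <- sum(r1$xB[basis > n])
  if (art_val > 1e-7 * max(1, max(abs(b2)))) {
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  }
  # pin any residual artificials to zero so phase 2 cannot move them
  ufull[art] <- 0

  # ---- phase 2
  c2 <- c(cvec, rep(0, m))
  r2 <- run_phase(c2, basis, at_upper, allow_enter = seq_len(n), phase1 = FALSE)
  if (r2$code == "unbounded") {
    return(list(status = "unbounded", x = NULL, objval = NA_real_))
  }
  basis <- r2$basis; at_upper <- r2$at_upper

  # assemble solution (one clean dense solve for accuracy)
  y <- numeric(ntot)
  nonbasic <- setdiff(seq_len(ntot), basis)
  y[nonbasic] <- ifelse(at_upper[nonbasic], ufull[nonbasic], 0)
  rhs <- b2 - Afull[, nonbasic, drop = FALSE] %*% y[nonbasic]
  y[basis] <- as.numeric(solve(Afull[, basis, drop = FALSE], rhs))
  y <- y[seq_len(n)]
  y[y < 0 & y > -1e-8] <- 0
  x <- y + lb
  list(status = "optimal", x = x, objval = sum(obj * x))
}

#' Solve an LP with equality and optional inequality rows
#'
#' Convenience wrapper around [lp_solve()] that accepts additional
#' `A_ge %*% x >= b_ge` rows (used for lexicographic tier-retention
#' constraints); these are converted to equalities with surplus variables.
#'
#' @inheritParams lp_solve
#' @param A_ge,b_ge optional inequality block (`>=` rows).
#' @keywords internal
lp_solve_geq <- function(obj, A, b, lb, ub, sense = "max",
                         A_ge = NULL, b_ge = NULL, tol = 1e-9) {
  n <- length(obj)
  if (is.null(A_ge) || nrow(A_ge) == 0L) {
    return(lp_solve(obj, A, b, lb, ub, sense, tol))
  }
  k <- nrow(A_ge)
  Afull <- rbind(cbind(as.matrix(A), matrix(0, nrow(A), k)),
                 cbind(as.matrix(A_ge), -diag(k)))
  res <- lp_solve(c(obj, rep(0, k)), Afull, c(b, b_ge),
                  c(lb, rep(0, k)), c(ub, rep(Inf, k)), sense, tol)
  if (res$status == "optimal") res$x <- res$x[seq_len(n)]
  res
}
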