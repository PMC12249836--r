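# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the LP oracle enumerates basic solutions by
# brute force, and the BH oracle applies the step-up definition directly.

# Brute-force LP oracle: enumerate all basic solutions of
#   optimize c'x  s.t.  A x = b, lb <= x <= ub
# (vertices have n - rank(A) variables at a bound) and return the best
# objective value, or NULL if no feasible vertex exists.
vertex_enum_lp <- function(obj, A, b, lb, ub, sense = "max") {
  n <- length(obj)
  r <- qr(A)$rank
  nfree <- n - r
  if (nfree < 0) return(NULL)
  combs <- if (nfree == 0) list(integer(0)) else
    utils::combn(n, nfree, simplify = FALSE)
  best <- NULL
  for (F in combs) {
    Bv <- setdiff(seq_len(n), F)
    grid <- if (length(F)) {
      expand.grid(rep(list(c(FALSE, TRUE)), length(F)))
    } else {
      data.frame(row.names = 1)
    }
    for (g in seq_len(max(nrow(grid), 1L))) {
      xf <- numeric(length(F))
      if (length(F)) {
        hi <- as.logical(grid[g, ])
        xf <- ifelse(hi, ub[F], lb[F])
        if (any(!is.finite(xf))) next
      }
      AB <- A[, Bv, drop = FALSE]
      if (length(Bv) && qr(AB)$rank < length(Bv)) next
      rhs <- b - if (length(F)) A[, F, drop = FALSE] %*% xf else 0
      xb <- tryCatch(qr.solve(AB, rhs), error = function(e) NULL)
      if (is.null(xb) && length(Bv)) next
      x <- numeric(n); x[F] <- xf
      if (length(Bv)) x[Bv] <- xb
      if (any(x < lb - 1e-7) || any(x > ub + 1e-7)) next
      if (max(abs(A %*% x - b)) > 1e-7) next
      v <- sum(obj * x)
      if (is.null(best) ||
          (sense == "max" && v > best) || (sense == "min" && v < best)) {
        best <- v
      }
    }
  }
  best
}

# random small flux network with bounded variables (all-zero RHS, like FBA)
random_small_network <- function(n_mets = sample(2:4, 1),
                                 n_rxns = sample(3:8, 1)) {
  A <- matrix(sample(c(-2, -1, 0, 0, 1, 2), n_mets * n_rxns, replace = TRUE),
              n_mets, n_rxns)
  lb <- ifelse(stats::runif(n_rxns) < 0.4, -stats::runif(n_rxns, 0, 2), 0)
  ub <- lb + stats::runif(n_rxns, 0.5, 3)
  obj <- round(stats::rnorm(n_rxns), 2)
  list(A = A, b = rep(0, n_mets), lb = lb, ub = ub, obj = obj)
}

# direct step-up definition of Benjamini-Hochberg, no vectorization tricks:
# q_i = min over j with p_(j) >= p_(i) of min(1, m * p_(j) / j)
bh_brute_force <- function(p) {
  m <- length(p)
  if (m == 0L) return(numeric(0))
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(i:m, function(j) min(1, m * ps[j] / j), numeric(1))
    q[i] <- min(cand)
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# tiny two-metabolite chain used by several LP tests:
#   SRC: -> glc (uptake cap), CONV: glc -> 2 atp, SINK: atp ->
toy_chain_model <- function(uptake = 1) {
  mets <- data.frame(id = c("glc_e", "glc_c", "atp_c"),
                     name = c("glucose", "glucose", "ATP"),
                     compartment = c("e", "c", "c"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(
    id = c("EX_glc_e", "GLCt", "CONV", "SINK"),
    name = c("glucose exchange", "uptake", "conversion", "ATP sink"),
    lower_bound = c(-uptake, 0, 0, 0),
    upper_bound = c(0, 1000, 1000, 1000),
    subsystem = c("Transport/Exchange", "Transport/Exchange",
                  "Glycolysis", "ATP maintenance"),
    gpr = c("", "", "PKM", ""),
    stringsAsFactors = FALSE)
  sto <- list(EX_glc_e = c(glc_e = -1),
              GLCt = c(glc_e = -1, glc_c = 1),
              CONV = c(glc_c = -1, atp_c = 2),
              SINK = c(atp_c = -1))
  metabolic_model(mets, rxns, sto)
}

solve_atpm <- function(model, rid = "ATPM") {
  solve_fba(model, objective_tier(stats::setNames(1, rid), "max"))
}
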