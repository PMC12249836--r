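# Flux balance analysis engine: plain FBA, lexicographic multi-objective
# optimization, parsimonious FBA and flux variability analysis, all on top of
# the bounded-variable simplex in lp_simplex.R.

#' Define an objective tier
#'
#' One tier of a (possibly multi-tier) objective: a sparse linear objective
#' over reaction fluxes and an optimization sense.
#'
#' @param coefficients named numeric vector, reaction id -> coefficient.
#' @param sense `"max"` or `"min"`.
#' @export
objective_tier <- function(coefficients, sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            !is.null(names(coefficients)), all(nzchar(names(coefficients))))
  structure(list(coefficients = coefficients, sense = sense),
            class = "objective_tier")
}

#' Define a (lexicographic) objective specification
#'
#' Tiers are optimized in order: tier k is optimized subject to every earlier
#' tier being held within a relative tolerance `delta` of its optimum
#' (implemented as added linear constraints). The astrocyte default puts ATP
#' maintenance first and the glutamate/glutamine cycle second, reflecting the
#' priority of energetic demand over neurotransmitter recycling.
#'
#' @param ... one or more [objective_tier()] objects (or a single list of
#'   them).
#' @param delta relative tier-retention tolerance (default `1e-6`).
#' @export
objective_spec <- function(..., delta = 1e-6) {
  tiers <- list(...)
  if (length(tiers) == 1L && !inherits(tiers[[1]], "objective_tier")) {
    tiers <- tiers[[1]]
  }
  stopifnot(length(tiers) >= 1L,
            all(vapply(tiers, inherits, logical(1), "objective_tier")),
            is.numeric(delta), delta >= 0)
  structure(list(tiers = tiers, delta = delta), class = "objective_spec")
}

#' @export
print.objective_spec <- function(x, ...) {
  cat(sprintf("<objective_spec> %d tier(s), delta = %g\n", length(x$tiers),
              x$delta))
  for (k in seq_along(x$tiers)) {
    t <- x$tiers[[k]]
    cat(sprintf("  tier %d (%s): %s\n", k, t$sense,
                paste(sprintf("%+g %s", t$coefficients,
                              names(t$coefficients)), collapse = " ")))
  }
  invisible(x)
}

check_objective <- function(model, objective) {
  stopifnot(inherits(objective, "objective_spec"))
  for (t in objective$tiers) {
    bad <- setdiff(names(t$coefficients), model$reactions$id)
    if (length(bad)) {
      stop("objective names unknown reaction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

new_flux_distribution <- function(model, x, status, objective_values) {
  fluxes <- if (is.null(x)) NULL else stats::setNames(x, model$reactions$id)
  structure(list(fluxes = fluxes, status = status,
                 objective_values = objective_values),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status: %s", x$status))
  if (length(x$objective_values)) {
    cat(" | objective:", paste(signif(x$objective_values, 8), collapse = ", "))
  }
  cat("\n")
  if (!is.null(x$fluxes)) {
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat(sprintf("%d reactions, %d carrying flux (|v| > 1e-9)\n",
                length(x$fluxes), nz))
  }
  invisible(x)
}

#' @export
summary.flux_distribution <- function(object, ...) {
  print(object)
  if (!is.null(object$fluxes)) {
    act <- sort(abs(object$fluxes), decreasing = TRUE)
    act <- act[act > 1e-9]
    cat("largest fluxes (by magnitude):\n")
    top <- utils::head(act, 10)
    for (n in names(top)) {
      cat(sprintf("  %-16s %12.6g\n", n, object$fluxes[[n]]))
    }
  }
  invisible(object)
}

#' @export
coef.flux_distribution <- function(object, ...) object$fluxes

# dense objective vector over all model reactions
tier_cvec <- function(model, tier) {
  cv <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  cv[names(tier$coefficients)] <- tier$coefficients
  as.numeric(cv)
}

# retention constraint row for a solved tier, as a `>=` row over fluxes
tier_retention_row <- function(cvec, sense, z, delta) {
  slack <- delta * abs(z)
  if (sense == "max") list(a = cvec, b = z - slack)
  else list(a = -cvec, b = -(z + slack))
}

#' Flux balance analysis (single objective)
#'
#' Maximizes (or minimizes) a single-tier linear objective subject to
#' steady-state mass balance `S v = 0` and the model's flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective an [objective_spec()] with exactly one tier, or a single
#'   [objective_tier()].
#' @param tol LP tolerance.
#' @return a `flux_distribution` with `status` one of `"optimal"`,
#'   `"infeasible"`, `"unbounded"`.
#' @export
solve_fba <- function(model, objective, tol = 1e-9) {
  if (inherits(objective, "objective_tier")) {
    objective <- objective_spec(objective)
  }
  check_objective(model, objective)
  if (length(objective$tiers) != 1L) {
    stop("solve_fba takes a single-tier objective; use solve_lexicographic",
         call. = FALSE)
  }
  S <- build_stoichiometric_matrix(model)
  bnd <- model_bounds(model)
  tier <- objective$tiers[[1]]
  res <- lp_solve(tier_cvec(model, tier), S, rep(0, nrow(S)),
                  bnd[, "lb"], bnd[, "ub"], tier$sense, tol)
  new_flux_distribution(model, res$x, res$status,
                        if (res$status == "optimal") res$objval else numeric(0))
}

#' Lexicographic multi-objective FBA
#'
#' Optimizes the tiers of `objective` in order; after each tier its optimum
#' is locked in (within the objective specification's relative `delta`) as a
#' linear constraint before the next tier is optimized. By default the final
#' flux vector is additionally passed through a parsimonious-FBA step
#' (minimize total absolute flux subject to all tier constraints), so the
#' returned distribution is a unique, reproducible representative of the
#' optimal set.
#'
#' @param model a `metabolic_model`.
#' @param objective an [objective_spec()].
#' @param parsimonize run the terminal parsimonious step (default `TRUE`).
#' @param tol LP tolerance.
#' @return a `flux_distribution`; `objective_values` holds each tier's
#'   optimum in tier order. On infeasibility introduced by a tier the status
#'   is `"infeasible"` and the offending tier index is reported in the error
#'   condition message attribute `tier`.
#' @export
solve_lexicographic <- function(model, objective, parsimonize = TRUE,
                                tol = 1e-9) {
  check_objective(model, objective)
  S <- build_stoichiometric_matrix(model)
  bnd <- model_bounds(model)
  b0 <- rep(0, nrow(S))
  A_ge <- NULL; b_ge <- NULL
  zs <- numeric(0)
  x <- NULL
  for (k in seq_along(objective$tiers)) {
    tier <- objective$tiers[[k]]
    cv <- tier_cvec(model, tier)
    res <- lp_solve_geq(cv, S, b0, bnd[, "lb"], bnd[, "ub"], tier$sense,
                        A_ge = A_ge, b_ge = b_ge, tol = tol)
    if (res$status != "optimal") {
      fd <- new_flux_distribution(model, NULL, res$status, zs)
      attr(fd, "tier") <- k
      return(fd)
    }
    zs <- c(zs, res$objval)
    x <- res$x
    row <- tier_retention_row(cv, tier$sense, res$objval, objective$delta)
    A_ge <- rbind(A_ge, row$a); b_ge <- c(b_ge, row$b)
  }
  if (parsimonize) {
    x <- pfba_step(model, S, bnd, A_ge, b_ge, tol)
  }
  new_flux_distribution(model, x, "optimal", zs)
}

# minimize sum |v| subject to S v = 0, bounds, and the accumulated tier rows;
# standard split into nonnegative parts
pfba_step <- function(model, S, bnd, A_ge, b_ge, tol = 1e-9) {
  n <- ncol(S)
  lb <- bnd[, "lb"]; ub <- bnd[, "ub"]
  Ssplit <- cbind(S, -S)
  lbp <- pmax(lb, 0); ubp <- pmax(ub, 0)
  lbn <- pmax(-ub, 0); ubn <- pmax(-lb, 0)
  Age2 <- if (is.null(A_ge)) NULL else cbind(A_ge, -A_ge)
  res <- lp_solve_geq(rep(1, 2 * n), Ssplit, rep(0, nrow(S)),
                      c(lbp, lbn), c(ubp, ubn), "min",
                      A_ge = Age2, b_ge = b_ge, tol = tol)
  if (res$status != "optimal") {
    stop("parsimonious step unexpectedly ", res$status, call. = FALSE)
  }
  res$x[seq_len(n)] - res$x[seq_len(n) + n]
}

#' Parsimonious FBA
#'
#' Computes each tier optimum of `objective` and returns, among all flux
#' vectors retaining those optima within the specification's `delta`, one minimizing
#' total absolute flux. With a single tier this is classical pFBA.
#'
#' @inheritParams solve_lexicographic
#' @return a `flux_distribution`.
#' @export
solve_pfba <- function(model, objective, tol = 1e-9) {
  if (inherits(objective, "objective_tier")) {
    objective <- objective_spec(objective)
  }
  solve_lexicographic(model, objective, parsimonize = TRUE, tol = tol)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to the tier-1 objective
#' retaining at least `retention` of its optimum. Quantifies how much any
#' single reported flux depends on the parsimonious representative chosen by
#' [solve_lexicographic()].
#'
#' @param model a `metabolic_model`.
#' @param objective an [objective_spec()]; only tier 1 is used.
#' @param retention fraction of the tier-1 optimum to retain, in (0, 1].
#' @param reactions reaction ids to analyze (default: all).
#' @param tol LP tolerance.
#' @return data.frame of class `"fva_ranges"` with columns `reaction_id`,
#'   `min`, `max`.
#' @export
run_fva <- function(model, objective, retention = 1.0, reactions = NULL,
                    tol = 1e-9) {
  if (inherits(objective, "objective_tier")) {
    objective <- objective_spec(objective)
  }
  check_objective(model, objective)
  stopifnot(retention > 0, retention <= 1)
  if (is.null(reactions)) reactions <- model$reactions$id
  bad <- setdiff(reactions, model$reactions$id)
  if (length(bad)) stop("unknown reaction(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  S <- build_stoichiometric_matrix(model)
  bnd <- model_bounds(model)
  tier <- objective$tiers[[1]]
  cv <- tier_cvec(model, tier)
  base <- lp_solve(cv, S, rep(0, nrow(S)), bnd[, "lb"], bnd[, "ub"],
                   tier$sense, tol)
  if (base$status != "optimal") {
    stop("FVA: base problem is ", base$status, call. = FALSE)
  }
  z <- base$objval
  keep <- if (z >= 0) retention * z else z / retention
  row <- if (tier$sense == "max") list(a = cv, b = keep)
         else list(a = -cv, b = -(z + (1 - retention) * abs(z)))
  out <- data.frame(reaction_id = reactions, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  n <- ncol(S)
  for (i in seq_along(reactions)) {
    ei <- numeric(n); ei[match(reactions[i], model$reactions$id)] <- 1
    lo <- lp_solve_geq(ei, S, rep(0, nrow(S)), bnd[, "lb"], bnd[, "ub"],
                       "min", A_ge = matrix(row$a, 1), b_ge = row$b, tol = tol)
    hi <- lp_solve_geq(ei, S, rep(0, nrow(S)), bnd[, "lb"], bnd[, "ub"],
                       "max", A_ge = matrix(row$a, 1), b_ge = row$b, tol = tol)
    out$min[i] <- if (lo$status == "optimal") lo$objval else NA_real_
    out$max[i] <- if (hi$status == "optimal") hi$objval else NA_real_
  }
  class(out) <- c("fva_ranges", "data.frame")
  out
}

#' Verify a flux distribution against its model
#'
#' Reports the worst steady-state mass-balance residual and the worst bound
#' violation of a solved flux distribution. Accepted solutions satisfy
#' `max |S v| <= 1e-8 * max(1, max |v|)` and stay within bounds up to 1e-9.
#'
#' @param model a `metabolic_model`.
#' @param dist a `flux_distribution`.
#' @return object of class `"verification_report"`: list with `verifiable`,
#'   `max_residual`, `max_bound_violation`, `ok`.
#' @export
verify_solution <- function(model, dist) {
  stopifnot(inherits(dist, "flux_distribution"))
  if (dist$status != "optimal" || is.null(dist$fluxes)) {
    return(structure(list(verifiable = FALSE, max_residual = NA_real_,
                          max_bound_violation = NA_real_, ok = FALSE),
                     class = "verification_report"))
  }
  S <- build_stoichiometric_matrix(model)
  v <- dist$fluxes[colnames(S)]
  resid <- max(abs(S %*% v))
  bnd <- model_bounds(model)
  viol <- max(c(bnd[, "lb"] - v, v - bnd[, "ub"], 0))
  ok <- resid <= 1e-8 * max(1, max(abs(v))) && viol <= 1e-9
  structure(list(verifiable = TRUE, max_residual = resid,
                 max_bound_violation = viol, ok = ok),
            class = "verification_report")
}

#' @export
print.verification_report <- function(x, ...) {
  if (!x$verifiable) {
    cat("Solution not verifiable (no optimal flux vector).\n")
  } else {
    cat(sprintf("max |S v| residual:    %.3g\n", x$max_residual))
    cat(sprintf("max bound violation:   %.3g\n", x$max_bound_violation))
    cat(sprintf("within tolerances:     %s\n", ifelse(x$ok, "yes", "NO")))
  }
  invisible(x)
}
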