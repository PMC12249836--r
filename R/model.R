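# Constraint-based metabolic model container.
#
# A metabolic_model is a plain list with
#   metabolites:    data.frame(id, name, compartment, formula)
#   reactions:      data.frame(id, name, lower_bound, upper_bound, subsystem, gpr)
#   stoichiometry:  named list, reaction id -> named numeric vector
#                   (metabolite id -> signed coefficient, negative = consumed)
#   compartments:   named character vector (id -> descriptive name)
#   objective:      default objective_spec or NULL
# Bounds are in µmol/g/min throughout; exchange fluxes are signed with the
# convention negative = uptake, positive = release.

DEFAULT_BOUND <- 1000

#' Construct a constraint-based metabolic model
#'
#' Assembles and validates a metabolic model from its parts. Most users will
#' get a model from [load_model()] or [generate_toy_astrocyte_model()] rather
#' than calling this directly.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   and optionally `formula`.
#' @param reactions data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `subsystem`, `gpr` (GPR rule text, `""` if none).
#' @param stoichiometry named list mapping each reaction id to a named
#'   numeric vector of metabolite coefficients (negative = consumed).
#' @param compartments named character vector of compartment ids; defaults to
#'   the compartments used by `metabolites`.
#' @param objective optional default [objective_spec()].
#' @param check if `TRUE` (default) hard invariants are enforced.
#' @return object of class `"metabolic_model"`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            compartments = NULL, objective = NULL,
                            check = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(compartments)) {
    cp <- sort(unique(metabolites$compartment))
    compartments <- stats::setNames(cp, cp)
  }
  m <- structure(list(metabolites = metabolites,
                      reactions = reactions,
                      stoichiometry = stoichiometry,
                      compartments = compartments,
                      objective = objective),
                 class = "metabolic_model")
  if (check) {
    rep <- validate_model(m)
    if (length(rep$violations)) {
      stop("invalid metabolic model:\n  ",
           paste(rep$violations, collapse = "\n  "), call. = FALSE)
    }
  }
  m
}

#' Validate a metabolic model
#'
#' Mechanical consistency checks: unique ids, declared compartments,
#' stoichiometry keys resolving to declared metabolites, bound ordering,
#' exchange-reaction shape, plus informational findings (dead-end
#' metabolites, orphan metabolites, reactions pinned to zero).
#'
#' @param model a `metabolic_model` (checked structurally, so a broken model
#'   can be inspected).
#' @return object of class `"model_validation"`: list with `violations`
#'   (character; empty means the model satisfies all hard invariants),
#'   `dead_ends` (metabolites appearing in at most one reaction), `orphans`
#'   (metabolites used by no reaction) and `zero_locked` (reactions with
#'   `lb == ub == 0`).
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites; rxns <- model$reactions
  v <- character(0)
  if (anyDuplicated(mets$id)) {
    v <- c(v, paste("duplicated metabolite ids:",
                    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", ")))
  }
  if (anyDuplicated(rxns$id)) {
    v <- c(v, paste("duplicated reaction ids:",
                    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", ")))
  }
  bad_cp <- setdiff(unique(mets$compartment), names(model$compartments))
  if (length(bad_cp)) {
    v <- c(v, paste("undeclared compartments:", paste(bad_cp, collapse = ", ")))
  }
  missing_sto <- setdiff(rxns$id, names(model$stoichiometry))
  if (length(missing_sto)) {
    v <- c(v, paste("reactions without stoichiometry:",
                    paste(missing_sto, collapse = ", ")))
  }
  usage <- stats::setNames(integer(nrow(mets)), mets$id)
  for (rid in intersect(rxns$id, names(model$stoichiometry))) {
    sto <- model$stoichiometry[[rid]]
    if (length(sto) == 0L) {
      v <- c(v, paste0("reaction '", rid, "' has empty stoichiometry"))
      next
    }
    unknown <- setdiff(names(sto), mets$id)
    if (length(unknown)) {
      v <- c(v, paste0("reaction '", rid, "' references undeclared metabolite(s): ",
                       paste(unknown, collapse = ", ")))
    }
    known <- intersect(names(sto), names(usage))
    usage[known] <- usage[known] + 1L
  }
  bad_bounds <- rxns$id[rxns$lower_bound > rxns$upper_bound]
  if (length(bad_bounds)) {
    v <- c(v, paste("lower_bound > upper_bound for:",
                    paste(bad_bounds, collapse = ", ")))
  }
  # exchange shape: boundary reactions must touch exactly one extracellular
  # metabolite
  for (rid in exchange_reactions(model)) {
    sto <- model$stoichiometry[[rid]]
    cp <- mets$compartment[match(names(sto), mets$id)]
    if (length(sto) != 1L || !identical(cp, "e")) {
      v <- c(v, paste0("exchange reaction '", rid,
                       "' must reference exactly one extracellular metabolite"))
    }
  }
  if (length(exchange_reactions(model)) == 0L) {
    v <- c(v, "model declares no exchange reaction")
  }
  # GPR parseability
  for (i in seq_len(nrow(rxns))) {
    ok <- tryCatch({ parse_gpr(rxns$gpr[i]); TRUE }, error = function(e) FALSE)
    if (!ok) v <- c(v, paste0("reaction '", rxns$id[i], "' has unparseable GPR"))
  }
  structure(list(
    violations = v,
    orphans = names(usage)[usage == 0L],
    dead_ends = names(usage)[usage <= 1L],
    zero_locked = rxns$id[rxns$lower_bound == 0 & rxns$upper_bound == 0]
  ), class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  if (length(x$violations) == 0L) {
    cat("Model valid: no invariant violations.\n")
  } else {
    cat("Invariant violations:\n")
    cat(paste0("  - ", x$violations, collapse = "\n"), "\n")
  }
  cat(sprintf("Dead-end metabolites (<= 1 reaction): %d\n", length(x$dead_ends)))
  cat(sprintf("Orphan metabolites (no reaction):     %d\n", length(x$orphans)))
  cat(sprintf("Reactions locked to zero (lb=ub=0):   %d\n", length(x$zero_locked)))
  invisible(x)
}

#' Reactions classified as exchanges
#'
#' An exchange reaction is a boundary reaction whose stoichiometry touches a
#' single extracellular (`e`) metabolite, or any reaction whose id carries
#' the conventional `EX_` prefix (the latter lets [validate_model()] flag
#' malformed exchanges). Negative flux is uptake, positive is release.
#' Single-metabolite boundary reactions on intracellular species (demands
#' and sinks) are deliberately not exchanges.
#'
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(model) {
  mets <- model$metabolites
  out <- character(0)
  for (rid in model$reactions$id) {
    sto <- model$stoichiometry[[rid]]
    single_e <- length(sto) == 1L &&
      identical(mets$compartment[match(names(sto), mets$id)], "e")
    if (single_e || startsWith(rid, "EX_")) out <- c(out, rid)
  }
  out
}

#' Build the stoichiometric matrix S
#'
#' @param model a `metabolic_model`.
#' @return numeric matrix (metabolites x reactions) with dimnames set to the
#'   model's metabolite and reaction ids; entry (i, j) is the coefficient of
#'   metabolite i in reaction j.
#' @export
build_stoichiometric_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids),
              dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    sto <- model$stoichiometry[[rids[j]]]
    if (length(sto)) S[names(sto), j] <- as.numeric(sto)
  }
  S
}

#' Map reactions to their catalyzing enzyme complexes
#'
#' Parses every reaction's GPR rule and returns, per reaction, the list of
#' enzyme complexes (DNF of the rule). Reactions with an empty GPR map to an
#' empty list.
#'
#' @param model a `metabolic_model`.
#' @return named list: reaction id -> list of character vectors.
#' @export
map_reaction_enzymes <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  out <- lapply(model$reactions$gpr, function(g) parse_gpr(g)$complexes)
  names(out) <- model$reactions$id
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d metabolites, %d reactions, %d exchanges\n",
              nrow(x$metabolites), nrow(x$reactions),
              length(exchange_reactions(x))))
  cat("compartments:", paste(names(x$compartments), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.metabolic_model <- function(object, ...) {
  sub <- table(object$reactions$subsystem)
  cat(sprintf("Metabolic model: %d metabolites / %d reactions\n",
              nrow(object$metabolites), nrow(object$reactions)))
  cat("Reactions per subsystem:\n")
  for (s in names(sort(sub, decreasing = TRUE))) {
    cat(sprintf("  %-28s %d\n", ifelse(nzchar(s), s, "(none)"), sub[[s]]))
  }
  rep <- validate_model(object)
  cat(sprintf("Invariant violations: %d\n", length(rep$violations)))
  invisible(object)
}

# bounds as a 2-column matrix, rows = reactions
model_bounds <- function(model) {
  cbind(lb = model$reactions$lower_bound, ub = model$reactions$upper_bound)
}

# replace bounds for one reaction (id checked)
set_bounds <- function(model, rid, lb = NULL, ub = NULL) {
  i <- match(rid, model$reactions$id)
  if (is.na(i)) stop(sprintf("unknown reaction id '%s'", rid), call. = FALSE)
  if (!is.null(lb)) model$reactions$lower_bound[i] <- lb
  if (!is.null(ub)) model$reactions$upper_bound[i] <- ub
  model
}
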