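# Condition encoding: physiological uptake/release rates (steady state) and
# the hypoxia / acidosis / combined perturbations as reusable bound-override
# sets. Direction convention, used everywhere: exchange flux negative =
# uptake, positive = release.

#' Read a metabolite rate table
#'
#' Reads a TSV with columns `metabolite`, `rate` (µmol/g/min, nonnegative)
#' and `direction` (`uptake` or `release`).
#'
#' @param path TSV file path.
#' @return data.frame with the three columns, checked.
#' @export
read_rate_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("metabolite", "rate", "direction")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("rate table misses column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  tab <- tab[need]
  if (any(!is.finite(tab$rate)) || any(tab$rate < 0)) {
    stop("rates must be nonnegative numbers", call. = FALSE)
  }
  bad <- setdiff(unique(tab$direction), c("uptake", "release"))
  if (length(bad)) {
    stop("unknown direction value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tab
}

# normalize a metabolite label for matching ("CMR_O_2_" -> "cmro2")
normalize_met_label <- function(x) {
  gsub("[^a-z0-9]", "", tolower(x))
}

# aliases: cerebral metabolic rates name the gas they measure
RATE_ALIASES <- c(cmro2 = "oxygen", cmrco2 = "carbondioxide",
                  llactate = "lactate")

#' Constrain exchange bounds from a physiological rate table
#'
#' For every rate-table entry matching one of the model's exchange reactions
#' (by extracellular metabolite name, case/punctuation-insensitive, with
#' CMR_O2/CMR_CO2 understood as oxygen/CO2), sets the uptake bound
#' (`lower_bound = -rate`) or release bound (`upper_bound = rate`) of that
#' exchange. All other bounds are untouched. Entries matching no exchange
#' are collected in the `"unmatched_rates"` attribute of the returned model
#' (or raise an error in strict mode).
#'
#' @param model a `metabolic_model`.
#' @param rates data.frame from [read_rate_table()] (or equivalent).
#' @param strict error on unmatched entries instead of collecting them.
#' @return the constrained model; `attr(, "unmatched_rates")` holds the
#'   unmatched metabolite names (possibly empty).
#' @export
apply_uptake_rates <- function(model, rates, strict = FALSE) {
  stopifnot(inherits(model, "metabolic_model"))
  ex_ids <- exchange_reactions(model)
  ex_met <- vapply(ex_ids, function(rid) {
    names(model$stoichiometry[[rid]])[1]
  }, character(1))
  ex_name <- normalize_met_label(
    model$metabolites$name[match(ex_met, model$metabolites$id)])
  unmatched <- character(0)
  for (i in seq_len(nrow(rates))) {
    key <- normalize_met_label(rates$metabolite[i])
    if (key %in% names(RATE_ALIASES)) key <- RATE_ALIASES[[key]]
    hit <- ex_ids[ex_name == key]
    if (length(hit) == 0L) {
      if (strict) {
        stop(sprintf("no exchange reaction matches rate-table entry '%s'",
                     rates$metabolite[i]), call. = FALSE)
      }
      unmatched <- c(unmatched, rates$metabolite[i])
      next
    }
    if (length(hit) > 1L) {
      stop(sprintf("rate-table entry '%s' matches several exchanges: %s",
                   rates$metabolite[i], paste(hit, collapse = ", ")),
           call. = FALSE)
    }
    if (rates$direction[i] == "uptake") {
      model <- set_bounds(model, hit, lb = -rates$rate[i])
    } else {
      model <- set_bounds(model, hit, ub = rates$rate[i])
    }
  }
  attr(model, "unmatched_rates") <- unmatched
  model
}

#' Build a named stress-condition specification
#'
#' Encodes the perturbations as bound overrides relative to the steady-state
#' model:
#' * `steady_state`: no overrides (identity).
#' * `hypoxia`: the oxygen exchange bound scaled by `o2_fraction`
#'   (default 0.02, i.e. 2 % of the physiological oxygen uptake).
#' * `acidosis`: reduced buffering capacity — the Na+/H+ exchanger and the
#'   CO2/bicarbonate system reactions scaled by `buffer_fraction`
#'   (default 0.5).
#' * `combined`: the union of both override sets.
#'
#' Reaction ids differ between reconstructions, so the oxygen-exchange and
#' acid-handling ids are parameters; the defaults name the toy model's
#' reactions.
#'
#' @param name condition name.
#' @param o2_fraction fraction of baseline oxygen uptake admitted under
#'   hypoxia.
#' @param buffer_fraction fraction of baseline acid-handling capacity
#'   retained under acidosis.
#' @param o2_exchange_id oxygen exchange reaction id.
#' @param acid_reaction_ids ids of the Na+/H+ exchanger and CO2/bicarbonate
#'   system reactions.
#' @return object of class `"condition_spec"`.
#' @export
make_condition <- function(name = c("steady_state", "hypoxia", "acidosis",
                                    "combined"),
                           o2_fraction = 0.02, buffer_fraction = 0.5,
                           o2_exchange_id = "EX_o2_e",
                           acid_reaction_ids = c("NHE", "HCO3t", "EX_co2_e")) {
  name <- match.arg(name)
  stopifnot(o2_fraction >= 0, o2_fraction <= 1,
            buffer_fraction >= 0, buffer_fraction <= 1)
  scale_override <- function(rid, factor) {
    list(reaction_id = rid, mode = "scale", factor = factor)
  }
  hyp <- list(scale_override(o2_exchange_id, o2_fraction))
  aci <- lapply(acid_reaction_ids, scale_override, factor = buffer_fraction)
  overrides <- switch(name,
                      steady_state = list(),
                      hypoxia = hyp,
                      acidosis = aci,
                      combined = c(hyp, aci))
  structure(list(name = name, overrides = overrides,
                 parameters = list(o2_fraction = o2_fraction,
                                   buffer_fraction = buffer_fraction)),
            class = "condition_spec")
}

#' @export
print.condition_spec <- function(x, ...) {
  cat(sprintf("<condition_spec> %s (%d override(s))\n", x$name,
              length(x$overrides)))
  for (ov in x$overrides) {
    if (ov$mode == "scale") {
      cat(sprintf("  %-12s scale x %g\n", ov$reaction_id, ov$factor))
    } else {
      cat(sprintf("  %-12s bounds [%g, %g]\n", ov$reaction_id, ov$lower,
                  ov$upper))
    }
  }
  invisible(x)
}

#' Apply a condition's bound overrides to a model
#'
#' Returns a modified copy; the input model is untouched. Scale overrides
#' multiply both baseline bounds by the factor (0 <= factor <= 1), shrinking
#' their magnitudes toward zero — a condition can only restrict the feasible
#' region, never widen it, so any condition optimum is bounded by the
#' steady-state optimum. Applying the same scale condition twice composes
#' multiplicatively.
#'
#' @param model a `metabolic_model`.
#' @param condition a `condition_spec` (or condition name, built with
#'   default parameters).
#' @return the perturbed model.
#' @export
apply_condition <- function(model, condition) {
  stopifnot(inherits(model, "metabolic_model"))
  if (is.character(condition)) condition <- make_condition(condition)
  stopifnot(inherits(condition, "condition_spec"))
  for (ov in condition$overrides) {
    i <- match(ov$reaction_id, model$reactions$id)
    if (is.na(i)) {
      stop(sprintf("condition '%s' names unknown reaction '%s'",
                   condition$name, ov$reaction_id), call. = FALSE)
    }
    if (ov$mode == "scale") {
      if (ov$factor < 0 || ov$factor > 1) {
        stop("scale factor must lie in [0, 1]", call. = FALSE)
      }
      model$reactions$lower_bound[i] <- model$reactions$lower_bound[i] * ov$factor
      model$reactions$upper_bound[i] <- model$reactions$upper_bound[i] * ov$factor
    } else if (ov$mode == "absolute") {
      if (ov$lower > ov$upper) stop("absolute override has lower > upper",
                                    call. = FALSE)
      model$reactions$lower_bound[i] <- ov$lower
      model$reactions$upper_bound[i] <- ov$upper
    } else {
      stop("unknown override mode '", ov$mode, "'", call. = FALSE)
    }
  }
  model
}
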