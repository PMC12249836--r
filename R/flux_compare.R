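# Comparison of condition fluxes to steady state: signed percent changes,
# the robust-change flag, enzyme attribution, subsystem summaries and the
# steady-state physiology checks.

#' Per-reaction percent flux changes between two solved states
#'
#' For every reaction, computes the signed percent change
#' `100 * (v_condition - v_steady) / |v_steady|`. Fluxes with magnitude at
#' most `eps` count as zero: a reaction that is zero in both states has
#' percent change 0 (`change_type "zero"`); a reaction switching on gets
#' the `"newly_active"` sentinel and one switching off `"silenced"` (their
#' `pct_change` is `NA`). Enzyme complexes from the reaction's GPR are
#' attached for downstream attribution.
#'
#' @param steady,condition optimal `flux_distribution`s over the same
#'   reaction set.
#' @param model the `metabolic_model` both were solved on.
#' @param eps numerical-zero flux threshold (µmol/g/min), matching the LP
#'   tolerance.
#' @return data.frame of class `"flux_changes"` with columns `reaction_id`,
#'   `subsystem`, `v_steady`, `v_cond`, `pct_change`, `change_type`,
#'   `robust` (`NA` until [flag_robust()]) and `enzymes` (complexes as
#'   `"A+B; C"` text).
#' @export
compute_percent_changes <- function(steady, condition, model, eps = 1e-9) {
  stopifnot(inherits(steady, "flux_distribution"),
            inherits(condition, "flux_distribution"))
  if (steady$status != "optimal" || condition$status != "optimal") {
    stop("both flux distributions must be optimal", call. = FALSE)
  }
  sdiff <- c(setdiff(names(steady$fluxes), names(condition$fluxes)),
             setdiff(names(condition$fluxes), names(steady$fluxes)))
  if (length(sdiff)) {
    stop("flux distributions cover different reactions: ",
         paste(sdiff, collapse = ", "), call. = FALSE)
  }
  ids <- model$reactions$id
  vs <- steady$fluxes[ids]
  vc <- condition$fluxes[ids]
  type <- rep("finite", length(ids))
  type[abs(vs) <= eps & abs(vc) <= eps] <- "zero"
  type[abs(vs) <= eps & abs(vc) > eps] <- "newly_active"
  type[abs(vs) > eps & abs(vc) <= eps] <- "silenced"
  pct <- ifelse(type == "finite", 100 * (vc - vs) / abs(vs),
                ifelse(type == "zero", 0, NA_real_))
  enz <- map_reaction_enzymes(model)
  enz_txt <- vapply(enz[ids], function(cx) {
    paste(vapply(cx, paste, character(1), collapse = "+"), collapse = "; ")
  }, character(1))
  out <- data.frame(reaction_id = ids,
                    subsystem = model$reactions$subsystem,
                    v_steady = as.numeric(vs), v_cond = as.numeric(vc),
                    pct_change = pct, change_type = type,
                    robust = NA, enzymes = enz_txt,
                    stringsAsFactors = FALSE)
  class(out) <- c("flux_changes", "data.frame")
  out
}

#' Flag robust flux changes
#'
#' A reaction exhibits a robust change when its relative change strictly
#' exceeds the threshold (default 10 %), or when it switches on or off
#' (sentinel records), a qualitative change larger than any percent
#' threshold. A change of exactly the threshold is not robust.
#'
#' @param records a `flux_changes` data.frame.
#' @param threshold percent threshold (nonnegative).
#' @return the records with `robust` filled; the number of robust records is
#'   attached as attribute `"n_robust"`.
#' @export
flag_robust <- function(records, threshold = 10) {
  stopifnot(inherits(records, "flux_changes"))
  if (!is.numeric(threshold) || threshold < 0) {
    stop("threshold must be a nonnegative percent value", call. = FALSE)
  }
  # the small guard keeps "strictly exceeding" decisions stable against
  # floating-point residue in the percent changes
  records$robust <- ifelse(
    records$change_type %in% c("newly_active", "silenced"), TRUE,
    ifelse(records$change_type == "zero", FALSE,
           abs(records$pct_change) > threshold + 1e-9))
  attr(records, "n_robust") <- sum(records$robust)
  records
}

#' Summarize flux changes by subsystem
#'
#' One row per subsystem with the number of reactions, the number of robust
#' changes, and the mean, median and summed percent change. Sentinel records
#' (on/off switches) are excluded from the mean/median/sum but counted in
#' `n_robust`.
#'
#' @param records a `flux_changes` data.frame (after [flag_robust()]).
#' @return data.frame of class `"subsystem_summary"`.
#' @export
summarize_subsystems <- function(records) {
  stopifnot(inherits(records, "flux_changes"))
  subs <- sort(unique(records$subsystem))
  rows <- lapply(subs, function(s) {
    r <- records[records$subsystem == s, ]
    fin <- r$pct_change[!is.na(r$pct_change)]
    data.frame(subsystem = s,
               n_reactions = nrow(r),
               n_robust = sum(r$robust %in% TRUE),
               n_sentinel = sum(r$change_type %in%
                                  c("newly_active", "silenced")),
               mean_pct_change = if (length(fin)) mean(fin) else NA_real_,
               median_pct_change = if (length(fin)) stats::median(fin)
                                   else NA_real_,
               sum_pct_change = if (length(fin)) sum(fin) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("subsystem_summary", "data.frame")
  out
}

#' Total absolute flux carried by a subsystem
#'
#' Convenience aggregate for directionality statements such as "hypoxia
#' raises glycolytic flux": the sum of |v| over the reactions labeled with
#' `subsystem`.
#'
#' @param dist an optimal `flux_distribution`.
#' @param model the model it was solved on.
#' @param subsystem subsystem label.
#' @export
subsystem_flux <- function(dist, model, subsystem) {
  stopifnot(inherits(dist, "flux_distribution"), dist$status == "optimal")
  ids <- model$reactions$id[model$reactions$subsystem == subsystem]
  if (length(ids) == 0L) stop("no reactions in subsystem '", subsystem, "'",
                              call. = FALSE)
  sum(abs(dist$fluxes[ids]))
}

#' Steady-state physiology checks
#'
#' Verifies, on a solved flux distribution, the hallmarks expected of an
#' astrocyte model at physiological steady state: active glycogen synthesis
#' (glycogen synthase flux), active glycogen degradation (glycogen
#' phosphorylase flux), formation of the glycolytic regulator
#' fructose-2,6-bisphosphate, conversion of pyruvate to lactate, and a
#' well-defined NAD+/NADH redox state (nonzero turnover of both pools).
#'
#' @param dist an optimal `flux_distribution`.
#' @param model the model it was solved on.
#' @param bindings named character vector mapping the roles `GS`, `GP`,
#'   `PFKFB`, `LDH` to reaction ids of `model`.
#' @param nad_pair metabolite ids of the cytosolic NAD+ and NADH pools.
#' @param eps numerical-zero flux threshold.
#' @return object of class `"physiology_report"`: data.frame with columns
#'   `check`, `pass`, `value` (supporting flux or turnover).
#' @export
check_physiology <- function(dist, model,
                             bindings = c(GS = "GS", GP = "GP",
                                          PFKFB = "PFKFB", LDH = "LDH"),
                             nad_pair = c("nad_c", "nadh_c"), eps = 1e-9) {
  stopifnot(inherits(dist, "flux_distribution"), dist$status == "optimal")
  need <- c("GS", "GP", "PFKFB", "LDH")
  miss <- setdiff(need, names(bindings))
  if (length(miss)) stop("missing physiology binding(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  absent <- bindings[!(bindings %in% model$reactions$id)]
  if (length(absent)) {
    stop("physiology binding names absent reaction(s): ",
         paste(sprintf("%s -> '%s'", names(absent), absent), collapse = ", "),
         call. = FALSE)
  }
  flux_of <- function(role) as.numeric(dist$fluxes[[bindings[[role]]]])
  S <- build_stoichiometric_matrix(model)
  turnover <- function(met) {
    if (!met %in% rownames(S)) {
      stop("NAD pool metabolite '", met, "' not in model", call. = FALSE)
    }
    contrib <- S[met, ] * dist$fluxes[colnames(S)]
    sum(contrib[contrib > 0])
  }
  to <- vapply(nad_pair, turnover, numeric(1))
  rows <- data.frame(
    check = c("glycogen_synthesis_active", "glycogen_degradation_active",
              "f26bp_formation_active", "pyruvate_to_lactate_active",
              "nad_redox_turnover"),
    pass = c(abs(flux_of("GS")) > eps, abs(flux_of("GP")) > eps,
             abs(flux_of("PFKFB")) > eps, abs(flux_of("LDH")) > eps,
             all(to > eps)),
    value = c(flux_of("GS"), flux_of("GP"), flux_of("PFKFB"),
              flux_of("LDH"), min(to)),
    stringsAsFactors = FALSE)
  class(rows) <- c("physiology_report", "data.frame")
  rows
}

#' @export
print.physiology_report <- function(x, ...) {
  cat("Steady-state physiology checks:\n")
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  [%s] %-28s (%.4g)\n",
                ifelse(x$pass[i], "ok", "FAIL"), x$check[i], x$value[i]))
  }
  invisible(x)
}
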