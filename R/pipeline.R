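# End-to-end pipeline driver: model -> physiological constraints ->
# conditions -> flux changes -> proteomics -> integration, with all outputs
# written as TSV plus a deterministic run log.

#' Default pipeline configuration
#'
#' @return named list of all configuration keys with their defaults; any
#'   subset can be overridden via the `config` argument of
#'   [run_pipeline()] or a YAML file with the same keys.
#' @export
default_pipeline_config <- function() {
  list(
    model = "toy",                 # "toy" or path to a JSON/SBML model
    # demand-driven comparisons: ATP maintenance pinned at the
    # anaerobic-feasible level so every condition can meet demand and the
    # comparison isolates metabolic rerouting (see the methods vignette)
    toy = list(include_glycogen_turnover = TRUE, atp_demand = 0.38),
    rates = "builtin",             # "builtin", path to TSV, or NULL
    conditions = c("hypoxia", "acidosis", "combined"),
    o2_fraction = 0.02,
    buffer_fraction = 0.5,
    o2_exchange_id = "EX_o2_e",
    acid_reaction_ids = c("NHE", "HCO3t", "EX_co2_e"),
    robust_threshold = 10,
    change_metric = "signed",      # documented alternative: "magnitude"
    proteomics = "synthetic",      # "synthetic" or path to a DEP TSV
    n_per_group = 3,
    fc_min = 1.2, p_max = 0.10, q_max = 0.05,
    fva = FALSE,                   # also compute FVA ranges per condition
    solver = "simplex",            # LP backend (only the built-in simplex)
    seed = 1L
  )
}

#' Run the astrocyte stress-modeling pipeline
#'
#' Loads or generates a model, applies the physiological uptake/release
#' rates, solves the lexicographic objective (parsimonious representative)
#' at steady state and under each stress condition, computes percent flux
#' changes with the robust-change flag and subsystem summaries, derives
#' differentially expressed proteins (from a file or the synthetic
#' generator), and builds the enzyme-reaction integration table with its
#' sign-concordance summary. All randomness is governed by `seed`; given the
#' same configuration and seed the outputs are byte-identical across runs.
#'
#' @param config named list overriding [default_pipeline_config()] keys, or
#'   the path of a YAML file with those keys.
#' @param out_dir output directory for TSVs and the run log; `NULL` writes
#'   nothing and only returns results.
#' @param seed overrides `config$seed` when given.
#' @return (invisibly) list of class `"astroflux_run"` with elements
#'   `model`, `steady`, `physiology`, `conditions` (per condition: `spec`,
#'   `dist`, `changes`, `subsystems`, optionally `fva`), `deps`, `pairs`,
#'   `integration`, `concordance`, `config`, `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(default_pipeline_config(), config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!identical(cfg$solver, "simplex")) {
    stop("unknown solver backend '", cfg$solver, "'", call. = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## model
  model <- stage("model", {
    if (identical(cfg$model, "toy")) {
      do.call(toy_model_spec, cfg$toy) |> generate_toy_astrocyte_model()
    } else {
      load_model(cfg$model)
    }
  })
  unmatched <- character(0)
  model <- stage("conditions", {
    if (identical(cfg$rates, "builtin")) {
      m2 <- apply_uptake_rates(model, astrocyte_rate_table())
    } else if (is.null(cfg$rates)) {
      if (!identical(cfg$model, "toy")) {
        stop("a rate table is required for file-based models")
      }
      m2 <- model
    } else {
      m2 <- apply_uptake_rates(model, read_rate_table(cfg$rates))
    }
    unmatched <<- attr(m2, "unmatched_rates") %||% character(0)
    m2
  })
  objective <- model$objective %||%
    stop("[stage model] model declares no default objective", call. = FALSE)

  ## steady state
  steady <- stage("fba", {
    d <- solve_lexicographic(model, objective)
    if (d$status != "optimal") stop("steady state is ", d$status)
    d
  })
  physiology <- if (identical(cfg$model, "toy")) {
    stage("physiology", check_physiology(steady, model))
  } else NULL

  ## conditions
  cond_names <- setdiff(cfg$conditions, "steady_state")
  conds <- list()
  for (cn in cond_names) {
    conds[[cn]] <- stage(cn, {
      spec <- make_condition(cn, o2_fraction = cfg$o2_fraction,
                             buffer_fraction = cfg$buffer_fraction,
                             o2_exchange_id = cfg$o2_exchange_id,
                             acid_reaction_ids = cfg$acid_reaction_ids)
      pm <- apply_condition(model, spec)
      d <- solve_lexicographic(pm, objective)
      if (d$status != "optimal") stop("condition solve is ", d$status)
      ch <- flag_robust(compute_percent_changes(steady, d, model),
                        threshold = cfg$robust_threshold)
      res <- list(spec = spec, dist = d, changes = ch,
                  subsystems = summarize_subsystems(ch))
      if (isTRUE(cfg$fva)) res$fva <- run_fva(pm, objective)
      res
    })
  }

  ## proteomics
  deps <- stage("proteomics", {
    tab <- if (identical(cfg$proteomics, "synthetic")) {
      compute_differential(generate_synthetic_proteomics(
        proteomics_spec(n_per_group = cfg$n_per_group, seed = cfg$seed)))
    } else {
      read_dep_table(cfg$proteomics)
    }
    if (anyNA(tab$qvalue)) tab <- bh_fill(tab)
    filter_deps(tab, fc_min = cfg$fc_min, p_max = cfg$p_max,
                q_max = cfg$q_max)
  })

  ## integration
  pairs <- integration <- concordance <- NULL
  if (length(conds)) {
    pairs <- stage("integration", pair_enzyme_reactions(deps, model))
    integration <- stage("integration", build_split_heatmap(
      pairs, deps, lapply(conds, `[[`, "changes"),
      conditions = names(conds)))
    concordance <- stage("integration", concordance_score(integration))
  }

  res <- structure(list(model = model, steady = steady,
                        physiology = physiology, conditions = conds,
                        deps = deps, pairs = pairs,
                        integration = integration,
                        concordance = concordance,
                        config = cfg, out_dir = out_dir),
                   class = "astroflux_run")
  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(res, out_dir,
                                          unmatched = unmatched))
  }
  invisible(res)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(res, out_dir, unmatched = character(0)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)

  flux_df <- function(d) data.frame(reaction_id = names(d$fluxes),
                                    flux = as.numeric(d$fluxes),
                                    stringsAsFactors = FALSE)
  write_tsv(flux_df(res$steady), p("fluxes_steady_state.tsv"))
  for (cn in names(res$conditions)) {
    cc <- res$conditions[[cn]]
    write_tsv(flux_df(cc$dist), p(sprintf("fluxes_%s.tsv", cn)))
    write_tsv(as.data.frame(cc$changes), p(sprintf("changes_%s.tsv", cn)))
    write_tsv(as.data.frame(cc$subsystems),
              p(sprintf("subsystems_%s.tsv", cn)))
    if (!is.null(cc$fva)) {
      write_tsv(as.data.frame(cc$fva), p(sprintf("fva_%s.tsv", cn)))
    }
  }
  write_tsv(as.data.frame(res$deps$records), p("deps.tsv"))
  if (!is.null(res$integration)) {
    write_tsv(as.data.frame(res$integration), p("integration.tsv"))
    write_tsv(as.data.frame(res$concordance), p("concordance.tsv"))
  }

  rep <- validate_model(res$model)
  con <- file(p("model_report.txt"), "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("metabolites: %d", nrow(res$model$metabolites)),
    sprintf("reactions: %d", nrow(res$model$reactions)),
    sprintf("exchanges: %d", length(exchange_reactions(res$model))),
    sprintf("invariant violations: %d", length(rep$violations)),
    sprintf("dead-end metabolites: %d", length(rep$dead_ends)),
    if (!is.null(res$physiology)) {
      c("physiology checks:",
        sprintf("  %s: %s", res$physiology$check,
                ifelse(res$physiology$pass, "pass", "FAIL")))
    }), con)

  log <- c(
    "astroflux run log",
    sprintf("seed: %d", res$config$seed),
    sprintf("model: %s", res$config$model),
    sprintf("conditions: %s", paste(names(res$conditions), collapse = ", ")),
    sprintf("o2_fraction: %g, buffer_fraction: %g",
            res$config$o2_fraction, res$config$buffer_fraction),
    sprintf("robust threshold: %g%%", res$config$robust_threshold),
    sprintf("DEP thresholds: |FC| >= %g, p < %g, q <= %g",
            res$config$fc_min, res$config$p_max, res$config$q_max),
    sprintf("unmatched rate-table entries: %s",
            if (length(unmatched)) paste(unmatched, collapse = ", ")
            else "(none)"),
    sprintf("steady-state objective(s): %s",
            paste(signif(res$steady$objective_values, 10), collapse = ", ")),
    vapply(names(res$conditions), function(cn) {
      sprintf("%s: objective %s, robust changes %d", cn,
              paste(signif(res$conditions[[cn]]$dist$objective_values, 10),
                    collapse = ", "),
              attr(res$conditions[[cn]]$changes, "n_robust"))
    }, character(1)),
    sprintf("DEPs passing: %d of %d", res$deps$counts[["n_pass"]],
            res$deps$counts[["n"]]))
  writeLines(log, p("run_log.txt"))
  invisible(out_dir)
}

#' @export
print.astroflux_run <- function(x, ...) {
  cat("<astroflux_run>\n")
  cat(sprintf("  steady-state objective: %s\n",
              paste(signif(x$steady$objective_values, 8), collapse = ", ")))
  for (cn in names(x$conditions)) {
    cc <- x$conditions[[cn]]
    cat(sprintf("  %-10s objective %s | %d robust flux changes\n", cn,
                paste(signif(cc$dist$objective_values, 8), collapse = ", "),
                attr(cc$changes, "n_robust")))
  }
  cat(sprintf("  DEPs: %d of %d pass\n", x$deps$counts[["n_pass"]],
              x$deps$counts[["n"]]))
  if (!is.null(x$concordance)) {
    ov <- x$concordance[x$concordance$subsystem == "(all)", ]
    for (i in seq_len(nrow(ov))) {
      cat(sprintf("  concordance %-10s %s\n", ov$condition[i],
                  ifelse(is.na(ov$fraction[i]), "undefined",
                         sprintf("%.2f (%d/%d)", ov$fraction[i],
                                 ov$n_concordant[i], ov$n_applicable[i]))))
    }
  }
  invisible(x)
}
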