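# Integration of proteomic fold changes with predicted flux changes:
# enzyme-reaction pairing through GPR rules, the split-heatmap table (one
# row per enzyme-reaction pair, fold change beside per-condition percent
# flux changes) and a sign-concordance summary.

#' Pair differentially expressed enzymes with model reactions
#'
#' For every passing DEP gene symbol, emits one pair per reaction whose GPR
#' rule mentions the symbol (in any complex). Symbols matching no reaction
#' are returned separately.
#'
#' @param deps passing DEP gene symbols: a character vector, a `dep_table`
#'   (rows with `passes == TRUE` are used if the column exists, otherwise
#'   all rows) or a `dep_filter` result.
#' @param model a `metabolic_model`.
#' @return list with `pairs` (data.frame `enzyme`, `reaction_id`,
#'   `subsystem`) and `unmapped` (character).
#' @export
pair_enzyme_reactions <- function(deps, model) {
  genes <- dep_symbols(deps)
  enz <- map_reaction_enzymes(model)
  rxn_genes <- lapply(enz, function(cx) unique(unlist(cx)))
  rows <- list()
  unmapped <- character(0)
  for (g in genes) {
    hits <- names(rxn_genes)[vapply(rxn_genes, function(gs) g %in% gs,
                                    logical(1))]
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, g)
    } else {
      rows[[g]] <- data.frame(
        enzyme = g, reaction_id = hits,
        subsystem = model$reactions$subsystem[match(hits, model$reactions$id)],
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(enzyme = character(0), reaction_id = character(0),
               subsystem = character(0), stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  list(pairs = pairs, unmapped = unmapped)
}

dep_symbols <- function(deps) {
  if (inherits(deps, "dep_filter")) return(unique(deps$passing$gene))
  if (inherits(deps, "dep_table") || is.data.frame(deps)) {
    if (!is.null(deps$passes)) return(unique(deps$gene[deps$passes]))
    return(unique(deps$gene))
  }
  unique(as.character(deps))
}

#' Build the enzyme-reaction split-heatmap table
#'
#' One row per enzyme-reaction pair, carrying the enzyme's proteomic log2
#' fold change next to the percent flux change of its reaction under each
#' condition, sorted by (subsystem, enzyme, reaction) to emphasize
#' pathway-level patterns. A condition cell is concordant when the sign of
#' the fold change equals the sign of the percent flux change; cells where
#' either side is zero, or where the flux change is an on/off sentinel, are
#' not applicable (`NA`).
#'
#' @param pairs result of [pair_enzyme_reactions()] (or its `pairs`
#'   data.frame).
#' @param deps a `dep_table` (or `dep_filter`) providing `log2fc` per gene.
#' @param changes named list of `flux_changes` tables, one per condition.
#' @param conditions condition names that must be present in `changes`.
#' @param pct_eps percent changes of magnitude at most this are treated as
#'   "no change" for concordance purposes (guards against floating-point
#'   residue in the LP solutions).
#' @return data.frame of class `"integration_table"` with columns `enzyme`,
#'   `reaction_id`, `subsystem`, `log2fc`, then per condition
#'   `pct_<condition>`, `type_<condition>`, `concordant_<condition>`.
#' @export
build_split_heatmap <- function(pairs, deps, changes,
                                conditions = c("hypoxia", "acidosis",
                                               "combined"),
                                pct_eps = 1e-6) {
  if (is.list(pairs) && !is.data.frame(pairs) && !is.null(pairs$pairs)) {
    pairs <- pairs$pairs
  }
  miss <- setdiff(conditions, names(changes))
  if (length(miss)) {
    stop("missing flux-change table for condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tab <- if (inherits(deps, "dep_filter")) deps$records else deps
  out <- pairs
  out$log2fc <- tab$log2fc[match(out$enzyme, tab$gene)]
  for (cn in conditions) {
    ch <- changes[[cn]]
    stopifnot(inherits(ch, "flux_changes"))
    i <- match(out$reaction_id, ch$reaction_id)
    pct <- ch$pct_change[i]
    typ <- ch$change_type[i]
    conc <- ifelse(typ != "finite" | is.na(pct) | abs(pct) <= pct_eps |
                     is.na(out$log2fc) | out$log2fc == 0,
                   NA, sign(out$log2fc) == sign(pct))
    out[[paste0("pct_", cn)]] <- pct
    out[[paste0("type_", cn)]] <- typ
    out[[paste0("concordant_", cn)]] <- conc
  }
  out <- out[order(out$subsystem, out$enzyme, out$reaction_id), ]
  rownames(out) <- NULL
  class(out) <- c("integration_table", "data.frame")
  attr(out, "conditions") <- conditions
  out
}

#' Sign-concordance summary of an integration table
#'
#' Fraction of applicable enzyme-reaction cells whose proteomic fold change
#' and predicted flux change agree in direction, per condition, overall and
#' per subsystem. With no applicable cell the fraction is undefined (`NA`),
#' not zero.
#'
#' @param rows an `integration_table`.
#' @return data.frame of class `"concordance_summary"` with columns
#'   `condition`, `subsystem` (`"(all)"` for the overall row), `n_pairs`,
#'   `n_applicable`, `n_concordant`, `fraction`.
#' @export
concordance_score <- function(rows) {
  stopifnot(inherits(rows, "integration_table"))
  conditions <- attr(rows, "conditions")
  score <- function(r, cn) {
    cc <- r[[paste0("concordant_", cn)]]
    napp <- sum(!is.na(cc))
    data.frame(n_pairs = nrow(r), n_applicable = napp,
               n_concordant = sum(cc %in% TRUE),
               fraction = if (napp) sum(cc %in% TRUE) / napp else NA_real_)
  }
  out <- list()
  for (cn in conditions) {
    out[[length(out) + 1L]] <- cbind(
      data.frame(condition = cn, subsystem = "(all)",
                 stringsAsFactors = FALSE),
      score(rows, cn))
    for (s in sort(unique(rows$subsystem))) {
      out[[length(out) + 1L]] <- cbind(
        data.frame(condition = cn, subsystem = s, stringsAsFactors = FALSE),
        score(rows[rows$subsystem == s, , drop = FALSE], cn))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("concordance_summary", "data.frame")
  res
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat("Sign concordance (proteomic fold change vs flux change):\n")
  ov <- x[x$subsystem == "(all)", ]
  for (i in seq_len(nrow(ov))) {
    cat(sprintf("  %-10s %d/%d applicable pairs concordant (%s)\n",
                ov$condition[i], ov$n_concordant[i], ov$n_applicable[i],
                ifelse(is.na(ov$fraction[i]), "undefined",
                       sprintf("%.2f", ov$fraction[i]))))
  }
  invisible(x)
}
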