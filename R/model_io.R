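# Model input/output: the community JSON dialect for constraint-based models
# and SBML Level 3 (with fbc flux bounds where present).

#' Load a constraint-based model from file
#'
#' Reads a metabolic model from the community JSON dialect
#' (`metabolites`/`reactions`/`gene_reaction_rule` fields, as written by
#' [write_model_json()]) or from SBML Level 3 (flux bounds via the `fbc`
#' package, with a fallback to kinetic-law `LOWER_BOUND`/`UPPER_BOUND`
#' parameters). Bounds absent from the file default to (-1000, 1000) for
#' reversible reactions and (0, 1000) otherwise.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"json"` or `"sbml"`.
#' @return a validated [metabolic_model()].
#' @export
load_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("model file not found: '%s'", path), call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", xml = "sbml", sbml = "sbml",
                     stop(sprintf("cannot infer model format from '%s'", path),
                          call. = FALSE))
  }
  switch(format,
         json = load_model_json(path),
         sbml = load_model_sbml(path))
}

load_model_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions)) {
    stop("JSON model must contain 'metabolites' and 'reactions'",
         call. = FALSE)
  }
  one <- function(x, field, default = NA_character_) {
    v <- x[[field]]
    if (is.null(v)) default else as.character(v)
  }
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = one(m, "id"),
               name = one(m, "name", one(m, "id")),
               compartment = one(m, "compartment",
                                 guess_compartment(one(m, "id"))),
               formula = one(m, "formula"),
               stringsAsFactors = FALSE)
  }))
  sto <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    rev_default <- is.null(r$lower_bound) &&
      isTRUE(as.logical(r$reversibility %||% TRUE))
    lb <- if (!is.null(r$lower_bound)) as.numeric(r$lower_bound)
          else if (rev_default) -DEFAULT_BOUND else 0
    ub <- if (!is.null(r$upper_bound)) as.numeric(r$upper_bound)
          else DEFAULT_BOUND
    data.frame(id = one(r, "id"),
               name = one(r, "name", one(r, "id")),
               lower_bound = lb, upper_bound = ub,
               subsystem = one(r, "subsystem", ""),
               gpr = one(r, "gene_reaction_rule", ""),
               stringsAsFactors = FALSE)
  }))
  rxns$subsystem[is.na(rxns$subsystem)] <- ""
  rxns$gpr[is.na(rxns$gpr)] <- ""
  for (r in doc$reactions) {
    sto[[as.character(r$id)]] <-
      stats::setNames(vapply(r$metabolites, as.numeric, numeric(1)),
                      names(r$metabolites))
  }
  cps <- NULL
  if (!is.null(doc$compartments)) {
    cps <- stats::setNames(vapply(doc$compartments, as.character, character(1)),
                           names(doc$compartments))
  }
  metabolic_model(mets, rxns, sto, compartments = cps)
}

# compartment from a conventional id suffix (_c/_m/_e); SBML compartment
# attributes take precedence over this when both are available
guess_compartment <- function(id) {
  m <- regmatches(id, regexpr("_([a-z])$", id))
  if (length(m) && nzchar(m)) sub("^_", "", m) else "c"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf("cannot parse SBML: %s",
                                                   conditionMessage(e)),
                                           call. = FALSE))
  xml2::xml_ns_strip(doc)
  strip_prefix <- function(x, p) sub(paste0("^", p), "", x)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp <- sp[!vapply(sp, function(s)
    identical(xml2::xml_attr(s, "boundaryCondition"), "true"), logical(1))]
  mets <- data.frame(
    id = strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
    name = ifelse(is.na(xml2::xml_attr(sp, "name")),
                  strip_prefix(xml2::xml_attr(sp, "id"), "M_"),
                  xml2::xml_attr(sp, "name")),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "chemicalFormula"),
    stringsAsFactors = FALSE)

  # fbc parameters for bounds
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  parval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                            xml2::xml_attr(pars, "id"))
  # gene product labels (fbc-prefixed nodes need local-name matching even
  # after namespace stripping)
  gps <- xml2::xml_find_all(doc, ".//*[local-name()='geneProduct']")
  gplab <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(gps, "label")),
           strip_prefix(xml2::xml_attr(gps, "id"), "G_"),
           xml2::xml_attr(gps, "label")),
    xml2::xml_attr(gps, "id"))

  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  sto <- list()
  rows <- lapply(rx, function(r) {
    rid <- strip_prefix(xml2::xml_attr(r, "id"), "R_")
    rev <- !identical(xml2::xml_attr(r, "reversible"), "false")
    lb <- NA_real_; ub <- NA_real_
    lbref <- xml2::xml_attr(r, "lowerFluxBound")
    ubref <- xml2::xml_attr(r, "upperFluxBound")
    if (!is.na(lbref) && lbref %in% names(parval)) lb <- parval[[lbref]]
    if (!is.na(ubref) && ubref %in% names(parval)) ub <- parval[[ubref]]
    if (is.na(lb) || is.na(ub)) {   # legacy kinetic-law bounds
      kl <- xml2::xml_find_all(r, ".//kineticLaw//parameter")
      if (length(kl)) {
        kid <- xml2::xml_attr(kl, "id")
        kv <- as.numeric(xml2::xml_attr(kl, "value"))
        if (is.na(lb) && "LOWER_BOUND" %in% kid) lb <- kv[kid == "LOWER_BOUND"][1]
        if (is.na(ub) && "UPPER_BOUND" %in% kid) ub <- kv[kid == "UPPER_BOUND"][1]
      }
    }
    if (is.na(lb)) lb <- if (rev) -DEFAULT_BOUND else 0
    if (is.na(ub)) ub <- DEFAULT_BOUND

    coef <- numeric(0)
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, paste0("./", side, "/speciesReference"))
      if (length(refs)) {
        ids <- strip_prefix(xml2::xml_attr(refs, "species"), "M_")
        st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
        st[is.na(st)] <- 1
        if (side == "listOfReactants") st <- -st
        for (k in seq_along(ids)) {
          coef[ids[k]] <- (if (ids[k] %in% names(coef)) coef[[ids[k]]] else 0) + st[k]
        }
      }
    }
    coef <- coef[names(coef) %in% mets$id]  # drop boundary species
    sto[[rid]] <<- coef

    gpa <- xml2::xml_find_first(r, ".//*[local-name()='geneProductAssociation']")
    gpr <- if (inherits(gpa, "xml_missing")) "" else sbml_gpa_text(gpa, gplab)
    notes <- xml2::xml_text(xml2::xml_find_first(r, ".//notes"))
    subsystem <- ""
    if (!is.na(notes)) {
      mm <- regmatches(notes, regexpr("SUBSYSTEM:\\s*[^<\n]+", notes))
      if (length(mm)) subsystem <- trimws(sub("SUBSYSTEM:\\s*", "", mm))
    }
    data.frame(id = rid,
               name = ifelse(is.na(xml2::xml_attr(r, "name")), rid,
                             xml2::xml_attr(r, "name")),
               lower_bound = lb, upper_bound = ub,
               subsystem = subsystem, gpr = gpr, stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rows)
  cpn <- xml2::xml_find_all(doc, ".//listOfCompartments/compartment")
  cps <- stats::setNames(
    ifelse(is.na(xml2::xml_attr(cpn, "name")), xml2::xml_attr(cpn, "id"),
           xml2::xml_attr(cpn, "name")),
    xml2::xml_attr(cpn, "id"))
  metabolic_model(mets, rxns, sto, compartments = cps)
}

# render an fbc geneProductAssociation subtree as rule text
sbml_gpa_text <- function(node, gplab) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductAssociation") {
    kids <- xml2::xml_children(node)
    if (length(kids) == 0L) return("")
    return(sbml_gpa_text(kids[[1]], gplab))
  }
  if (nm == "geneProductRef") {
    ref <- xml2::xml_attr(node, "geneProduct")
    return(if (ref %in% names(gplab)) gplab[[ref]] else sub("^G_", "", ref))
  }
  op <- switch(nm, and = " and ", or = " or ",
               stop(sprintf("unsupported GPR node '%s' in SBML", nm),
                    call. = FALSE))
  parts <- vapply(xml2::xml_children(node), sbml_gpa_text, character(1),
                  gplab = gplab)
  paste0("(", paste(parts, collapse = op), ")")
}

#' Write a model to the community JSON dialect
#'
#' The emitted file reloads with [load_model()] to an equivalent model (ids,
#' names, stoichiometry, bounds, subsystem and GPR text preserved).
#'
#' @param model a `metabolic_model`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    sto <- model$stoichiometry[[r$id]]
    list(id = r$id, name = r$name,
         metabolites = as.list(stats::setNames(as.numeric(sto), names(sto))),
         lower_bound = r$lower_bound, upper_bound = r$upper_bound,
         subsystem = r$subsystem,
         gene_reaction_rule = r$gpr)
  })
  doc <- list(id = "model",
              compartments = as.list(model$compartments),
              metabolites = mets, reactions = rxns)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
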