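test_that("enzyme-reaction pairing follows GPR membership", {
  m <- generate_toy_astrocyte_model()
  pr <- pair_enzyme_reactions(c("PYGB", "NOTINMODEL", "COX4I1"), m)
  expect_equal(pr$pairs$reaction_id[pr$pairs$enzyme == "PYGB"], "GP")
  expect_equal(pr$unmapped, "NOTINMODEL")
  # a symbol appearing in two reactions' GPRs yields two pairs
  expect_setequal(pr$pairs$reaction_id[pr$pairs$enzyme == "COX4I1"],
                  c("OXPHOS_NADH", "OXPHOS_FADH2"))
})

test_that("every passing DEP symbol lands in rows or in the unmapped list", {
  expt <- generate_synthetic_proteomics(proteomics_spec(seed = 2))
  fl <- filter_deps(bh_fill(compute_differential(expt)))
  m <- generate_toy_astrocyte_model()
  pr <- pair_enzyme_reactions(fl, m)
  expect_setequal(c(unique(pr$pairs$enzyme), pr$unmapped), fl$passing$gene)
  expect_length(intersect(unique(pr$pairs$enzyme), pr$unmapped), 0L)
})

make_changes <- function(model, pct, types = NULL) {
  ids <- model$reactions$id
  ch <- data.frame(reaction_id = ids,
                   subsystem = model$reactions$subsystem,
                   v_steady = 1, v_cond = 1 + pct[ids] / 100,
                   pct_change = unname(pct[ids]),
                   change_type = if (is.null(types)) "finite"
                                 else unname(types[ids]),
                   robust = NA, enzymes = "", stringsAsFactors = FALSE)
  if (is.null(types)) ch$change_type <- ifelse(is.na(ch$pct_change),
                                               "newly_active", "finite")
  class(ch) <- c("flux_changes", "data.frame")
  ch
}

test_that("split-heatmap concordance follows the sign rule", {
  m <- generate_toy_astrocyte_model()
  deps <- data.frame(gene = c("PKM", "LDHA", "PYGB"),
                     log2fc = c(1, -0.5, 2),
                     pvalue = 0.01, qvalue = 0.01)
  class(deps) <- c("dep_table", "data.frame")
  pr <- pair_enzyme_reactions(deps$gene, m)
  pct <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  pct[["GLYC"]] <- 25; pct[["LDH"]] <- 15; pct[["GP"]] <- NA
  ch <- make_changes(m, pct)
  it <- build_split_heatmap(pr, deps, list(hypoxia = ch, acidosis = ch,
                                           combined = ch))
  expect_true(it$concordant_hypoxia[it$enzyme == "PKM"])       # +1 vs +25 %
  expect_false(it$concordant_hypoxia[it$enzyme == "LDHA"])     # -0.5 vs +15 %
  expect_true(is.na(it$concordant_hypoxia[it$enzyme == "PYGB"])) # sentinel
  # rows are sorted by subsystem, enzyme, reaction
  expect_equal(it[order(it$subsystem, it$enzyme, it$reaction_id), ],
               it, ignore_attr = TRUE)
  expect_error(build_split_heatmap(pr, deps, list(hypoxia = ch)),
               "acidosis")
})

test_that("concordance fractions count applicable cells only", {
  m <- generate_toy_astrocyte_model()
  deps <- data.frame(gene = c("PKM", "LDHA"), log2fc = c(1, -1),
                     pvalue = 0.01, qvalue = 0.01)
  class(deps) <- c("dep_table", "data.frame")
  pr <- pair_enzyme_reactions(deps$gene, m)
  pct <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  pct[["GLYC"]] <- 30; pct[["LDH"]] <- -40
  ch <- make_changes(m, pct)
  it <- build_split_heatmap(pr, deps, list(h = ch), conditions = "h")
  sc <- concordance_score(it)
  ov <- sc[sc$subsystem == "(all)", ]
  expect_equal(ov$fraction, 1.0)        # both applicable cells concordant
  expect_equal(ov$n_applicable, 2L)

  # none concordant
  deps2 <- deps; deps2$log2fc <- -deps$log2fc
  it2 <- build_split_heatmap(pr, deps2, list(h = ch), conditions = "h")
  expect_equal(concordance_score(it2)$fraction[1], 0.0)

  # no applicable cells: undefined, not zero
  pct0 <- stats::setNames(rep(0, nrow(m$reactions)), m$reactions$id)
  it0 <- build_split_heatmap(pr, deps, list(h = make_changes(m, pct0)),
                             conditions = "h")
  expect_true(is.na(concordance_score(it0)$fraction[1]))

  # shuffling rows leaves the summary unchanged
  shuf <- it[sample(nrow(it)), ]
  class(shuf) <- class(it)
  attr(shuf, "conditions") <- attr(it, "conditions")
  expect_equal(concordance_score(shuf), sc)
})

test_that("end-to-end fixture is fully concordant; one sign flip costs 1/n", {
  run <- run_pipeline()
  ov <- run$concordance[run$concordance$subsystem == "(all)" &
                          run$concordance$condition == "hypoxia", ]
  expect_gte(ov$n_applicable, 2L)
  expect_equal(ov$fraction, 1.0)

  # flip one planted enzyme whose reaction responds to hypoxia
  planted <- proteomics_spec()$planted
  planted[["NDUFA11"]] <- -planted[["NDUFA11"]]
  expt <- generate_synthetic_proteomics(proteomics_spec(planted = planted))
  fl <- filter_deps(bh_fill(compute_differential(expt)))
  pr <- pair_enzyme_reactions(fl, run$model)
  it <- build_split_heatmap(pr, fl,
                            lapply(run$conditions, `[[`, "changes"),
                            conditions = names(run$conditions))
  sc <- concordance_score(it)
  ov2 <- sc[sc$subsystem == "(all)" & sc$condition == "hypoxia", ]
  expect_equal(ov2$n_applicable, ov$n_applicable)
  expect_equal(ov2$fraction, 1 - 1 / ov2$n_applicable, tolerance = 1e-12)
})
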