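# builds a flux_distribution by hand over a model's reactions
manual_dist <- function(model, values) {
  fl <- stats::setNames(numeric(nrow(model$reactions)), model$reactions$id)
  fl[names(values)] <- values
  structure(list(fluxes = fl, status = "optimal",
                 objective_values = numeric(0)),
            class = "flux_distribution")
}

test_that("percent changes follow the signed convention with sentinels", {
  m <- toy_chain_model()
  a <- manual_dist(m, c(EX_glc_e = -1, GLCt = 1.0, CONV = -0.5, SINK = 0))
  b <- manual_dist(m, c(EX_glc_e = -1, GLCt = 1.3, CONV = -0.6, SINK = 0.2))
  ch <- compute_percent_changes(a, b, m)
  expect_equal(ch$pct_change[ch$reaction_id == "GLCt"], 30)
  # negative fluxes: denominator is |v_steady|, direction preserved
  expect_equal(ch$pct_change[ch$reaction_id == "CONV"], -20)
  expect_equal(ch$change_type[ch$reaction_id == "SINK"], "newly_active")
  expect_true(is.na(ch$pct_change[ch$reaction_id == "SINK"]))
  ch2 <- compute_percent_changes(b, a, m)
  expect_equal(ch2$change_type[ch2$reaction_id == "SINK"], "silenced")
  expect_equal(ch2$pct_change[ch2$reaction_id == "EX_glc_e"], 0)
  expect_equal(ch2$change_type[ch2$reaction_id == "EX_glc_e"], "finite")

  # zero in both states
  z <- compute_percent_changes(a, a, m)
  expect_equal(z$pct_change[z$reaction_id == "SINK"], 0)
  expect_equal(z$change_type[z$reaction_id == "SINK"], "zero")

  # mismatched reaction sets are rejected with the symmetric difference
  bb <- b
  names(bb$fluxes)[2] <- "OTHER"
  expect_error(compute_percent_changes(a, bb, m), "OTHER")
})

test_that("antisymmetry identity holds on random flux pairs", {
  m <- toy_chain_model()
  set.seed(11)
  for (i in 1:25) {
    va <- stats::runif(4, 0.1, 2) * sample(c(-1, 1), 4, replace = TRUE)
    vb <- stats::runif(4, 0.1, 2) * sample(c(-1, 1), 4, replace = TRUE)
    a <- manual_dist(m, stats::setNames(va, m$reactions$id))
    b <- manual_dist(m, stats::setNames(vb, m$reactions$id))
    ab <- compute_percent_changes(a, b, m)$pct_change
    ba <- compute_percent_changes(b, a, m)$pct_change
    expect_equal(ab, -ba * abs(vb) / abs(va), tolerance = 1e-9)
  }
})

test_that("robust flagging is strict at the threshold and monotone in it", {
  m <- toy_chain_model()
  a <- manual_dist(m, c(EX_glc_e = -1, GLCt = 1, CONV = 1, SINK = 1))
  b <- manual_dist(m, c(EX_glc_e = -1.1, GLCt = 1.1, CONV = 0.875,
                        SINK = 1.05))
  ch <- compute_percent_changes(a, b, m)
  # +10.000000% exactly: "exceeding" read strictly, not robust
  fl <- flag_robust(ch, threshold = 10)
  expect_false(fl$robust[fl$reaction_id == "GLCt"])
  expect_true(fl$robust[fl$reaction_id == "CONV"])    # -12.5 %
  expect_false(fl$robust[fl$reaction_id == "SINK"])   # +5 %
  expect_equal(attr(fl, "n_robust"), sum(fl$robust))

  # sentinels are always robust
  s <- manual_dist(m, c(EX_glc_e = -1.1, GLCt = 1.1, CONV = 0.875, SINK = 0))
  fs <- flag_robust(compute_percent_changes(a, s, m), threshold = 1e6)
  expect_true(fs$robust[fs$reaction_id == "SINK"])

  counts <- vapply(c(0, 5, 10, 12.5, 20, 50),
                   function(th) attr(flag_robust(ch, th), "n_robust"),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(flag_robust(ch, threshold = -1), "nonnegative")
})

test_that("subsystem summaries aggregate correctly and ignore row order", {
  m <- generate_toy_astrocyte_model()
  base <- stats::setNames(rep(1, nrow(m$reactions)), m$reactions$id)
  pert <- base
  pert[["GLYC"]] <- 1.2; pert[["LDH"]] <- 1.4     # Glycolysis: +20 %, +40 %
  pert[["OXPHOS_NADH"]] <- 0                      # silenced sentinel
  ch <- flag_robust(compute_percent_changes(
    manual_dist(m, base), manual_dist(m, pert), m))
  sm <- summarize_subsystems(ch)
  gly <- sm[sm$subsystem == "Glycolysis", ]
  expect_equal(gly$mean_pct_change, mean(c(20, 40, 0)))  # PFKFB unchanged
  expect_equal(gly$n_robust, 2L)
  oxp <- sm[sm$subsystem == "OxPhos", ]
  expect_equal(oxp$n_sentinel, 1L)
  expect_equal(oxp$n_robust, 1L)
  # sentinel excluded from the mean (remaining OxPhos reactions unchanged)
  expect_equal(oxp$mean_pct_change, 0)
  # totals partition the reaction set
  expect_equal(sum(sm$n_reactions), nrow(m$reactions))
  # order invariance
  shuf <- ch[sample(nrow(ch)), ]
  class(shuf) <- class(ch)
  expect_equal(summarize_subsystems(shuf), sm)
})

test_that("enzyme attribution covers every reaction", {
  m <- generate_toy_astrocyte_model()
  enz <- map_reaction_enzymes(m)
  expect_setequal(names(enz), m$reactions$id)
  expect_equal(enz[["GP"]], list("PYGB"))
  expect_equal(enz[["EX_glc_e"]], list())
  expect_equal(enz[["MAS"]], list(c("GOT1", "MDH1")))
})

test_that("physiology checks pass on the glycogen-turnover steady state", {
  m <- generate_toy_astrocyte_model(
    toy_model_spec(include_glycogen_turnover = TRUE))
  d <- solve_lexicographic(m, m$objective)
  rep <- check_physiology(d, m)
  expect_true(all(rep$pass))

  # an all-zero flux vector fails every check
  z <- manual_dist(m, c(GLYC = 0))
  repz <- check_physiology(z, m)
  expect_false(any(repz$pass))

  # bindings must resolve
  expect_error(check_physiology(d, m, bindings = c(GS = "GS", GP = "NOPE",
                                                   PFKFB = "PFKFB",
                                                   LDH = "LDH")),
               "GP.*NOPE")
  expect_error(check_physiology(d, m, bindings = c(GS = "GS", PFKFB = "PFKFB",
                                                   LDH = "LDH")),
               "missing physiology binding")
})
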