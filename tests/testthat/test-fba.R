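test_that("FBA solves the hand-checked chain and reports statuses faithfully", {
  m <- toy_chain_model(uptake = 1)
  r <- solve_fba(m, objective_tier(c(SINK = 1), "max"))
  expect_equal(r$status, "optimal")
  expect_equal(r$objective_values, 2.0, tolerance = 1e-12)
  expect_lte(max(abs(build_stoichiometric_matrix(m) %*% r$fluxes)), 1e-9)

  # degenerate all-zero objective
  r0 <- solve_fba(m, objective_tier(c(SINK = 0), "max"))
  expect_equal(r0$status, "optimal")
  expect_equal(r0$objective_values, 0)

  # forcing flux through a reaction whose substrate has no source
  m2 <- set_bounds(toy_chain_model(uptake = 0), "CONV", lb = 1)
  ri <- solve_fba(m2, objective_tier(c(SINK = 1), "max"))
  expect_equal(ri$status, "infeasible")
  expect_null(ri$fluxes)
})

test_that("lexicographic tiers retain earlier optima; glutamate cycling hits its uptake bound", {
  m <- generate_toy_astrocyte_model()
  obj <- m$objective
  r <- solve_lexicographic(m, obj)
  expect_equal(r$status, "optimal")
  # tier 2: glutamate/glutamine cycle saturates the glutamate uptake bound
  expect_equal(r$objective_values[2], 0.232, tolerance = 1e-9)
  # the parsimonious representative may give away the delta retention slack
  expect_equal(unname(r$fluxes[["GLNS"]]), 0.232, tolerance = 1e-5)
  # tier-1 retention on the returned fluxes
  expect_gte(r$fluxes[["ATPM"]], (1 - 1e-6) * r$objective_values[1] - 1e-9)

  # single-tier lexicographic equals solve_fba + pFBA
  one <- objective_spec(objective_tier(c(ATPM = 1), "max"))
  r1 <- solve_lexicographic(m, one)
  expect_equal(r1$objective_values, solve_fba(m, one)$objective_values,
               tolerance = 1e-9)
  expect_equal(r1$fluxes, solve_pfba(m, one)$fluxes, tolerance = 1e-9)

  # two identical tiers give the same optimum twice
  twice <- objective_spec(objective_tier(c(ATPM = 1), "max"),
                          objective_tier(c(ATPM = 1), "max"))
  r2 <- solve_lexicographic(m, twice)
  expect_equal(r2$objective_values[1], r2$objective_values[2],
               tolerance = 1e-8)
})

# two parallel routes doing the same conversion, one direct (A) and one in
# two steps (B1+B2); any split is FBA-optimal, pFBA must route through A
parallel_routes_model <- function() {
  mets <- data.frame(id = c("s_e", "s_c", "i_c", "p_c"),
                     name = c("substrate", "substrate", "intermediate",
                              "product"),
                     compartment = c("e", "c", "c", "c"))
  rxns <- data.frame(
    id = c("EX_s_e", "UP", "A", "B1", "B2", "DM"),
    name = c("exchange", "uptake", "direct", "step1", "step2", "demand"),
    lower_bound = c(-1, 0, 0, 0, 0, 0), upper_bound = c(0, rep(1000, 5)),
    subsystem = "x", gpr = "")
  sto <- list(EX_s_e = c(s_e = -1), UP = c(s_e = -1, s_c = 1),
              A = c(s_c = -1, p_c = 1), B1 = c(s_c = -1, i_c = 1),
              B2 = c(i_c = -1, p_c = 1), DM = c(p_c = -1))
  metabolic_model(mets, rxns, sto)
}

test_that("pFBA picks the shortest of two parallel routes", {
  m <- parallel_routes_model()
  obj <- objective_spec(objective_tier(c(DM = 1), "max"))
  r <- solve_pfba(m, obj)
  expect_equal(r$objective_values[1], 1, tolerance = 1e-9)
  expect_equal(unname(r$fluxes[["A"]]), 1, tolerance = 1e-5)
  expect_equal(unname(r$fluxes[["B1"]]), 0, tolerance = 1e-5)

  # network with unique optimum: pFBA equals FBA
  mc <- toy_chain_model()
  oc <- objective_spec(objective_tier(c(SINK = 1), "max"))
  expect_equal(solve_pfba(mc, oc)$fluxes, solve_fba(mc, oc)$fluxes,
               tolerance = 1e-5)

  # zero demand: the all-zero vector is the parsimonious optimum
  mz <- set_bounds(m, "DM", ub = 0)
  rz <- solve_pfba(mz, obj)
  expect_equal(max(abs(rz$fluxes)), 0, tolerance = 1e-9)
})

test_that("pFBA total flux never exceeds the plain FBA solution's", {
  set.seed(7)
  m <- generate_toy_astrocyte_model()
  obj <- objective_spec(objective_tier(c(ATPM = 1), "max"))
  vf <- solve_lexicographic(m, obj, parsimonize = FALSE)$fluxes
  vp <- solve_pfba(m, obj)$fluxes
  expect_lte(sum(abs(vp)), sum(abs(vf)) + 1e-9)
})

test_that("optimal fluxes scale linearly with all bounds (equivariance)", {
  m <- generate_toy_astrocyte_model()
  obj <- objective_spec(objective_tier(c(ATPM = 1), "max"))
  lam <- 2.5
  ms <- m
  ms$reactions$lower_bound <- lam * ms$reactions$lower_bound
  ms$reactions$upper_bound <- lam * ms$reactions$upper_bound
  r1 <- solve_pfba(m, obj)
  r2 <- solve_pfba(ms, obj)
  expect_equal(r2$objective_values[1], lam * r1$objective_values[1],
               tolerance = 1e-8)
  expect_equal(unname(r2$fluxes), unname(lam * r1$fluxes), tolerance = 1e-6)
})

test_that("FVA brackets alternate optima and collapses on unique ones", {
  m <- parallel_routes_model()
  obj <- objective_spec(objective_tier(c(DM = 1), "max"))
  fva <- run_fva(m, obj, retention = 1.0)
  a <- fva[fva$reaction_id == "A", ]
  expect_equal(c(a$min, a$max), c(0, 1), tolerance = 1e-8)
  b1 <- fva[fva$reaction_id == "B1", ]
  expect_equal(c(b1$min, b1$max), c(0, 1), tolerance = 1e-8)

  # irreversible reaction with no feasible support is pinned at [0, 0]
  mdead <- parallel_routes_model()
  mdead$metabolites <- rbind(mdead$metabolites,
                             data.frame(id = "d_c", name = "dead",
                                        compartment = "c",
                                        formula = NA_character_))
  mdead$reactions <- rbind(mdead$reactions,
                           data.frame(id = "DEAD", name = "dead",
                                      lower_bound = 0, upper_bound = 1000,
                                      subsystem = "x", gpr = ""))
  mdead$stoichiometry$DEAD <- c(s_c = -1, d_c = 1)
  fvad <- run_fva(mdead, obj, retention = 1.0, reactions = "DEAD")
  expect_equal(c(fvad$min, fvad$max), c(0, 0), tolerance = 1e-8)

  # unique-optimum model: ranges degenerate to the FBA fluxes
  mc <- toy_chain_model()
  oc <- objective_spec(objective_tier(c(SINK = 1), "max"))
  fvac <- run_fva(mc, oc, retention = 1.0)
  v <- solve_fba(mc, oc)$fluxes
  expect_equal(fvac$min, unname(v[fvac$reaction_id]), tolerance = 1e-8)
  expect_equal(fvac$max, unname(v[fvac$reaction_id]), tolerance = 1e-8)

  # any optimal flux lies within the FVA bracket
  m2 <- generate_toy_astrocyte_model()
  obj2 <- objective_spec(objective_tier(c(ATPM = 1), "max"))
  fva2 <- run_fva(m2, obj2, retention = 1.0,
                  reactions = c("GLYC", "LDH", "OXPHOS_NADH", "PYRt"))
  vp <- solve_pfba(m2, obj2)$fluxes
  for (i in seq_len(nrow(fva2))) {
    vi <- vp[[fva2$reaction_id[i]]]
    expect_gte(vi, fva2$min[i] - 1e-7)
    expect_lte(vi, fva2$max[i] + 1e-7)
  }
})

test_that("solution verification accepts optima and flags corruption", {
  m <- toy_chain_model()
  r <- solve_fba(m, objective_tier(c(SINK = 1), "max"))
  rep <- verify_solution(m, r)
  expect_true(rep$ok)
  expect_lte(rep$max_residual, 1e-8)

  bad <- r
  bad$fluxes[["CONV"]] <- bad$fluxes[["CONV"]] + 1
  repb <- verify_solution(m, bad)
  expect_false(repb$ok)
  expect_gt(repb$max_residual, 0.5)

  inf <- structure(list(fluxes = NULL, status = "infeasible",
                        objective_values = numeric(0)),
                   class = "flux_distribution")
  repi <- verify_solution(m, inf)
  expect_false(repi$verifiable)
})
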