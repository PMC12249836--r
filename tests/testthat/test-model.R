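test_that("JSON round trip preserves the model", {
  m <- generate_toy_astrocyte_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  m2 <- load_model(path)
  expect_equal(nrow(m2$reactions), nrow(m$reactions))
  expect_equal(m2$reactions$id, m$reactions$id)
  expect_equal(m2$reactions$lower_bound, m$reactions$lower_bound)
  expect_equal(m2$reactions$upper_bound, m$reactions$upper_bound)
  expect_equal(m2$reactions$subsystem, m$reactions$subsystem)
  expect_equal(m2$reactions$gpr, m$reactions$gpr)
  expect_equal(m2$metabolites$id, m$metabolites$id)
  expect_equal(m2$metabolites$compartment, m$metabolites$compartment)
  for (rid in m$reactions$id) {
    expect_equal(m2$stoichiometry[[rid]][order(names(m2$stoichiometry[[rid]]))],
                 m$stoichiometry[[rid]][order(names(m$stoichiometry[[rid]]))],
                 info = rid)
  }
  # a second write/reload cycle is byte-stable
  path2 <- withr::local_tempfile(fileext = ".json")
  write_model_json(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("loader rejects undeclared metabolites, naming the reaction", {
  doc <- list(
    metabolites = list(list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(list(id = "BAD", name = "bad",
                          metabolites = list(a_c = -1, xyz_c = 1),
                          lower_bound = 0, upper_bound = 10)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(load_model(path), "BAD.*xyz_c")
  expect_error(load_model(tempfile(fileext = ".json")), "not found")
})

test_that("missing bounds default by reversibility", {
  doc <- list(
    metabolites = list(list(id = "a_e", name = "a", compartment = "e"),
                       list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(
      list(id = "EX_a_e", name = "ex", metabolites = list(a_e = -1)),
      list(id = "T1", name = "t1", metabolites = list(a_e = -1, a_c = 1),
           reversibility = FALSE),
      list(id = "DM", name = "dm", metabolites = list(a_c = -1),
           lower_bound = 0)))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  m <- load_model(path)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "EX_a_e"], -1000)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "EX_a_e"], 1000)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "T1"], 0)
  expect_equal(m$reactions$lower_bound[m$reactions$id == "DM"], 0)
})

test_that("stoichiometric matrix reproduces reaction definitions", {
  m <- toy_chain_model()
  S <- build_stoichiometric_matrix(m)
  expect_equal(dim(S), c(3L, 4L))
  expect_equal(S[, "CONV"], c(glc_e = 0, glc_c = -1, atp_c = 2))
  # exchange column has exactly one nonzero entry
  expect_equal(sum(S[, "EX_glc_e"] != 0), 1L)
  # rebuilding every reaction from its column reproduces the stoichiometry
  for (rid in m$reactions$id) {
    col <- S[, rid]
    rebuilt <- col[col != 0]
    sto <- m$stoichiometry[[rid]]
    expect_equal(rebuilt[order(names(rebuilt))], sto[order(names(sto))],
                 info = rid)
  }
})

test_that("validation reports violations, dead ends and zero-locked reactions", {
  m <- toy_chain_model()
  expect_length(validate_model(m)$violations, 0L)

  bad <- m
  bad$reactions$lower_bound[3] <- 5
  bad$reactions$upper_bound[3] <- 1
  rep <- validate_model(bad)
  expect_match(rep$violations, "lower_bound > upper_bound.*CONV", all = FALSE)

  orphaned <- m
  orphaned$metabolites <- rbind(
    orphaned$metabolites,
    data.frame(id = "unused_c", name = "unused", compartment = "c",
               formula = NA_character_))
  rep2 <- validate_model(orphaned)
  expect_length(rep2$violations, 0L)
  expect_true("unused_c" %in% rep2$orphans)
  expect_true("unused_c" %in% rep2$dead_ends)

  locked <- m
  locked$reactions$lower_bound[4] <- 0
  locked$reactions$upper_bound[4] <- 0
  expect_equal(validate_model(locked)$zero_locked, "SINK")

  # the constructor enforces hard invariants
  expect_error(
    metabolic_model(m$metabolites,
                    m$reactions,
                    c(m$stoichiometry[-3],
                      list(CONV = c(glc_c = -1, nope_c = 1)))),
    "CONV.*nope_c")
})

test_that("an SBML level-3 fbc model loads with bounds and GPRs", {
  path <- test_path("fixtures", "mini_fbc.xml")
  m <- load_model(path)
  expect_s3_class(m, "metabolic_model")
  expect_equal(sort(m$metabolites$id), c("atp_c", "glc_c", "glc_e"))
  r <- m$reactions
  expect_equal(r$lower_bound[r$id == "EX_glc_e"], -0.19)
  expect_equal(r$upper_bound[r$id == "GLYC"], 1000)
  expect_equal(parse_gpr(r$gpr[r$id == "GLYC"])$complexes,
               list(c("HK1", "PKM"), "PYGB"))
  expect_equal(m$stoichiometry$GLYC[["atp_c"]], 2)
  # kinetic-law fallback bound
  expect_equal(r$lower_bound[r$id == "ATPM"], 0.1)
})
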