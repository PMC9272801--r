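# Model container, serialization, medium handling, target resolution.

test_that("JSON and SBML serialization round-trip field-for-field", {
  m <- toy_redox_model()
  for (fmt in c("json", "sbml")) {
    path <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m, path, format = fmt)
    m2 <- resolve_target(load_model(path), "EXP")
    expect_equal(m2[names(m)], m[names(m)], info = fmt)
    # load -> save -> load is a fixed point
    path2 <- tempfile(fileext = if (fmt == "json") ".json" else ".xml")
    write_model(m2, path2, format = fmt)
    m3 <- resolve_target(load_model(path2), "EXP")
    expect_equal(m3[names(m2)], m2[names(m2)], info = fmt)
    unlink(c(path, path2))
  }
})

test_that("COBRApy reads the serialized formats and agrees on the optimum", {
  m <- toy_redox_model()
  jp <- tempfile(fileext = ".json"); xp <- tempfile(fileext = ".xml")
  write_model(m, jp); write_model(m, xp)
  script <- sprintf(paste0(
    "import cobra\n",
    "a = cobra.io.load_json_model('%s')\n",
    "b = cobra.io.read_sbml_model('%s')\n",
    "print(len(a.metabolites), len(a.reactions), a.optimize().objective_value)\n",
    "print(len(b.metabolites), len(b.reactions), b.optimize().objective_value)\n"),
    jp, xp)
  sf <- tempfile(fileext = ".py"); writeLines(script, sf)
  out <- suppressWarnings(system2("python", sf, stdout = TRUE, stderr = FALSE))
  unlink(c(jp, xp, sf))
  nums <- lapply(strsplit(out, " "), as.numeric)
  for (row in nums) {
    expect_equal(row[1], 4)    # metabolites
    expect_equal(row[2], 7)    # reactions
    expect_equal(row[3], fba_max_growth(m), tolerance = 1e-6)
  }
})

test_that("structural invariants are enforced", {
  m <- toy_redox_model()
  expect_error(
    metabolic_model(m$metabolite_ids, m$reaction_ids, m$stoich,
                    lb = replace(m$lb, 3, 5), ub = replace(m$ub, 3, 1),
                    objective_index = m$objective_index),
    "lb > ub")
  expect_error(
    metabolic_model(m$metabolite_ids, m$reaction_ids, m$stoich,
                    m$lb, m$ub, objective_index = 4, target_index = 4),
    "differ from the biomass")
  # bound capping keeps every LP bounded
  m2 <- metabolic_model(m$metabolite_ids, m$reaction_ids, m$stoich,
                        lb = rep(-Inf, 7), ub = rep(Inf, 7),
                        objective_index = 4)
  expect_true(all(m2$lb == -1000) && all(m2$ub == 1000))
  expect_true(all(m$exchange_flags ==
                    (Matrix::colSums(m$stoich != 0) == 1)))
})

test_that("a model file without a declared objective is rejected", {
  m <- toy_redox_model()
  path <- tempfile(fileext = ".json")
  write_model(m, path)
  doc <- jsonlite::read_json(path)
  doc$reactions <- lapply(doc$reactions, function(r) {
    r$objective_coefficient <- NULL; r
  })
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_model(path), "no objective")
  unlink(path)
})

test_that("apply_medium sets listed bounds and closes unlisted uptakes", {
  m <- toy_redox_model()
  out <- apply_medium(m, data.frame(exchange_id = "SRC", lb = 0, ub = 10))
  expect_equal(out[names(m)], m[names(m)])  # toy already in this medium
  # richer uptake allowed
  out2 <- apply_medium(m, data.frame(exchange_id = "SRC", lb = 0, ub = 4))
  expect_equal(out2$ub[1], 4)
  expect_equal(out2$ub[-1], m$ub[-1])
  # empty medium: all uptakes closed, no growth possible
  starved <- apply_medium(m, data.frame(exchange_id = character(0),
                                        lb = numeric(0), ub = numeric(0)))
  expect_equal(as.numeric(fba_max_growth(starved)), 0)
  expect_error(
    apply_medium(m, data.frame(exchange_id = "GRW", lb = 0, ub = 1)),
    "not exchange")
  expect_error(
    apply_medium(m, data.frame(exchange_id = "NOPE", lb = 0, ub = 1)),
    "unknown reaction")
})

test_that("medium plus knockout never enlarges any flux bound interval", {
  m <- toy_redox_model()
  med <- apply_medium(m, data.frame(exchange_id = "SRC", lb = 0, ub = 6))
  set.seed(42)
  for (rep in 1:20) {
    ko <- sample(7, sample(0:3, 1))
    lb2 <- med$lb; ub2 <- med$ub
    lb2[ko] <- 0; ub2[ko] <- 0
    expect_true(all(lb2 >= m$lb - 1e-12))
    expect_true(all(ub2 <= m$ub + 1e-12))
  }
})

test_that("target resolution handles reactions, metabolites and demands", {
  m <- toy_redox_model()
  m$target_index <- NA_integer_
  byrxn <- resolve_target(m, "EXP")
  expect_equal(byrxn$target_index, 7L)
  bymet <- resolve_target(m, "P")
  expect_equal(bymet$target_index, 7L)
  expect_error(resolve_target(m, "GRW"), "not an exchange")
  expect_error(resolve_target(m, "B"), "no exchange reaction")
  expect_error(resolve_target(m, "ZZZ"), "matches no reaction or metabolite")
  withdm <- resolve_target(m, "B", add_demand = TRUE)
  expect_equal(withdm$reaction_ids[withdm$target_index], "DM_B")
  expect_equal(withdm$lb[withdm$target_index], 0)
  expect_equal(withdm$ub[withdm$target_index], 1000)
  validate_model(withdm)
})

test_that("medium files read back with the expected columns", {
  path <- tempfile(fileext = ".tsv")
  writeLines("exchange_id\tlb\tub\nSRC\t0\t10", path)
  med <- read_medium(path)
  expect_equal(med, data.frame(exchange_id = "SRC", lb = 0, ub = 10))
  writeLines("id\tlow\thigh\nSRC\t0\t10", path)
  expect_error(read_medium(path), "must have columns")
  unlink(path)
})
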