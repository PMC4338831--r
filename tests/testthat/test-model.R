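test_that("quantity strings parse to internal units", {
  expect_equal(parse_quantity("75 nM"), 7.5e-8)
  expect_equal(parse_quantity("1 uM"), 1e-6)
  expect_equal(parse_quantity("5 mM"), 5e-3)
  expect_equal(parse_quantity("48 h"), 172800)
  expect_equal(parse_quantity("60 s"), 60)
  expect_equal(parse_quantity(3.5), 3.5)
  expect_equal(parse_quantity("2 d"), 2 * 86400)
  expect_error(parse_quantity("10 furlongs"), "unknown unit")
  expect_error(parse_quantity("abc"), "cannot parse")
})

test_that("the reference network has the expected Phase 0-III structure", {
  m <- reference_model_cached()
  # exactly one Phase 0 efflux reaction, acting on cytoplasmic drug
  phase0 <- Filter(function(rx) {
    identical(rx$law$species$enzyme, "ABC0")
  }, m$reactions)
  expect_length(phase0, 1)
  expect_identical(phase0[[1]]$law$species$substrate, "X_c")
  expect_identical(names(which(phase0[[1]]$stoich > 0)), "X_e")

  # bookkeeping species for the exported conjugates
  roles <- vapply(m$species, `[[`, character(1), "role")
  expect_setequal(names(roles)[roles == "bookkeeping"], c("Xpp_e", "Xpp_be"))

  # X_e is the boundary drug pool
  expect_true(m$species$X_e$boundary)
  expect_identical(m$species$X_e$role, "drug")

  # partitioned laws: GST and ABCIII each shared between the xenobiotic and
  # background branches
  part <- Filter(function(rx) {
    rx$law$variant == "MichaelisMentenPartitioned"
  }, m$reactions)
  enzymes <- vapply(part, function(rx) rx$law$species$enzyme, character(1))
  expect_equal(sort(unname(enzymes)), c("ABCIII", "ABCIII", "GST", "GST"))

  # no dimerization anywhere: all stoichiometric coefficients are +-1
  coefs <- unlist(lapply(m$reactions, `[[`, "stoich"))
  expect_true(all(abs(coefs) == 1))

  expect_equal(validation_errors(validate_model(m)), 0)
})

test_that("a CYP knockout leaves the oxidized metabolite at background", {
  m0 <- build_reference_model(list(CYP_kcat = 0))
  p <- sim_protocol(xe = "300 nM", duration = hours(6))
  st <- pre_equilibrate(m0, p)
  tr <- simulate_model(m0, p, initial = st)
  # the only X'_c source is background-independent oxidation; knocked out,
  # its concentration never rises above the (zero) pre-equilibration level
  expect_lte(max(tr$conc[, "Xp_c"]), 1e-15)
  # background conjugation still runs
  expect_gt(tr$conc[nrow(tr$conc), "Xp_bc"], 0)
})

test_that("parameter multipliers scale copies and reject bad input", {
  m <- reference_model_cached()
  m1 <- apply_parameter_multiplier(m, "GST_Km", 1)
  expect_identical(m1$parameters, m$parameters)
  m2 <- apply_parameter_multiplier(m, "GST_Km", 10)
  expect_equal(m2$parameters[["GST_Km"]], 10 * m$parameters[["GST_Km"]])
  # the input model is untouched
  expect_identical(m$parameters[["GST_Km"]],
                   reference_parameters()[["GST_Km"]])
  expect_error(apply_parameter_multiplier(m, "no_such_par", 2), "unknown")
  expect_error(apply_parameter_multiplier(m, "GST_Km", 0), "positive")
  expect_error(apply_parameter_multiplier(m, "GST_Km", -1), "positive")
})

test_that("overrides accept zero and reject unknown ids", {
  m <- build_reference_model(list(CYP_kcat = 0))
  expect_equal(m$parameters[["CYP_kcat"]], 0)
  expect_error(build_reference_model(list(not_a_par = 1)), "unknown")
})

test_that("validation flags structural defects", {
  good <- tiny_model()
  expect_equal(validation_errors(validate_model(good)), 0)

  bad_km <- tiny_model()
  bad_km$reactions$conv$law$params$k <- -1
  rep1 <- validate_model(bad_km)
  expect_equal(validation_errors(rep1), 1)
  expect_match(rep1$location[rep1$severity == "error"], "conv")

  bad_comp <- tiny_model()
  bad_comp$species$A$compartment <- "nowhere"
  rep2 <- validate_model(bad_comp)
  expect_gte(validation_errors(rep2), 1)
  expect_true(any(grepl("nowhere", rep2$message)))

  dangling <- tiny_model()
  dangling$reactions$conv$stoich <- c(A = -1, Z = 1)
  expect_gte(validation_errors(validate_model(dangling)), 1)

  # unpaired partitioned law
  unpaired <- tiny_model()
  unpaired$reactions$conv$law <- rate_law(
    "MichaelisMentenPartitioned", list(kcat = 1, Km = 1e-6),
    list(substrate = "A", cosubstrate = "B", enzyme = "B"))
  expect_gte(validation_errors(validate_model(unpaired)), 1)

  # the simulator refuses invalid models
  expect_error(simulate_model(bad_km, sim_protocol(duration = 60)),
               "failed validation")
})

test_that("the parameter table exports id/value pairs", {
  tab <- parameter_table(reference_model_cached())
  expect_identical(names(tab), c("id", "value"))
  expect_equal(nrow(tab), length(reference_parameters()))
  expect_equal(tab$value[tab$id == "ABC0_Km"],
               unname(reference_parameters()["ABC0_Km"]))
})

test_that("fixture models have their advertised shapes", {
  mini <- make_fixture_model("minimal-efflux")
  expect_length(mini$reactions, 2)
  expect_length(boundary_ids(mini), 1)
  expect_equal(validation_errors(validate_model(mini)), 0)

  frozen <- make_fixture_model("no-regulation")
  p <- sim_protocol(xe = "75 nM", duration = hours(2))
  tr <- simulate_model(frozen, p)
  for (enz in c("ABC0", "CYP", "GST", "ABCIII")) {
    expect_equal(diff(range(tr$conc[, enz])), 0)
  }

  expect_identical(make_fixture_model("full-reference")$id,
                   build_reference_model()$id)
  expect_error(make_fixture_model("bogus"))
})
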