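roundtrip <- function(model) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  write_sbml(model, path)
  read_sbml(path)
}

test_that("the reference model round-trips through SBML exactly", {
  m <- reference_model_cached()
  m2 <- roundtrip(m)
  expect_identical(names(m2$species), names(m$species))
  expect_identical(names(m2$reactions), names(m$reactions))
  expect_equal(m2$parameters[names(m$parameters)], m$parameters)
  for (id in names(m$reactions)) {
    expect_equal(m2$reactions[[id]]$stoich[names(m$reactions[[id]]$stoich)],
                 m$reactions[[id]]$stoich)
  }
  for (id in names(m$species)) {
    expect_equal(m2$species[[id]]$initial, m$species[[id]]$initial)
    expect_identical(m2$species[[id]]$boundary, m$species[[id]]$boundary)
    expect_identical(m2$species[[id]]$role, m$species[[id]]$role)
  }
  expect_equal(validation_errors(validate_model(m2)), 0)

  # and the round-tripped model simulates identically
  p <- sim_protocol(xe = "75 nM", duration = hours(1))
  t1 <- simulate_model(m, p, initial = reference_steady_state())
  st2 <- pre_equilibrate(m2, p)
  t2 <- simulate_model(m2, p, initial = st2)
  expect_equal(max(abs(t1$conc - t2$conc)), 0)
  expect_equal(max(abs(t1$cum - t2$cum)), 0)
})

test_that("fitness parameters, rules and events survive a round-trip", {
  m <- attach_fitness(reference_model_cached(),
                      toxicity_profile(X_c = "5 nM", Xp_c = "5 uM",
                                       Xpp_c = "5 mM"))
  m2 <- roundtrip(m)
  expect_length(m2$rules, length(m$rules))
  expect_length(m2$events, length(m$events))
  expect_true(any(vapply(m2$events, `[[`, logical(1), "terminal")))
  expect_setequal(m2$varying, m$varying)

  # a lethal dose produces the same truncated trajectory either way
  p <- sim_protocol(xe = "150 nM", duration = hours(60))
  t1 <- simulate_model(m, p)
  t2 <- simulate_model(m2, p)
  expect_identical(t1$termination, "cell-death")
  expect_identical(t2$termination, "cell-death")
  expect_equal(max(t1$times), max(t2$times))
  expect_equal(t1$vars[, "Fitness"], t2$vars[, "Fitness"])
})

test_that("an empty model writes to a valid document and reads back", {
  empty <- kin_model(
    id = "empty",
    compartments = list(list(id = "cell", volume = 1)),
    species = list(),
    parameters = c(k = 1)
  )
  m2 <- roundtrip(empty)
  expect_length(m2$reactions, 0)
  expect_equal(m2$parameters[["k"]], 1)
})

test_that("malformed or unsupported documents are refused loudly", {
  expect_error(read_sbml("<notxml"), "parse error")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml level='3' version='1'><model id='x'/></sbml>", bad)
  expect_error(read_sbml(bad), "Level 2")

  not_sbml <- withr::local_tempfile(fileext = ".xml")
  writeLines("<foo/>", not_sbml)
  expect_error(read_sbml(not_sbml), "not an SBML")

  algebraic <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    "<sbml level='2' version='4'><model id='x'><listOfRules>",
    "<algebraicRule><math><ci>x</ci></math></algebraicRule>",
    "</listOfRules></model></sbml>"), algebraic)
  expect_error(read_sbml(algebraic), "algebraicRule")

  delayed <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    "<sbml level='2' version='4'><model id='x'><listOfEvents>",
    "<event id='e'><trigger><math><true/></math></trigger>",
    "<delay><math><cn>5</cn></math></delay>",
    "</event></listOfEvents></model></sbml>"), delayed)
  expect_error(read_sbml(delayed), "delay")

  amounts_only <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    "<sbml level='2' version='4'><model id='x'>",
    "<listOfCompartments><compartment id='c' size='1'/></listOfCompartments>",
    "<listOfSpecies><species id='s' compartment='c' initialAmount='1' ",
    "hasOnlySubstanceUnits='true'/></listOfSpecies></model></sbml>"),
    amounts_only)
  expect_error(read_sbml(amounts_only), "hasOnlySubstanceUnits")
})

test_that("amounts, local parameters and function definitions are handled", {
  doc <- paste0(
    "<sbml xmlns='http://www.sbml.org/sbml/level2/version4' ",
    "level='2' version='4'><model id='foreign'>",
    "<listOfFunctionDefinitions><functionDefinition id='mm'>",
    "<math xmlns='http://www.w3.org/1998/Math/MathML'><lambda>",
    "<bvar><ci>s</ci></bvar><bvar><ci>v</ci></bvar><bvar><ci>k</ci></bvar>",
    "<apply><divide/><apply><times/><ci>v</ci><ci>s</ci></apply>",
    "<apply><plus/><ci>k</ci><ci>s</ci></apply></apply>",
    "</lambda></math></functionDefinition></listOfFunctionDefinitions>",
    "<listOfCompartments><compartment id='cell' size='2'/>",
    "</listOfCompartments>",
    "<listOfSpecies>",
    "<species id='S' compartment='cell' initialAmount='4'/>",
    "<species id='P' compartment='cell' initialConcentration='0'/>",
    "</listOfSpecies>",
    "<listOfReactions><reaction id='r1'>",
    "<listOfReactants><speciesReference species='S'/></listOfReactants>",
    "<listOfProducts><speciesReference species='P'/></listOfProducts>",
    "<kineticLaw><math xmlns='http://www.w3.org/1998/Math/MathML'>",
    "<apply><ci>mm</ci><ci>S</ci><ci>vm</ci><ci>km</ci></apply></math>",
    "<listOfParameters><parameter id='vm' value='10'/>",
    "<parameter id='km' value='2'/></listOfParameters>",
    "</kineticLaw></reaction></listOfReactions>",
    "</model></sbml>")
  m <- read_sbml(doc)
  # initialAmount 4 in a volume-2 compartment -> concentration 2
  expect_equal(m$species$S$initial, 2)
  law <- m$reactions$r1$law
  expect_identical(law$variant, "Generic")
  # inlined function with inlined local parameters: 10*S/(2+S)
  expect_equal(evaluate_rate_law(law, c(S = 2)), 5)
  expect_equal(evaluate_rate_law(law, c(S = 0)), 0)
})

test_that("generic MathML kinetic laws simulate like their typed source", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, path)
  # strip the typed-law annotations to force the generic MathML path
  doc <- xml2::read_xml(path)
  anns <- xml2::xml_find_all(doc, "//*[local-name()='annotation']")
  xml2::xml_remove(anns)
  stripped <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, stripped)
  m2 <- read_sbml(stripped)
  expect_identical(m2$reactions$conv$law$variant, "Generic")

  p <- sim_protocol(duration = 3600, interval = 60)
  t1 <- simulate_model(m, p, initial = kin_state_for(m))
  t2 <- simulate_model(m2, p, initial = kin_state_for(m2))
  expect_equal(t1$conc, t2$conc, tolerance = 1e-12)
})

test_that("MathML expression translation is self-inverse", {
  exprs <- list(
    quote(1 + a * b - c / d),
    quote(2^x + exp(y) - log(z)),
    quote(max(0, min(1, 1 + wd * D + wr * G))),
    quote(ifelse(L > cap, kd * (L - cap), 0)),
    quote((a + b) * (c - d)),
    quote(k * (out - in_c)),
    quote(sqrt(abs(q))),
    quote(time * 2)
  )
  for (e in exprs) {
    root <- xml2::xml_new_root("wrap")
    xenodyn:::expr_to_mathml(root, e)
    math <- xml2::xml_find_first(root, "./*")
    back <- xenodyn:::mathml_to_expr(math)
    env <- list(a = 2, b = 3, c = 4, d = 5, x = 1.5, y = 0.3, z = 2,
                wd = 1, wr = 1, D = -0.25, G = 0.1, L = 2, cap = 1,
                kd = 1e-5, k = 2, out = 5, in_c = 1, q = -9, time = 7)
    expect_equal(eval(back, env), eval(e, env), tolerance = 1e-12,
                 label = deparse(e))
  }
})
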