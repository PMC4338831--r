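test_that("Michaelis-Menten flux matches hand values and saturates", {
  mm <- rate_law("MichaelisMentenIrreversible",
                 params = list(Vmax = 10, Km = 5e-9),
                 species = list(substrate = "S"))
  # half-saturation
  expect_equal(evaluate_rate_law(mm, c(S = 5e-9)), 5)
  expect_equal(evaluate_rate_law(mm, c(S = 0)), 0)
  # monotone nondecreasing in [S], bounded above by Vmax
  s_grid <- 10^seq(-12, -3, length.out = 40)
  flux <- vapply(s_grid, function(s) evaluate_rate_law(mm, c(S = s)),
                 numeric(1))
  expect_true(all(diff(flux) >= 0))
  expect_true(all(flux <= 10))
  # enzyme form scales linearly with enzyme and volume
  mm_e <- rate_law("MichaelisMentenIrreversible",
                   params = list(kcat = 2, Km = 1e-6),
                   species = list(substrate = "S", enzyme = "E"),
                   volume = 1e-12)
  expect_equal(evaluate_rate_law(mm_e, c(S = 1e-6, E = 1e-7)),
               2 * 1e-7 * 1e-12 * 0.5)
})

test_that("mass action, diffusion, Hill, decay and source laws evaluate", {
  ma <- rate_law("MassAction", params = list(k = 2),
                 species = list(substrates = c("A", "B")))
  expect_equal(evaluate_rate_law(ma, c(A = 3, B = 4)), 24)

  pd <- rate_law("PassiveDiffusion", params = list(k = 1e-12),
                 species = list(outside = "out", inside = "in"))
  expect_equal(evaluate_rate_law(pd, c(out = 5e-9, "in" = 5e-9)), 0)
  expect_gt(evaluate_rate_law(pd, c(out = 1e-8, "in" = 0)), 0)
  expect_lt(evaluate_rate_law(pd, c(out = 0, "in" = 1e-8)), 0)

  hill <- rate_law("HillActivatedSynthesis",
                   params = list(basal = 1, Vmax = 4, K = 1e-8, n = 1),
                   species = list(activator = "A"))
  expect_equal(evaluate_rate_law(hill, c(A = 0)), 1)
  expect_equal(evaluate_rate_law(hill, c(A = 1e-8)), 3)

  dec <- rate_law("FirstOrderDecay", params = list(k = 0.1),
                  species = list(substrate = "S"))
  expect_equal(evaluate_rate_law(dec, c(S = 2)), 0.2)

  src <- rate_law("ConstantSource", params = list(k = 7e-21))
  expect_equal(evaluate_rate_law(src, c(S = 123)), 7e-21)
})

test_that("rate laws resolve parameters from the global table", {
  mm <- rate_law("MichaelisMentenIrreversible",
                 params = list(Vmax = "vmax_id", Km = "km_id"),
                 species = list(substrate = "S"))
  pars <- c(vmax_id = 10, km_id = 5e-9)
  expect_equal(evaluate_rate_law(mm, c(S = 5e-9), pars), 5)
  expect_error(evaluate_rate_law(mm, c(S = 5e-9)), "unknown model parameter")
})

test_that("rate-law evaluation rejects bad input", {
  mm <- rate_law("MichaelisMentenIrreversible",
                 params = list(Vmax = 10, Km = 5e-9),
                 species = list(substrate = "S"))
  expect_error(evaluate_rate_law(mm, c(S = -1e-9)), "negative")
  expect_error(evaluate_rate_law(mm, c(Q = 1e-9)), "absent")
})

test_that("all laws give nonnegative flux for nonnegative concentrations", {
  set.seed(11)
  laws <- list(
    rate_law("MassAction", list(k = 0.5), list(substrates = c("A", "B"))),
    rate_law("MichaelisMentenIrreversible", list(Vmax = 3, Km = 1e-7),
             list(substrate = "A")),
    rate_law("MichaelisMentenPartitioned", list(kcat = 3, Km = 1e-7),
             list(substrate = "A", cosubstrate = "B", enzyme = "E")),
    rate_law("HillActivatedSynthesis", list(basal = 0.1, Vmax = 1,
                                            K = 1e-8, n = 2),
             list(activator = "A")),
    rate_law("FirstOrderDecay", list(k = 2), list(substrate = "A")),
    rate_law("ConstantSource", list(k = 1))
  )
  for (i in 1:50) {
    conc <- c(A = runif(1, 0, 1e-5), B = runif(1, 0, 1e-5),
              E = runif(1, 0, 1e-6))
    for (law in laws) {
      expect_gte(evaluate_rate_law(law, conc), 0)
    }
  }
})

test_that("enzyme partitioning conserves the total and handles edge cases", {
  expect_equal(partition_enzyme(10, 2, 3), c(4, 6))
  expect_equal(partition_enzyme(5, 1, 0), c(5, 0))
  expect_equal(partition_enzyme(8, 0, 0), c(4, 4))
  expect_error(partition_enzyme(-1, 1, 1), "nonnegative")
  expect_error(partition_enzyme(1, -1, 1), "nonnegative")
  set.seed(42)
  for (i in 1:200) {
    total <- runif(1, 0, 1e-6)
    s <- runif(2, 0, 1e-5) * rbinom(2, 1, 0.8)
    parts <- partition_enzyme(total, s[1], s[2])
    expect_equal(sum(parts), total, tolerance = 1e-12)
    expect_true(all(parts >= 0))
  }
})

test_that("partitioned pairs split the enzyme consistently with the flux", {
  law1 <- rate_law("MichaelisMentenPartitioned", list(kcat = 1, Km = 1e-6),
                   list(substrate = "S1", cosubstrate = "S2", enzyme = "E"))
  law2 <- rate_law("MichaelisMentenPartitioned", list(kcat = 1, Km = 1e-6),
                   list(substrate = "S2", cosubstrate = "S1", enzyme = "E"))
  conc <- c(S1 = 2e-6, S2 = 6e-6, E = 1e-7)
  v1 <- evaluate_rate_law(law1, conc)
  v2 <- evaluate_rate_law(law2, conc)
  # enzyme shares 1:3; with both substrates above Km the fluxes reflect it
  expect_equal(v1, 1 * 1e-7 * 0.25 * 2e-6 / (1e-6 + 2e-6))
  expect_equal(v2, 1 * 1e-7 * 0.75 * 6e-6 / (1e-6 + 6e-6))
  # zero-substrate pair gives zero flux despite the equal split
  expect_equal(evaluate_rate_law(law1, c(S1 = 0, S2 = 0, E = 1e-7)), 0)
})
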