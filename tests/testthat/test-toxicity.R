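test_that("chemical load sums critical-concentration fractions", {
  prof <- toxicity_profile(X_c = 1e-9, Xp_c = 1e-6, Xpp_c = 1e-4,
                           X_n = Inf)
  expect_equal(chemical_load(c(X_c = 0, Xp_c = 0, Xpp_c = 0), prof), 0)
  expect_equal(chemical_load(c(X_c = 1e-9), prof), 1)
  expect_equal(chemical_load(c(X_c = 5e-10, Xp_c = 5e-7), prof), 1)
  # infinite criticals contribute nothing
  expect_equal(chemical_load(c(X_n = 1e-3), prof), 0)
  # nonlinearity exponent
  prof2 <- toxicity_profile(X_c = 1e-9, h = 2)
  expect_equal(chemical_load(c(X_c = 2e-9), prof2), 4)
  expect_error(chemical_load(c(X_c = -1e-9), prof), "negative")
})

test_that("profile construction validates its inputs", {
  expect_error(toxicity_profile(X_c = 0), "critical")
  expect_error(toxicity_profile(X_c = 1e-9, kd = -1), "positive")
  expect_error(toxicity_profile(X_c = 1e-9, capacity = 0), "positive")
  # X_n inherits the X_c critical by default
  prof <- toxicity_profile(X_c = "5 nM")
  expect_equal(unname(prof$criticals["X_n"]), 5e-9)
  # unit strings accepted
  expect_equal(unname(toxicity_profile(Xp_c = "1 uM")$criticals["Xp_c"]),
               1e-6)
})

test_that("the cell's state classifies by load, capacity and fitness", {
  expect_identical(classify_mode(2, 1, 0.8), "damage")
  expect_identical(classify_mode(0.5, 1, 0.8), "regeneration")
  expect_identical(classify_mode(0.5, 1, 1.0), "idle")
  expect_identical(classify_mode(2, 1, 0), "dead")
  expect_identical(classify_mode(0.1, 1, 0), "dead")
})

test_that("damage and regeneration rates integrate the load excess", {
  prof <- toxicity_profile(X_c = 1e-9, kd = 1e-4, kr = 2e-4)
  # damage: dD = -kd (L - cap), no regeneration
  d <- fitness_derivatives(list(Fitness = 1), 3, prof)
  expect_equal(d, c(-1e-4 * 2, 0))
  # regeneration: dG = kr (cap - L), no damage
  d <- fitness_derivatives(list(Fitness = 0.5), 0.25, prof)
  expect_equal(d, c(0, 2e-4 * 0.75))
  # idle and dead: both zero
  expect_equal(fitness_derivatives(list(Fitness = 1), 0.2, prof), c(0, 0))
  expect_equal(fitness_derivatives(list(Fitness = 0), 5, prof), c(0, 0))
  # constant-rate integral: L = cap + 1 for time T from F = 1
  T <- 3600
  expect_equal(fitness_value(-prof$kd * T, 0, prof),
               max(0, 1 - prof$kd * T))
})

test_that("a square load pulse dips fitness and lets it recover", {
  prof <- pulse_profile()   # X_c critical 1 uM, defaults otherwise
  times <- seq(0, 20 * 3600, by = 60)
  load <- ifelse(times < 4 * 3600, 3, 0)   # 4 h at L = 3, then clean
  out <- fitness_from_trajectory(load_trajectory(times, load), prof)
  f <- out$Fitness
  dip <- min(f)
  expect_lt(dip, 1)
  expect_gt(dip, 0)
  # recovery toward 1 after the pulse
  expect_gt(f[length(f)], dip)
  # the dip matches the damage-rate integral: kd * (L - cap) * t_pulse
  expect_equal(1 - dip, prof$kd * 2 * 4 * 3600, tolerance = 0.02)
})

test_that("a symmetric load excursion restores fitness exactly", {
  prof <- pulse_profile()   # wd = wr, kd = kr
  times <- seq(0, 30 * 3600, by = 30)
  # 2 h at L = cap + 1, then L = cap - 1 for longer than 2 h, then idle
  load <- ifelse(times < 2 * 3600, 2, 0)
  out <- fitness_from_trajectory(load_trajectory(times, load), prof)
  f <- out$Fitness
  expect_lt(min(f), 1)
  # the regeneration area eventually equals the damage area; the
  # completion event pins fitness exactly at 1
  expect_equal(f[length(f)], 1)
  expect_identical(out$mode[length(f)], 0L)  # idle
  # fitness never overshoots
  expect_true(all(f <= 1 & f >= 0))
})

test_that("fitness is monotone against the load-capacity relation", {
  prof <- pulse_profile()
  times <- seq(0, 12 * 3600, by = 60)
  load <- 1.5 + sin(times / 3600)     # wanders around the capacity
  out <- fitness_from_trajectory(load_trajectory(times, load), prof)
  dF <- diff(out$Fitness)
  # classify intervals by both endpoints so capacity crossings within an
  # interval are not miscounted
  left <- load[-length(load)] > prof$capacity
  right <- load[-1] > prof$capacity
  expect_true(all(dF[left & right] <= 1e-12))
  expect_true(all(dF[!left & !right] >= -1e-12))
})

test_that("attaching fitness with infinite criticals is inert", {
  m <- reference_model_cached()
  fm <- attach_fitness(m, toxicity_profile())
  p <- sim_protocol(xe = "300 nM", duration = hours(6))
  tr <- simulate_model(fm, p)
  expect_identical(tr$termination, "completed")
  expect_true(all(tr$vars[, "Fitness"] == 1))
})

test_that("attach_fitness validates its species and runs jointly", {
  m <- tiny_model()
  expect_error(attach_fitness(m, toxicity_profile(Xp_c = 1e-6)),
               "absent from the model")
  prof <- toxicity_profile(X_c = "5 nM", Xp_c = "5 uM", Xpp_c = "5 mM")
  fm <- attach_fitness(reference_model_cached(), prof)
  p <- sim_protocol(xe = "150 nM", duration = hours(60))
  tr <- simulate_model(fm, p)
  expect_identical(tr$termination, "cell-death")
  expect_equal(min_fitness(tr), 0)
  expect_equal(unname(tr$vars[nrow(tr$vars), "Fitness"]), 0)
  # death interrupts the run before the nominal end
  expect_lt(max(tr$times), hours(60))
})

test_that("lowering a critical concentration never helps the cell", {
  m <- reference_model_cached()
  p <- sim_protocol(xe = "60 nM", duration = hours(24))
  mf <- vapply(c(5e-9, 2.5e-9, 1e-9), function(crit) {
    tr <- simulate_model(attach_fitness(m, toxicity_profile(X_c = crit)), p)
    min_fitness(tr)
  }, numeric(1))
  expect_true(all(diff(mf) <= 1e-9))
})

test_that("the standalone calculator reproduces the joint fitness series", {
  prof <- toxicity_profile(X_c = "5 nM", Xp_c = "5 uM", Xpp_c = "5 mM")
  fm <- attach_fitness(reference_model_cached(), prof)
  p <- sim_protocol(xe = "60 nM", duration = hours(24))
  tr <- simulate_model(fm, p)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_trajectory(tr, path)
  post <- fitness_from_trajectory(path, prof)
  expect_equal(post$Fitness, unname(tr$vars[, "Fitness"]), tolerance = 1e-3)
})
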