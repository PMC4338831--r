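test_that("pre-equilibration reaches the drug-free steady state", {
  st <- reference_steady_state()
  v <- st$values
  # no drug anywhere, but the background branch is populated
  expect_lt(abs(v[["X_c"]]), 1e-12)
  expect_gt(v[["Xp_bc"]], 1e-8)
  expect_gt(v[["Xpp_bc"]], 1e-8)
  # enzymes expressed at basal levels
  for (enz in c("ABC0", "CYP", "GST", "ABCIII")) {
    expect_gt(v[[enz]], 1e-8)
  }
  # bookkeeping pools restart at zero for the main experiment
  expect_equal(v[["Xpp_e"]], 0)
  expect_equal(v[["Xpp_be"]], 0)
})

test_that("the steady state is insensitive to tightening the tolerances", {
  m <- reference_model_cached()
  st <- reference_steady_state()
  tight <- sim_protocol(rtol = 1e-10, atol = 1e-14)
  st_tight <- pre_equilibrate(m, tight)
  # species at numerical zero (drug-free forms) must stay at zero; the
  # populated ones must agree to 1e-4 relative
  zero_ids <- names(st_tight$values)[abs(st_tight$values) < 1e-11]
  live_ids <- setdiff(names(st_tight$values), zero_ids)
  expect_true(all(abs(st$values[zero_ids]) < 1e-11))
  rel <- abs(st$values[live_ids] - st_tight$values[live_ids]) /
    abs(st_tight$values[live_ids])
  expect_lt(max(rel), 1e-4)
})

test_that("a larger GST Km for background species raises basal ABC0", {
  m <- reference_model_cached()
  m10 <- apply_parameter_multiplier(m, "GST_Km", 10)
  st <- reference_steady_state()
  st10 <- pre_equilibrate(m10, sim_protocol())
  expect_gt(st10$values[["Xp_bc"]], st$values[["Xp_bc"]])
  expect_gt(st10$values[["ABC0"]], st$values[["ABC0"]])
})

test_that("pre-equilibration reports non-convergence", {
  m <- tiny_model()
  # a pure source makes A grow forever: no steady state exists
  m$reactions$conv$law <- rate_law("ConstantSource", list(k = 1e-20))
  m$reactions$conv$stoich <- c(A = 1)
  p <- sim_protocol(pre_duration = 1000)
  expect_error(pre_equilibrate(m, p), "did not converge")
})

test_that("the minimal efflux fixture hits its closed-form steady state", {
  mini <- make_fixture_model("minimal-efflux")
  xe <- 7.5e-8
  p <- sim_protocol(xe = xe, duration = hours(4))
  tr <- simulate_model(mini, p)
  xc <- unname(tr$conc[nrow(tr$conc), "X_c"])
  # kd (Xe - Xc) = Vmax Xc / (Km + Xc): positive root of the quadratic
  kd <- mini$parameters[["kdiff_pm"]]
  vmax <- mini$parameters[["ABC0_Vmax"]]
  km <- mini$parameters[["ABC0_Km"]]
  a <- kd
  b <- vmax + kd * km - kd * xe
  cc <- -kd * km * xe
  root <- (-b + sqrt(b^2 - 4 * a * cc)) / (2 * a)
  expect_equal(xc, root, tolerance = 1e-6)
})

test_that("the cytoplasmic drug level stays below the extracellular dose", {
  tr <- reference_run_75nM()
  expect_lt(max(tr$conc[, "X_c"]), 7.5e-8)
  # quasi-steady within the first output intervals, then declining
  xc <- tr$conc[, "X_c"]
  expect_gt(xc[2], 0.5 * max(xc))
  expect_lt(xc[length(xc)], max(xc[2:10]))
})

test_that("trajectories satisfy their structural contract", {
  tr <- reference_run_75nM()
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(diff(tr$cum[, "n_Xin"]) >= 0))
  expect_true(all(diff(tr$cum[, "n_Xpp_e"]) >= -1e-30))
  expect_true(all(diff(tr$cum[, "n_Xpp_be"]) >= -1e-30))
  expect_true(all(tr$conc >= 0))
  df <- as.data.frame(tr)
  # 1 time + species + 4 fitness + 3 cumulative columns
  expect_equal(ncol(df), 1 + length(tr$species) + 4 + 3)
  expect_identical(names(df)[1], "time")
  expect_true(all(c("Fitness", "Damage", "Regeneration", "mode",
                    "n_Xin", "n_Xpp_e", "n_Xpp_be") %in% names(df)))
})

test_that("identical inputs give bit-identical trajectories", {
  m <- reference_model_cached()
  p <- sim_protocol(xe = "75 nM", duration = hours(1))
  st <- reference_steady_state()
  t1 <- simulate_model(m, p, initial = st)
  t2 <- simulate_model(m, p, initial = st)
  expect_identical(t1$conc, t2$conc)
  expect_identical(t1$cum, t2$cum)
})

test_that("exported trajectories re-import losslessly", {
  m <- tiny_model()
  p <- sim_protocol(duration = 600, interval = 60)
  tr <- simulate_model(m, p, initial = kin_state_for(m))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_trajectory(tr, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), length(tr$times))
  expect_equal(back$A, unname(tr$conc[, "A"]), tolerance = 1e-15)
  expect_equal(back$time, tr$times, tolerance = 1e-15)

  # header-only export for an empty (single-point) trajectory
  p0 <- sim_protocol(duration = 60, interval = 60)
  tr0 <- simulate_model(m, p0, initial = kin_state_for(m))
  expect_equal(nrow(as.data.frame(tr0)), 2)
})

test_that("two dose regimes appear across the 1 nM - 10 uM sweep", {
  m <- reference_model_cached()
  st <- reference_steady_state()
  doses <- c(1e-9, 1e-8, 7.5e-8, 3e-7, 1e-6, 1e-5)
  p <- sim_protocol(duration = hours(60), interval = 300)
  peaks <- ratios <- numeric(length(doses))
  for (i in seq_along(doses)) {
    p$xe <- doses[i]
    tr <- simulate_model(m, p, initial = st)
    peaks[i] <- max(tr$conc[, "Xp_c"])
    n <- nrow(tr$cum)
    ratios[i] <- tr$cum[n, "n_Xpp_e"] / tr$cum[n, "n_Xin"]
  }
  # low-dose regime: peak X'_c roughly proportional to dose; high-dose
  # regime (GST saturated): a qualitative break with a much larger jump
  fold <- diff(log10(peaks)) / diff(log10(doses))
  expect_lt(max(fold[1:2]), 1.5)
  expect_gt(max(fold), 2.5)
  # export/intake ratio near 1 at low doses, collapsing at the highest
  expect_gt(ratios[1], 0.75)
  expect_lt(ratios[length(doses)], 0.3 * ratios[1])
})

test_that("the rk4 method needs a step and refuses rules or events", {
  m <- reference_model_cached()
  p <- sim_protocol(xe = "75 nM", duration = 600, method = "rk4")
  expect_error(simulate_model(m, p, initial = reference_steady_state()),
               "step")
  p$step <- 0.1
  fm <- attach_fitness(m, toxicity_profile(X_c = "5 nM"))
  expect_error(simulate_model(fm, p), "without rules or events")
})
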