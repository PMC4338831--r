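#' Toxicity profile of a xenobiotic and its metabolites
#'
#' Each intracellular toxic species has a critical concentration: the
#' threshold it must exceed to damage the cell when it is the sole toxic
#' species present. The instantaneous chemical load is a nonlinear function
#' of the summed concentration/critical ratios (see [chemical_load()]); a
#' constant regeneration capacity sets the load level below which repair
#' keeps up.
#'
#' Species with critical concentration `Inf` contribute nothing to the load.
#' By default the nuclear form `X_n` inherits the critical concentration of
#' `X_c`, and the background species carry no toxicity; both are
#' configurable.
#'
#' @param X_c,Xp_c,Xpp_c critical concentrations (mol/L, or strings like
#'   `"5 nM"`) of the unmodified cytoplasmic drug, its oxidized metabolite,
#'   and the conjugate.
#' @param X_n critical concentration of the nuclear drug form (defaults to
#'   that of `X_c`).
#' @param Xp_bc,Xpp_bc critical concentrations of the background reactive
#'   species and their conjugate (default `Inf`: nontoxic).
#' @param capacity regeneration capacity, in load units.
#' @param h load exponent: chemical load is `(sum of ratios)^h`.
#' @param kd,kr damage and regeneration rate scales (1/s). The default
#'   integrates a sustained unit load-excess to a fitness loss of about
#'   0.35 over a 48-hour assay, so moderate doses produce partial growth
#'   inhibition rather than an all-or-nothing response.
#' @param wd,wr weights of Damage and Regeneration in the fitness sum.
#' @return an object of class `toxicity_profile`.
#' @examples
#' toxicity_profile(X_c = "0.5 nM", Xp_c = "1 uM", Xpp_c = "100 uM")
#' @export
toxicity_profile <- function(X_c = Inf, Xp_c = Inf, Xpp_c = Inf, X_n = NULL,
                             Xp_bc = Inf, Xpp_bc = Inf,
                             capacity = 1, h = 1,
                             kd = 2e-6, kr = 2e-6, wd = 1, wr = 1) {
  pq <- function(x) if (is.null(x)) NULL else parse_quantity(x)
  criticals <- c(X_c = pq(X_c), X_n = if (is.null(X_n)) pq(X_c) else pq(X_n),
                 Xp_c = pq(Xp_c), Xpp_c = pq(Xpp_c),
                 Xp_bc = pq(Xp_bc), Xpp_bc = pq(Xpp_bc))
  if (any(criticals <= 0, na.rm = TRUE)) {
    stop("critical concentrations must be > 0 (use Inf for nontoxic species)",
         call. = FALSE)
  }
  for (nm in c("capacity", "h", "kd", "kr", "wd", "wr")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single positive number", call. = FALSE)
    }
  }
  structure(
    list(criticals = criticals, capacity = capacity, h = h,
         kd = kd, kr = kr, wd = wd, wr = wr),
    class = "toxicity_profile"
  )
}

#' @export
print.toxicity_profile <- function(x, ...) {
  cat("<toxicity_profile>\n  criticals (mol/L):\n")
  print(x$criticals)
  cat(sprintf("  capacity=%g h=%g kd=%g kr=%g wd=%g wr=%g\n",
              x$capacity, x$h, x$kd, x$kr, x$wd, x$wr))
  invisible(x)
}

#' Instantaneous chemical load
#'
#' The load is `f(sum_i c_i / C_i)` where `c_i` are the concentrations of
#' the toxic species, `C_i` their critical concentrations and
#' `f(u) = u^h` the (configurable) nonlinearity; `f` is monotone
#' nondecreasing with `f(0) = 0`. Species with infinite critical
#' concentration contribute zero.
#'
#' @param concentrations named numeric vector (mol/L); names matched against
#'   the profile's toxic species. Species missing from the vector are
#'   treated as absent.
#' @param profile a [toxicity_profile()].
#' @return dimensionless load (scalar >= 0).
#' @export
chemical_load <- function(concentrations, profile) {
  stopifnot(inherits(profile, "toxicity_profile"))
  ids <- intersect(names(profile$criticals), names(concentrations))
  conc <- concentrations[ids]
  if (any(conc < 0)) {
    stop("negative concentration passed to chemical_load()", call. = FALSE)
  }
  crit <- profile$criticals[ids]
  frac <- ifelse(is.finite(crit), conc / crit, 0)
  u <- sum(frac)
  if (u == 0) 0 else u^profile$h
}

#' Classify the cell's toxicodynamic state
#'
#' The cell is in one of three live states: `damage` when the chemical load
#' exceeds the regeneration capacity (repair cannot keep up, fitness
#' decreases), `regeneration` when the load is within capacity but fitness
#' is below its maximum, and `idle` when the load is within capacity and the
#' cell is already in perfect shape. `dead` (fitness 0) overrides all.
#'
#' @param load chemical load (>= 0).
#' @param capacity regeneration capacity (> 0).
#' @param fitness current fitness in `[0, 1]`.
#' @return one of `"damage"`, `"regeneration"`, `"idle"`, `"dead"`.
#' @export
classify_mode <- function(load, capacity, fitness) {
  stopifnot(load >= 0, fitness >= 0, fitness <= 1)
  if (fitness == 0) return("dead")
  if (load > capacity) return("damage")
  if (fitness < 1) return("regeneration")
  "idle"
}

# integer coding used in trajectory tables
mode_levels <- c(idle = 0L, regeneration = 1L, damage = 2L, dead = 3L)

#' Damage and regeneration rates
#'
#' In the damage state, Damage (a nonpositive variable) accrues at rate
#' `-kd * (load - capacity)`; in the regeneration state, Regeneration (a
#' nonnegative variable) accrues at `kr * (capacity - load)`; in the idle
#' and dead states both rates are zero. Damage is thus proportional to the
#' time-integrated area of the load above capacity, and Regeneration to the
#' area below it, each gated by the cell's state.
#'
#' @param state list with elements `Damage`, `Regeneration`, `Fitness`
#'   (a `FitnessState`); only `Fitness` is consulted for gating.
#' @param load current chemical load.
#' @param profile a [toxicity_profile()].
#' @return numeric vector `c(dDamage, dRegeneration)` (1/s).
#' @export
fitness_derivatives <- function(state, load, profile) {
  stopifnot(inherits(profile, "toxicity_profile"))
  mode <- classify_mode(load, profile$capacity, state$Fitness)
  switch(mode,
    damage = c(-profile$kd * (load - profile$capacity), 0),
    regeneration = c(0, profile$kr * (profile$capacity - load)),
    c(0, 0)
  )
}

#' Current fitness from the damage and regeneration integrals
#'
#' Fitness adds the weighted nonpositive Damage and nonnegative Regeneration
#' to the maximal fitness of 1, clamped to `[0, 1]`.
#'
#' @param damage nonpositive damage integral.
#' @param regeneration nonnegative regeneration integral.
#' @param profile a [toxicity_profile()].
#' @return fitness in `[0, 1]`.
#' @export
fitness_value <- function(damage, regeneration, profile) {
  pmin(1, pmax(0, 1 + profile$wd * damage + profile$wr * regeneration))
}

#' Attach the cellular-fitness framework to a kinetic model
#'
#' Augments a model with the toxicodynamic layer so that [simulate()] runs
#' kinetics and fitness jointly: `ChemicalLoad` and `Fitness` become
#' assignment rules, `Damage` and `Regeneration` rate rules, and two events
#' complete the semantics — one pins the regeneration integral when fitness
#' returns to its maximum, and a terminal one interrupts the simulation at
#' cell death (fitness 0, `alive` set to 0). The augmented model is plain
#' SBML-representable state (parameters, rules, events) and survives a
#' round-trip through [write_sbml()]/[read_sbml()].
#'
#' @param model a [kin_model()].
#' @param profile a [toxicity_profile()]; every finite-critical species must
#'   exist in the model.
#' @return the augmented model.
#' @export
attach_fitness <- function(model, profile) {
  stopifnot(inherits(model, "kin_model"), inherits(profile, "toxicity_profile"))
  finite <- names(profile$criticals)[is.finite(profile$criticals)]
  unknown <- setdiff(finite, names(model$species))
  if (length(unknown) > 0) {
    stop("toxicity profile references species absent from the model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pars <- c(tox_capacity = profile$capacity, tox_h = profile$h,
            tox_kd = profile$kd, tox_kr = profile$kr,
            tox_wd = profile$wd, tox_wr = profile$wr,
            Damage = 0, Regeneration = 0, alive = 1,
            ChemicalLoad = 0, Fitness = 1)
  crit <- if (length(finite) > 0) {
    stats::setNames(profile$criticals[finite], paste0("crit_", finite))
  } else {
    numeric(0)
  }
  model$parameters <- c(model$parameters, pars, crit)
  model$varying <- union(model$varying,
                         c("Damage", "Regeneration", "alive",
                           "ChemicalLoad", "Fitness"))

  load_terms <- lapply(finite, function(id) {
    call("/", as.name(id), as.name(paste0("crit_", id)))
  })
  load_sum <- if (length(load_terms) == 0) {
    0
  } else {
    Reduce(function(a, b) call("+", a, b), load_terms)
  }
  load_expr <- call("^", call("(", load_sum), as.name("tox_h"))
  raw <- quote(1 + tox_wd * Damage + tox_wr * Regeneration)
  fitness_expr <- substitute(max(0, min(1, RAW)), list(RAW = raw))

  model$rules <- c(model$rules, list(
    list(type = "assignment", variable = "ChemicalLoad", expr = load_expr),
    list(type = "assignment", variable = "Fitness", expr = fitness_expr),
    list(type = "rate", variable = "Damage",
         expr = quote(-(tox_kd) * max(ChemicalLoad - tox_capacity, 0) * alive)),
    list(type = "rate", variable = "Regeneration",
         expr = quote(ifelse(tox_wd * Damage + tox_wr * Regeneration < 0,
                             tox_kr * max(tox_capacity - ChemicalLoad, 0),
                             0) * alive))
  ))
  model$events <- c(model$events, list(
    # fitness is back at its maximum: pin Regeneration so the raw sum is
    # exactly zero and the idle state is entered cleanly (the tiny offset
    # keeps the trigger away from its root in the fresh steady state)
    list(id = "ev_regen_complete",
         trigger = quote(tox_wd * Damage + tox_wr * Regeneration >= -1e-9),
         assignments = list(
           Regeneration = quote(-(tox_wd / tox_wr) * Damage)
         ),
         terminal = FALSE),
    # severe damage: the cell dies and the simulation is interrupted
    list(id = "ev_death",
         trigger = quote(1 + tox_wd * Damage + tox_wr * Regeneration <= 0),
         assignments = list(alive = 0),
         terminal = TRUE)
  ))
  model$meta$fitness <- list(profile = profile, toxic_species = finite)
  model
}

#' Recompute the fitness layer from a stored trajectory
#'
#' Standalone toxicodynamics: given any concentration trajectory (e.g. a TSV
#' written by [export_trajectory()], or a data frame with a `time` column
#' and one column per species), integrates the damage/regeneration dynamics
#' for a toxicity profile post hoc. Concentrations between grid points are
#' interpolated linearly.
#'
#' @param trajectory a `kin_trajectory`, a data frame, or a path to a
#'   TSV/CSV trajectory file.
#' @param profile a [toxicity_profile()].
#' @return a data frame with columns `time`, `ChemicalLoad`, `Damage`,
#'   `Regeneration`, `Fitness`, `mode`.
#' @export
fitness_from_trajectory <- function(trajectory, profile) {
  df <- if (inherits(trajectory, "kin_trajectory")) {
    as.data.frame(trajectory)
  } else if (is.character(trajectory)) {
    sep <- if (grepl("\\.csv$", trajectory)) "," else "\t"
    utils::read.table(trajectory, header = TRUE, sep = sep,
                      check.names = FALSE)
  } else {
    as.data.frame(trajectory)
  }
  stopifnot("time" %in% names(df))
  times <- df$time
  finite <- names(profile$criticals)[is.finite(profile$criticals)]
  present <- intersect(finite, names(df))
  load_series <- if (length(present) == 0) {
    rep(0, length(times))
  } else {
    u <- rowSums(sapply(present, function(id) {
      df[[id]] / profile$criticals[[id]]
    }))
    u^profile$h
  }
  load_fun <- stats::approxfun(times, load_series, rule = 2)

  rhs <- function(t, y, parms) {
    L <- load_fun(t)
    raw <- 1 + profile$wd * y[1L] + profile$wr * y[2L]
    dD <- -profile$kd * max(L - profile$capacity, 0)
    dG <- if (raw < 1) profile$kr * max(profile$capacity - L, 0) else 0
    list(c(dD, dG))
  }
  # fire the regeneration-complete pin only on the upward (recovery)
  # crossing; the downward crossing at damage onset just flips the flag
  state <- new.env(parent = emptyenv())
  state$was_max <- TRUE
  rootfun <- function(t, y, parms) {
    raw <- 1 + profile$wd * y[1L] + profile$wr * y[2L]
    c(profile$wd * y[1L] + profile$wr * y[2L] + 1e-9, raw)
  }
  eventfun <- function(t, y, parms) {
    margin <- profile$wd * y[1L] + profile$wr * y[2L] + 1e-9
    if (abs(margin) < 1e-8) {
      if (!state$was_max) {
        y[2L] <- -(profile$wd / profile$wr) * y[1L]
        state$was_max <- TRUE
      } else {
        state$was_max <- FALSE
      }
    }
    y
  }
  sol <- deSolve::lsoda(
    c(D = 0, G = 0), times, rhs, parms = NULL,
    rtol = 1e-8, atol = 1e-12,
    rootfunc = rootfun,
    events = list(func = eventfun, root = TRUE, terminalroot = 2L)
  )
  D <- sol[, "D"]
  G <- sol[, "G"]
  n <- nrow(sol)
  fit <- fitness_value(D, G, profile)
  if (n < length(times)) fit[n] <- 0  # death interrupt
  L <- load_series[seq_len(n)]
  mode <- mapply(function(l, f) mode_levels[[classify_mode(l, profile$capacity, f)]],
                 L, fit)
  data.frame(time = times[seq_len(n)], ChemicalLoad = L, Damage = D,
             Regeneration = G, Fitness = fit, mode = as.integer(mode))
}
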