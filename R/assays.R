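#' Minimal fitness of a trajectory
#'
#' The in silico analogue of a viability readout: the minimum of the
#' Fitness series over the observed grid (0 for death-terminated runs).
#' Minimal — rather than final — fitness is used because a transient
#' fitness dip maps to growth inhibition in a cytotoxicity test even if the
#' cell later recovers.
#'
#' @param trajectory a `kin_trajectory` carrying a fitness series.
#' @return value in `[0, 1]`.
#' @export
min_fitness <- function(trajectory) {
  stopifnot(inherits(trajectory, "kin_trajectory"))
  if (!"Fitness" %in% colnames(trajectory$vars)) {
    stop("trajectory has no fitness series", call. = FALSE)
  }
  if (trajectory$termination == "cell-death") {
    return(0)
  }
  min(trajectory$vars[, "Fitness"])
}

#' Logarithmic dose grid
#'
#' @param from,to range of extracellular concentrations (mol/L or quantity
#'   strings).
#' @param n number of log-spaced points (default 24).
#' @return increasing numeric vector.
#' @export
xe_grid <- function(from, to, n = 24) {
  from <- parse_quantity(from)
  to <- parse_quantity(to)
  stopifnot(from > 0, to > from, n >= 2)
  10^seq(log10(from), log10(to), length.out = n)
}

#' Run an in silico cytotoxicity assay
#'
#' For each extracellular drug concentration in `grid`, simulates the model
#' with the fitness layer attached (48-hour time courses from the common
#' drug-free steady state, dose applied at t = 0) and records the minimal
#' fitness; the resulting minimal-fitness-versus-dose curve is interpolated
#' monotonically in log-concentration and the EC50 — the dose at which
#' minimal fitness crosses 0.5 — extracted from the interpolant.
#'
#' The steady state is computed once per parameter set, not per dose: the
#' dose only changes the boundary condition at t = 0.
#'
#' @param model a [kin_model()] without a fitness layer (it is attached
#'   here).
#' @param profile a [toxicity_profile()].
#' @param grid increasing vector of extracellular concentrations (mol/L),
#'   e.g. from [xe_grid()].
#' @param duration assay length in seconds (default 48 h).
#' @param protocol optional base [sim_protocol()]; its `xe` and `duration`
#'   are overridden per dose.
#' @param verbose print one line per dose.
#' @return an object of class `cytotox_curve`: data frame of
#'   `(xe, min_fitness)` pairs plus the EC50 (`NA` if the curve never
#'   reaches 0.5).
#' @export
run_cytotoxicity <- function(model, profile, grid,
                             duration = hours(48), protocol = NULL,
                             verbose = FALSE) {
  grid <- vapply(grid, parse_quantity, numeric(1))
  stopifnot(length(grid) >= 1, all(grid > 0), !is.unsorted(grid, strictly = TRUE))
  if (is.null(protocol)) protocol <- sim_protocol()
  protocol$duration <- parse_quantity(duration)
  fit_model <- attach_fitness(model, profile)
  state <- pre_equilibrate(fit_model, protocol)
  mf <- numeric(length(grid))
  for (i in seq_along(grid)) {
    protocol$xe <- grid[i]
    traj <- simulate_model(fit_model, protocol, initial = state)
    mf[i] <- min_fitness(traj)
    if (verbose) {
      message(sprintf("  [X_e] = %.4g nM -> min fitness %.4f (%s)",
                      grid[i] * 1e9, mf[i], traj$termination))
    }
  }
  curve <- structure(
    list(data = data.frame(xe = grid, min_fitness = mf),
         duration = protocol$duration,
         interpolation = "monotone cubic in log10 concentration",
         ec50 = NA_real_),
    class = "cytotox_curve"
  )
  if (length(grid) >= 4) {
    curve$ec50 <- compute_ec50(curve)
  }
  curve
}

#' @export
print.cytotox_curve <- function(x, ...) {
  cat("<cytotox_curve> ", nrow(x$data), " doses over ",
      format(x$duration / 3600, digits = 3), " h, EC50 = ",
      if (is.na(x$ec50)) "none" else paste0(format(x$ec50 * 1e9, digits = 4),
                                            " nM"),
      "\n", sep = "")
  invisible(x)
}

#' Extract the EC50 from a cytotoxicity curve
#'
#' The EC50 is the smallest extracellular concentration at which the
#' monotone piecewise-cubic interpolant of minimal fitness versus log10
#' concentration crosses 0.5. Returns `NA` when the curve never reaches
#' 0.5.
#'
#' @param curve a `cytotox_curve` (or a data frame with columns `xe`,
#'   `min_fitness`) sampled on at least 4 doses.
#' @return EC50 in mol/L, or `NA_real_`.
#' @export
compute_ec50 <- function(curve) {
  df <- if (inherits(curve, "cytotox_curve")) curve$data else curve
  stopifnot(all(c("xe", "min_fitness") %in% names(df)))
  if (is.unsorted(df$xe, strictly = TRUE)) {
    stop("cytotoxicity curve must be sampled on strictly increasing doses",
         call. = FALSE)
  }
  if (nrow(df) < 4) {
    stop("EC50 extraction needs at least 4 sampled doses", call. = FALSE)
  }
  lx <- log10(df$xe)
  f <- df$min_fitness
  spl <- stats::splinefun(lx, f, method = "monoH.FC")
  for (i in seq_len(nrow(df) - 1L)) {
    if (f[i] == 0.5) return(df$xe[i])
    if (f[i] > 0.5 && f[i + 1L] <= 0.5) {
      root <- stats::uniroot(function(z) spl(z) - 0.5,
                             lower = lx[i], upper = lx[i + 1L],
                             tol = 1e-12)$root
      return(10^root)
    }
  }
  if (f[nrow(df)] == 0.5) return(df$xe[nrow(df)])
  NA_real_
}

#' Scan a parameter across multipliers
#'
#' Runs one pre-equilibration plus time course per multiplier (the steady
#' state depends on the parameter set, so it is recomputed each time). A
#' vector of parameter ids applies the same multiplier jointly to each —
#' e.g. the two membrane diffusion constants, or a compensating pair.
#'
#' @param model a [kin_model()].
#' @param parameter id (or ids) of global parameters to scale.
#' @param multipliers positive multipliers (applied to the default value).
#' @param protocol a [sim_protocol()] (carries the dose and duration).
#' @param verbose print one line per multiplier.
#' @return an object of class `scan_result`: list with `parameter`,
#'   `multipliers` and one `kin_trajectory` per multiplier.
#' @export
scan_parameter <- function(model, parameter, multipliers,
                           protocol = sim_protocol(), verbose = FALSE) {
  stopifnot(all(multipliers > 0))
  trajectories <- vector("list", length(multipliers))
  for (i in seq_along(multipliers)) {
    m <- model
    for (p in parameter) {
      m <- apply_parameter_multiplier(m, p, multipliers[i])
    }
    if (verbose) {
      message(sprintf("  scan %s x %g", paste(parameter, collapse = "+"),
                      multipliers[i]))
    }
    trajectories[[i]] <- simulate_model(m, protocol)
  }
  structure(
    list(parameter = parameter, multipliers = multipliers,
         trajectories = trajectories),
    class = "scan_result"
  )
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result ", paste(x$parameter, collapse = "+"), "> multipliers: ",
      paste(x$multipliers, collapse = ", "), "\n", sep = "")
  invisible(x)
}
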