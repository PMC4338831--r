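#' Simulation protocol
#'
#' Bundles the numerical settings of a time-course experiment. The defaults
#' mirror the study design: a 30-day drug-free pre-equilibration to steady
#' state, a 60-hour main time course sampled every 60 seconds, and an
#' extracellular drug setpoint applied at t = 0 (cytotoxicity assays use a
#' 48-hour duration).
#'
#' @param xe extracellular drug concentration applied at t = 0 (mol/L, or a
#'   string such as `"75 nM"`).
#' @param duration main simulation length in seconds (default 60 h).
#' @param interval output interval in seconds (default 60 s).
#' @param pre_duration pre-equilibration length in seconds (default 30 d).
#' @param rtol,atol relative/absolute solver tolerances. Tighter than the
#'   solver's own defaults because EC50s are read to three significant
#'   figures.
#' @param ss_tol steady-state tolerance: maximal allowed species derivative
#'   (mol/L/s) at the end of pre-equilibration.
#' @param intake_mode how cumulative drug intake `n_Xin` is counted:
#'   `"net"` (default) integrates the cell's net drug uptake — passive
#'   plasma-membrane diffusion net of the Phase 0 efflux return — which is
#'   the measure against which the exported-conjugate ratio approaches 1 at
#'   low doses; `"gross"` integrates the inward passive diffusion flux
#'   only.
#' @param method `"lsoda"` (adaptive, stiff-capable; default) or `"rk4"`
#'   (fixed-step explicit 4th order, for cross-checks; requires `step` and a
#'   model with typed rate laws and no rules/events).
#' @param step fixed step size in seconds for `method = "rk4"`.
#' @param track_reactions reaction ids whose net flux should be integrated
#'   along the trajectory (columns `cum_<id>` of the result).
#' @param xe_species id of the boundary species to which `xe` is applied;
#'   defaults to the model's boundary drug species.
#' @return an object of class `sim_protocol`.
#' @export
sim_protocol <- function(xe = 0, duration = hours(60), interval = 60,
                         pre_duration = days(30), rtol = 1e-8, atol = 1e-12,
                         ss_tol = 1e-12, intake_mode = c("net", "gross"),
                         method = c("lsoda", "rk4"), step = NULL,
                         track_reactions = character(), xe_species = NULL) {
  duration <- parse_quantity(duration)
  interval <- parse_quantity(interval)
  pre_duration <- parse_quantity(pre_duration)
  stopifnot(duration > 0, interval > 0, interval <= duration,
            pre_duration > 0)
  structure(
    list(xe = parse_quantity(xe), duration = duration, interval = interval,
         pre_duration = pre_duration, rtol = rtol, atol = atol,
         ss_tol = ss_tol, intake_mode = match.arg(intake_mode),
         method = match.arg(method), step = step,
         track_reactions = track_reactions, xe_species = xe_species),
    class = "sim_protocol"
  )
}

#' System state at one instant
#'
#' @param time time point (s).
#' @param values named numeric vector over the compiled state ids.
#' @return an object of class `kin_state`.
#' @keywords internal
kin_state <- function(time, values) {
  structure(list(time = time, values = values), class = "kin_state")
}

#' @export
print.kin_state <- function(x, ...) {
  cat("<kin_state t=", x$time, "s>\n", sep = "")
  print(x$values)
  invisible(x)
}

#' Pre-equilibrate a model to its drug-free steady state
#'
#' Runs a long drug-free time course (default 30 days) with the
#' extracellular drug pool held at zero, then asserts that the largest
#' species time-derivative is below the protocol's steady-state tolerance.
#' Fitness bookkeeping is reset (Fitness = 1, Damage = Regeneration = 0) so
#' the returned state is the clean initial condition of a main experiment.
#'
#' @param model a [kin_model()].
#' @param protocol a [sim_protocol()].
#' @param verbose print the residual derivative norm.
#' @return a `kin_state` at steady state.
#' @export
pre_equilibrate <- function(model, protocol = sim_protocol(),
                            verbose = FALSE) {
  compiled <- compile_model(model, intake_mode = protocol$intake_mode,
                            track_reactions = protocol$track_reactions)
  y0 <- initial_state(compiled)
  drug <- protocol$xe_species
  if (is.null(drug)) drug <- drug_boundary_id(model)
  if (!is.null(drug)) y0[[drug]] <- 0

  # a handful of intermediate outputs keeps the per-interval step budget sane
  pre_times <- seq(0, protocol$pre_duration, length.out = 33L)
  sol <- run_lsoda(compiled, y0, times = pre_times, protocol = protocol)
  if (nrow(sol$out) < length(pre_times)) {
    stop("pre-equilibration failed: ", sol$termination, call. = FALSE)
  }
  yT <- sol$out[nrow(sol$out), compiled$state_ids]
  dy <- compiled$rhs(protocol$pre_duration, yT, NULL)[[1L]]
  # bookkeeping export pools accumulate forever by design; they are not part
  # of the steady-state criterion
  bookkeeping <- vapply(model$species, function(s) {
    identical(s$role, "bookkeeping")
  }, logical(1))
  check <- which(!compiled$boundary[compiled$species_ids] &
                   !bookkeeping[compiled$species_ids])
  worst <- which.max(abs(dy[check]))
  residual <- abs(dy[check][worst])
  if (verbose) {
    message(sprintf("pre-equilibration residual %.3e mol/L/s (worst: %s)",
                    residual, compiled$species_ids[check][worst]))
  }
  if (residual > protocol$ss_tol) {
    stop(sprintf(paste0("pre-equilibration did not converge: max species ",
                        "derivative %.3e mol/L/s (species '%s') exceeds ",
                        "tolerance %.1e"),
                 residual, compiled$species_ids[check][worst],
                 protocol$ss_tol),
         call. = FALSE)
  }
  values <- yT
  # cumulative export bookkeeping restarts with the main experiment
  for (id in compiled$species_ids[bookkeeping[compiled$species_ids]]) {
    values[[id]] <- 0
  }
  for (id in intersect(c("Damage", "Regeneration"), names(values))) {
    values[[id]] <- 0
  }
  if ("alive" %in% names(values)) values[["alive"]] <- 1
  # cumulative trackers restart with the main experiment
  for (id in compiled$trackers) values[[id]] <- 0
  kin_state(0, values)
}

#' Run a time-course simulation
#'
#' Integrates the model from a steady state (computed by
#' [pre_equilibrate()] unless an explicit initial state is given), with the
#' extracellular drug setpoint applied at t = 0. Events are located by
#' root-finding on their trigger crossings; if the cell-death event fires,
#' the run terminates early with `termination = "cell-death"` and final
#' Fitness 0. Cumulative drug intake (`n_Xin`) integrates the inward
#' plasma-membrane diffusion flux.
#'
#' @param model a [kin_model()].
#' @param protocol a [sim_protocol()]; `protocol$xe` is the dose.
#' @param initial optional `kin_state` (from [pre_equilibrate()]); computed
#'   on the fly when omitted.
#' @param verbose print progress information.
#' @return a `kin_trajectory`.
#' @export
simulate_model <- function(model, protocol = sim_protocol(), initial = NULL,
                           verbose = FALSE) {
  compiled <- compile_model(model, intake_mode = protocol$intake_mode,
                            track_reactions = protocol$track_reactions)
  if (is.null(initial)) {
    initial <- pre_equilibrate(model, protocol, verbose = verbose)
  }
  y0 <- initial_state(compiled)
  shared <- intersect(names(initial$values), names(y0))
  y0[shared] <- initial$values[shared]

  drug <- protocol$xe_species
  if (is.null(drug)) drug <- drug_boundary_id(model)
  if (protocol$xe > 0 && is.null(drug)) {
    stop("protocol sets a drug concentration but the model has no boundary ",
         "drug species (and 'xe_species' was not given)", call. = FALSE)
  }
  if (!is.null(drug)) y0[[drug]] <- protocol$xe

  times <- seq(0, protocol$duration, by = protocol$interval)
  if (protocol$method == "rk4") {
    out <- run_rk4(compiled, y0, protocol)
    termination <- "completed"
  } else {
    sol <- run_lsoda(compiled, y0, times, protocol)
    out <- sol$out
    termination <- sol$termination
  }
  build_trajectory(compiled, out, termination, protocol)
}

# adaptive stiff integration via deSolve::lsoda, with root events
run_lsoda <- function(compiled, y0, times, protocol) {
  args <- list(
    y = y0, times = times, func = compiled$rhs, parms = NULL,
    rtol = protocol$rtol, atol = protocol$atol, maxsteps = 50000
  )
  if (!is.null(compiled$rootfun)) {
    # initialize trigger truth values at the initial state
    compiled$event_state$last_truth <-
      compiled$rootfun(times[1L], y0, NULL) >= 0
    args$rootfunc <- compiled$rootfun
    args$events <- list(func = compiled$eventfun, root = TRUE)
    if (length(compiled$terminal_index) > 0) {
      args$events$terminalroot <- compiled$terminal_index
    }
  }
  out <- suppressWarnings(do.call(deSolve::lsoda, args))
  colnames(out)[1L] <- "time"
  termination <- "completed"
  if (nrow(out) < length(times)) {
    died <- FALSE
    if (length(compiled$terminal_index) > 0) {
      yT <- out[nrow(out), compiled$state_ids]
      m <- compiled$rootfun(out[nrow(out), "time"], yT, NULL)
      died <- any(m[compiled$terminal_index] >= -1e-6)
    }
    if (died) {
      termination <- "cell-death"
    } else {
      stop(sprintf("integration failed at t = %.6g s (diagnostic: %s)",
                   out[nrow(out), "time"],
                   paste(attr(out, "istate")[1L], collapse = " ")),
           call. = FALSE)
    }
  }
  list(out = out, termination = termination)
}

# fixed-step RK4 cross-check integrator (compiled C++ core)
run_rk4 <- function(compiled, y0, protocol) {
  if (is.null(protocol$step) || protocol$step <= 0) {
    stop("method 'rk4' requires a positive 'step'", call. = FALSE)
  }
  if (length(compiled$model$rules) > 0 || length(compiled$model$events) > 0) {
    stop("method 'rk4' supports models without rules or events",
         call. = FALSE)
  }
  record_every <- round(protocol$interval / protocol$step)
  if (abs(record_every * protocol$step - protocol$interval) > 1e-9) {
    stop("'interval' must be an integer multiple of 'step'", call. = FALSE)
  }
  nrec <- floor(protocol$duration / protocol$interval)
  tables <- build_cpp_tables(compiled)
  mat <- rk4_integrate(
    unname(y0), protocol$step, nrec, record_every,
    tables$variant, tables$par, tables$spec, tables$vol,
    tables$trip_r, tables$trip_s, tables$trip_m, tables$n_track,
    tables$track_slot, tables$track_type, tables$track_reac,
    tables$track_weight
  )
  out <- cbind(seq(0, by = protocol$interval, length.out = nrec + 1L), mat)
  colnames(out) <- c("time", compiled$state_ids)
  out
}

# encode typed rate laws as numeric tables for the C++ integrator
build_cpp_tables <- function(compiled) {
  model <- compiled$model
  sp_index <- stats::setNames(seq_along(compiled$state_ids) - 1L,
                              compiled$state_ids)
  reacs <- model$reactions
  n <- length(reacs)
  variant <- integer(n)
  par <- matrix(0, n, 5L)
  spec <- matrix(-1L, n, 3L)
  vol <- numeric(n)
  resolve <- function(law, name, default = NULL) {
    v <- law$params[[name]]
    if (is.null(v)) {
      if (is.null(default)) stop("missing law parameter ", name)
      return(default)
    }
    resolve_law_param(v, model$parameters, name)
  }
  for (i in seq_len(n)) {
    law <- reacs[[i]]$law
    vol[i] <- law$volume
    switch(law$variant,
      MassAction = {
        subs <- law$species$substrates
        if (length(subs) > 3L) {
          stop("rk4 path supports mass action up to order 3", call. = FALSE)
        }
        variant[i] <- 1L
        par[i, 1L] <- resolve(law, "k")
        spec[i, seq_along(subs)] <- sp_index[subs]
      },
      MichaelisMentenIrreversible = {
        if (!is.null(law$species$enzyme)) {
          variant[i] <- 3L
          par[i, 1L] <- resolve(law, "kcat")
          spec[i, 2L] <- sp_index[[law$species$enzyme]]
        } else {
          variant[i] <- 2L
          par[i, 1L] <- resolve(law, "Vmax")
        }
        par[i, 2L] <- resolve(law, "Km")
        spec[i, 1L] <- sp_index[[law$species$substrate]]
      },
      MichaelisMentenPartitioned = {
        variant[i] <- 4L
        par[i, 1L] <- resolve(law, "kcat")
        par[i, 2L] <- resolve(law, "Km")
        spec[i, 1L] <- sp_index[[law$species$substrate]]
        spec[i, 2L] <- sp_index[[law$species$cosubstrate]]
        spec[i, 3L] <- sp_index[[law$species$enzyme]]
      },
      PassiveDiffusion = {
        variant[i] <- 5L
        par[i, 1L] <- resolve(law, "k")
        spec[i, 1L] <- sp_index[[law$species$outside]]
        spec[i, 2L] <- sp_index[[law$species$inside]]
      },
      HillActivatedSynthesis = {
        variant[i] <- 6L
        par[i, 1L] <- resolve(law, "basal", 0)
        par[i, 2L] <- resolve(law, "Vmax")
        par[i, 3L] <- resolve(law, "K")
        par[i, 4L] <- resolve(law, "n", 1)
        par[i, 5L] <- resolve(law, "scale", 1)
        spec[i, 1L] <- sp_index[[law$species$activator]]
      },
      FirstOrderDecay = {
        variant[i] <- 7L
        par[i, 1L] <- resolve(law, "k")
        spec[i, 1L] <- sp_index[[law$species$substrate]]
      },
      ConstantSource = {
        variant[i] <- 8L
        par[i, 1L] <- resolve(law, "k")
      },
      stop("the rk4 integrator requires typed rate laws (reaction '",
           reacs[[i]]$id, "' has a ", law$variant, " law)", call. = FALSE)
    )
  }
  trip_r <- integer(0); trip_s <- integer(0); trip_m <- numeric(0)
  for (i in seq_len(n)) {
    st <- reacs[[i]]$stoich
    for (sp in names(st)) {
      if (compiled$boundary[[sp]]) next
      v <- compiled$vol_by_comp[[model$species[[sp]]$compartment]]
      trip_r <- c(trip_r, i - 1L)
      trip_s <- c(trip_s, sp_index[[sp]])
      trip_m <- c(trip_m, st[[sp]] / v)
    }
  }
  # tracker rows: (slot, type, reaction, weight); several rows may add into
  # the same cumulative slot (net intake = diffusion - Phase 0 efflux)
  track_slot <- integer(0); track_type <- integer(0)
  track_reac <- integer(0); track_weight <- numeric(0)
  for (k in seq_along(compiled$trackers)) {
    tr <- compiled$trackers[[k]]
    if (tr == "n_Xin") {
      intake <- model$meta$intake
      if (identical(compiled$intake_mode, "gross")) {
        track_slot <- c(track_slot, k - 1L)
        track_type <- c(track_type, 1L)
        track_reac <- c(track_reac, which(names(reacs) == intake$gross) - 1L)
        track_weight <- c(track_weight, 1)
      } else {
        for (rid in names(intake$net)) {
          track_slot <- c(track_slot, k - 1L)
          track_type <- c(track_type, 0L)
          track_reac <- c(track_reac, which(names(reacs) == rid) - 1L)
          track_weight <- c(track_weight, intake$net[[rid]])
        }
      }
    } else {
      rid <- sub("^cum_", "", tr)
      track_slot <- c(track_slot, k - 1L)
      track_type <- c(track_type, 0L)
      track_reac <- c(track_reac, which(names(reacs) == rid) - 1L)
      track_weight <- c(track_weight, 1)
    }
  }
  list(variant = variant, par = par, spec = spec, vol = vol,
       trip_r = trip_r, trip_s = trip_s, trip_m = trip_m,
       n_track = length(compiled$trackers),
       track_slot = track_slot, track_type = track_type,
       track_reac = track_reac, track_weight = track_weight)
}
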