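# Model compilation: typed rate laws -> R expressions -> a generated
# right-hand-side function for the ODE solver, plus root/event functions
# implementing SBML event semantics (fire on false->true trigger crossings).

# Quoted R expression for the flux of a rate law (amount/s), over species
# and global-parameter ids.
law_to_expr <- function(law) {
  p <- function(name, default = NULL) {
    v <- law$params[[name]]
    if (is.null(v)) {
      if (is.null(default)) {
        stop("rate law is missing parameter '", name, "'", call. = FALSE)
      }
      return(default)
    }
    if (is.character(v)) as.name(v) else v
  }
  s <- function(role) as.name(law$species[[role]])
  V <- law$volume
  switch(law$variant,
    MassAction = {
      prod_expr <- Reduce(function(a, b) call("*", a, b),
                          lapply(law$species$substrates, as.name))
      substitute(K * PROD * V, list(K = p("k"), PROD = prod_expr, V = V))
    },
    MichaelisMentenIrreversible = {
      if (!is.null(law$species$enzyme)) {
        substitute(KCAT * E * V * S / (KM + S),
                   list(KCAT = p("kcat"), E = s("enzyme"), V = V,
                        S = s("substrate"), KM = p("Km")))
      } else {
        substitute(VMAX * S / (KM + S),
                   list(VMAX = p("Vmax"), S = s("substrate"), KM = p("Km")))
      }
    },
    MichaelisMentenPartitioned = {
      substitute(
        ifelse(S + S2 > 0, KCAT * E * (S / (S + S2)) * V * S / (KM + S), 0),
        list(KCAT = p("kcat"), E = s("enzyme"), S = s("substrate"),
             S2 = s("cosubstrate"), V = V, KM = p("Km"))
      )
    },
    PassiveDiffusion = {
      substitute(K * (OUT - IN),
                 list(K = p("k"), OUT = s("outside"), IN = s("inside")))
    },
    HillActivatedSynthesis = {
      substitute(SC * (B + VM * A^N / (K^N + A^N)) * V,
                 list(SC = p("scale", 1), B = p("basal", 0), VM = p("Vmax"),
                      A = s("activator"), N = p("n", 1), K = p("K"), V = V))
    },
    FirstOrderDecay = {
      substitute(K * S * V, list(K = p("k"), S = s("substrate"), V = V))
    },
    ConstantSource = p("k"),
    Generic = law$expr
  )
}

# gross inward part of a reaction's flux (for cumulative drug intake)
law_to_gross_expr <- function(law) {
  if (law$variant == "PassiveDiffusion") {
    p <- law$params$k
    substitute(K * OUT, list(K = if (is.character(p)) as.name(p) else p,
                             OUT = as.name(law$species$outside)))
  } else {
    substitute(max(FLUX, 0), list(FLUX = law_to_expr(law)))
  }
}

# trigger expression -> margin expression (margin >= 0 <=> trigger true)
trigger_margin_expr <- function(trigger) {
  if (!is.call(trigger) || length(trigger) != 3L) {
    stop("unsupported event trigger (only simple relational triggers ",
         "are supported): ", deparse(trigger), call. = FALSE)
  }
  op <- as.character(trigger[[1L]])
  lhs <- trigger[[2L]]
  rhs <- trigger[[3L]]
  switch(op,
    ">" = , ">=" = call("-", lhs, rhs),
    "<" = , "<=" = call("-", rhs, lhs),
    stop("unsupported event trigger operator '", op, "'", call. = FALSE)
  )
}

#' @keywords internal
compile_model <- function(model, intake_mode = c("net", "gross"),
                          track_reactions = character()) {
  intake_mode <- match.arg(intake_mode)
  stop_if_invalid(model)

  sp_ids <- names(model$species)
  assignment_rules <- Filter(function(r) r$type == "assignment", model$rules)
  rate_rules <- Filter(function(r) r$type == "rate", model$rules)
  assignment_vars <- vapply(assignment_rules, `[[`, character(1), "variable")
  rate_vars <- setdiff(vapply(rate_rules, `[[`, character(1), "variable"),
                       sp_ids)
  event_vars <- setdiff(
    unique(unlist(lapply(model$events, function(e) names(e$assignments)))),
    c(sp_ids, rate_vars, assignment_vars)
  )

  trackers <- character()
  # cumulative drug intake: either the gross inward plasma-membrane
  # diffusion flux, or the cell's net drug uptake (diffusion net of the
  # Phase 0 efflux return)
  intake <- model$meta$intake
  has_intake <- !is.null(intake) &&
    ((intake_mode == "gross" && intake$gross %in% names(model$reactions)) ||
     (intake_mode == "net" &&
        all(names(intake$net) %in% names(model$reactions))))
  if (has_intake) trackers <- "n_Xin"
  track_reactions <- intersect(track_reactions, names(model$reactions))
  if (length(track_reactions) > 0) {
    trackers <- c(trackers, paste0("cum_", track_reactions))
  }

  state_ids <- c(sp_ids, rate_vars, event_vars, trackers)
  n_state <- length(state_ids)
  idx <- stats::setNames(seq_len(n_state), state_ids)

  boundary <- vapply(model$species, `[[`, logical(1), "boundary")
  vol_by_comp <- stats::setNames(
    vapply(model$compartments, `[[`, numeric(1), "volume"),
    names(model$compartments)
  )

  lines <- character()
  add <- function(...) lines <<- c(lines, paste0(...))

  add("time <- t")
  for (i in seq_len(n_state)) {
    if (state_ids[[i]] %in% sp_ids) {
      # concentrations can dip a hair below zero within solver tolerance;
      # rate laws are evaluated on the clamped value so kinks at zero stay
      # one-sided and fluxes never amplify the noise
      add(state_ids[[i]], " <- max(y[[", i, "L]], 0)")
    } else {
      add(state_ids[[i]], " <- y[[", i, "L]]")
    }
  }
  fixed_pars <- setdiff(names(model$parameters),
                        c(rate_vars, event_vars, assignment_vars))
  for (id in fixed_pars) {
    add(id, " <- ", sprintf("%.17g", model$parameters[[id]]))
  }
  for (id in names(vol_by_comp)) {
    add(id, " <- ", sprintf("%.17g", vol_by_comp[[id]]))
  }
  for (rule in assignment_rules) {
    add(rule$variable, " <- ", deparse1(rule$expr))
  }

  flux_name <- stats::setNames(
    paste0("v_", make.names(names(model$reactions), unique = TRUE)),
    names(model$reactions)
  )
  for (rx in model$reactions) {
    add(flux_name[[rx$id]], " <- ", deparse1(law_to_expr(rx$law)))
  }

  # species derivatives: sum(stoich * flux) / compartment volume
  terms <- stats::setNames(vector("list", length(sp_ids)), sp_ids)
  for (rx in model$reactions) {
    for (sp in names(rx$stoich)) {
      if (boundary[[sp]]) next
      mult <- rx$stoich[[sp]] / vol_by_comp[[model$species[[sp]]$compartment]]
      terms[[sp]] <- c(terms[[sp]],
                       sprintf("%.17g * %s", mult, flux_name[[rx$id]]))
    }
  }
  derivs <- character(n_state)
  for (i in seq_along(sp_ids)) {
    sp <- sp_ids[[i]]
    derivs[i] <- if (boundary[[sp]] || length(terms[[sp]]) == 0) {
      "0"
    } else {
      paste(terms[[sp]], collapse = " + ")
    }
  }
  for (rule in rate_rules) {
    derivs[idx[[rule$variable]]] <- deparse1(rule$expr)
  }
  for (ev in event_vars) {
    derivs[idx[[ev]]] <- "0"
  }
  if ("n_Xin" %in% trackers) {
    derivs[idx[["n_Xin"]]] <- if (intake_mode == "gross") {
      deparse1(law_to_gross_expr(model$reactions[[intake$gross]]$law))
    } else {
      paste(sprintf("%.17g * %s", unname(intake$net),
                    flux_name[names(intake$net)]),
            collapse = " + ")
    }
  }
  for (rid in track_reactions) {
    derivs[idx[[paste0("cum_", rid)]]] <- flux_name[[rid]]
  }

  deriv_vec <- paste0("c(", paste(derivs, collapse = ",\n    "), ")")
  ret <- if (length(assignment_vars) > 0) {
    paste0("list(", deriv_vec, ", c(",
           paste(sprintf("%s = %s", assignment_vars, assignment_vars),
                 collapse = ", "),
           "))")
  } else {
    paste0("list(", deriv_vec, ")")
  }

  preamble <- paste(lines, collapse = "\n")
  rhs_text <- paste0("function(t, y, parms) {\n", preamble, "\n", ret, "\n}")
  rhs <- eval(parse(text = rhs_text)[[1L]], envir = baseenv())

  rootfun <- NULL
  eventfun <- NULL
  event_state <- NULL
  terminal_index <- integer(0)
  if (length(model$events) > 0) {
    margins <- vapply(model$events, function(ev) {
      deparse1(trigger_margin_expr(ev$trigger))
    }, character(1))
    root_text <- paste0("function(t, y, parms) {\n", preamble, "\nc(",
                        paste(margins, collapse = ",\n  "), ")\n}")
    rootfun <- eval(parse(text = root_text)[[1L]], envir = baseenv())
    terminal_index <- which(vapply(model$events, function(e) isTRUE(e$terminal),
                                   logical(1)))
    event_state <- new.env(parent = emptyenv())
    event_state$last_truth <- rep(FALSE, length(model$events))
    events <- model$events
    eventfun <- function(t, y, parms) {
      m <- rootfun(t, y, parms)
      truth <- m >= 0
      fired <- which(truth & !event_state$last_truth |
                       (abs(m) < 1e-9 & !event_state$last_truth))
      for (k in fired) {
        env <- eval_symbol_env(t, y, state_ids, model, assignment_rules,
                               vol_by_comp)
        for (var in names(events[[k]]$assignments)) {
          y[[idx[[var]]]] <- eval(events[[k]]$assignments[[var]], envir = env)
        }
      }
      # re-evaluate truth after assignments so chained states stay consistent
      event_state$last_truth <- rootfun(t, y, parms) >= 0
      y
    }
  }

  list(
    model = model, rhs = rhs, rootfun = rootfun, eventfun = eventfun,
    event_state = event_state, terminal_index = terminal_index,
    intake_mode = intake_mode,
    state_ids = state_ids, species_ids = sp_ids, rate_vars = rate_vars,
    event_vars = event_vars, trackers = trackers,
    assignment_vars = assignment_vars, boundary = boundary,
    vol_by_comp = vol_by_comp, idx = idx
  )
}

# evaluation environment exposing all model symbols at a state point
eval_symbol_env <- function(t, y, state_ids, model, assignment_rules,
                            vol_by_comp) {
  env <- new.env(parent = baseenv())
  assign("time", t, envir = env)
  for (i in seq_along(state_ids)) {
    assign(state_ids[[i]], y[[i]], envir = env)
  }
  for (id in names(model$parameters)) {
    if (!id %in% state_ids && !exists(id, envir = env, inherits = FALSE)) {
      assign(id, model$parameters[[id]], envir = env)
    }
  }
  for (id in names(vol_by_comp)) {
    assign(id, vol_by_comp[[id]], envir = env)
  }
  for (rule in assignment_rules) {
    assign(rule$variable, eval(rule$expr, envir = env), envir = env)
  }
  env
}

# initial state vector for a compiled model
initial_state <- function(compiled) {
  model <- compiled$model
  y0 <- numeric(length(compiled$state_ids))
  names(y0) <- compiled$state_ids
  for (id in compiled$species_ids) {
    y0[[id]] <- model$species[[id]]$initial
  }
  for (id in c(compiled$rate_vars, compiled$event_vars)) {
    y0[[id]] <- if (id %in% names(model$parameters)) {
      model$parameters[[id]]
    } else {
      0
    }
  }
  y0
}
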