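#' Construct a kinetic model
#'
#' The executable network: compartments, species, global parameters,
#' reactions with typed or generic rate laws, assignment/rate rules, and
#' events. This is the in-memory counterpart of an SBML Level 2 Version 4
#' document restricted to the subset the simulator supports.
#'
#' @param id model identifier.
#' @param compartments named list; each element `list(id, volume)` with
#'   volume in litres.
#' @param species named list; each element
#'   `list(id, compartment, initial, boundary, role)`. `boundary = TRUE`
#'   species are held constant by the integrator (the extracellular drug
#'   pool). `role` is a free tag (`"drug"`, `"oxidized"`, `"conjugated"`,
#'   `"background"`, `"enzyme"`, `"mRNA"`, `"regulator"`, `"bookkeeping"`).
#' @param parameters named numeric vector of global parameters. Parameters
#'   named in `varying` may be changed by rate rules or events (SBML
#'   `constant="false"`).
#' @param reactions named list; each element
#'   `list(id, stoich, law, compartment)` where `stoich` is a named numeric
#'   vector (species id -> signed stoichiometric coefficient) and `law` a
#'   [rate_law()].
#' @param rules list of `list(type = "assignment"|"rate", variable, expr)`
#'   entries; `expr` is a quoted R expression over species, parameter and
#'   compartment ids (plus `time`). Assignment rules are evaluated in the
#'   order given.
#' @param events list of `list(id, trigger, assignments, terminal)` entries.
#'   `trigger` is a quoted relational expression (e.g. `quote(F <= 0)`);
#'   `assignments` a named list of quoted expressions assigned to variables
#'   when the trigger switches from false to true. `terminal = TRUE` marks
#'   the cell-death interrupt: integration stops when it fires.
#' @param varying character vector of parameter ids that rules or events may
#'   modify.
#' @param meta free-form list for package bookkeeping (not serialized).
#' @return an object of class `kin_model`.
#' @seealso [build_reference_model()], [validate_model()], [simulate()]
#' @export
kin_model <- function(id, compartments, species, parameters = numeric(),
                      reactions = list(), rules = list(), events = list(),
                      varying = character(), meta = list()) {
  names(compartments) <- vapply(compartments, `[[`, character(1), "id")
  names(species) <- vapply(species, `[[`, character(1), "id")
  if (length(reactions) > 0) {
    names(reactions) <- vapply(reactions, `[[`, character(1), "id")
  }
  structure(
    list(id = id, compartments = compartments, species = species,
         parameters = parameters, reactions = reactions, rules = rules,
         events = events, varying = varying, meta = meta),
    class = "kin_model"
  )
}

#' @export
print.kin_model <- function(x, ...) {
  cat("<kin_model '", x$id, "'>\n", sep = "")
  cat("  compartments:", length(x$compartments),
      " species:", length(x$species),
      " reactions:", length(x$reactions), "\n")
  cat("  parameters:", length(x$parameters),
      " rules:", length(x$rules),
      " events:", length(x$events), "\n")
  invisible(x)
}

#' @rdname kin_model
#' @param model a `kin_model`.
#' @export
species_ids <- function(model) names(model$species)

#' @rdname kin_model
#' @export
boundary_ids <- function(model) {
  names(model$species)[vapply(model$species, `[[`, logical(1), "boundary")]
}

# species ids with a given role tag
role_ids <- function(model, role) {
  names(model$species)[
    vapply(model$species, function(s) identical(s$role, role), logical(1))
  ]
}

# the externally fixed drug pool (X_e in the reference network)
drug_boundary_id <- function(model) {
  ids <- intersect(boundary_ids(model), role_ids(model, "drug"))
  if (length(ids) == 0) NULL else ids[[1L]]
}

compartment_volume <- function(model, id) {
  comp <- model$compartments[[id]]
  if (is.null(comp)) stop("unknown compartment '", id, "'", call. = FALSE)
  comp$volume
}

#' Override model parameters
#'
#' Returns a copy of the model with the given global parameters replaced.
#' Unlike [apply_parameter_multiplier()], explicit overrides may set a
#' parameter to zero (e.g. a knockout of an enzyme's turnover).
#'
#' @param model a [kin_model()].
#' @param overrides named numeric vector or list of new parameter values.
#' @return the modified model (the input is unchanged).
#' @export
set_parameters <- function(model, overrides) {
  overrides <- unlist(overrides)
  if (length(overrides) == 0) return(model)
  unknown <- setdiff(names(overrides), names(model$parameters))
  if (length(unknown) > 0) {
    stop("unknown parameter id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  model$parameters[names(overrides)] <- as.numeric(overrides)
  model
}

#' Scale one model parameter by a factor
#'
#' Parameter scans and the expression-modulation experiments express
#' perturbations as multiples of the default value. The factor must be
#' strictly positive; use [set_parameters()] (or the `overrides` argument of
#' [build_reference_model()]) for knockouts.
#'
#' @param model a [kin_model()].
#' @param parameter id of a global parameter.
#' @param factor strictly positive scale factor.
#' @return a copy of the model with the parameter scaled.
#' @export
apply_parameter_multiplier <- function(model, parameter, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0) {
    stop("'factor' must be a single positive number", call. = FALSE)
  }
  if (!parameter %in% names(model$parameters)) {
    stop("unknown parameter id: ", parameter, call. = FALSE)
  }
  model$parameters[[parameter]] <- model$parameters[[parameter]] * factor
  model
}

#' Export the parameter table
#'
#' @param model a [kin_model()].
#' @return a data frame with columns `id` and `value`, one row per global
#'   parameter (writable as TSV).
#' @export
parameter_table <- function(model) {
  data.frame(id = names(model$parameters),
             value = unname(model$parameters),
             stringsAsFactors = FALSE)
}

# All symbols known to the model: species, parameters, compartments, time.
model_symbols <- function(model) {
  c(names(model$species), names(model$parameters),
    names(model$compartments), "time")
}

expr_symbols <- function(expr) {
  if (is.name(expr)) return(as.character(expr))
  if (is.call(expr)) {
    return(unique(unlist(lapply(as.list(expr)[-1L], expr_symbols))))
  }
  character()
}
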