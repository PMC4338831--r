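#' Validate a kinetic model
#'
#' Structural validation run before any simulation: the simulator refuses
#' models whose report contains at least one error.
#'
#' Errors: dangling species/compartment/parameter references, negative
#' kinetic constants, negative initial concentrations, nonpositive
#' compartment volumes, partitioned-law pairs not sharing an enzyme, rule or
#' event variables that are neither species nor varying parameters.
#' Warnings: species referenced by nothing.
#'
#' @param model a [kin_model()].
#' @return a data frame of class `validation_report` with columns
#'   `severity` (`"error"`/`"warning"`), `location`, `message`.
#' @export
validate_model <- function(model) {
  findings <- list()
  note <- function(severity, location, message) {
    findings[[length(findings) + 1L]] <<-
      data.frame(severity = severity, location = location, message = message,
                 stringsAsFactors = FALSE)
  }

  sp_ids <- names(model$species)
  if (anyDuplicated(sp_ids)) {
    note("error", "species", "duplicated species ids")
  }
  for (comp in model$compartments) {
    if (!is.numeric(comp$volume) || comp$volume <= 0) {
      note("error", comp$id, "compartment volume must be > 0")
    }
  }
  for (sp in model$species) {
    if (!sp$compartment %in% names(model$compartments)) {
      note("error", sp$id,
           paste0("species placed in nonexistent compartment '",
                  sp$compartment, "'"))
    }
    if (!is.numeric(sp$initial) || is.na(sp$initial) || sp$initial < 0) {
      note("error", sp$id, "negative or missing initial concentration")
    }
  }

  known <- model_symbols(model)
  referenced <- character()

  for (rx in model$reactions) {
    loc <- paste0("reaction:", rx$id)
    bad <- setdiff(names(rx$stoich), sp_ids)
    if (length(bad) > 0) {
      note("error", loc,
           paste0("stoichiometry references unknown species: ",
                  paste(bad, collapse = ", ")))
    }
    referenced <- c(referenced, names(rx$stoich))
    law <- rx$law
    if (law$variant == "Generic") {
      syms <- expr_symbols(law$expr)
      bad <- setdiff(syms, c(known, math_builtin_symbols()))
      if (length(bad) > 0) {
        note("error", loc,
             paste0("kinetic law references unknown symbols: ",
                    paste(bad, collapse = ", ")))
      }
      referenced <- c(referenced, intersect(syms, sp_ids))
    } else {
      ids <- law_species_ids(law)
      bad <- setdiff(ids, sp_ids)
      if (length(bad) > 0) {
        note("error", loc,
             paste0("rate law references unknown species: ",
                    paste(bad, collapse = ", ")))
      }
      referenced <- c(referenced, ids)
      for (pn in names(law$params)) {
        pv <- law$params[[pn]]
        if (is.character(pv)) {
          if (!pv %in% names(model$parameters)) {
            note("error", loc,
                 paste0("rate-law parameter '", pn,
                        "' references unknown model parameter '", pv, "'"))
          } else if (model$parameters[[pv]] < 0) {
            note("error", loc,
                 paste0("kinetic constant '", pv, "' is negative"))
          }
        } else if (is.numeric(pv) && is.finite(pv) && pv < 0) {
          note("error", loc, paste0("kinetic constant '", pn, "' is negative"))
        }
      }
    }
  }

  # partitioned laws must come in pairs sharing the enzyme, with swapped
  # substrate/cosubstrate
  part <- Filter(function(rx) rx$law$variant == "MichaelisMentenPartitioned",
                 model$reactions)
  if (length(part) > 0) {
    by_enzyme <- split(part, vapply(part, function(rx) rx$law$species$enzyme,
                                    character(1)))
    for (enz in names(by_enzyme)) {
      grp <- by_enzyme[[enz]]
      subs <- vapply(grp, function(rx) rx$law$species$substrate, character(1))
      cosubs <- vapply(grp, function(rx) rx$law$species$cosubstrate,
                       character(1))
      if (length(grp) != 2L || !setequal(subs, cosubs)) {
        note("error", paste0("enzyme:", enz),
             "partitioned laws must form a pair sharing one enzyme with swapped substrates")
      }
    }
  }

  rule_vars <- character()
  for (rule in model$rules) {
    loc <- paste0("rule:", rule$variable)
    if (!rule$variable %in% c(sp_ids, model$varying)) {
      note("error", loc,
           "rule variable is neither a species nor a varying parameter")
    }
    rule_vars <- c(rule_vars, rule$variable)
    bad <- setdiff(expr_symbols(rule$expr), c(known, math_builtin_symbols()))
    if (length(bad) > 0) {
      note("error", loc, paste0("rule references unknown symbols: ",
                                paste(bad, collapse = ", ")))
    }
  }
  for (ev in model$events) {
    loc <- paste0("event:", ev$id)
    bad <- setdiff(expr_symbols(ev$trigger), c(known, math_builtin_symbols()))
    if (length(bad) > 0) {
      note("error", loc, paste0("trigger references unknown symbols: ",
                                paste(bad, collapse = ", ")))
    }
    for (var in names(ev$assignments)) {
      if (!var %in% c(sp_ids, model$varying)) {
        note("error", loc,
             paste0("event assigns to '", var,
                    "', which is neither a species nor a varying parameter"))
      }
      bad <- setdiff(expr_symbols(ev$assignments[[var]]),
                     c(known, math_builtin_symbols()))
      if (length(bad) > 0) {
        note("error", loc, paste0("event assignment references unknown ",
                                  "symbols: ", paste(bad, collapse = ", ")))
      }
    }
  }

  rule_syms <- unlist(lapply(model$rules, function(r) expr_symbols(r$expr)))
  used <- unique(c(referenced, rule_syms, rule_vars))
  unused <- setdiff(sp_ids, used)
  for (id in unused) {
    note("warning", id, "species is referenced by no reaction or rule")
  }

  report <- if (length(findings) == 0) {
    data.frame(severity = character(), location = character(),
               message = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
  class(report) <- c("validation_report", "data.frame")
  report
}

#' @export
print.validation_report <- function(x, ...) {
  n_err <- sum(x$severity == "error")
  n_warn <- sum(x$severity == "warning")
  cat("<validation_report> ", n_err, " error(s), ", n_warn,
      " warning(s)\n", sep = "")
  if (nrow(x) > 0) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Count error-severity findings in a validation report
#'
#' @param report a report from [validate_model()].
#' @return number of `"error"` rows.
#' @export
validation_errors <- function(report) sum(report$severity == "error")

# symbols allowed in math expressions besides model ids
math_builtin_symbols <- function() c("pi", "T", "F")

stop_if_invalid <- function(model) {
  report <- validate_model(model)
  if (validation_errors(report) > 0) {
    bad <- report[report$severity == "error", , drop = FALSE]
    stop("model '", model$id, "' failed validation:\n",
         paste0("  [", bad$location, "] ", bad$message, collapse = "\n"),
         call. = FALSE)
  }
  invisible(report)
}
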