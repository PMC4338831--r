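#' Read an SBML Level 2 model
#'
#' Parses an SBML Level 2 document (canonically Version 4) into a
#' [kin_model()]. The supported subset is: compartments, species (with
#' `boundaryCondition`), global and local parameters, reactions with MathML
#' kinetic laws, assignment and rate rules, events with trigger and event
#' assignments, and function definitions (inlined). Anything outside the
#' subset — algebraic rules, initial assignments, constraints, event delays,
#' `stoichiometryMath`, species declared as amounts-only — raises an
#' unsupported-feature error naming the element rather than being silently
#' dropped.
#'
#' Species given as `initialAmount` are normalized to concentrations using
#' the compartment size; local kinetic-law parameters are inlined into the
#' math as numeric constants.
#'
#' @param path file path, URL or connection understood by
#'   [xml2::read_xml()], or a string of XML.
#' @return a [kin_model()].
#' @seealso [write_sbml()]
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      stop("SBML parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
  xml2::xml_ns_strip(doc)
  if (xml2::xml_name(doc) != "sbml") {
    stop("not an SBML document (root element is <",
         xml2::xml_name(doc), ">)", call. = FALSE)
  }
  level <- xml2::xml_attr(doc, "level")
  if (!identical(level, "2")) {
    stop("unsupported SBML level: ", level, " (only Level 2 is supported)",
         call. = FALSE)
  }
  mod <- xml2::xml_find_first(doc, "./model")
  if (inherits(mod, "xml_missing")) {
    stop("SBML document has no <model> element", call. = FALSE)
  }

  refuse <- function(xpath, what) {
    if (length(xml2::xml_find_all(mod, xpath)) > 0) {
      stop("unsupported SBML construct: ", what, call. = FALSE)
    }
  }
  refuse("./listOfRules/algebraicRule", "algebraicRule")
  refuse("./listOfInitialAssignments", "initialAssignment")
  refuse("./listOfConstraints", "constraint")
  refuse(".//event/delay", "event delay")
  refuse(".//speciesReference/stoichiometryMath", "stoichiometryMath")
  refuse("./listOfSpecies/species[@hasOnlySubstanceUnits='true']",
         "species with hasOnlySubstanceUnits")
  refuse("./listOfReactions/reaction[@fast='true']", "fast reaction")

  # function definitions: id -> list(args, body); inlined into all math
  fundefs <- list()
  for (fd in xml2::xml_find_all(mod, "./listOfFunctionDefinitions/functionDefinition")) {
    id <- xml2::xml_attr(fd, "id")
    lambda <- xml2::xml_find_first(fd, "./math/lambda")
    if (inherits(lambda, "xml_missing")) {
      stop("unsupported SBML construct: functionDefinition without lambda",
           call. = FALSE)
    }
    bvars <- vapply(xml2::xml_find_all(lambda, "./bvar/ci"),
                    function(n) trimws(xml2::xml_text(n)), character(1))
    kids <- xml2::xml_children(lambda)
    body_node <- kids[[length(kids)]]
    fundefs[[id]] <- list(args = bvars, body = mathml_to_expr(body_node))
  }
  read_math <- function(node) {
    math <- xml2::xml_find_first(node, "./math")
    if (inherits(math, "xml_missing")) {
      stop("missing <math> element under <", xml2::xml_name(node), ">",
           call. = FALSE)
    }
    inline_fundefs(mathml_to_expr(math), fundefs)
  }

  compartments <- lapply(
    xml2::xml_find_all(mod, "./listOfCompartments/compartment"),
    function(n) {
      size <- xml2::xml_attr(n, "size")
      list(id = xml2::xml_attr(n, "id"),
           volume = if (is.na(size)) 1 else as.numeric(size))
    }
  )
  vol_of <- stats::setNames(
    vapply(compartments, `[[`, numeric(1), "volume"),
    vapply(compartments, `[[`, character(1), "id")
  )

  species <- lapply(xml2::xml_find_all(mod, "./listOfSpecies/species"),
                    function(n) {
    id <- xml2::xml_attr(n, "id")
    comp <- xml2::xml_attr(n, "compartment")
    conc <- xml2::xml_attr(n, "initialConcentration")
    amount <- xml2::xml_attr(n, "initialAmount")
    initial <- if (!is.na(conc)) {
      as.numeric(conc)
    } else if (!is.na(amount)) {
      if (!comp %in% names(vol_of)) {
        stop("species '", id, "' declares initialAmount but its compartment ",
             "is unknown", call. = FALSE)
      }
      as.numeric(amount) / vol_of[[comp]]
    } else {
      0
    }
    role_node <- xml2::xml_find_first(n, "./annotation/*[local-name()='species']")
    role <- if (!inherits(role_node, "xml_missing")) {
      xml2::xml_attr(role_node, "role")
    } else {
      "unspecified"
    }
    boundary <- identical(xml2::xml_attr(n, "boundaryCondition"), "true") ||
      identical(xml2::xml_attr(n, "constant"), "true")
    list(id = id, compartment = comp, initial = initial,
         boundary = boundary, role = role)
  })

  par_nodes <- xml2::xml_find_all(mod, "./listOfParameters/parameter")
  parameters <- stats::setNames(
    vapply(par_nodes, function(n) {
      v <- xml2::xml_attr(n, "value")
      if (is.na(v)) 0 else as.numeric(v)
    }, numeric(1)),
    vapply(par_nodes, function(n) xml2::xml_attr(n, "id"), character(1))
  )
  varying <- names(parameters)[
    vapply(par_nodes, function(n) {
      identical(xml2::xml_attr(n, "constant"), "false")
    }, logical(1))
  ]

  rules <- lapply(xml2::xml_find_all(mod, "./listOfRules/*"), function(n) {
    type <- switch(xml2::xml_name(n),
                   assignmentRule = "assignment",
                   rateRule = "rate",
                   stop("unsupported SBML construct: ", xml2::xml_name(n),
                        call. = FALSE))
    list(type = type, variable = xml2::xml_attr(n, "variable"),
         expr = read_math(n))
  })

  reactions <- lapply(xml2::xml_find_all(mod, "./listOfReactions/reaction"),
                      function(n) read_sbml_reaction(n, read_math))

  events <- lapply(xml2::xml_find_all(mod, "./listOfEvents/event"),
                   function(n) {
    trg <- xml2::xml_find_first(n, "./trigger")
    if (inherits(trg, "xml_missing")) {
      stop("event without trigger", call. = FALSE)
    }
    assignments <- list()
    for (ea in xml2::xml_find_all(n, "./listOfEventAssignments/eventAssignment")) {
      assignments[[xml2::xml_attr(ea, "variable")]] <- read_math(ea)
    }
    terminal_node <- xml2::xml_find_first(n, "./annotation/*[local-name()='event']")
    terminal <- !inherits(terminal_node, "xml_missing") &&
      identical(xml2::xml_attr(terminal_node, "terminal"), "true")
    list(id = xml2::xml_attr(n, "id"), trigger = read_math(trg),
         assignments = assignments, terminal = terminal)
  })

  meta <- list()
  intake_node <- xml2::xml_find_first(mod,
                                      "./annotation/*[local-name()='intake']")
  if (!inherits(intake_node, "xml_missing")) {
    net_spec <- strsplit(xml2::xml_attr(intake_node, "net"), ",",
                         fixed = TRUE)[[1L]]
    parts <- strsplit(net_spec, ":", fixed = TRUE)
    meta$intake <- list(
      gross = xml2::xml_attr(intake_node, "gross"),
      net = stats::setNames(
        vapply(parts, function(p) as.numeric(p[2L]), numeric(1)),
        vapply(parts, `[[`, character(1), 1L)
      )
    )
  }

  kin_model(
    id = if (is.na(xml2::xml_attr(mod, "id"))) "sbml_model"
         else xml2::xml_attr(mod, "id"),
    compartments = compartments,
    species = species,
    parameters = parameters,
    reactions = reactions,
    rules = rules,
    events = events,
    varying = varying,
    meta = meta
  )
}

read_sbml_reaction <- function(node, read_math) {
  id <- xml2::xml_attr(node, "id")
  stoich <- numeric()
  add_refs <- function(xpath, sign) {
    for (sr in xml2::xml_find_all(node, xpath)) {
      sp <- xml2::xml_attr(sr, "species")
      st <- xml2::xml_attr(sr, "stoichiometry")
      coef <- sign * if (is.na(st)) 1 else as.numeric(st)
      stoich[sp] <<- if (sp %in% names(stoich)) stoich[[sp]] + coef else coef
    }
  }
  add_refs("./listOfReactants/speciesReference", -1)
  add_refs("./listOfProducts/speciesReference", +1)

  kl <- xml2::xml_find_first(node, "./kineticLaw")
  if (inherits(kl, "xml_missing")) {
    stop("reaction '", id, "' has no kineticLaw", call. = FALSE)
  }
  expr <- read_math(kl)
  # inline local parameters as numeric constants
  local_pars <- xml2::xml_find_all(kl, "./listOfParameters/parameter")
  if (length(local_pars) > 0) {
    subs <- stats::setNames(
      lapply(local_pars, function(p) as.numeric(xml2::xml_attr(p, "value"))),
      vapply(local_pars, function(p) xml2::xml_attr(p, "id"), character(1))
    )
    expr <- substitute_symbols(expr, subs)
  }

  ann <- xml2::xml_find_first(node, "./annotation/*[local-name()='law']")
  law <- if (!inherits(ann, "xml_missing")) {
    typed_law_from_annotation(ann)
  } else {
    rate_law("Generic", expr = expr)
  }
  compartment <- if (!inherits(ann, "xml_missing")) {
    xml2::xml_attr(ann, "compartment")
  } else {
    NA_character_
  }
  list(id = id, stoich = stoich, law = law, compartment = compartment)
}

typed_law_from_annotation <- function(ann) {
  attrs <- xml2::xml_attrs(ann)
  variant <- attrs[["variant"]]
  volume <- as.numeric(attrs[["volume"]])
  params <- list()
  species <- list()
  for (nm in names(attrs)) {
    if (startsWith(nm, "p_")) {
      val <- attrs[[nm]]
      params[[substring(nm, 3L)]] <- if (startsWith(val, "ref:")) {
        substring(val, 5L)
      } else {
        as.numeric(substring(val, 5L))
      }
    } else if (startsWith(nm, "s_")) {
      ids <- strsplit(attrs[[nm]], ",", fixed = TRUE)[[1L]]
      species[[substring(nm, 3L)]] <- ids
    }
  }
  rate_law(variant, params = params, species = species, volume = volume)
}

# replace symbols by values/expressions throughout an expression
substitute_symbols <- function(expr, subs) {
  if (is.name(expr)) {
    nm <- as.character(expr)
    if (nm %in% names(subs)) return(subs[[nm]])
    return(expr)
  }
  if (is.call(expr)) {
    parts <- as.list(expr)
    parts[-1L] <- lapply(parts[-1L], substitute_symbols, subs = subs)
    return(as.call(parts))
  }
  expr
}

# inline SBML function definitions (beta-reduction, recursively)
inline_fundefs <- function(expr, fundefs) {
  if (length(fundefs) == 0 || !is.call(expr)) return(expr)
  fun <- expr[[1L]]
  args <- lapply(as.list(expr)[-1L], inline_fundefs, fundefs = fundefs)
  if (is.name(fun) && as.character(fun) %in% names(fundefs)) {
    fd <- fundefs[[as.character(fun)]]
    if (length(args) != length(fd$args)) {
      stop("function '", as.character(fun), "' applied to ", length(args),
           " arguments, expected ", length(fd$args), call. = FALSE)
    }
    body <- substitute_symbols(fd$body, stats::setNames(args, fd$args))
    return(inline_fundefs(body, fundefs))
  }
  as.call(c(fun, args))
}
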