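SBML_L2V4_NS <- "http://www.sbml.org/sbml/level2/version4"
XD_NS <- "https://xenodyn.invalid/sbml-annotations"

#' Write a model as SBML Level 2 Version 4
#'
#' Serializes a [kin_model()] to SBML: compartments, species (with boundary
#' flags), global parameters (`constant="false"` for rule/event-driven
#' variables), reactions with MathML kinetic laws, assignment and rate
#' rules, and events. Typed rate laws additionally carry a small annotation
#' so that [read_sbml()] can reconstruct the typed form; foreign SBML
#' readers see only the standard MathML. The model is validated first and
#' refused if invalid.
#'
#' @param model a [kin_model()] passing [validate_model()] without errors.
#' @param path file path or connection to write to.
#' @return invisibly, the path.
#' @seealso [read_sbml()]
#' @export
write_sbml <- function(model, path) {
  stop_if_invalid(model)
  doc <- xml2::xml_new_root(
    "sbml", xmlns = SBML_L2V4_NS, `xmlns:xd` = XD_NS,
    level = "2", version = "4"
  )
  mod <- xml2::xml_add_child(doc, "model", id = model$id)

  if (!is.null(model$meta$intake)) {
    ann <- xml2::xml_add_child(mod, "annotation")
    net <- model$meta$intake$net
    xml2::xml_add_child(
      ann, "xd:intake", gross = model$meta$intake$gross,
      net = paste(sprintf("%s:%.17g", names(net), unname(net)),
                  collapse = ","))
  }

  locs <- xml2::xml_add_child(mod, "listOfCompartments")
  for (comp in model$compartments) {
    xml2::xml_add_child(locs, "compartment", id = comp$id,
                        size = num_attr(comp$volume))
  }

  los <- xml2::xml_add_child(mod, "listOfSpecies")
  for (sp in model$species) {
    node <- xml2::xml_add_child(
      los, "species", id = sp$id, compartment = sp$compartment,
      initialConcentration = num_attr(sp$initial),
      boundaryCondition = if (isTRUE(sp$boundary)) "true" else "false"
    )
    ann <- xml2::xml_add_child(node, "annotation")
    xml2::xml_add_child(ann, "xd:species", role = sp$role)
  }

  if (length(model$parameters) > 0) {
    lop <- xml2::xml_add_child(mod, "listOfParameters")
    for (id in names(model$parameters)) {
      xml2::xml_add_child(
        lop, "parameter", id = id,
        value = num_attr(model$parameters[[id]]),
        constant = if (id %in% model$varying) "false" else "true"
      )
    }
  }

  if (length(model$rules) > 0) {
    lor <- xml2::xml_add_child(mod, "listOfRules")
    for (rule in model$rules) {
      tag <- if (rule$type == "assignment") "assignmentRule" else "rateRule"
      node <- xml2::xml_add_child(lor, tag, variable = rule$variable)
      expr_to_mathml(node, rule$expr)
    }
  }

  if (length(model$reactions) > 0) {
    lorx <- xml2::xml_add_child(mod, "listOfReactions")
    for (rx in model$reactions) {
      write_sbml_reaction(lorx, rx, model)
    }
  }

  if (length(model$events) > 0) {
    loe <- xml2::xml_add_child(mod, "listOfEvents")
    for (ev in model$events) {
      node <- xml2::xml_add_child(loe, "event", id = ev$id)
      if (isTRUE(ev$terminal)) {
        ann <- xml2::xml_add_child(node, "annotation")
        xml2::xml_add_child(ann, "xd:event", terminal = "true")
      }
      trg <- xml2::xml_add_child(node, "trigger")
      expr_to_mathml(trg, ev$trigger)
      loa <- xml2::xml_add_child(node, "listOfEventAssignments")
      for (var in names(ev$assignments)) {
        ea <- xml2::xml_add_child(loa, "eventAssignment", variable = var)
        expr_to_mathml(ea, ev$assignments[[var]])
      }
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

write_sbml_reaction <- function(parent, rx, model) {
  law <- rx$law
  reversible <- law$variant %in% c("PassiveDiffusion", "Generic")
  node <- xml2::xml_add_child(parent, "reaction", id = rx$id,
                              reversible = if (reversible) "true" else "false")
  if (law$variant != "Generic") {
    ann <- xml2::xml_add_child(node, "annotation")
    attrs <- list(variant = law$variant, volume = num_attr(law$volume),
                  compartment = rx$compartment)
    for (pn in names(law$params)) {
      pv <- law$params[[pn]]
      attrs[[paste0("p_", pn)]] <-
        if (is.character(pv)) paste0("ref:", pv) else paste0("num:", num_attr(pv))
    }
    for (sn in names(law$species)) {
      attrs[[paste0("s_", sn)]] <- paste(law$species[[sn]], collapse = ",")
    }
    do.call(xml2::xml_add_child, c(list(ann, "xd:law"), attrs))
  }

  reactants <- rx$stoich[rx$stoich < 0]
  products <- rx$stoich[rx$stoich > 0]
  if (length(reactants) > 0) {
    lore <- xml2::xml_add_child(node, "listOfReactants")
    for (id in names(reactants)) {
      xml2::xml_add_child(lore, "speciesReference", species = id,
                          stoichiometry = num_attr(-reactants[[id]]))
    }
  }
  if (length(products) > 0) {
    lopr <- xml2::xml_add_child(node, "listOfProducts")
    for (id in names(products)) {
      xml2::xml_add_child(lopr, "speciesReference", species = id,
                          stoichiometry = num_attr(products[[id]]))
    }
  }
  law_sp <- if (law$variant == "Generic") {
    intersect(expr_symbols(law$expr), names(model$species))
  } else {
    law_species_ids(law)
  }
  modifiers <- setdiff(law_sp, names(rx$stoich))
  if (length(modifiers) > 0) {
    lom <- xml2::xml_add_child(node, "listOfModifiers")
    for (id in modifiers) {
      xml2::xml_add_child(lom, "modifierSpeciesReference", species = id)
    }
  }
  kl <- xml2::xml_add_child(node, "kineticLaw")
  expr_to_mathml(kl, law_to_expr(law))
  node
}

num_attr <- function(x) format(x, digits = 17, scientific = TRUE, trim = TRUE)
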