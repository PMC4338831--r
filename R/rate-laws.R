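#' Kinetic rate laws
#'
#' A rate law describes the flux (amount per second) of one reaction. Seven
#' typed variants cover the reference chemoimmune network; models imported
#' from SBML may additionally carry `"Generic"` laws holding an arbitrary
#' parsed math expression.
#'
#' Typed variants and their parameters (values may be numbers or the id of a
#' global model parameter, resolved at evaluation time):
#'
#' * `MassAction`: `k * prod(substrates) * volume`. `species$substrates` is a
#'   character vector, repeated ids giving higher orders; species listed there
#'   but absent from the reaction stoichiometry act as modifiers.
#' * `MichaelisMentenIrreversible`: either `Vmax * S / (Km + S)` with an
#'   explicit `Vmax` in amount/s, or `kcat * E * S / (Km + S) * volume` when
#'   an `enzyme` species is named.
#' * `MichaelisMentenPartitioned`: as the enzyme form above, but the enzyme is
#'   shared between two alternative substrates and the effective enzyme
#'   concentration is `E * S / (S + S2)` (see [partition_enzyme()]). These
#'   laws come in pairs referencing the same enzyme.
#' * `PassiveDiffusion`: net flux `k * ([outside] - [inside])`; `k` has units
#'   L/s so the result is already amount/s. Sign follows the gradient.
#' * `HillActivatedSynthesis`:
#'   `scale * (basal + Vmax * A^n / (K^n + A^n)) * volume`, with `basal` and
#'   `Vmax` in concentration/s.
#' * `FirstOrderDecay`: `k * S * volume`.
#' * `ConstantSource`: `k` (amount/s).
#'
#' `volume` is the size of the compartment the reaction takes place in; it
#' defaults to 1 so standalone laws can be written directly in amount units.
#'
#' @param variant one of the variant names above.
#' @param params named list of kinetic constants (numeric, or character ids of
#'   global parameters).
#' @param species named list naming the species the law reads
#'   (`substrate`, `cosubstrate`, `enzyme`, `outside`, `inside`, `activator`,
#'   or `substrates` for mass action).
#' @param volume compartment volume factor in litres (default 1).
#' @param expr quoted R expression, only for `variant = "Generic"`.
#' @return an object of class `rate_law`.
#' @seealso [evaluate_rate_law()], [partition_enzyme()]
#' @export
rate_law <- function(variant, params = list(), species = list(), volume = 1,
                     expr = NULL) {
  variants <- c(
    "MassAction", "MichaelisMentenIrreversible", "MichaelisMentenPartitioned",
    "PassiveDiffusion", "HillActivatedSynthesis", "FirstOrderDecay",
    "ConstantSource", "Generic"
  )
  variant <- match.arg(variant, variants)
  if (variant == "Generic" && is.null(expr)) {
    stop("Generic rate laws need an 'expr'", call. = FALSE)
  }
  stopifnot(is.numeric(volume), length(volume) == 1L, volume > 0)
  structure(
    list(variant = variant, params = params, species = species,
         volume = volume, expr = expr),
    class = "rate_law"
  )
}

#' @export
print.rate_law <- function(x, ...) {
  ps <- vapply(x$params, function(p) {
    if (is.character(p)) p else format(p)
  }, character(1))
  cat("<rate_law ", x$variant, "> ",
      paste(names(ps), ps, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Resolve a law parameter that may be a reference to a global parameter.
resolve_law_param <- function(value, parameters, what) {
  if (is.character(value)) {
    if (is.null(parameters) || !value %in% names(parameters)) {
      stop("rate-law parameter '", what, "' references unknown model ",
           "parameter '", value, "'", call. = FALSE)
    }
    return(unname(parameters[[value]]))
  }
  as.numeric(value)
}

law_species_ids <- function(law) {
  unique(unlist(law$species, use.names = FALSE))
}

#' Evaluate a rate law at given concentrations
#'
#' Computes the instantaneous flux of a single rate law, in amount per
#' second, from a named vector of species concentrations (mol/L).
#'
#' All variants return a nonnegative flux for nonnegative concentrations
#' except `PassiveDiffusion`, whose sign equals the sign of the
#' outside-minus-inside concentration difference.
#'
#' @param law a [rate_law()].
#' @param concentrations named numeric vector of species concentrations
#'   (mol/L); must contain every species the law references.
#' @param parameters optional named numeric vector used to resolve law
#'   parameters given as global-parameter ids.
#' @return flux in amount per second (numeric scalar).
#' @examples
#' mm <- rate_law("MichaelisMentenIrreversible",
#'                params = list(Vmax = 10, Km = 5e-9),
#'                species = list(substrate = "S"))
#' evaluate_rate_law(mm, c(S = 5e-9))  # half-saturation: 5
#' @export
evaluate_rate_law <- function(law, concentrations, parameters = NULL) {
  stopifnot(inherits(law, "rate_law"))
  needed <- law_species_ids(law)
  missing_sp <- setdiff(needed, names(concentrations))
  if (length(missing_sp) > 0) {
    stop("rate law references species absent from 'concentrations': ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  if (any(concentrations[needed] < 0)) {
    stop("negative concentration passed to evaluate_rate_law()",
         call. = FALSE)
  }
  p <- function(name, default = NULL) {
    v <- law$params[[name]]
    if (is.null(v)) {
      if (is.null(default)) {
        stop("rate law is missing parameter '", name, "'", call. = FALSE)
      }
      return(default)
    }
    resolve_law_param(v, parameters, name)
  }
  cc <- function(id) unname(concentrations[[id]])
  switch(law$variant,
    MassAction = {
      subs <- law$species$substrates
      p("k") * prod(vapply(subs, cc, numeric(1))) * law$volume
    },
    MichaelisMentenIrreversible = {
      s <- cc(law$species$substrate)
      km <- p("Km")
      if (!is.null(law$species$enzyme)) {
        p("kcat") * cc(law$species$enzyme) * law$volume * s / (km + s)
      } else {
        p("Vmax") * s / (km + s)
      }
    },
    MichaelisMentenPartitioned = {
      s <- cc(law$species$substrate)
      s2 <- cc(law$species$cosubstrate)
      e <- cc(law$species$enzyme)
      e_eff <- partition_enzyme(e, s, s2)[1L]
      p("kcat") * e_eff * law$volume * s / (p("Km") + s)
    },
    PassiveDiffusion = {
      p("k") * (cc(law$species$outside) - cc(law$species$inside))
    },
    HillActivatedSynthesis = {
      a <- cc(law$species$activator)
      n <- p("n", 1)
      k <- p("K")
      act <- if (a <= 0 && n > 0) 0 else a^n / (k^n + a^n)
      p("scale", 1) * (p("basal", 0) + p("Vmax") * act) * law$volume
    },
    FirstOrderDecay = {
      p("k") * cc(law$species$substrate) * law$volume
    },
    ConstantSource = p("k"),
    Generic = {
      env <- as.list(concentrations)
      if (!is.null(parameters)) env <- c(env, as.list(parameters))
      eval(law$expr, envir = env)
    }
  )
}

#' Split a shared enzyme between two alternative substrates
#'
#' The reference network avoids full competitive-inhibition kinetics for the
#' two enzyme/substrate pairs (GST acting on the oxidized xenobiotic and on
#' background reactive species; the Phase III transporter acting on the two
#' conjugates) by dividing the total enzyme amount in proportion to the
#' concentrations of the alternative substrates.
#'
#' When both substrate concentrations are zero the enzyme is split equally;
#' any convention would do, since the downstream Michaelis-Menten flux is
#' zero either way, and the equal split avoids a division by zero.
#'
#' @param total total enzyme amount or concentration (>= 0).
#' @param s1,s2 concentrations of the two alternative substrates (>= 0).
#' @return numeric vector `c(e1, e2)` with `e1 + e2 == total`; `e1` is the
#'   share allotted to the substrate at concentration `s1`.
#' @examples
#' partition_enzyme(10, 2, 3)  # c(4, 6)
#' partition_enzyme(5, 1, 0)   # c(5, 0)
#' @export
partition_enzyme <- function(total, s1, s2) {
  if (total < 0 || s1 < 0 || s2 < 0) {
    stop("partition_enzyme() requires nonnegative inputs", call. = FALSE)
  }
  denom <- s1 + s2
  if (denom == 0) {
    return(c(total / 2, total / 2))
  }
  c(total * s1 / denom, total * s2 / denom)
}
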