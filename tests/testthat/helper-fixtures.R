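# Shared fixtures for the test suite. Heavier simulations are cached within
# a session so several test files can reuse one 60-hour reference run.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = fixture_cache)
  }
  get(key, envir = fixture_cache, inherits = FALSE)
}

reference_model_cached <- function() {
  cached("reference_model", function() build_reference_model())
}

reference_steady_state <- function() {
  cached("reference_steady_state", function() {
    pre_equilibrate(reference_model_cached(), sim_protocol())
  })
}

# 60 h reference run at 75 nM, shared across tests
reference_run_75nM <- function() {
  cached("run_75nM", function() {
    p <- sim_protocol(xe = "75 nM", duration = hours(60))
    simulate_model(reference_model_cached(), p,
                   initial = reference_steady_state())
  })
}

# a tiny two-species model with a single first-order conversion, handy for
# SBML and simulator plumbing tests
tiny_model <- function() {
  kin_model(
    id = "tiny",
    compartments = list(list(id = "cell", volume = 1e-12)),
    species = list(
      list(id = "A", compartment = "cell", initial = 1e-6,
           boundary = FALSE, role = "drug"),
      list(id = "B", compartment = "cell", initial = 0,
           boundary = FALSE, role = "conjugated")
    ),
    parameters = c(k_conv = 1e-3),
    reactions = list(
      list(id = "conv", stoich = c(A = -1, B = 1),
           law = rate_law("FirstOrderDecay", list(k = "k_conv"),
                          list(substrate = "A"), volume = 1e-12),
           compartment = "cell")
    )
  )
}

# synthetic trajectory with a prescribed chemical-load time course for one
# toxic species (critical concentration 1 uM => load == conc in uM)
load_trajectory <- function(times, load) {
  data.frame(time = times, X_c = load * 1e-6)
}

pulse_profile <- function(...) {
  toxicity_profile(X_c = "1 uM", ...)
}

# initial state straight from the species' declared initial concentrations
kin_state_for <- function(model) {
  xenodyn:::kin_state(0, stats::setNames(
    vapply(model$species, `[[`, numeric(1), "initial"),
    names(model$species)))
}
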