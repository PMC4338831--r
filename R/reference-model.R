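#' Default parameters of the reference chemoimmune network
#'
#' Returns the parameter table used by [build_reference_model()]. Units:
#' diffusion constants L/s, catalytic constants 1/s, Michaelis and binding
#' constants mol/L, transcription rates mol/L/s, first-order rates 1/s,
#' constant sources mol/s. The rationale for the values is laid out in the
#' package vignette.
#'
#' @return named numeric vector of parameter defaults.
#' @export
reference_parameters <- function() {
  pars <- c(
    # membrane transport of the unmodified xenobiotic
    kdiff_pm = 1e-12,     # plasma-membrane diffusion, L/s
    kdiff_nm = 5e-13,     # nuclear-membrane diffusion, L/s
    ABC0_kcat = 25, ABC0_Km = 1e-6,
    # Phase I / II / III effectors
    CYP_kcat = 3.5, CYP_Km = 1e-5,
    GST_kcat = 3.5e-3, GST_Km = 2e-6,
    ABCIII_kcat = 0.05, ABCIII_Km = 1e-5,
    # endogenous production of background reactive species
    k_bg = 5e-23,         # mol/s
    # xenobiotic-sensing nuclear receptor
    NR_kon = 1e5, NR_koff = 1e-3,
    # Keap1 release of Nrf2, stimulated by oxidized species
    k_rel_basal = 1e-5, k_rel_ox = 1e3, k_seq = 1e-3
  )
  genes <- c("ABC0", "CYP", "GST", "ABCIII", "Nrf2")
  for (g in genes) {
    basal <- if (g == "ABCIII") 1e-13 else 4e-13
    vmax_nr <- if (g == "ABCIII") 3e-13 else 1.2e-12
    gp <- c(tsc_basal = basal, tsc_vmax_NR = vmax_nr, tsc_K_NR = 5e-8,
            tsc_n_NR = 1, tsc_scale = 1, tln_k = 2e-3, mrna_deg = 2e-4,
            pdeg = 2e-5)
    if (g %in% c("ABC0", "GST", "ABCIII")) {
      vmax_nrf2 <- if (g == "ABCIII") 2e-13 else 8e-13
      gp <- c(gp, tsc_vmax_Nrf2 = vmax_nrf2, tsc_K_Nrf2 = 5e-8,
              tsc_n_Nrf2 = 1)
    }
    names(gp) <- paste(g, names(gp), sep = "_")
    pars <- c(pars, gp)
  }
  pars
}

#' Build the reference chemoimmune network model
#'
#' Hand-coded kinetic model of cellular xenobiotic defense. A xenobiotic X
#' diffuses from a fixed extracellular pool (`X_e`, boundary species) into
#' the cytoplasm (`X_c`) and further into the nucleus (`X_n`). Phase 0
#' efflux (`ABC0`) pumps `X_c` back out; Phase I oxidation (`CYP`) yields
#' `Xp_c` (X'), Phase II conjugation (`GST`) yields `Xpp_c` (X''), and Phase
#' III efflux (`ABCIII`) exports the conjugate, booked extracellularly as
#' `Xpp_e`. A constant endogenous source produces background reactive
#' species `Xp_bc`, conjugated to `Xpp_bc` and exported as `Xpp_be`; GST and
#' ABCIII are shared between the xenobiotic and background branches by
#' proportional enzyme partitioning. `X_c` binds a nuclear receptor (`NR`,
#' forming `XNR_c`) which drives transcription of all four effectors and of
#' Nrf2; Nrf2 is held in a Keap1-sequestered pool (`Nrf2_keap`) and released
#' by oxidized species (`Xp_c`, `Xp_bc`), the free form (`Nrf2`) adding a
#' second transcriptional input to `ABC0`, `GST` and `ABCIII`. Each effector
#' has an mRNA species with first-order turnover at both mRNA and protein
#' level.
#'
#' @param overrides named list/vector of parameter overrides (ids from
#'   [reference_parameters()]); unlike multipliers, overrides may be zero
#'   (knockouts).
#' @return a [kin_model()] that passes [validate_model()] with no errors.
#' @examples
#' mod <- build_reference_model()
#' mod
#' @export
build_reference_model <- function(overrides = list()) {
  V_e <- 1      # extracellular bath: effectively infinite drug reservoir, L
  V_c <- 1e-12  # cytoplasm, L
  V_n <- 5e-13  # nucleus, L

  compartments <- list(
    list(id = "extracellular", volume = V_e),
    list(id = "cytoplasm", volume = V_c),
    list(id = "nucleus", volume = V_n)
  )

  sp <- function(id, compartment, initial = 0, boundary = FALSE, role) {
    list(id = id, compartment = compartment, initial = initial,
         boundary = boundary, role = role)
  }
  species <- list(
    sp("X_e", "extracellular", 0, TRUE, "drug"),
    sp("X_c", "cytoplasm", 0, FALSE, "drug"),
    sp("X_n", "nucleus", 0, FALSE, "drug"),
    sp("Xp_c", "cytoplasm", 0, FALSE, "oxidized"),
    sp("Xpp_c", "cytoplasm", 0, FALSE, "conjugated"),
    sp("Xpp_e", "extracellular", 0, FALSE, "bookkeeping"),
    sp("Xp_bc", "cytoplasm", 0, FALSE, "background"),
    sp("Xpp_bc", "cytoplasm", 0, FALSE, "background"),
    sp("Xpp_be", "extracellular", 0, FALSE, "bookkeeping"),
    sp("NR", "cytoplasm", 1e-7, FALSE, "regulator"),
    sp("XNR_c", "cytoplasm", 0, FALSE, "regulator"),
    sp("Nrf2_keap", "cytoplasm", 1e-9, FALSE, "regulator"),
    sp("Nrf2", "cytoplasm", 1e-10, FALSE, "regulator"),
    sp("ABC0", "cytoplasm", 1e-9, FALSE, "enzyme"),
    sp("CYP", "cytoplasm", 1e-9, FALSE, "enzyme"),
    sp("GST", "cytoplasm", 1e-9, FALSE, "enzyme"),
    sp("ABCIII", "cytoplasm", 1e-9, FALSE, "enzyme"),
    sp("mRNA_ABC0", "cytoplasm", 1e-10, FALSE, "mRNA"),
    sp("mRNA_CYP", "cytoplasm", 1e-10, FALSE, "mRNA"),
    sp("mRNA_GST", "cytoplasm", 1e-10, FALSE, "mRNA"),
    sp("mRNA_ABCIII", "cytoplasm", 1e-10, FALSE, "mRNA"),
    sp("mRNA_Nrf2", "cytoplasm", 1e-10, FALSE, "mRNA")
  )

  rx <- function(id, stoich, law, compartment = "cytoplasm") {
    list(id = id, stoich = stoich, law = law, compartment = compartment)
  }
  reactions <- list(
    # transport of the unmodified xenobiotic
    rx("diff_pm", c(X_e = -1, X_c = 1),
       rate_law("PassiveDiffusion", list(k = "kdiff_pm"),
                list(outside = "X_e", inside = "X_c")),
       "cytoplasm"),
    rx("diff_nm", c(X_c = -1, X_n = 1),
       rate_law("PassiveDiffusion", list(k = "kdiff_nm"),
                list(outside = "X_c", inside = "X_n")),
       "nucleus"),
    rx("abc0_efflux", c(X_c = -1, X_e = 1),
       rate_law("MichaelisMentenIrreversible",
                list(kcat = "ABC0_kcat", Km = "ABC0_Km"),
                list(substrate = "X_c", enzyme = "ABC0"), volume = V_c)),
    # Phase I / II / III metabolism
    rx("cyp_oxidation", c(X_c = -1, Xp_c = 1),
       rate_law("MichaelisMentenIrreversible",
                list(kcat = "CYP_kcat", Km = "CYP_Km"),
                list(substrate = "X_c", enzyme = "CYP"), volume = V_c)),
    rx("gst_conj_x", c(Xp_c = -1, Xpp_c = 1),
       rate_law("MichaelisMentenPartitioned",
                list(kcat = "GST_kcat", Km = "GST_Km"),
                list(substrate = "Xp_c", cosubstrate = "Xp_bc",
                     enzyme = "GST"), volume = V_c)),
    rx("gst_conj_bg", c(Xp_bc = -1, Xpp_bc = 1),
       rate_law("MichaelisMentenPartitioned",
                list(kcat = "GST_kcat", Km = "GST_Km"),
                list(substrate = "Xp_bc", cosubstrate = "Xp_c",
                     enzyme = "GST"), volume = V_c)),
    rx("abciii_efflux_x", c(Xpp_c = -1, Xpp_e = 1),
       rate_law("MichaelisMentenPartitioned",
                list(kcat = "ABCIII_kcat", Km = "ABCIII_Km"),
                list(substrate = "Xpp_c", cosubstrate = "Xpp_bc",
                     enzyme = "ABCIII"), volume = V_c)),
    rx("abciii_efflux_bg", c(Xpp_bc = -1, Xpp_be = 1),
       rate_law("MichaelisMentenPartitioned",
                list(kcat = "ABCIII_kcat", Km = "ABCIII_Km"),
                list(substrate = "Xpp_bc", cosubstrate = "Xpp_c",
                     enzyme = "ABCIII"), volume = V_c)),
    # endogenous reactive species
    rx("bg_source", c(Xp_bc = 1),
       rate_law("ConstantSource", list(k = "k_bg"))),
    # nuclear receptor binding of the unmodified xenobiotic
    rx("nr_bind", c(X_c = -1, NR = -1, XNR_c = 1),
       rate_law("MassAction", list(k = "NR_kon"),
                list(substrates = c("X_c", "NR")), volume = V_c)),
    rx("nr_release", c(XNR_c = -1, X_c = 1, NR = 1),
       rate_law("MassAction", list(k = "NR_koff"),
                list(substrates = "XNR_c"), volume = V_c)),
    # Keap1-Nrf2: release of sequestered Nrf2, stimulated by oxidized species
    rx("nrf2_release_basal", c(Nrf2_keap = -1, Nrf2 = 1),
       rate_law("MassAction", list(k = "k_rel_basal"),
                list(substrates = "Nrf2_keap"), volume = V_c)),
    rx("nrf2_release_ox_x", c(Nrf2_keap = -1, Nrf2 = 1),
       rate_law("MassAction", list(k = "k_rel_ox"),
                list(substrates = c("Nrf2_keap", "Xp_c")), volume = V_c)),
    rx("nrf2_release_ox_bg", c(Nrf2_keap = -1, Nrf2 = 1),
       rate_law("MassAction", list(k = "k_rel_ox"),
                list(substrates = c("Nrf2_keap", "Xp_bc")), volume = V_c)),
    rx("nrf2_sequester", c(Nrf2 = -1, Nrf2_keap = 1),
       rate_law("MassAction", list(k = "k_seq"),
                list(substrates = "Nrf2"), volume = V_c))
  )

  # transcription / translation / turnover per regulated gene
  genes <- c("ABC0", "CYP", "GST", "ABCIII", "Nrf2")
  for (g in genes) {
    mrna <- paste0("mRNA_", g)
    protein <- if (g == "Nrf2") "Nrf2_keap" else g
    stoich1 <- stats::setNames(1, mrna)
    reactions <- c(reactions, list(
      rx(paste0("tsc_", g, "_nr"), stoich1,
         rate_law("HillActivatedSynthesis",
                  list(basal = paste0(g, "_tsc_basal"),
                       Vmax = paste0(g, "_tsc_vmax_NR"),
                       K = paste0(g, "_tsc_K_NR"),
                       n = paste0(g, "_tsc_n_NR"),
                       scale = paste0(g, "_tsc_scale")),
                  list(activator = "XNR_c"), volume = V_c))
    ))
    if (g %in% c("ABC0", "GST", "ABCIII")) {
      reactions <- c(reactions, list(
        rx(paste0("tsc_", g, "_nrf2"), stoich1,
           rate_law("HillActivatedSynthesis",
                    list(basal = 0,
                         Vmax = paste0(g, "_tsc_vmax_Nrf2"),
                         K = paste0(g, "_tsc_K_Nrf2"),
                         n = paste0(g, "_tsc_n_Nrf2"),
                         scale = paste0(g, "_tsc_scale")),
                    list(activator = "Nrf2"), volume = V_c))
      ))
    }
    reactions <- c(reactions, list(
      rx(paste0("tln_", g), stats::setNames(1, protein),
         rate_law("MassAction", list(k = paste0(g, "_tln_k")),
                  list(substrates = mrna), volume = V_c)),
      rx(paste0("deg_mrna_", g), stats::setNames(-1, mrna),
         rate_law("FirstOrderDecay", list(k = paste0(g, "_mrna_deg")),
                  list(substrate = mrna), volume = V_c)),
      rx(paste0("deg_prot_", g), stats::setNames(-1, protein),
         rate_law("FirstOrderDecay", list(k = paste0(g, "_pdeg")),
                  list(substrate = protein), volume = V_c))
    ))
  }
  # free Nrf2 is degraded too
  reactions <- c(reactions, list(
    rx("deg_nrf2_free", c(Nrf2 = -1),
       rate_law("FirstOrderDecay", list(k = "Nrf2_pdeg"),
                list(substrate = "Nrf2"), volume = V_c))
  ))

  model <- kin_model(
    id = "chemoimmune_reference",
    compartments = compartments,
    species = species,
    parameters = reference_parameters(),
    reactions = reactions,
    meta = list(intake = list(
      gross = "diff_pm",
      net = c(diff_pm = 1, abc0_efflux = -1)
    ))
  )
  set_parameters(model, overrides)
}

#' Small analytically tractable fixture models
#'
#' Reduced models used for oracle tests and demonstrations.
#'
#' * `"minimal-efflux"`: one boundary species (`X_e`), one cytoplasmic
#'   species (`X_c`), exactly two reactions: passive diffusion in/out and a
#'   saturable Phase 0 efflux pump with fixed capacity (`ABC0_Vmax`,
#'   amount/s). Its terminal state solves
#'   `kdiff (Xe - Xc) = Vmax Xc / (Km + Xc)` in closed form.
#' * `"no-regulation"`: the reference network with all transcription,
#'   translation and turnover removed and enzyme/regulator levels frozen at
#'   their typical basal values; enzyme concentrations are constant along
#'   any trajectory.
#' * `"full-reference"`: identical to `build_reference_model()`.
#'
#' @param kind fixture name (see above).
#' @return a [kin_model()].
#' @export
make_fixture_model <- function(kind = c("minimal-efflux", "no-regulation",
                                        "full-reference")) {
  kind <- match.arg(kind)
  if (kind == "full-reference") {
    return(build_reference_model())
  }
  if (kind == "minimal-efflux") {
    V_c <- 1e-12
    model <- kin_model(
      id = "minimal_efflux",
      compartments = list(
        list(id = "extracellular", volume = 1),
        list(id = "cytoplasm", volume = V_c)
      ),
      species = list(
        list(id = "X_e", compartment = "extracellular", initial = 0,
             boundary = TRUE, role = "drug"),
        list(id = "X_c", compartment = "cytoplasm", initial = 0,
             boundary = FALSE, role = "drug")
      ),
      parameters = c(kdiff_pm = 1e-12, ABC0_Vmax = 2e-19, ABC0_Km = 1e-7),
      reactions = list(
        list(id = "diff_pm", stoich = c(X_e = -1, X_c = 1),
             law = rate_law("PassiveDiffusion", list(k = "kdiff_pm"),
                            list(outside = "X_e", inside = "X_c")),
             compartment = "cytoplasm"),
        list(id = "abc0_efflux", stoich = c(X_c = -1, X_e = 1),
             law = rate_law("MichaelisMentenIrreversible",
                            list(Vmax = "ABC0_Vmax", Km = "ABC0_Km"),
                            list(substrate = "X_c")),
             compartment = "cytoplasm")
      ),
      meta = list(intake = list(
        gross = "diff_pm",
        net = c(diff_pm = 1, abc0_efflux = -1)
      ))
    )
    return(model)
  }
  # no-regulation: freeze the expression machinery of the reference network
  model <- build_reference_model()
  drop_prefix <- c("tsc_", "tln_", "deg_mrna_", "deg_prot_", "deg_nrf2",
                   "nrf2_release", "nrf2_sequester")
  keep <- vapply(model$reactions, function(rx) {
    !any(startsWith(rx$id, drop_prefix))
  }, logical(1))
  model$reactions <- model$reactions[keep]
  # drop the now-disconnected mRNA species, freeze proteins/regulators at
  # typical basal levels
  mrnas <- grep("^mRNA_", names(model$species), value = TRUE)
  model$species <- model$species[setdiff(names(model$species), mrnas)]
  frozen <- c(ABC0 = 3.1e-7, CYP = 2e-7, GST = 3.1e-7, ABCIII = 7.7e-8,
              Nrf2 = 1.9e-8, Nrf2_keap = 1.8e-7)
  for (id in names(frozen)) {
    model$species[[id]]$initial <- frozen[[id]]
  }
  model$id <- "chemoimmune_no_regulation"
  model
}
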