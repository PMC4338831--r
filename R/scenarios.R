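#' Run a published experiment scenario
#'
#' Scripted reproductions of the package's standard dose-response and
#' perturbation experiments on the reference network:
#'
#' * `"fig2"`: six doses from 1 nM to 10 uM, 60 h time courses, including
#'   the cumulative-export/intake ratio n(X''_e)/n(X_in).
#' * `"fig3"`: five-multiplier scans (four orders of magnitude) of the
#'   membrane diffusion constants and of the Phase 0 transporter Km at
#'   75 nM.
#' * `"fig4"`: the same five-multiplier scan of the GST Km at 75 nM and at
#'   300 nM.
#' * `"fig6a"`: cytotoxicity curves varying the critical concentration of
#'   the unmodified drug (0.05 nM to 5 uM) with oxidized/conjugated
#'   criticals fixed at 1 uM / 100 uM.
#' * `"fig6b"`, `"fig6c"`: cytotoxicity curves under 0.2x / 5x modulation of
#'   the ABC0 or CYP transcription rate, with the drug more toxic than its
#'   metabolite (b, X_c critical 0.05 nM) or less toxic (c, 5 uM).
#' * `"s2fig"`: three doses spanning transient damage, partial growth
#'   inhibition and cell death (criticals 5 nM / 5 uM / 5 mM).
#' * `"s3fig"`: joint diffusion x f and ABC0-Km x f scan showing mutual
#'   compensation.
#'
#' @param name scenario name (see above).
#' @param model base model (default [build_reference_model()]).
#' @param overrides parameter overrides applied before the scenario.
#' @param outdir optional directory; when given, per-panel TSV files are
#'   written there.
#' @param points doses per cytotoxicity curve (fig6 scenarios).
#' @param verbose print progress.
#' @return a list with scenario-specific elements (`trajectories`, `scans`
#'   or `curves`) and a `summary` data frame.
#' @export
run_scenario <- function(name, model = NULL, overrides = list(),
                         outdir = NULL, points = 12, verbose = FALSE) {
  names_ok <- c("fig2", "fig3", "fig4", "fig6a", "fig6b", "fig6c",
                "s2fig", "s3fig")
  if (!name %in% names_ok) {
    stop("unknown scenario '", name, "' (available: ",
         paste(names_ok, collapse = ", "), ")", call. = FALSE)
  }
  if (is.null(model)) model <- build_reference_model()
  model <- set_parameters(model, overrides)
  result <- switch(name,
    fig2 = scenario_fig2(model, verbose),
    fig3 = scenario_fig3(model, verbose),
    fig4 = scenario_fig4(model, verbose),
    fig6a = scenario_fig6a(model, points, verbose),
    fig6b = scenario_fig6bc(model, parse_quantity("0.05 nM"), points, verbose),
    fig6c = scenario_fig6bc(model, parse_quantity("5 uM"), points, verbose),
    s2fig = scenario_s2fig(model, verbose),
    s3fig = scenario_s3fig(model, verbose)
  )
  result$name <- name
  if (!is.null(outdir)) {
    write_scenario_outputs(result, outdir)
  }
  result
}

scenario_fig2 <- function(model, verbose) {
  doses <- c(1, 10, 75, 300, 1000, 10000) * 1e-9
  protocol <- sim_protocol(duration = hours(60))
  state <- pre_equilibrate(model, protocol)
  trajectories <- lapply(doses, function(xe) {
    if (verbose) message(sprintf("  fig2 dose %.4g nM", xe * 1e9))
    protocol$xe <- xe
    simulate_model(model, protocol, initial = state)
  })
  summary <- do.call(rbind, lapply(seq_along(doses), function(i) {
    traj <- trajectories[[i]]
    n <- nrow(traj$cum)
    ratio <- if (traj$cum[n, "n_Xin"] > 0) {
      traj$cum[n, "n_Xpp_e"] / traj$cum[n, "n_Xin"]
    } else {
      NA_real_
    }
    data.frame(xe = doses[i],
               peak_Xp_c = max(traj$conc[, "Xp_c"]),
               peak_Xpp_c = max(traj$conc[, "Xpp_c"]),
               final_X_c = traj$conc[n, "X_c"],
               export_intake_ratio = ratio)
  }))
  list(trajectories = trajectories, doses = doses, summary = summary)
}

scan_multipliers <- function() c(0.01, 0.1, 1, 10, 100)

scenario_fig3 <- function(model, verbose) {
  protocol <- sim_protocol(xe = "75 nM", duration = hours(60))
  scans <- list(
    diffusion = scan_parameter(model, c("kdiff_pm", "kdiff_nm"),
                               scan_multipliers(), protocol, verbose),
    abc0_km = scan_parameter(model, "ABC0_Km", scan_multipliers(), protocol,
                             verbose)
  )
  summary <- scan_summary(scans)
  list(scans = scans, summary = summary)
}

scenario_fig4 <- function(model, verbose) {
  scans <- list(
    gst_km_75nM = scan_parameter(model, "GST_Km", scan_multipliers(),
                                 sim_protocol(xe = "75 nM",
                                              duration = hours(60)),
                                 verbose),
    gst_km_300nM = scan_parameter(model, "GST_Km", scan_multipliers(),
                                  sim_protocol(xe = "300 nM",
                                               duration = hours(60)),
                                  verbose)
  )
  summary <- scan_summary(scans)
  list(scans = scans, summary = summary)
}

scan_summary <- function(scans) {
  do.call(rbind, lapply(names(scans), function(nm) {
    sc <- scans[[nm]]
    do.call(rbind, lapply(seq_along(sc$multipliers), function(i) {
      traj <- sc$trajectories[[i]]
      data.frame(scan = nm, multiplier = sc$multipliers[i],
                 baseline_ABC0 = traj$conc[1L, "ABC0"],
                 peak_X_c = max(traj$conc[, "X_c"]),
                 peak_Xp_c = max(traj$conc[, "Xp_c"]),
                 peak_Xpp_c = max(traj$conc[, "Xpp_c"]))
    }))
  }))
}

fig6_grid <- function(points) xe_grid("0.2 nM", "2 uM", points)

scenario_fig6a <- function(model, points, verbose) {
  crits <- c(5e-11, 5e-10, 5e-9, 5e-6)
  grid <- fig6_grid(points)
  curves <- lapply(crits, function(crit) {
    if (verbose) message(sprintf("  fig6a X_c,crit = %.4g nM", crit * 1e9))
    run_cytotoxicity(model,
                     toxicity_profile(X_c = crit, Xp_c = 1e-6, Xpp_c = 1e-4),
                     grid, verbose = verbose)
  })
  names(curves) <- paste0("crit_", format(crits * 1e9), "nM")
  summary <- data.frame(X_c_crit = crits,
                        ec50 = vapply(curves, function(cu) cu$ec50,
                                      numeric(1)))
  list(curves = curves, summary = summary)
}

scenario_fig6bc <- function(model, xc_crit, points, verbose) {
  profile <- toxicity_profile(X_c = xc_crit, Xp_c = 1e-6, Xpp_c = 1e-4)
  grid <- fig6_grid(points)
  settings <- list(
    default = list(),
    ABC0_x0.2 = list(ABC0_tsc_scale = 0.2),
    ABC0_x5 = list(ABC0_tsc_scale = 5),
    CYP_x0.2 = list(CYP_tsc_scale = 0.2),
    CYP_x5 = list(CYP_tsc_scale = 5)
  )
  curves <- lapply(names(settings), function(nm) {
    if (verbose) message("  fig6b/c setting ", nm)
    m <- model
    mods <- settings[[nm]]
    for (p in names(mods)) {
      m <- apply_parameter_multiplier(m, p, mods[[p]])
    }
    run_cytotoxicity(m, profile, grid, verbose = verbose)
  })
  names(curves) <- names(settings)
  summary <- data.frame(setting = names(settings),
                        ec50 = vapply(curves, function(cu) cu$ec50,
                                      numeric(1)))
  list(curves = curves, summary = summary, X_c_crit = xc_crit)
}

scenario_s2fig <- function(model, verbose) {
  profile <- toxicity_profile(X_c = "5 nM", Xp_c = "5 uM", Xpp_c = "5 mM")
  fit_model <- attach_fitness(model, profile)
  protocol <- sim_protocol(duration = hours(60))
  state <- pre_equilibrate(fit_model, protocol)
  doses <- c(2.5e-8, 7.5e-8, 1.5e-7)
  trajectories <- lapply(doses, function(xe) {
    if (verbose) message(sprintf("  s2fig dose %.4g nM", xe * 1e9))
    protocol$xe <- xe
    simulate_model(fit_model, protocol, initial = state)
  })
  summary <- do.call(rbind, lapply(seq_along(doses), function(i) {
    traj <- trajectories[[i]]
    data.frame(xe = doses[i], min_fitness = min_fitness(traj),
               final_fitness = traj$vars[nrow(traj$vars), "Fitness"],
               termination = traj$termination)
  }))
  list(trajectories = trajectories, doses = doses, summary = summary)
}

scenario_s3fig <- function(model, verbose) {
  protocol <- sim_protocol(xe = "75 nM", duration = hours(60))
  scan <- scan_parameter(model, c("kdiff_pm", "kdiff_nm", "ABC0_Km"),
                         scan_multipliers(), protocol, verbose)
  ref <- scan$trajectories[[which(scan$multipliers == 1)]]
  summary <- do.call(rbind, lapply(seq_along(scan$multipliers), function(i) {
    traj <- scan$trajectories[[i]]
    dev <- vapply(c("X_c", "Xp_c", "Xpp_c"), function(sp) {
      ref_max <- max(abs(ref$conc[, sp]))
      if (ref_max == 0) return(0)
      max(abs(traj$conc[, sp] - ref$conc[, sp])) / ref_max
    }, numeric(1))
    data.frame(multiplier = scan$multipliers[i],
               max_rel_deviation = max(dev))
  }))
  list(scans = list(compensation = scan), summary = summary)
}

write_scenario_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(result$summary,
                     file.path(outdir, paste0(result$name, "_summary.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$trajectories)) {
    for (i in seq_along(result$trajectories)) {
      export_trajectory(result$trajectories[[i]],
                        file.path(outdir, sprintf("%s_traj_%02d.tsv",
                                                  result$name, i)))
    }
  }
  if (!is.null(result$curves)) {
    for (nm in names(result$curves)) {
      utils::write.table(result$curves[[nm]]$data,
                         file.path(outdir,
                                   paste0(result$name, "_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  if (!is.null(result$scans)) {
    for (nm in names(result$scans)) {
      sc <- result$scans[[nm]]
      for (i in seq_along(sc$multipliers)) {
        export_trajectory(sc$trajectories[[i]],
                          file.path(outdir,
                                    sprintf("%s_%s_x%g.tsv", result$name, nm,
                                            sc$multipliers[i])))
      }
    }
  }
  invisible(outdir)
}
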