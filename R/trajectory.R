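# Trajectory container: time grid x (species concentrations, fitness
# variables, cumulative fluxes), plus the termination cause.

build_trajectory <- function(compiled, out, termination, protocol) {
  times <- out[, "time"]
  n_t <- length(times)
  conc <- out[, compiled$species_ids, drop = FALSE]

  # floating-point noise guard: clip small negative undershoots (the rate
  # laws already treat them as zero), refuse anything beyond solver noise
  for (j in seq_len(ncol(conc))) {
    col <- conc[, j]
    floor_tol <- -max(1e3 * protocol$atol, 1e-7 * max(col, 0))
    bad <- col < floor_tol
    if (any(bad)) {
      stop(sprintf(
        "species '%s' reached %.3e mol/L, beyond solver noise (%.1e)",
        colnames(conc)[j], min(col), floor_tol), call. = FALSE)
    }
    conc[col < 0, j] <- 0
  }

  cols <- colnames(out)
  pick <- function(id, default) {
    if (id %in% cols) out[, id] else rep(default, n_t)
  }
  fitness <- pick("Fitness", 1)
  damage <- pick("Damage", 0)
  regen <- pick("Regeneration", 0)
  load <- pick("ChemicalLoad", 0)
  alive <- pick("alive", 1)
  has_fitness <- "Fitness" %in% cols
  if (termination == "cell-death") {
    fitness[n_t] <- 0
    alive[n_t] <- 0
  }
  pars <- compiled$model$parameters
  capacity <- if ("tox_capacity" %in% names(pars)) pars[["tox_capacity"]] else NULL
  mode <- if (has_fitness && !is.null(capacity)) {
    vapply(seq_len(n_t), function(i) {
      f <- if (alive[i] == 0) 0 else fitness[i]
      mode_levels[[classify_mode(load[i], capacity, f)]]
    }, integer(1))
  } else {
    rep(mode_levels[["idle"]], n_t)
  }
  vars <- cbind(ChemicalLoad = load, Damage = damage, Regeneration = regen,
                Fitness = fitness, alive = alive, mode = mode)

  # cumulative series: drug intake and the exported-conjugate bookkeeping
  model <- compiled$model
  amount_of <- function(id) {
    if (id %in% compiled$species_ids) {
      v <- compiled$vol_by_comp[[model$species[[id]]$compartment]]
      conc[, id] * v
    } else {
      rep(0, n_t)
    }
  }
  cum <- cbind(
    n_Xin = pick("n_Xin", 0),
    n_Xpp_e = amount_of("Xpp_e"),
    n_Xpp_be = amount_of("Xpp_be")
  )
  for (tr in setdiff(compiled$trackers, "n_Xin")) {
    cum <- cbind(cum, out[, tr])
    colnames(cum)[ncol(cum)] <- tr
  }

  structure(
    list(times = times, conc = conc, vars = vars, cum = cum,
         termination = termination, protocol = protocol,
         model_id = model$id,
         species = compiled$species_ids),
    class = "kin_trajectory"
  )
}

#' @export
print.kin_trajectory <- function(x, ...) {
  cat("<kin_trajectory '", x$model_id, "'> ", length(x$times),
      " points over ", format(max(x$times) / 3600, digits = 4), " h, ",
      length(x$species), " species, termination: ", x$termination,
      "\n", sep = "")
  invisible(x)
}

#' Coerce a trajectory to a data frame
#'
#' Column layout: `time`, one column per species (concentrations in mol/L),
#' the four fitness variables (`Fitness`, `Damage`, `Regeneration`, `mode`),
#' and three cumulative series (`n_Xin`, `n_Xpp_e`, `n_Xpp_be`, amounts in
#' mol).
#'
#' @param x a `kin_trajectory`.
#' @param ... unused.
#' @return a data frame with one row per output time.
#' @export
as.data.frame.kin_trajectory <- function(x, ...) {
  data.frame(
    time = x$times,
    as.data.frame(x$conc),
    Fitness = x$vars[, "Fitness"],
    Damage = x$vars[, "Damage"],
    Regeneration = x$vars[, "Regeneration"],
    mode = as.integer(x$vars[, "mode"]),
    n_Xin = x$cum[, "n_Xin"],
    n_Xpp_e = x$cum[, "n_Xpp_e"],
    n_Xpp_be = x$cum[, "n_Xpp_be"],
    check.names = FALSE
  )
}

#' Write a trajectory to a delimited text file
#'
#' One header row (`time`, species ids, fitness variables, cumulative
#' fluxes) and one row per output point, numbers in full precision.
#'
#' @param trajectory a `kin_trajectory`.
#' @param path output file path or connection.
#' @param format `"tsv"` (default) or `"csv"`.
#' @return invisibly, the path.
#' @export
export_trajectory <- function(trajectory, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  df <- as.data.frame(trajectory)
  utils::write.table(
    format(df, digits = 17, scientific = TRUE, trim = TRUE),
    file = path, sep = if (format == "tsv") "\t" else ",",
    quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

# last state of a trajectory as a named vector (species only)
final_concentrations <- function(trajectory) {
  trajectory$conc[nrow(trajectory$conc), ]
}
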