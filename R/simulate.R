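#' Define an enrichment condition
#'
#' One row of the experimental design: which intermediates are spiked into
#' the fresh medium, the initial pH, and the headspace gas loading.
#'
#' @param name Condition label.
#' @param intermediates Named numeric vector of nominal additions, mM.
#' @param pH Initial pH.
#' @param loading A [gas_loading()].
#' @param liquid_volume_L Liquid working volume (default 0.1 L: 300 mL serum
#'   vial with 100 mL broth).
#' @param targets Target product names for scoring and selection.
#' @return An object of class `condition`.
#' @export
condition <- function(name, intermediates, pH, loading,
                      liquid_volume_L = 0.1,
                      targets = c("butyric acid", "caproic acid", "butanol")) {
  stopifnot(inherits(loading, "gas_loading"), liquid_volume_L > 0)
  structure(list(name = name, intermediates = intermediates, pH = pH,
                 loading = loading, liquid_volume = liquid_volume_L,
                 targets = targets),
            class = "condition")
}

#' Preset enrichment conditions
#'
#' The mesophilic (37 degC, 310.15 K) serial-transfer design: 300 mL serum
#' vials, 100 mL broth (200 mL headspace), 1.8 atm, plus the inoculum
#' activation flasks (500 mL, 165 mL broth, 1.8 bar at room temperature).
#' Intermediates: series 1 and 3 get 39 mM acetic acid + 93 mM ethanol
#' (ethanol-rich relative to the 5:3 elongation stoichiometry, to allow for
#' extra acetate formed from the gas); series 2 gets 15 mM butyric acid.
#'
#' @return A named list of [condition()] objects.
#' @export
preset_conditions <- function() {
  vial <- function(fr, temperature = 310.15)
    gas_loading(1.8, 0.200, temperature, fr)
  ae <- c("acetic acid" = 39, "ethanol" = 93)
  ba <- c("butyric acid" = 15)
  list(
    series1_syngas = condition("series1_syngas", ae, 6.5,
      vial(c(H2 = 0.70, CO = 0.10, CO2 = 0.20))),
    series1_n2_co2 = condition("series1_n2_co2", ae, 6.5,
      vial(c(N2 = 0.80, CO2 = 0.20))),
    series1_co2_h2 = condition("series1_co2_h2", ae, 6.5,
      vial(c(H2 = 0.72, CO2 = 0.28))),
    series2_syngas_ph65 = condition("series2_syngas_ph65", ba, 6.5,
      vial(c(H2 = 0.72, CO = 0.11, CO2 = 0.17))),
    series2_syngas_ph55 = condition("series2_syngas_ph55", ba, 5.5,
      vial(c(H2 = 0.72, CO = 0.11, CO2 = 0.17))),
    series2_co2_h2_ph65 = condition("series2_co2_h2_ph65", ba, 6.5,
      vial(c(H2 = 0.75, CO2 = 0.25))),
    series2_co2_h2_ph55 = condition("series2_co2_h2_ph55", ba, 5.5,
      vial(c(H2 = 0.75, CO2 = 0.25))),
    series3_co_h2 = condition("series3_co_h2", ae, 6.5,
      vial(c(N2 = 0.67, H2 = 0.22, CO = 0.11))),
    series3_h2 = condition("series3_h2", ae, 6.5,
      vial(c(N2 = 0.78, H2 = 0.22))),
    activation = condition("activation", stats::setNames(numeric(0),
      character(0)), 6.5,
      gas_loading(1.8, 0.335, 298.15, c(H2 = 0.51, CO = 0.22, CO2 = 0.27),
                  pressure_unit = "bar"),
      liquid_volume_L = 0.165)
  )
}

#' Read an enrichment condition from YAML
#'
#' Schema: `name`, `vessel: {total_mL, liquid_mL}`,
#' `pressure: {value, unit}`, `temperature_C`, `gas:` (name -> percent or
#' fraction), `intermediates:` (compound -> mM), `initial_pH`, optional
#' `targets`.
#'
#' @param path YAML file path.
#' @return A [condition()].
#' @export
read_condition <- function(path) {
  cfg <- yaml::read_yaml(path)
  headspace_L <- (cfg$vessel$total_mL - cfg$vessel$liquid_mL) / 1000
  loading <- gas_loading(cfg$pressure$value, headspace_L,
                         cfg$temperature_C + 273.15,
                         unlist(cfg$gas),
                         pressure_unit = cfg$pressure$unit)
  condition(name = cfg$name %||% basename(path),
            intermediates = if (length(cfg$intermediates))
              unlist(cfg$intermediates) else
              stats::setNames(numeric(0), character(0)),
            pH = cfg$initial_pH, loading = loading,
            liquid_volume_L = cfg$vessel$liquid_mL / 1000,
            targets = if (!is.null(cfg$targets)) unlist(cfg$targets) else
              c("butyric acid", "caproic acid", "butanol"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Specify a serial-transfer enrichment simulation
#'
#' The generator draws per-reaction extents from independent Gamma
#' distributions (non-negative support; mean/dispersion parameterisation,
#' dispersion = coefficient of variation of the extent), truncates them to
#' feasibility greedily in network order, applies the stoichiometric matrix,
#' and overlays multiplicative log-normal measurement noise on every
#' measured amount at both sampling times. Enrichment is modelled as the
#' target reactions' extent means growing by `gain` each transfer.
#'
#' @param condition A [condition()].
#' @param network A `reaction_network`.
#' @param extent_mean Named vector of mean extents (mmol) for the active
#'   reactions at transfer 0. The defaults portray a freshly activated
#'   inoculum: homoacetogenesis (R1) and CO acetogenesis (R2) carry much of
#'   the electron flux, while chain elongation (R6, R7) and butyrate
#'   reduction (R8) start weak and are amplified by `gain` as the community
#'   enriches. Ethanol oxidation (R9) is left inactive by default; its
#'   acetate signature largely overlaps homoacetogenesis and the two are
#'   only weakly separable from start/end data.
#' @param extent_dispersion Gamma CV of each extent (recycled).
#' @param transfers Number of batch stages (default 4: stages 0-3).
#' @param replicates Vials per stage (default 3).
#' @param gain Multiplier (>= 1) applied to target-reaction extent means at
#'   each successive transfer (default 1.6).
#' @param target_reactions Reactions whose products are the enrichment
#'   target (default R6, R7, R8).
#' @param noise_cv Multiplicative measurement noise CV (default 0.02).
#' @param carryover Inoculum carry-over fraction of the previous best
#'   vial's final broth (default 0.18).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(condition,
                            network = default_network(),
                            extent_mean = c(R1 = 1.2, R2 = 0.3, R6 = 0.15,
                                            R7 = 0.08, R8 = 0.03),
                            extent_dispersion = 0.2,
                            transfers = 4L, replicates = 3L,
                            gain = 1.6,
                            target_reactions = c("R6", "R7", "R8"),
                            noise_cv = 0.02, carryover = 0.18) {
  stopifnot(inherits(condition, "condition"),
            inherits(network, "reaction_network"),
            transfers >= 1, replicates >= 1, noise_cv >= 0,
            carryover > 0, carryover < 1, gain >= 1,
            all(names(extent_mean) %in% colnames(network$S)),
            all(extent_mean >= 0))
  # drop reactions whose substrates the condition cannot supply at all
  structure(list(condition = condition, network = network,
                 extent_mean = extent_mean,
                 extent_dispersion = rep_len(extent_dispersion,
                                             length(extent_mean)),
                 transfers = as.integer(transfers),
                 replicates = as.integer(replicates), gain = gain,
                 target_reactions = target_reactions,
                 noise_cv = noise_cv, carryover = carryover),
            class = "simulation_spec")
}

# Initial amounts (mmol, network compound space) for a fresh batch:
# nominal intermediate additions plus carried-over broth, plus fresh gas.
initial_state <- function(spec, inoculum_mM = NULL) {
  cond <- spec$condition
  liq_mM <- stats::setNames(numeric(0), character(0))
  for (nm in names(cond$intermediates))
    liq_mM[nm] <- cond$intermediates[[nm]]
  if (!is.null(inoculum_mM)) {
    for (nm in names(inoculum_mM)) {
      liq_mM[nm] <- (if (nm %in% names(liq_mM)) liq_mM[nm] else 0) +
        spec$carryover * inoculum_mM[[nm]]
    }
  }
  gas <- moles_from_headspace(cond$loading)
  list(liquid_mM = liq_mM, gas_mmol = unclass(gas))
}

# Draw extents, truncate to feasibility greedily in network column order,
# and return the realised final state. Water is given an unlimited pool
# (solvent), inert gas is untouched by reactions.
# x0 may span a superset of the network compounds (inert gases, minor
# analytes); reactions only touch the rows of S.
realize_extents <- function(spec, x0, extent_mean) {
  S <- spec$network$S
  xi_draw <- stats::setNames(numeric(ncol(S)), colnames(S))
  disp <- spec$extent_dispersion
  for (i in seq_along(extent_mean)) {
    m <- extent_mean[[i]]
    if (m <= 0) next
    d <- disp[[i]]
    xi_draw[names(extent_mean)[i]] <- if (d > 0) {
      stats::rgamma(1, shape = 1 / d^2, scale = m * d^2)
    } else m
  }
  x <- x0
  x["H2O"] <- 1e9  # solvent pool, never limiting
  xi <- xi_draw
  for (r in colnames(S)) {
    if (xi[r] <= 0) next
    nu <- S[, r]
    need <- rownames(S)[nu < 0]
    lim <- min(x[need] / -nu[need])
    xi[r] <- min(xi[r], max(lim, 0))
    x[rownames(S)] <- x[rownames(S)] + nu * xi[r]
    x[x < 0] <- 0  # guard rounding
  }
  x["H2O"] <- 0
  list(extents = xi, final = x)
}

add_noise <- function(v, cv) {
  if (cv <= 0 || !length(v)) return(v)
  sdlog <- sqrt(log(1 + cv^2))
  v * exp(stats::rnorm(length(v), mean = -sdlog^2 / 2, sd = sdlog))
}

#' Simulate one batch vial
#'
#' Uses the current R random number generator; call `set.seed()` (or use
#' [run_enrichment()]'s `seed` argument) for reproducibility.
#'
#' @param spec A [simulation_spec()].
#' @param inoculum_mM Named vector of liquid concentrations (mM) carried
#'   over from the inoculum vial, or `NULL` for a fresh start.
#' @param transfer Transfer stage index (scales target extent means by
#'   `gain^transfer`).
#' @param vial Vial id.
#' @return A [batch_observation()] with the true extents and the noise-free
#'   state attached as attributes `truth` and `true_observation`.
#' @export
simulate_batch <- function(spec, inoculum_mM = NULL, transfer = 0L,
                           vial = "v1") {
  stopifnot(inherits(spec, "simulation_spec"))
  st <- initial_state(spec, inoculum_mM)
  cmpds <- Reduce(union, list(rownames(spec$network$S),
                              names(st$liquid_mM), names(st$gas_mmol)))
  x0 <- stats::setNames(numeric(length(cmpds)), cmpds)
  for (nm in names(st$liquid_mM)) {
    x0[nm] <- x0[nm] + st$liquid_mM[[nm]] * spec$condition$liquid_volume
  }
  for (nm in names(st$gas_mmol)) {
    x0[nm] <- x0[nm] + st$gas_mmol[[nm]]
  }
  if (all(x0[setdiff(cmpds, c("H2O", "N2"))] <= 0)) {
    stop("infeasible condition: no substrate present", call. = FALSE)
  }
  em <- spec$extent_mean
  em[names(em) %in% spec$target_reactions] <-
    em[names(em) %in% spec$target_reactions] * spec$gain^transfer
  rez <- realize_extents(spec, x0, em)

  gases <- names(st$gas_mmol)
  liquids <- setdiff(cmpds, c(gases, "H2O"))
  liq_conc <- function(x) x[liquids] / spec$condition$liquid_volume
  split_obs <- function(x_init, x_fin, noisy) {
    mk <- function(v) if (noisy) add_noise(v, spec$noise_cv) else v
    batch_observation(
      vial = vial, transfer = transfer,
      liquid_volume_L = spec$condition$liquid_volume,
      liquid_initial = mk(liq_conc(x_init)),
      liquid_final = mk(liq_conc(x_fin)),
      gas_initial = mk(x_init[gases]),
      gas_final = mk(x_fin[gases]),
      pH_initial = spec$condition$pH)
  }
  obs <- split_obs(x0, rez$final, noisy = spec$noise_cv > 0)
  attr(obs, "truth") <- rez$extents
  attr(obs, "true_observation") <- split_obs(x0, rez$final, noisy = FALSE)
  obs
}

#' Run a serial-transfer enrichment simulation
#'
#' For each transfer stage, `replicates` vials are simulated from the same
#' inoculum; each vial is scored by the summed e-mol yield of the target
#' products (computed from its noisy measurements, as in the laboratory),
#' and the best vial's true final broth is diluted by the carry-over
#' fraction into the next stage's fresh medium. Target-reaction extent
#' means grow by `gain` per transfer, emulating enrichment of the
#' chain-elongating community.
#'
#' @param spec A [simulation_spec()].
#' @param seed Optional integer seed.
#' @return A list of class `enrichment_run`: `observations` (all vials,
#'   with transfer indices) and `trace` (data.frame with the selected vial
#'   and its target-yield score per stage).
#' @export
run_enrichment <- function(spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  observations <- list()
  trace <- data.frame(transfer = integer(), selected = character(),
                      target_yield = numeric())
  inoc <- NULL
  for (t in seq_len(spec$transfers) - 1L) {
    scores <- numeric(spec$replicates)
    batch <- vector("list", spec$replicates)
    for (k in seq_len(spec$replicates)) {
      obs <- simulate_batch(spec, inoculum_mM = inoc, transfer = t,
                            vial = sprintf("t%d_v%d", t, k))
      batch[[k]] <- obs
      lg <- batch_ledger(obs, spec$network$registry,
                         targets = spec$condition$targets)
      scores[k] <- sum(lg$target_summary)
    }
    best <- which.max(scores)
    observations <- c(observations, batch)
    trace <- rbind(trace, data.frame(
      transfer = t, selected = batch[[best]]$vial,
      target_yield = scores[best]))
    true_best <- attr(batch[[best]], "true_observation")
    inoc <- true_best$liquid_final
  }
  structure(list(observations = observations, trace = trace, spec = spec),
            class = "enrichment_run")
}

#' @export
print.enrichment_run <- function(x, ...) {
  cat("<enrichment_run> ", x$spec$transfers, " transfers x ",
      x$spec$replicates, " vials (", x$spec$condition$name, ")\n", sep = "")
  print(x$trace)
  invisible(x)
}

#' Parameter-recovery study for extent estimation
#'
#' Repeatedly simulates a transfer-0 batch, fits reaction extents to the
#' noisy net changes by non-negative least squares, and tabulates the
#' estimation error per active reaction together with the apparent electron
#' recovery of each noisy vial. Because the measurement noise is
#' multiplicative, the fit is weighted by the inverse standard deviation of
#' each compound's net change implied by the noise model (a small floor
#' avoids infinite weight on compounds near the detection limit).
#'
#' @param spec A [simulation_spec()].
#' @param n_runs Number of simulated vials.
#' @param seed Optional integer seed.
#' @return A list with `per_run` (data.frame: run, reaction, true and
#'   estimated extents, relative error), `recovery` (per-run apparent
#'   recovery, percent), and `summary` (per-reaction bias, RMSE and median
#'   relative error), plus `full_rank` from the fit.
#' @export
recovery_study <- function(spec, n_runs = 200, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_runs >= 1)
  active <- names(spec$extent_mean)[spec$extent_mean > 0]
  rows <- vector("list", n_runs)
  recov <- numeric(n_runs)
  full_rank <- TRUE
  for (i in seq_len(n_runs)) {
    obs <- simulate_batch(spec, vial = sprintf("run%d", i))
    truth <- attr(obs, "truth")[active]
    d <- net_amount_changes(obs, spec$network$registry)
    w <- NULL
    if (spec$noise_cv > 0) {
      start <- phase_amounts(obs, "initial")
      end <- phase_amounts(obs, "final")
      keys <- names(d)
      sdv <- spec$noise_cv * sqrt(start[keys]^2 + end[keys]^2)
      w <- 1 / pmax(sdv, spec$noise_cv * 0.05, na.rm = TRUE)
      names(w) <- keys
    }
    fit <- estimate_extents(spec$network, d, reactions = active,
                            weights = w)
    full_rank <- full_rank && fit$full_rank
    recov[i] <- emol_recovery(obs, spec$network$registry)
    rows[[i]] <- data.frame(
      run = i, reaction = active, true = unname(truth),
      estimated = unname(fit$extents[active]),
      rel_error = ifelse(truth > 0,
                         abs(fit$extents[active] - truth) / truth, NA_real_))
  }
  per_run <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_run, per_run$reaction),
    function(s) data.frame(
      reaction = s$reaction[1],
      bias = mean(s$estimated - s$true),
      rmse = sqrt(mean((s$estimated - s$true)^2)),
      median_rel_error = stats::median(s$rel_error, na.rm = TRUE))))
  rownames(summary) <- NULL
  list(per_run = per_run, recovery = recov, summary = summary,
       full_rank = full_rank)
}
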