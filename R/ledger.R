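#' A single batch vial observation
#'
#' Start/end snapshot of one vial: liquid concentrations (mM) and headspace
#' gas amounts (mmol) at inoculation and at harvest. Compounds absent from
#' one snapshot are taken as zero, so start and end share the same key set.
#'
#' @param vial Vial identifier.
#' @param transfer Transfer stage index (0 = first batch of a series).
#' @param liquid_volume_L Liquid working volume in litres.
#' @param liquid_initial,liquid_final Named numeric vectors, mM.
#' @param gas_initial,gas_final Named numeric vectors, mmol.
#' @param pH_initial,pH_final Optional pH metadata.
#' @return An object of class `batch_observation`.
#' @export
batch_observation <- function(vial, transfer, liquid_volume_L,
                              liquid_initial = numeric(),
                              liquid_final = numeric(),
                              gas_initial = numeric(),
                              gas_final = numeric(),
                              pH_initial = NA_real_, pH_final = NA_real_) {
  stopifnot(liquid_volume_L > 0,
            all(liquid_initial >= 0), all(liquid_final >= 0),
            all(gas_initial >= 0), all(gas_final >= 0))
  align <- function(a, b) {
    keys <- union(names(a), names(b))
    list(start = stats::setNames(ifelse(is.na(a[keys]), 0, a[keys]), keys),
         end = stats::setNames(ifelse(is.na(b[keys]), 0, b[keys]), keys))
  }
  liq <- align(unlist(liquid_initial), unlist(liquid_final))
  gas <- align(unlist(gas_initial), unlist(gas_final))
  structure(
    list(vial = vial, transfer = as.integer(transfer),
         liquid_volume = liquid_volume_L,
         liquid_initial = liq$start, liquid_final = liq$end,
         gas_initial = gas$start, gas_final = gas$end,
         pH_initial = pH_initial, pH_final = pH_final),
    class = "batch_observation"
  )
}

#' @export
print.batch_observation <- function(x, ...) {
  cat(sprintf("<batch_observation> vial %s, transfer %d, %.0f mL broth\n",
              x$vial, x$transfer, 1000 * x$liquid_volume))
  cat("  liquid (mM):", paste(names(x$liquid_initial), collapse = ", "), "\n")
  cat("  gas (mmol):", paste(names(x$gas_initial), collapse = ", "), "\n")
  invisible(x)
}

# mmol per compound at one sampling time, both phases pooled.
phase_amounts <- function(obs, when = c("initial", "final")) {
  when <- match.arg(when)
  liq <- if (when == "initial") obs$liquid_initial else obs$liquid_final
  gas <- if (when == "initial") obs$gas_initial else obs$gas_final
  out <- stats::setNames(numeric(0), character(0))
  for (nm in names(liq)) out[nm] <- liq[[nm]] * obs$liquid_volume  # mM * L = mmol
  for (nm in names(gas)) out[nm] <- (if (nm %in% names(out)) out[nm] else 0) + gas[[nm]]
  out
}

#' Net amount and electron changes of a batch
#'
#' `net_amount_changes()` returns the signed end-minus-start amount per
#' compound in mmol; `net_emol_changes()` multiplies each by the compound's
#' e-mol per mole, giving the signed electron-millimole change that Eqs. of
#' the yield framework operate on.
#'
#' @param obs A [batch_observation()].
#' @param registry A `compound_registry`.
#' @return Named numeric vector (mmol or e-mmol, signed).
#' @export
net_amount_changes <- function(obs, registry = default_registry()) {
  stopifnot(inherits(obs, "batch_observation"))
  start <- phase_amounts(obs, "initial")
  end <- phase_amounts(obs, "final")
  keys <- union(names(start), names(end))
  val <- function(v, k) if (k %in% names(v)) v[[k]] else 0
  stats::setNames(
    vapply(keys, function(k) val(end, k) - val(start, k), numeric(1)), keys)
}

#' @rdname net_amount_changes
#' @export
net_emol_changes <- function(obs, registry = default_registry()) {
  d <- net_amount_changes(obs, registry)
  e <- vapply(names(d), function(nm) get_compound(registry, nm)$e_per_mol,
              numeric(1))
  d * e
}

# Total e-mmol in a snapshot.
emol_total <- function(obs, registry, when) {
  amt <- phase_amounts(obs, when)
  if (!length(amt)) return(0)
  e <- vapply(names(amt), function(nm) get_compound(registry, nm)$e_per_mol,
              numeric(1))
  sum(amt * e)
}

# Zero out electron changes below the dead band (a fraction of total
# consumed e-mmol) so replicate-level measurement noise cannot flip a
# compound between the consumed and produced sets.
apply_dead_band <- function(de, dead_band) {
  consumed <- -sum(de[de < 0])
  if (consumed > 0 && dead_band > 0) de[abs(de) < dead_band * consumed] <- 0
  de
}

#' Electron-mole yields of products and substrates
#'
#' For each compound, the percentage of its electron change relative to the
#' total electrons consumed:
#' `Y_i = 100 * delta_e_i / sum_j |delta_e_j|` over consumed compounds `j`.
#' Produced compounds get positive yields, consumed compounds negative ones;
#' the consumed yields sum to -100 by construction.
#'
#' @param changes Signed per-compound e-mmol changes from
#'   [net_emol_changes()].
#' @param dead_band Fraction of consumed e-mmol below which a compound's
#'   change is treated as zero (default 0.005).
#' @return Named numeric vector of signed percentages.
#' @export
emol_yields <- function(changes, dead_band = 0.005) {
  de <- apply_dead_band(changes, dead_band)
  consumed <- -sum(de[de < 0])
  if (consumed <= 0) {
    stop("yield undefined: no compound with net electron consumption",
         call. = FALSE)
  }
  100 * de / consumed
}

#' Electron recovery of a batch
#'
#' Total e-mol at harvest over total e-mol at inoculation, in percent. 100%
#' means every electron fed (gas and liquid) is accounted for in measured
#' compounds; values below 100% indicate unmeasured products or biomass.
#'
#' @inheritParams net_amount_changes
#' @return Recovery in percent.
#' @export
emol_recovery <- function(obs, registry = default_registry()) {
  start <- emol_total(obs, registry, "initial")
  if (start <= 0) stop("recovery undefined: zero electrons at start",
                       call. = FALSE)
  100 * emol_total(obs, registry, "final") / start
}

#' Distribution of net products
#'
#' Over the net-produced compounds only, each product's share of the
#' produced electrons: `D_i = 100 * delta_e_i / sum_i delta_e_i` for
#' `delta_e_i > 0`. Sums to 100.
#'
#' @inheritParams emol_yields
#' @return Named numeric vector of percentages over net products.
#' @export
emol_distribution <- function(changes, dead_band = 0.005) {
  de <- apply_dead_band(changes, dead_band)
  prod <- de[de > 0]
  if (!length(prod)) stop("distribution undefined: no net product",
                          call. = FALSE)
  100 * prod / sum(prod)
}

#' Full electron ledger for one vial
#'
#' Combines amount and electron changes, yields, recovery and net-product
#' distribution into one result, plus a summary for the target products of
#' the enrichment (C4/C6 acids and butanol by default).
#'
#' @inheritParams net_amount_changes
#' @param targets Character vector of target product names.
#' @param dead_band See [emol_yields()].
#' @return An object of class `ledger_result`.
#' @examples
#' # the exact chain-elongation batch: 5 ethanol + 3 acetate ->
#' # 4 butyrate + 2 H2 (+ 3 H2O)
#' obs <- batch_observation("v1", 0, 0.1,
#'   liquid_initial = c("ethanol" = 50, "acetic acid" = 30),
#'   liquid_final = c("ethanol" = 0, "acetic acid" = 0, "butyric acid" = 40),
#'   gas_final = c(H2 = 2))
#' batch_ledger(obs)
#' @export
batch_ledger <- function(obs, registry = default_registry(),
                         targets = c("butyric acid", "caproic acid", "butanol"),
                         dead_band = 0.005) {
  dmmol <- net_amount_changes(obs, registry)
  de <- apply_dead_band(net_emol_changes(obs, registry), dead_band)
  y <- emol_yields(de, dead_band = 0)
  res <- structure(
    list(
      vial = obs$vial, transfer = obs$transfer,
      delta_mmol = dmmol, delta_emmol = de,
      consumed = names(de)[de < 0], produced = names(de)[de > 0],
      yields_percent = y,
      recovery_percent = emol_recovery(obs, registry),
      distribution_percent = emol_distribution(de, dead_band = 0),
      target_summary = stats::setNames(
        vapply(targets, function(t) if (t %in% names(y)) y[[t]] else 0,
               numeric(1)), targets),
      targets = targets
    ),
    class = "ledger_result"
  )
  res
}

#' @export
print.ledger_result <- function(x, ...) {
  cat(sprintf("<ledger_result> vial %s, transfer %d\n", x$vial, x$transfer))
  cat(sprintf("  e-recovery: %.1f%%\n", x$recovery_percent))
  up <- sort(x$yields_percent[x$produced], decreasing = TRUE)
  dn <- sort(x$yields_percent[x$consumed])
  if (length(up)) cat("  products:",
      paste(sprintf("%s %.1f%%", names(up), up), collapse = ", "), "\n")
  if (length(dn)) cat("  sources: ",
      paste(sprintf("%s %.1f%%", names(dn), dn), collapse = ", "), "\n")
  invisible(x)
}

#' Ledger for a serial-transfer series
#'
#' Computes one `ledger_result` per transfer stage. Replicate vials within a
#' transfer are first averaged on the electron-change scale (the yield
#' algebra is linear in the changes), and the per-vial results are kept
#' alongside.
#'
#' @param observations List of [batch_observation()] with transfer indices
#'   consecutive from 0.
#' @inheritParams batch_ledger
#' @return An object of class `ledger_series`: a list with `per_transfer`
#'   (one aggregated `ledger_result` per stage) and `per_vial`.
#' @export
series_ledger <- function(observations, registry = default_registry(),
                          targets = c("butyric acid", "caproic acid", "butanol"),
                          dead_band = 0.005) {
  if (!length(observations)) stop("empty observation list", call. = FALSE)
  idx <- vapply(observations, function(o) o$transfer, integer(1))
  stages <- sort(unique(idx))
  if (!identical(stages, seq.int(0L, max(stages)))) {
    stop("transfer indices must be consecutive from 0; got {",
         paste(stages, collapse = ", "), "}", call. = FALSE)
  }
  per_vial <- lapply(observations, batch_ledger, registry = registry,
                     targets = targets, dead_band = dead_band)
  per_transfer <- lapply(stages, function(t) {
    vials <- per_vial[idx == t]
    keys <- Reduce(union, lapply(vials, function(v) names(v$delta_emmol)))
    val <- function(v, k) if (k %in% names(v)) v[[k]] else 0
    de <- stats::setNames(vapply(keys, function(k) {
      mean(vapply(vials, function(v) val(v$delta_emmol, k), numeric(1)))
    }, numeric(1)), keys)
    dm <- stats::setNames(vapply(keys, function(k) {
      mean(vapply(vials, function(v) val(v$delta_mmol, k), numeric(1)))
    }, numeric(1)), keys)
    y <- emol_yields(de, dead_band = 0)
    structure(list(
      vial = paste0("mean(t", t, ")"), transfer = t,
      delta_mmol = dm, delta_emmol = de,
      consumed = names(de)[de < 0], produced = names(de)[de > 0],
      yields_percent = y,
      recovery_percent = mean(vapply(vials, function(v) v$recovery_percent,
                                     numeric(1))),
      distribution_percent = emol_distribution(de, dead_band = 0),
      target_summary = stats::setNames(
        vapply(targets, function(t2) if (t2 %in% names(y)) y[[t2]] else 0,
               numeric(1)), targets),
      targets = targets
    ), class = "ledger_result")
  })
  structure(list(per_transfer = per_transfer, per_vial = per_vial),
            class = "ledger_series")
}

#' Long-format yield table for stacked-bar plotting
#'
#' One row per (transfer, compound) with the signed e-mol yield: products
#' positive (stack up), consumed sources negative (stack down).
#'
#' @param series A `ledger_series` from [series_ledger()].
#' @return A data.frame with columns `transfer`, `compound`, `role`,
#'   `yield_percent`.
#' @export
yield_table <- function(series) {
  stopifnot(inherits(series, "ledger_series"))
  do.call(rbind, lapply(series$per_transfer, function(lr) {
    y <- lr$yields_percent[lr$yields_percent != 0]
    if (!length(y)) return(NULL)
    data.frame(transfer = lr$transfer, compound = names(y),
               role = ifelse(y > 0, "product", "source"),
               yield_percent = unname(y), row.names = NULL)
  }))
}

#' Read / write batch observations as tidy CSV
#'
#' Schema: one row per measurement with columns `vial`, `transfer`, `phase`
#' (`liquid`/`gas`), `compound`, `time` (`start`/`end`), `amount`, `unit`
#' (`mM` or `g/L` for liquid, `mmol` for gas), plus one `volume`-phase row
#' per vial holding the liquid working volume in litres. g/L amounts are
#' converted to mM through the registry's molar masses.
#'
#' @param path CSV path.
#' @param registry A `compound_registry`.
#' @return `read_batch_csv()` returns a list of [batch_observation()].
#' @export
read_batch_csv <- function(path, registry = default_registry()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vial", "transfer", "phase", "compound", "time", "amount", "unit")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("batch CSV is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!df$phase %in% c("liquid", "gas", "volume"))
  if (length(bad)) stop("batch CSV row ", bad[1], ": unknown phase '",
                        df$phase[bad[1]], "'", call. = FALSE)
  out <- list()
  for (key in unique(paste(df$vial, df$transfer, sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- df[df$vial == parts[1] & df$transfer == as.integer(parts[2]), ]
    volrow <- sub[sub$phase == "volume", ]
    if (nrow(volrow) != 1) stop("vial ", parts[1], " transfer ", parts[2],
                                ": expected exactly one volume row",
                                call. = FALSE)
    vol <- volrow$amount
    grab <- function(phase, time) {
      rows <- sub[sub$phase == phase & sub$time == time, ]
      if (!nrow(rows)) return(stats::setNames(numeric(0), character(0)))
      amt <- mapply(function(a, u, cmp) {
        if (phase == "liquid" && u == "g/L") {
          to_millimoles(a, 1, cmp, registry)  # g/L over 1 L = mM
        } else if ((phase == "liquid" && u == "mM") ||
                   (phase == "gas" && u == "mmol")) a
        else stop("unsupported unit '", u, "' for phase ", phase,
                  call. = FALSE)
      }, rows$amount, rows$unit, rows$compound)
      stats::setNames(as.numeric(amt), rows$compound)
    }
    out[[length(out) + 1L]] <- batch_observation(
      vial = parts[1], transfer = as.integer(parts[2]), liquid_volume_L = vol,
      liquid_initial = grab("liquid", "start"),
      liquid_final = grab("liquid", "end"),
      gas_initial = grab("gas", "start"),
      gas_final = grab("gas", "end"))
  }
  out
}

#' @rdname read_batch_csv
#' @param observations List of [batch_observation()].
#' @export
write_batch_csv <- function(observations, path) {
  rows <- lapply(observations, function(o) {
    mk <- function(phase, time, v, unit) {
      if (!length(v)) return(NULL)
      data.frame(vial = o$vial, transfer = o$transfer, phase = phase,
                 compound = names(v), time = time, amount = unname(v),
                 unit = unit, row.names = NULL)
    }
    rbind(
      data.frame(vial = o$vial, transfer = o$transfer, phase = "volume",
                 compound = "", time = "start", amount = o$liquid_volume,
                 unit = "L"),
      mk("liquid", "start", o$liquid_initial, "mM"),
      mk("liquid", "end", o$liquid_final, "mM"),
      mk("gas", "start", o$gas_initial, "mmol"),
      mk("gas", "end", o$gas_final, "mmol"))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
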