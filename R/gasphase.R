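# Ideal gas constant in the units the headspace bookkeeping uses.
R_GAS <- 0.082057  # L atm mol^-1 K^-1

#' Unit conversion between bar and atm
#'
#' @param x Pressure value(s).
#' @return Converted pressure (1 atm = 1.01325 bar).
#' @export
bar_to_atm <- function(x) x / 1.01325

#' @rdname bar_to_atm
#' @export
atm_to_bar <- function(x) x * 1.01325

#' Describe a vessel headspace loading
#'
#' Captures what is known about a sealed vessel at gassing time: total
#' pressure, headspace volume (vessel volume minus liquid working volume),
#' temperature and the gas mole fractions. Fractions may be given as
#' fractions (summing to 1) or percentages (summing to 100); either way they
#' must sum to one after normalisation by 100 where needed.
#'
#' @param pressure Total pressure.
#' @param headspace_L Headspace volume in litres.
#' @param temperature_K Temperature in kelvin (310.15 K = 37 degC incubation
#'   default).
#' @param fractions Named numeric vector of gas mole fractions (or
#'   percentages).
#' @param pressure_unit `"atm"` (default) or `"bar"`; stored internally in
#'   atm.
#' @return An object of class `gas_loading`.
#' @examples
#' gas_loading(1.8, 0.200, 310.15, c(H2 = 0.70, CO = 0.10, CO2 = 0.20))
#' @export
gas_loading <- function(pressure, headspace_L, temperature_K,
                        fractions, pressure_unit = c("atm", "bar")) {
  pressure_unit <- match.arg(pressure_unit)
  if (pressure_unit == "bar") pressure <- bar_to_atm(pressure)
  stopifnot(pressure > 0, headspace_L > 0, temperature_K > 0,
            length(fractions) >= 1, !is.null(names(fractions)),
            all(fractions >= 0))
  s <- sum(fractions)
  if (abs(s - 100) < 100 * 1e-6) fractions <- fractions / 100
  else if (abs(s - 1) > 1e-6) {
    stop("gas mole fractions must sum to 1 (or 100 if percentages); got ",
         signif(s, 6), call. = FALSE)
  }
  structure(
    list(total_pressure = pressure, headspace_volume = headspace_L,
         temperature = temperature_K, mole_fractions = fractions),
    class = "gas_loading"
  )
}

#' @export
print.gas_loading <- function(x, ...) {
  cat(sprintf("<gas_loading> %.3f atm, %.0f mL headspace, %.2f K\n",
              x$total_pressure, 1000 * x$headspace_volume, x$temperature))
  fr <- x$mole_fractions
  cat("  ", paste(sprintf("%s %.0f%%", names(fr), 100 * fr), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Per-gas amounts in a headspace
#'
#' Ideal-gas bookkeeping: each gas gets `fraction * P * V / (R * T)` moles,
#' reported in mmol. A 300 mL serum vial with 100 mL broth at 1.8 atm and
#' 37 degC holds 14.1 mmol of gas in its 200 mL headspace; at 70% H2 that is
#' 9.9 mmol H2.
#'
#' @param loading A [gas_loading()].
#' @return Named numeric vector of mmol per gas (class `gas_amounts`).
#' @export
moles_from_headspace <- function(loading) {
  stopifnot(inherits(loading, "gas_loading"))
  total_mmol <- loading$total_pressure * loading$headspace_volume /
    (R_GAS * loading$temperature) * 1000
  structure(loading$mole_fractions * total_mmol, class = "gas_amounts")
}

#' @export
print.gas_amounts <- function(x, ...) {
  df <- data.frame(gas = names(x), mmol = round(unclass(x), 2),
                   row.names = NULL)
  print(df)
  invisible(x)
}

#' Partial pressure of one gas
#'
#' @param loading A [gas_loading()].
#' @param gas Gas name.
#' @return Partial pressure in atm (`fraction * total pressure`).
#' @export
partial_pressure <- function(loading, gas) {
  stopifnot(inherits(loading, "gas_loading"))
  fr <- loading$mole_fractions[gas]
  if (is.na(fr)) stop("gas '", gas, "' not in loading", call. = FALSE)
  unname(fr * loading$total_pressure)
}

#' Syngas Quality Index
#'
#' The e-mol per C-mol of a gas mixture:
#' `SQI = 2 (%CO + %H2) / (%CO + %CO2)`, where 2 is the e-mol per mole of CO
#' and H2 and 1 the C-mol per mole of CO and CO2. Feed gas is blended so the
#' SQI matches the degree of reduction of the target product (5 for
#' butyrate, 5.33 for caproate, 6 for butanol). The index is invariant to
#' rescaling all fractions by a positive constant, so fractions or
#' percentages are equally acceptable.
#'
#' @param fractions Named numeric vector with any of `H2`, `CO`, `CO2`
#'   (other gases are ignored; missing gases count as zero).
#' @return The dimensionless index.
#' @examples
#' sqi(c(H2 = 70, CO = 10, CO2 = 20))  # 5.33
#' sqi(c(H2 = 75, CO2 = 25))           # 6
#' @export
sqi <- function(fractions) {
  stopifnot(!is.null(names(fractions)), all(fractions >= 0))
  pick <- function(g) if (g %in% names(fractions)) fractions[[g]] else 0
  co <- pick("CO"); h2 <- pick("H2"); co2 <- pick("CO2")
  denom <- co + co2
  if (denom <= 0) {
    stop("SQI is undefined: the mixture contains no carbon (no CO or CO2)",
         call. = FALSE)
  }
  2 * (co + h2) / denom
}
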