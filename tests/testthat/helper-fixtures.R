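# Shared fixtures, built in code.

REG <- default_registry()

# The exact chain-elongation batch: 5 mmol ethanol + 3 mmol acetate fully
# converted to 4 mmol butyrate + 2 mmol H2 in 100 mL broth.
eq1_observation <- function() {
  batch_observation(
    vial = "eq1", transfer = 0, liquid_volume_L = 0.1,
    liquid_initial = c("ethanol" = 50, "acetic acid" = 30),
    liquid_final = c("ethanol" = 0, "acetic acid" = 0, "butyric acid" = 40),
    gas_final = c(H2 = 2))
}

# A minimal condition whose only substrates are the liquid intermediates
# (inert headspace), for single-reaction simulations.
inert_condition <- function(intermediates = c("ethanol" = 50,
                                              "acetic acid" = 30)) {
  condition("inert", intermediates, 6.5,
            gas_loading(1.8, 0.2, 310.15, c(N2 = 1)))
}

# Independent electron-count oracle: balance the full-oxidation
# half-reaction  CcHhOoNn + w H2O -> c CO2 + n NH3 + p H+ + e e-
# from element and charge conservation, without using the 4C+H-2O-3N rule.
oracle_electrons <- function(counts) {
  w <- 2 * counts[["C"]] - counts[["O"]]          # oxygen balance
  p <- counts[["H"]] + 2 * w - 3 * counts[["N"]]  # hydrogen balance
  p                                               # charge balance: e = p
}
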