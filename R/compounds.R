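# Atomic weights (IUPAC standard weights, 3 decimals) for the CHON space the
# registry lives in. Degree of reduction is computed against the usual
# reference states CO2, H2O and NH3, so e per mole = 4C + H - 2O - 3N.
ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)
ELECTRONS_PER_ATOM <- c(C = 4, H = 1, O = -2, N = -3)

#' Parse a Hill-notation molecular formula
#'
#' Accepts formulas over C, H, O and N such as `"C4H8O2"`, `"H2"`, `"CO"` or
#' `"CO2"`. Element symbols may appear in any order; a missing count means 1.
#'
#' @param x A formula string.
#' @return A named integer vector with elements `C`, `H`, `O`, `N`.
#' @examples
#' parse_formula("C2H4O2")
#' parse_formula("CO")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  m <- gregexpr("([CHON])([0-9]*)", x, perl = TRUE)[[1]]
  tokens <- regmatches(x, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula '", x, "': only C, H, O, N are supported",
         call. = FALSE)
  }
  counts <- c(C = 0L, H = 0L, O = 0L, N = 0L)
  for (tok in tokens) {
    el <- substr(tok, 1L, 1L)
    n <- substr(tok, 2L, nchar(tok))
    counts[el] <- counts[el] + if (nzchar(n)) as.integer(n) else 1L
  }
  if (all(counts == 0L)) stop("empty formula", call. = FALSE)
  counts
}

#' Electrons released on full oxidation of one mole
#'
#' The electron-mole (e-mol) content of a compound: the number of electrons
#' one mole transfers when fully oxidized to CO2 and H2O (NH3 as the nitrogen
#' reference), i.e. `4C + H - 2O - 3N`. CO and H2 carry 2 e-mol/mol, acetic
#' acid 8, ethanol 12, CO2 zero.
#'
#' @param formula A formula string or a parsed count vector from
#'   [parse_formula()].
#' @param inert If `TRUE` the species is treated as redox-inert (used for N2
#'   filler gas) and 0 is returned regardless of the formula.
#' @return Integer e-mol per mole.
#' @examples
#' electrons_per_mole("C2H6O")  # ethanol: 12
#' electrons_per_mole("CO2")    # 0
#' @export
electrons_per_mole <- function(formula, inert = FALSE) {
  if (isTRUE(inert)) return(0L)
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  e <- sum(counts * ELECTRONS_PER_ATOM[names(counts)])
  if (e < 0) {
    stop("negative degree of reduction for non-inert species (formula ",
         paste0(names(counts)[counts > 0], counts[counts > 0], collapse = ""),
         "); unsupported species", call. = FALSE)
  }
  as.integer(e)
}

#' Create a compound
#'
#' @param name Unique compound name.
#' @param formula Hill-notation formula string over C, H, O, N.
#' @param phase `"gas"` or `"liquid"`.
#' @param inert Treat as redox-inert (e-mol per mole forced to 0); used for
#'   N2 filler gas.
#' @param report_default Include in default report tables (minor analytes
#'   such as 1,3-propanediol are registered but not reported by default).
#' @return An object of class `compound` with derived `molar_mass` (g/mol),
#'   `e_per_mol` and `c_per_mol`.
#' @export
compound <- function(name, formula, phase = c("liquid", "gas"),
                     inert = FALSE, report_default = TRUE) {
  phase <- match.arg(phase)
  counts <- parse_formula(formula)
  obj <- structure(
    list(
      name = name,
      formula = formula,
      counts = counts,
      phase = phase,
      inert = isTRUE(inert),
      report_default = isTRUE(report_default),
      molar_mass = sum(counts * ATOMIC_MASS[names(counts)]),
      e_per_mol = electrons_per_mole(counts, inert = inert),
      c_per_mol = unname(counts["C"])
    ),
    class = "compound"
  )
  stopifnot(obj$molar_mass > 0)
  obj
}

#' @export
print.compound <- function(x, ...) {
  cat(sprintf("<compound> %s (%s, %s)  M = %.3f g/mol  e-mol/mol = %d\n",
              x$name, x$formula, x$phase, x$molar_mass, x$e_per_mol))
  invisible(x)
}

#' Electrons per carbon mole (degree of reduction)
#'
#' e-mol per C-mol of a compound: acetate 4, butyrate 5, caproate 16/3
#' (5.33), ethanol and butanol 6. Undefined for carbon-free species such as
#' H2.
#'
#' @param x A `compound`.
#' @return A numeric scalar.
#' @export
electrons_per_cmol <- function(x) {
  stopifnot(inherits(x, "compound"))
  if (x$c_per_mol == 0) {
    stop("degree of reduction per C-mol is undefined for carbon-free ",
         "compound '", x$name, "'", call. = FALSE)
  }
  x$e_per_mol / x$c_per_mol
}

#' Build a compound registry
#'
#' @param compounds A list of [compound()] objects with unique names.
#' @return An object of class `compound_registry` (a named list).
#' @export
compound_registry <- function(compounds) {
  nms <- vapply(compounds, function(x) x$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate compound names in registry")
  structure(stats::setNames(compounds, nms), class = "compound_registry")
}

#' Default compound registry
#'
#' Ships the species tracked in a typical syngas / chain-elongation batch:
#' the headspace gases (H2, CO, CO2, N2 as inert filler), water, the C2-C6
#' volatile fatty acids and alcohols quantified by HPLC, plus minor analytes
#' (1,3-propanediol, lactic and formic acid) that are registered but left out
#' of default report tables.
#'
#' @return A `compound_registry`.
#' @examples
#' reg <- default_registry()
#' reg[["butyric acid"]]$e_per_mol  # 20
#' @export
default_registry <- function() {
  compound_registry(list(
    compound("H2", "H2", "gas"),
    compound("CO", "CO", "gas"),
    compound("CO2", "CO2", "gas"),
    compound("N2", "N2", "gas", inert = TRUE),
    compound("H2O", "H2O", "liquid", report_default = FALSE),
    compound("acetic acid", "C2H4O2", "liquid"),
    compound("ethanol", "C2H6O", "liquid"),
    compound("propionic acid", "C3H6O2", "liquid"),
    compound("butyric acid", "C4H8O2", "liquid"),
    compound("iso-butyric acid", "C4H8O2", "liquid"),
    compound("iso-valeric acid", "C5H10O2", "liquid"),
    compound("caproic acid", "C6H12O2", "liquid"),
    compound("butanol", "C4H10O", "liquid"),
    compound("hexanol", "C6H14O", "liquid"),
    compound("1,3-propanediol", "C3H8O2", "liquid", report_default = FALSE),
    compound("lactic acid", "C3H6O3", "liquid", report_default = FALSE),
    compound("formic acid", "CH2O2", "liquid", report_default = FALSE)
  ))
}

#' @export
print.compound_registry <- function(x, ...) {
  cat("<compound_registry> ", length(x), " compounds\n", sep = "")
  for (cp in x) {
    cat(sprintf("  %-18s %-8s %-6s M=%8.3f  e/mol=%3d%s\n", cp$name,
                cp$formula, cp$phase, cp$molar_mass, cp$e_per_mol,
                if (cp$inert) "  (inert)" else ""))
  }
  invisible(x)
}

get_compound <- function(registry, name) {
  cp <- registry[[name]]
  if (is.null(cp)) stop("unknown compound '", name, "'", call. = FALSE)
  cp
}

#' Convert a mass concentration to millimoles
#'
#' @param g_per_L Concentration in g/L.
#' @param volume_L Liquid volume in litres.
#' @param compound A `compound` or a name looked up in `registry`.
#' @param registry A `compound_registry` (default registry if omitted).
#' @return Amount in mmol.
#' @examples
#' to_millimoles(1.32, 0.1, "butyric acid")  # ~1.498 mmol (15 mM)
#' @export
to_millimoles <- function(g_per_L, volume_L, compound,
                          registry = default_registry()) {
  stopifnot(all(g_per_L >= 0), volume_L > 0)
  if (is.character(compound)) compound <- get_compound(registry, compound)
  g_per_L * volume_L / compound$molar_mass * 1000
}

#' Convert millimoles to a mass concentration (g/L)
#'
#' Inverse of [to_millimoles()]; round-trips to machine precision.
#'
#' @param mmol Amount in mmol.
#' @inheritParams to_millimoles
#' @return Concentration in g/L.
#' @export
to_concentration <- function(mmol, volume_L, compound,
                             registry = default_registry()) {
  stopifnot(all(mmol >= 0), volume_L > 0)
  if (is.character(compound)) compound <- get_compound(registry, compound)
  mmol / 1000 * compound$molar_mass / volume_L
}

#' Convert a molar concentration (mM) to g/L
#'
#' @param mM Concentration in mmol/L.
#' @inheritParams to_millimoles
#' @return Concentration in g/L.
#' @export
mM_to_gL <- function(mM, compound, registry = default_registry()) {
  if (is.character(compound)) compound <- get_compound(registry, compound)
  mM * compound$molar_mass / 1000
}

#' Read / write a compound registry as YAML
#'
#' The file is a list of entries with fields `name`, `formula`, `phase` and
#' optional `inert` and `report_default` flags.
#'
#' @param path File path.
#' @return `read_registry()` returns a `compound_registry`;
#'   `write_registry()` returns `path` invisibly.
#' @export
read_registry <- function(path) {
  entries <- yaml::read_yaml(path)
  compound_registry(lapply(entries, function(e) {
    compound(e$name, e$formula, phase = e$phase,
             inert = isTRUE(e$inert),
             report_default = !isFALSE(e$report_default))
  }))
}

#' @rdname read_registry
#' @param registry A `compound_registry`.
#' @export
write_registry <- function(registry, path) {
  entries <- lapply(unclass(registry), function(cp) {
    e <- list(name = cp$name, formula = cp$formula, phase = cp$phase)
    if (cp$inert) e$inert <- TRUE
    if (!cp$report_default) e$report_default <- FALSE
    e
  })
  yaml::write_yaml(unname(entries), path)
  invisible(path)
}
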