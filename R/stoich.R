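#' Define a stoichiometric reaction
#'
#' @param name Reaction name.
#' @param coefficients Named numeric vector of stoichiometric coefficients;
#'   substrates negative, products positive.
#' @return An object of class `reaction`.
#' @examples
#' # chain elongation of acetate with ethanol to butyrate
#' reaction("R6", c("ethanol" = -5, "acetic acid" = -3,
#'                  "butyric acid" = 4, "H2" = 2, "H2O" = 3))
#' @export
reaction <- function(name, coefficients) {
  stopifnot(is.character(name), length(coefficients) >= 2,
            !is.null(names(coefficients)), all(coefficients != 0))
  structure(list(name = name, coefficients = coefficients),
            class = "reaction")
}

#' @export
print.reaction <- function(x, ...) {
  nu <- x$coefficients
  side <- function(v) paste(sprintf("%s %s", ifelse(abs(v) == 1, "",
    format(abs(v))), names(v)), collapse = " + ")
  cat(sprintf("<reaction> %s: %s -> %s\n", x$name,
              side(nu[nu < 0]), side(nu[nu > 0])))
  invisible(x)
}

#' Check element and electron balance of a reaction
#'
#' Sums `coefficient * atom count` over C, H, O, N and
#' `coefficient * e-mol/mol`; the reaction passes when every residual is
#' zero. The electron residual follows from the element residuals for
#' non-inert species, but both are computed independently.
#'
#' @param rxn A [reaction()].
#' @param registry A `compound_registry` supplying formulas.
#' @param tol Absolute tolerance on residuals.
#' @return A list with `element_residuals`, `electron_residual` and
#'   `balanced`.
#' @export
check_balance <- function(rxn, registry = default_registry(), tol = 1e-9) {
  stopifnot(inherits(rxn, "reaction"))
  nu <- rxn$coefficients
  elem <- c(C = 0, H = 0, O = 0, N = 0)
  e_res <- 0
  for (nm in names(nu)) {
    cp <- get_compound(registry, nm)
    elem <- elem + nu[[nm]] * cp$counts
    e_res <- e_res + nu[[nm]] * cp$e_per_mol
  }
  list(reaction = rxn$name,
       element_residuals = elem,
       electron_residual = e_res,
       balanced = all(abs(elem) <= tol) && abs(e_res) <= tol)
}

#' Total electrons carried by each side of a reaction
#'
#' Returns the summed `|coefficient| * e-mol/mol` of substrates and of
#' products; equal sides certify electron balance (84 e-mol each side for
#' the ethanol/acetate elongation to butyrate).
#'
#' @inheritParams check_balance
#' @return Named numeric vector `c(substrates =, products =)`.
#' @export
electron_sides <- function(rxn, registry = default_registry()) {
  nu <- rxn$coefficients
  e <- vapply(names(nu), function(nm) get_compound(registry, nm)$e_per_mol,
              numeric(1))
  c(substrates = sum(-nu[nu < 0] * e[nu < 0]),
    products = sum(nu[nu > 0] * e[nu > 0]))
}

#' Build a reaction network
#'
#' Assembles reactions into a stoichiometric matrix S (compounds x
#' reactions). Every reaction must pass [check_balance()]. The measured
#' subset (used for extent fitting) excludes water, which is never
#' quantified, and inert filler gas.
#'
#' @param reactions List of [reaction()] objects.
#' @param registry A `compound_registry`.
#' @param measured Character vector of measured compound names; defaults to
#'   all network compounds except H2O and inert species.
#' @return An object of class `reaction_network` with elements `S`,
#'   `reactions`, `measured`, `registry`.
#' @export
reaction_network <- function(reactions, registry = default_registry(),
                             measured = NULL) {
  nms <- vapply(reactions, function(r) r$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate reaction names")
  for (r in reactions) {
    chk <- check_balance(r, registry)
    if (!chk$balanced) {
      stop("reaction '", r$name, "' is not balanced; element residuals: ",
           paste(sprintf("%s %+g", names(chk$element_residuals),
                         chk$element_residuals), collapse = ", "),
           "; electron residual ", chk$electron_residual, call. = FALSE)
    }
  }
  compounds <- Reduce(union, lapply(reactions, function(r) names(r$coefficients)))
  S <- matrix(0, length(compounds), length(reactions),
              dimnames = list(compounds, nms))
  for (r in reactions) S[names(r$coefficients), r$name] <- r$coefficients
  if (is.null(measured)) {
    inert <- vapply(compounds, function(nm) get_compound(registry, nm)$inert,
                    logical(1))
    measured <- setdiff(compounds[!inert], "H2O")
  }
  structure(list(S = S, reactions = stats::setNames(reactions, nms),
                 measured = measured, registry = registry),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("<reaction_network> ", ncol(x$S), " reactions over ", nrow(x$S),
      " compounds (", length(x$measured), " measured)\n", sep = "")
  for (r in x$reactions) print(r)
  invisible(x)
}

#' Default syngas / chain-elongation reaction network
#'
#' Nine balance-verified reactions covering the activity expected in a
#' mixed-culture syngas enrichment:
#' \describe{
#'   \item{R1}{homoacetogenesis: 2 CO2 + 4 H2 -> acetate + 2 H2O}
#'   \item{R2}{CO acetogenesis: 4 CO + 2 H2O -> acetate + 2 CO2}
#'   \item{R3}{ethanol from H2/CO2: 2 CO2 + 6 H2 -> ethanol + 3 H2O}
#'   \item{R4}{ethanol from CO: 6 CO + 3 H2O -> ethanol + 4 CO2}
#'   \item{R5}{acetate reduction: acetate + 2 H2 -> ethanol + H2O}
#'   \item{R6}{chain elongation to butyrate:
#'     5 ethanol + 3 acetate -> 4 butyrate + 2 H2 + 3 H2O}
#'   \item{R7}{elongation to caproate: ethanol + butyrate -> caproate + H2O}
#'   \item{R8}{butyrate reduction: butyrate + 2 H2 -> butanol + H2O}
#'   \item{R9}{ethanol oxidation: ethanol + H2O -> acetate + 2 H2}
#' }
#' R6 releases 0.4 H2 per mole of ethanol consumed while R7 releases none,
#' matching the observation that caproate formation generates less H2 per
#' mole ethanol than butyrate formation. R9 is the reverse of R5 and makes
#' the full network rank-deficient by construction; extent fitting is done
#' on the subset of reactions assumed active.
#'
#' @param registry A `compound_registry`.
#' @param caproate_rbo If `TRUE`, replace R7 with the reverse
#'   beta-oxidation variant
#'   5 ethanol + 4 butyrate -> 4 caproate + acetate + 2 H2 + 3 H2O.
#' @return A `reaction_network`.
#' @export
default_network <- function(registry = default_registry(),
                            caproate_rbo = FALSE) {
  r7 <- if (caproate_rbo) {
    reaction("R7", c("ethanol" = -5, "butyric acid" = -4,
                     "caproic acid" = 4, "acetic acid" = 1,
                     "H2" = 2, "H2O" = 3))
  } else {
    reaction("R7", c("ethanol" = -1, "butyric acid" = -1,
                     "caproic acid" = 1, "H2O" = 1))
  }
  reaction_network(list(
    reaction("R1", c("CO2" = -2, "H2" = -4, "acetic acid" = 1, "H2O" = 2)),
    reaction("R2", c("CO" = -4, "H2O" = -2, "acetic acid" = 1, "CO2" = 2)),
    reaction("R3", c("CO2" = -2, "H2" = -6, "ethanol" = 1, "H2O" = 3)),
    reaction("R4", c("CO" = -6, "H2O" = -3, "ethanol" = 1, "CO2" = 4)),
    reaction("R5", c("acetic acid" = -1, "H2" = -2, "ethanol" = 1, "H2O" = 1)),
    reaction("R6", c("ethanol" = -5, "acetic acid" = -3,
                     "butyric acid" = 4, "H2" = 2, "H2O" = 3)),
    r7,
    reaction("R8", c("butyric acid" = -1, "H2" = -2, "butanol" = 1, "H2O" = 1)),
    reaction("R9", c("ethanol" = -1, "H2O" = -1, "acetic acid" = 1, "H2" = 2))
  ), registry = registry)
}

#' Apply reaction extents to an initial state
#'
#' `final = initial + S %*% xi`. Extents are in mmol of reaction events.
#' Compounds in the network but absent from `initial` start at zero.
#'
#' @param network A `reaction_network`.
#' @param extents Named (or network-ordered) non-negative numeric vector of
#'   extents; reactions omitted get extent 0.
#' @param initial Named numeric vector of initial amounts (mmol).
#' @return Named numeric vector of final amounts over network compounds.
#' @export
apply_extents <- function(network, extents, initial) {
  stopifnot(inherits(network, "reaction_network"), all(extents >= 0))
  xi <- stats::setNames(numeric(ncol(network$S)), colnames(network$S))
  if (is.null(names(extents))) {
    stopifnot(length(extents) == length(xi))
    xi[] <- extents
  } else xi[names(extents)] <- extents
  x0 <- stats::setNames(numeric(nrow(network$S)), rownames(network$S))
  extra <- setdiff(names(initial), names(x0))
  if (length(extra)) stop("initial amounts name compounds outside the ",
                          "network: ", paste(extra, collapse = ", "),
                          call. = FALSE)
  x0[names(initial)] <- initial
  xf <- x0 + as.numeric(network$S %*% xi)
  names(xf) <- rownames(network$S)
  neg <- xf < -1e-9
  if (any(neg)) {
    stop("infeasible extents: compound(s) ",
         paste(names(xf)[neg], collapse = ", "), " driven negative",
         call. = FALSE)
  }
  pmax(xf, 0)
}

#' Estimate reaction extents from net changes
#'
#' Solves `min || S_m xi - delta ||_2` subject to `xi >= 0` over the
#' measured-compound rows of S, by non-negative least squares. When the
#' measured submatrix has full column rank and `delta = S_m xi*`, the true
#' extents are recovered exactly. Rank deficiency (e.g. fitting R5 and its
#' reverse R9 together) is reported as a warning listing a null-space
#' basis; the returned solution is then one of many.
#'
#' @param network A `reaction_network`.
#' @param delta Named numeric vector of net amount changes (mmol) over
#'   measured compounds; measured compounds omitted are taken as 0.
#' @param reactions Optional character vector restricting the fit to a
#'   subset of reactions (the ones assumed active).
#' @param weights Optional named vector of per-compound weights (typically
#'   inverse measurement standard deviations, so that multiplicatively
#'   noisy large amounts do not drown out precisely known small ones);
#'   missing compounds get weight 1.
#' @return A list with `extents` (named, >= 0), `residual_norm`, `rank`,
#'   `full_rank`.
#' @export
estimate_extents <- function(network, delta, reactions = NULL,
                             weights = NULL) {
  stopifnot(inherits(network, "reaction_network"))
  if (is.null(reactions)) reactions <- colnames(network$S)
  Sm <- network$S[network$measured, reactions, drop = FALSE]
  d <- stats::setNames(numeric(length(network$measured)), network$measured)
  extra <- setdiff(names(delta), rownames(network$S))
  if (length(extra)) stop("changes name compounds outside the network: ",
                          paste(extra, collapse = ", "), call. = FALSE)
  known <- intersect(names(delta), network$measured)
  d[known] <- delta[known]
  if (!is.null(weights)) {
    w <- stats::setNames(rep(1, length(network$measured)), network$measured)
    w[intersect(names(weights), names(w))] <-
      weights[intersect(names(weights), names(w))]
    Sm <- Sm * w
    d <- d * w
  }
  sv <- svd(Sm)
  rk <- sum(sv$d > max(dim(Sm)) * max(sv$d) * .Machine$double.eps)
  if (rk < ncol(Sm)) {
    null_basis <- sv$v[, (rk + 1):ncol(Sm), drop = FALSE]
    rownames(null_basis) <- reactions
    warning("measured stoichiometric matrix is rank-deficient (rank ", rk,
            " of ", ncol(Sm), "); extents are not identifiable. ",
            "Null-space involves: ",
            paste(reactions[rowSums(abs(null_basis)) > 1e-8],
                  collapse = ", "), call. = FALSE)
  }
  fit <- pracma::lsqnonneg(Sm, d)
  xi <- stats::setNames(fit$x, reactions)
  list(extents = xi,
       residual_norm = sqrt(sum((Sm %*% xi - d)^2)),
       rank = rk, full_rank = rk == ncol(Sm))
}

#' Read / write a reaction network as YAML
#'
#' The file maps reaction names to coefficient maps (substrates negative).
#'
#' @param path File path.
#' @param registry A `compound_registry` used to balance-check on read.
#' @return `read_network()` returns a `reaction_network`.
#' @export
read_network <- function(path, registry = default_registry()) {
  lst <- yaml::read_yaml(path)
  reaction_network(lapply(names(lst), function(nm) {
    reaction(nm, unlist(lst[[nm]]))
  }), registry = registry)
}

#' @rdname read_network
#' @param network A `reaction_network`.
#' @export
write_network <- function(network, path) {
  yaml::write_yaml(lapply(network$reactions, function(r)
    as.list(r$coefficients)), path)
  invisible(path)
}
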