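---
title: "Electron-mole accounting for batch gas fermentation and chain elongation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Electron-mole accounting for batch gas fermentation and chain elongation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emolr)
```

## The accounting model

Mixed-culture fermentations of syngas (CO/H2/CO2) and CO2/H2, supplemented
with acetate and ethanol, produce a mixture of acids and alcohols whose
amounts are not comparable on a mass or molar basis: a mole of caproate
carries four times the reducing power of a mole of acetate. `emolr` puts
every substrate and product on a common currency, the **electron mole**
(e-mol): the number of electrons one mole of a compound transfers when
fully oxidized to CO2 and H2O. For a compound $\mathrm{C}_c\mathrm{H}_h
\mathrm{O}_o\mathrm{N}_n$ (ammonia as the nitrogen reference),

$$e = 4c + h - 2o - 3n,$$

which gives CO and H2 2 e-mol/mol, acetate 8, ethanol 12, butyrate 20,
caproate 32, butanol 24, and CO2 zero. Dividing by the carbon number gives
the familiar *degree of reduction* per C-mol: acetate 4, butyrate 5,
caproate 5.33, ethanol and butanol 6. N2, used as filler gas, would be
assigned a negative value by the formula; the registry flags it inert with
$e = 0$ instead, which matches its role as a non-reactive diluent.

For one batch vial sampled at inoculation ($t_0$) and at harvest, with
$\Delta e_k$ the signed e-mol change of compound $k$ (liquid amounts from
concentration × working volume; headspace amounts from the ideal gas law):

* **yield** of every compound, as a percentage of the electrons consumed:
  $Y_k = 100\,\Delta e_k \big/ \sum_{j:\,\Delta e_j<0} |\Delta e_j|$ —
  products positive, substrates negative, the substrate yields summing to
  $-100$ by construction;
* **electron recovery**, $100 \sum_k e_k(t_{end}) / \sum_k e_k(t_0)$ — the
  fraction of fed electrons found in measured compounds (biomass is not
  tracked, so values a few percent below 100 are normal in practice);
* **distribution of net products**, each product's share of the produced
  electrons, summing to 100.

The **Syngas Quality Index** of a feed mixture,
$\mathrm{SQI} = 2(\%CO + \%H_2)/(\%CO + \%CO_2)$, is the e-mol per C-mol of
the gas phase; feeds are blended so the SQI matches the degree of
reduction of the intended product (5–5.33 for C4/C6 acids, 6 for butanol).

### Assumptions

* Start/end sampling only: any intra-batch cycling (H2 produced by
  elongation and re-consumed by homoacetogenesis) nets out and is
  invisible by design.
* Concentrations are total species; acid/anion speciation is ignored.
* Headspace gases are ideal; dissolved gas and gas–liquid transfer are
  neglected at 1.8 atm and 37 °C.
* Water and biomass are excluded from all electron sums (water carries 0
  e-mol; biomass is unmeasured).

## The reaction network

`default_network()` ships nine element- and electron-balanced reactions:
acetate and ethanol formation from CO2/H2 and from CO (R1–R4), acetate
reduction to ethanol (R5), chain elongation of acetate to butyrate with
ethanol (R6), elongation of butyrate to caproate (R7), butyrate reduction
to butanol (R8), and ethanol oxidation (R9, the reverse of R5). The
elongation stoichiometry is

$$5\,\mathrm{C_2H_5OH} + 3\,\mathrm{CH_3COOH} \rightarrow
  4\,\mathrm{C_3H_7COOH} + 2\,\mathrm{H_2} + 3\,\mathrm{H_2O},$$

with 84 e-mol on each side. Note the water coefficient: three, not four —
the value is fixed by the hydrogen and oxygen balances (the constructor
refuses any unbalanced reaction), and the electron count is unaffected
because water carries no electrons. R6 releases 0.4 H2 per mole of ethanol
consumed; R7, written as the minimal 1:1 ethanol condensation, releases
none — consistent with H2 supplementation favouring elongation of butyrate
over acetate. A reverse-β-oxidation variant of caproate formation
(5 ethanol + 4 butyrate → 4 caproate + acetate + 2 H2 + 3 H2O) is available
via `default_network(caproate_rbo = TRUE)` for users who prefer an
H2-evolving caproate stoichiometry; the minimal form is the default because
no caproate stoichiometry is established for these consortia.

**Extent estimation.** Net production vectors are fitted by non-negative
least squares, $\min \lVert S_m\,\xi - \Delta \rVert_2$ s.t. $\xi \ge 0$,
over the measured compounds (water excluded). Because measurement noise is
multiplicative, rows should be weighted by inverse standard deviation when
the noise level is known (`recovery_study()` does this automatically);
unweighted fits let the large, noisy gas rows dominate and degrade the
small extents. The full nine-reaction network is structurally
unidentifiable — R9 is the exact reverse of R5, and the fit warns with the
null-space membership rather than resolving the tie silently — so fitting
is done over the subset of reactions assumed active.

## The synthetic enrichment generator

`simulate_batch()` and `run_enrichment()` emulate the serial-transfer
enrichment design: triplicate 300 mL serum vials with 100 mL broth and a
200 mL headspace at 1.8 atm and 37 °C, intermediates spiked into fresh
medium (39 mM acetate + 93 mM ethanol for the elongation series — ethanol-
rich relative to the 5:3 elongation ratio, leaving room for acetate formed
from the gas — or 15 mM butyrate for the reduction series), 18% (v/v)
inoculum carry-over, and selection of the best vial (highest summed target
yield, scored on the noisy measurements as a laboratory would) as inoculum
for the next transfer. `preset_conditions()` provides each experimental
series plus the 500 mL activation flasks (165 mL broth, 1.8 bar at room
temperature — the flask loadings only reproduce near 298 K, unlike the
vials' 310.15 K, so vessels carry their own reference temperature).

Mechanics, and the reasoning behind each choice:

* **Extents, not kinetics.** Per-reaction extents are drawn from
  independent Gamma distributions (mean/dispersion parameterisation;
  non-negative support is the reason for the choice). This is a
  statistical stand-in for unknown kinetics, not a growth model.
* **Defaults as study conditions.** At transfer 0 the flux is dominated by
  acetogenesis (R1 = 1.0–1.2, R2 = 0.3 mmol) with weak elongation
  (R6 = 0.15, R7 = 0.08, R8 = 0.03 mmol); the target-reaction means grow
  by a gain of 1.6 per transfer, emulating enrichment. These values were
  chosen once so that a simulated final transfer lands in the
  concentration range typical of real enrichments (butyrate ≈ 2 g/L,
  caproate a few tenths g/L, butanol ≈ 0.1 g/L) while the target yield
  still has headroom to climb; they are not fitted to any dataset.
  Ethanol oxidation (R9) is inactive by default: its acetate signature
  overlaps homoacetogenesis almost completely in start/end data, so
  including it mainly injects unidentifiability.
* **Feasibility truncation** is greedy in declared reaction order
  (gas-consuming acetogenesis first, elongation next, reduction last,
  mimicking substrate precedence); a draw that would exhaust a substrate
  is capped at the feasible extent.
* **Noise** is multiplicative log-normal (mean-one) with CV 0.02 on every
  measured amount at both sampling times, of the order of replicate
  scatter in real triplicates. Carried-over broth uses the *true* final
  state — the pipette does not see measurement error.

With noise off, every simulated vial closes the electron balance exactly
(recovery 100%, product yields summing to 100%), which is the conservation
oracle the test suite leans on.

**What the generator does not emulate:** community dynamics and species
abundances, growth and OD, pH trajectories (initial pH is metadata only;
the final pH is not modelled, so pH-dependent solventogenesis is out of
mechanistic scope), gas–liquid transfer limitation, product inhibition,
and any unidentified product sink. Passing tests therefore certify the
accounting and estimation machinery, not biological realism of any
particular trajectory.

## Numerical choices

* **Dead band**: compounds whose |Δe| is below 0.5% of the consumed
  electrons are classed as unchanged before the consumed/produced split,
  so noise cannot flip set membership; the threshold is configurable and
  zero turns it off.
* **Gas constant** 0.082057 L·atm·mol⁻¹·K⁻¹; atomic masses C 12.011,
  H 1.008, O 15.999, N 14.007 (IUPAC, 3 decimals); 1 atm = 1.01325 bar.
* **Degenerate inputs** fail loudly: no consumed compound (yields), no net
  product (distribution), zero initial electrons (recovery), carbon-free
  gas mixtures (SQI), exhausted substrates (`apply_extents()` names the
  compound).
* **Problem sizes** used by the shipped acceptance study: 1000 noiseless
  vials for the conservation check, 200 noisy vials for the
  extent-recovery study, 100 seeded enrichment runs (4 transfers × 3
  vials) for the selection/monotonicity property; the whole suite runs in
  seconds.

## Limitations

Real enrichment yields cannot be recomputed from published concentration
tables alone: those report liquid end-points, while the yield denominator
requires the gas consumption of each vial. The package therefore validates
against exact stoichiometric batches and simulation round-trips, and
treats published end-point tables as I/O shapes (`report_series()`), not
as recomputable targets. Electron recovery is reported per vial; no
statistical comparison across enrichment strategies is provided.
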