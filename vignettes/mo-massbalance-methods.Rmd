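---
title: "Inferring minimum Archean O2 from the shale molybdenum record"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring minimum Archean O2 from the shale molybdenum record}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobalance)
```

## The problem

Molybdenum reaches the ocean today almost entirely through the oxidative
weathering of crustal sulfide minerals by O2. Archean and Paleoproterozoic
black shales nonetheless carry Mo enrichments above the detrital background
and delta98Mo values above igneous compositions — apparent signatures of
oxidative weathering under an atmosphere that independent proxies show was
essentially anoxic. `mobalance` quantifies how much Mo delivery, and hence
how much O2, those shales minimally demand.

The inference runs in four stages:

1. **Steady-state ocean mass balance.** Mo input balances burial in four
   sedimentary sinks — Fe-oxide-bearing, Mn-oxide-bearing,
   sulfidic-at-depth (SAD), and euxinic sediments. Removal to sink $i$ is
   $R_{out,i} = b_i\,[\mathrm{Mo}]_{sw}\,A_i$, with $b_i$ an effective
   burial rate constant and $A_i$ the depositional area; fractions
   $f_i = R_{out,i}/\sum_j R_{out,j}$ sum to one and the flux-weighted
   sediment compositions must recover the input composition
   ($\delta_{in} = \sum_i f_i \delta_i$).
2. **Monte Carlo exploration.** Because $b_i$, $A_i$, $[\mathrm{Mo}]_{sw}$
   and $\delta_{in}$ are individually unconstrained for the Archean, we
   sample millions of candidate ocean states across their plausible ranges
   and keep only those consistent with the shale record of a period.
3. **Record filtering.** Four accept/reject filters: the required input
   may not exceed the modern riverine flux (1.35e8 mol/yr); seawater
   delta98Mo (captured by euxinic shales) must lie in the period's window;
   euxinic depositional area must be smaller than SAD area; and the
   predicted euxinic authigenic enrichment across a ten-fold
   mass-accumulation-rate bracket must intersect the observed maximum
   enrichment window.
4. **Flux-to-O2 conversion.** The minimum surviving input, less a 1%
   hydrothermal allowance, converts to a sulfate flux through the modern
   riverine molar Mo/S ratio (4.5e-5; see `scripts/derive_mo_s_ratio.R`)
   and to an O2 consumption flux through complete pyrite oxidation
   ($\mathrm{FeS_2} + \tfrac{7}{2} \mathrm{O_2} + \mathrm{H_2O}
   \rightarrow \mathrm{Fe^{2+}} + 2\,\mathrm{SO_4^{2-}} + 2\,\mathrm{H^+}$,
   i.e. 7/4 mol O2 per mol sulfate-S). A two-regime weathering curve then
   inverts the corrected Mo flux to a minimum equivalent atmospheric PO2.

## Model conventions and why

**Isotope sign convention.** Sediments are taken to be *lighter* than
seawater by their fractionation factor,
$\delta_i = \delta_{sw} - \Delta_{sw\text{-}i}$ (Fe oxides 1.25, Mn
oxides 3, SAD 0.7, euxinic 0 per mil), so that removal into fractionating
sinks drives seawater heavier than the river input:
$\delta_{sw} = \delta_{in} + \sum_i f_i \Delta_{sw\text{-}i}$. This is the
only orientation under which seawater windows of 1.5–1.8 per mil are
reachable from river inputs of at most 0.7 per mil, and it matches the
observed behaviour of Mn-oxide sediments, which are strongly depleted in
heavy Mo relative to seawater. The euxinic offset of zero encodes
near-quantitative removal: euxinic shales record seawater directly, which
is also why the isotope filter is applied to $\delta_{sw}$ itself.

**Fixed constants.** Molar mass of Mo 95.95 g/mol; total seafloor area
3.6e8 km^2 (modern value; the four sink areas always sum to it); modern
riverine Mo flux 1.35e8 mol/yr; hydrothermal allowance 1% of the modern
flux; Fe-oxide fractionation factor 1.25 per mil, the median of the
mineral-specific values for magnetite (0.83), ferrihydrite (1.11),
goethite (1.40) and hematite (2.19). All live in `mo_constants()` and can
be overridden.

**Sampling distributions** (`sampling_ranges()`): $[\mathrm{Mo}]_{sw}$
uniform on 0.01–105 nM (no prior knowledge between near-zero and the
modern ocean); $\delta_{in}$ uniform on 0–0.7 per mil (igneous crust to
modern rivers); burial rate constants from truncated normals — mean at
the midpoint of the published range, standard deviation 25% of the mean
(they are measured modern values with roughly that uncertainty),
truncated to the range by resampling. Area fractions are drawn uniform on
their ranges (Fe 0.01–100%, Mn 0.01–10%, SAD 0.01–100%, euxinic 0.01–5%;
the capped sinks are continental-margin settings), renormalised to sum to
100% of the seafloor, with draws rejected if the renormalised Mn or
euxinic share exceeds its cap. Renormalisation is our resolution of an
under-specified constraint (four independent ranges cannot sum to 100%
exactly); rejection keeps the printed caps hard.

**Filter semantics.** All windows are closed intervals; the euxinic/SAD
area ordering is strict. The enrichment filter keeps a solution when the
predicted interval (evaluated at mass accumulation rates of 0.0125 and
0.00125 g cm^-2 yr^-1) *intersects* the observed window — a solution is
only rejected when its whole predicted range misses the record on one
side. Boundary conventions are measure-zero choices made explicit for
reproducibility.

**The weathering curve** (`weathering_params()`). The full
reaction-transport soil modelling this replaces is not reproduced here;
instead a calibrated two-regime curve captures its structure: an
O2-limited branch $F = F_{plateau}\,k\,(P/P_t)^n$ (default order $n = 1$)
meeting a sulfide-supply-limited plateau at the modern Mo flux. The
abiotic transition $P_t = 10^{-3.5}$ PAL is the log-midpoint of the
modelled transition zone ($10^{-4}$–$10^{-3}$ PAL); biotic sulfide
oxidation multiplies the O2-limited branch by 10 (experimental rate
enhancement), which at $n = 1$ lowers any inferred minimum PO2 by exactly
one order of magnitude. The biotic factor deliberately does not touch the
plateau: there the limiting reactant is pyrite supply, not kinetics. All
four constants are exposed, so a mechanistic soil model can be swapped in
by re-calibration.

## The synthetic record generator

`generate_shale_record()` emulates the statistical structure of a
compiled euxinic-shale record: each sample mixes a detrital end-member
(default 2 ug/g Mo at 0.3 per mil, an upper-crust-like composition) with
an authigenic component whose concentration follows from the true euxinic
burial flux at a per-sample mass accumulation rate drawn log-uniform
across the ten-fold bracket, and whose delta98Mo is the true seawater
value; bulk delta98Mo receives Gaussian analytical noise (sigma 0.05 per
mil, typical double-spike reproducibility). Concentration noise is off by
default (a lognormal option exists).

What it does *not* emulate: diagenetic overprinting, Mn-shuttle isotope
effects, basin restriction, or non-euxinic depositional environments.
Passing recovery tests therefore show that the *filtering logic* inverts
the record structure it assumes — not that real compiled records satisfy
those assumptions.

`derive_filter_windows()` mirrors how the per-period constraint windows
bracket record maxima: the enrichment window is the record's maximum bulk
Mo padded by a relative fraction (floored at the 2 ug/g detrital cutoff)
and the seawater window is centred on the heaviest observed delta98Mo
(shales are detritally diluted toward lighter values, never heavier).
The padding rule behind the published windows is not stated anywhere, so
the pad is an explicit free parameter (default 0.15) rather than a guess.
`recovery_experiment()` closes the loop: coverage of the true ocean state
by the filtered hull is evaluated only for truths that are themselves
admissible under the windows derived from their own record — a truth
whose required input exceeds the modern flux cap, for instance, is
unrecoverable by construction, and counting it would test nothing.

## Numerical choices

- Mass and isotope closure are identities of the implementation
  ($f_i$ computed as $b_iA_i/\sum b_jA_j$, which also stays defined in
  the degenerate $[\mathrm{Mo}]_{sw} = 0$ limit); tests enforce them to
  1e-12 relative.
- Box-and-whisker summaries use type-7 quartiles with whiskers at the
  most extreme data within 1.5 IQR of the box.
- Hydrothermally-corrected fluxes are floored at zero and flagged: a zero
  means the record is explainable by hydrothermal Mo alone and no O2
  requirement is demonstrable (the PO2 fields are then `NA`).
- The minimum-input cross-validation compares an exhaustive grid search
  and a plain Monte Carlo search on a *coarsened box*
  (`coarsened_box()`): rate constants pinned at their distribution modes,
  the seawater-Mo axis restricted to the interval where the enrichment
  filter can pass at all, the Mn area pinned at its minimum (dominated by
  Fe: same rate constant, larger fractionation) and the SAD area tied
  just above the euxinic area (its flux is pure cost, so at the minimum
  the strict ordering constraint binds). On the full ten-dimensional box
  the constrained minimum is a corner that requires jointly improbable
  tail draws, and random search cannot certify it at any practical size;
  on the reduced box, where every pinned coordinate is pinned by an
  optimality argument, grid and Monte Carlo agree to within a few
  percent.

## Problem sizes

The canonical reproduction run (`scripts/acceptance.R`, and the
acceptance test file) samples 2e6 ensemble members, the size at which the
published analysis is quoted ("several million solutions"); survivor
counts range from ~11,000 (Paleo-Mesoarchean) down to ~15 (the 2.5 Ga
anomalous interval, whose seawater window of 1.50–1.80 per mil is the
most restrictive). Unit and property tests use 2e5-member ensembles,
which leave all distributional checks comfortably converged; the
recovery experiment runs 40 scenarios against a shared 2e5 ensemble.

## Known limitations

- Sample minima are extreme statistics: the minimum surviving input at
  2e6 draws still moves by tens of percent between seeds (survivor
  counts for the tightest period are tens, not thousands), and every
  downstream O2 and PO2 figure inherits that variability — amplified
  where the minimum sits close to the 1% hydrothermal allowance being
  subtracted from it.
- The steady-state model has no ocean dynamics, no spatial structure and
  exactly four sink classes; the weathering curve is calibrated, not
  mechanistic, between its anchor points.
- Filter windows are hard accept/reject with no statistical weighting,
  as in the record analysis this package operationalises.
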