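---
title: "Methods: simulating and analysing a Dp(1;Y) duplication screen for dominant hybrid lethals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing a Dp(1;Y) duplication screen for dominant hybrid lethals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmimap)
```

## The experimental design being modelled

In *Drosophila*, hybrid males between *D. melanogaster* and its relatives
suffer disproportionately from X-linked incompatibilities. A duplication
screen probes the *dominant* side of these interactions: females carrying
a *melanogaster* attached-X (two X chromosomes on one centromere, either
*C(1)RM* or *C(1)DX*) together with a *Dp(1;Y)* chromosome — a fragment of
the *melanogaster* X attached to the Y — are crossed to males of another
species. Four genotype classes segregate, each a Mendelian quarter of the
clutch:

* **nullo-X** embryos (paternal Y over the Dp-bearing Y), which die before
  cellularization in every cross;
* **metafemales** (attached-X over the paternal X), with three X doses;
* **attached-X females** (attached-X over the paternal Y);
* **Dp(1;Y) males** (paternal X over the Dp-bearing Y) — the assayed
  class. These males are viable *unless* the X fragment carried on the Y
  contains a dominant (or semi-dominant) allele that is lethal against the
  paternal-species X background.

Tiling the X with a panel of Dp(1;Y) stocks and recording, for each
cross, how many embryos hatch, how many larvae pupate, and how many pupae
eclose therefore maps the dominant lethal content of the X at the
resolution of the duplication extents, stage by developmental stage.

`dmimap` implements this design end to end: a cytological coordinate
system for duplication extents, a generative model of the crosses with
planted lethal loci, the lethality-calling rule, minimal-region inference,
and the summary statistics. Everything downstream of the simulator also
runs unchanged on real census tables read with `read_viability()`.

## Cytological coordinates

Duplication extents are closed intervals of polytene bands
(`"2C1-3E4"`): euchromatic divisions 1–20, subdivisions A–F, positive
band numbers, followed by the centric heterochromatin blocks h25–h29,
which sort after all euchromatin by h-number. Three conventions matter:

* **Closed intervals.** A duplication carries its endpoint bands; extents
  are stated inclusively, so overlap is `max(starts) <= min(ends)`.
* **Outward completion of loose endpoints.** `"9C-10B"` means everything
  from the first band of 9C through the *last* band of 10B. No published
  catalogue fixes the number of bands per subdivision, so the right
  endpoint's missing band number becomes an ordered sentinel (`Inf`)
  greater than any concrete band number. This makes comparisons exact
  without a band catalogue; the completed interval contains `10B7` but
  not `10C1`.
* **Ordinal, not physical, coordinates.** `cyto_bed()` exports
  rank-indexed 0-based half-open coordinates computed from the order
  relation, for track-style plotting only; the header comment labels them
  ordinal. No mapping to assembly base pairs is attempted.

## The generative model

`simulate_cross()` draws, per replicate, genotype counts from a symmetric
four-way multinomial, then thins each class binomially through the three
stage transitions (embryo→L1, L1→pupa, pupa→adult) at the survival table's
probabilities. A planted locus (`planted_locus()`) is a point band with a
lethal stage, a penetrance, and the set of paternal species in which it
acts; a Dp(1;Y) male "carries" it iff the duplication interval contains
the band, and carriers die at that stage with probability equal to the
penetrance (independent multiplicative survival across carried loci).

The default survival table (`default_survival_table()`) encodes the
qualitative biology as fixed numbers:

| class | cross | embryonic | larval | pupal |
|---|---|---|---|---|
| nullo-X | all | 0 | — | — |
| metafemale, attached-X female | santomea | 0.05 | 0 | 0 |
| metafemale, attached-X female | simulans, mauritiana | 0.9 | 0.9 | 0 |
| attached-X female | melanogaster | 0.9 | 0.9 | 0.9 |
| metafemale | melanogaster | 0.9 | 0.002 | 0.9 |
| Dp(1;Y) male | all | 0.9 | 0.9 | 0.9 |

The published record for these crosses is qualitative (female classes
"fail to hatch" in the most divergent cross, "do not pupate" in the
closer ones; metafemale eclosion under 0.2% of females within species),
so the numbers are modelling choices made once: escaper rates of 5% keep
lethal classes visibly nonzero without approaching the 10% calling
threshold, and a 0.9 per-stage baseline puts unperturbed hatch fractions
(≈ 0.25 of all fertilized embryos in a santomea cross — only the male
quarter can hatch) far above it. The intraspecific column makes adult
sex ratios 1:1, which the screen's controls require.

Census conventions follow the protocol: `n_fertilized` counts all
fertilized embryos including nullo-X (a switch excludes them for
sensitivity analysis), `n_hatched` counts all hatchlings, and the
post-embryonic tallies are male-only, emulating mouthpart-pigment and
*Sxl::GFP* sex sorting; adult females are carried in an extra column so
the 1:1 control check stays computable.

Randomness: one root seed; each cross derives its own seed by a stable
FNV-style hash of (stock, background, species, line), so any cross is
reproducible in isolation and byte-identical reruns are guaranteed.

### What the simulator does and does not emulate

It reproduces the *count structure* of the screen — Mendelian
segregation, stage-specific attrition, lineage-specific planted lethals,
failed matings — which is exactly what the downstream inference consumes.
It does not model cuticle phenotypes, premating behaviour (insemination
is a Bernoulli flag), maternal effects, dosage compensation, or
overdispersion beyond binomial sampling. Passing recovery tests on
synthetic panels therefore validates the *inference machinery*, not the
biology of any particular cross: with real data the lethality calls
inherit whatever extra-binomial noise the vials contain.

## Lethality calling

`classify_cross()` pools replicates (the screen reports per-cross
outcomes, not per-replicate votes; a majority mode exists but is not the
default) and labels the cross by the *earliest* stage transition whose
pooled survival falls below the threshold (default 0.10) — later stages
are unobservable once a cohort is dead. The embryonic denominator is all
fertilized embryos, as the screen's rule states, even though only about
a quarter of the clutch (the male class) can hatch in the most divergent
cross; a `"male_only"` denominator mode rescales to the expected male
quarter for sensitivity analysis. Crosses without observed insemination,
without embryonic progeny, or with fewer than `min_replicates` (default
3, the screen's replication) are excluded with machine-readable reasons,
and a zero denominator yields an undefined (`NA`) proportion, never a
silent zero.

A duplication is a *hybrid lethal* only when both attached-X backgrounds
agree on the same lethal stage (`concordant_calls()`); single-background
lethals are retained with a discordance flag but never counted — the
dual-background requirement is the screen's guard against
background-specific artifacts.

## Minimal regions as minimum interval piercing

The counting rule — overlapping lethal duplications share their cause —
is stated pairwise, which is ambiguous for chains (A overlaps B, B
overlaps C, A and C disjoint: one cause or two?). We formalize it as
**minimum piercing**: the smallest set of bands such that every lethal
interval contains at least one. This reproduces "shared cause" exactly
(any set of intervals through one band can share one allele), is provably
minimal, and by interval-graph duality equals the maximum number of
pairwise disjoint lethal intervals — so it keeps the published
conservative character (a lower bound on distinct incompatibilities).
The right-endpoint greedy solves it exactly; ties on right endpoints
break by stock id for determinism, and the property suite checks the
greedy against exhaustive search on random instances.

Regions are inferred within each (paternal line, lethal stage) class
separately: two overlapping duplications lethal at different stages
cannot share a cause, which is how one cytological neighbourhood can
house two distinct lethal regions.

## Statistics

* **Stage uniformity.** Pearson goodness of fit of the stage tallies
  against an even allocation (12 regions → 4 per stage), df = stages − 1,
  upper-tail p from the χ² distribution (at df = 2 this is exactly
  `exp(-x/2)`, which the tests verify to 1e-12). The test is only run for
  lines with at least `uniformity_min_regions` (default 6) regions; with
  two regions over three stages the test is uninformative, which is why
  the closer crosses are not tested.
* **Homogeneity.** Pearson contingency χ² without continuity correction,
  with an explicit error on zero marginals.
* **Šidák thresholds.** `1 - (1 - alpha)^(1/m)` for m comparisons.
* **Snowball comparison.** OLS of region counts on synonymous divergence
  Ks, linear versus full quadratic (intercept + linear + quadratic — the
  conventional reading of "quadratic"; a pure `count ~ Ks^2` mode is
  available for sensitivity). Gaussian maximum likelihood
  `-(n/2)(log 2π + log(rss/n) + 1)` and `AIC = 2k − 2·loglik` with
  `k = coefficients + 1` for the residual scale — the standard
  Gaussian-MLE convention, which the source analysis does not state.
  A residual sum of squares below the floor (default 1e-12) flags the fit
  **degenerate**: the five-point study dataset has only three distinct
  abscissae with equal replicate ordinates, so the full quadratic
  interpolates exactly and its likelihood is unbounded. We surface the
  flag and report AIC as −Inf rather than a spuriously finite number; the
  preferred-model decision (quadratic) is unaffected. This is also why
  the printed AIC pair of the original analysis cannot be reconstructed
  from the five points alone under any standard convention we tried — the
  package reproduces the qualitative conclusion (quadratic ≪ linear) and
  the linear fit's finite AIC, and documents the degeneracy instead of
  matching unreproducible numbers. Intraspecific crosses enter the
  dataset at the within-species polymorphism proxy (π = 0.03) with their
  observed (zero) counts.

## Default study conditions and problem sizes

The simulated study mirrors the screen's shape: a 40-stock panel tiling
divisions 1–20 two tiles per division; five paternal lines (santomea at
Ks 0.24, simulans and mauritiana at 0.11, two intraspecific melanogaster
lines at π 0.03); 12 santomea-acting planted loci (9 embryonic, 3 pupal),
the 4C pupal locus shared by all three interspecific crosses, and a
sim/mau-only larval locus at 9D4; penetrance 1; clutches of 300 embryos,
3 replicates, both backgrounds. One full five-line run is ~400 crosses
(≈ 360,000 embryos) and takes about a second; the recovery test repeats
the santomea and intraspecific arms across 50 seeds. These sizes were
chosen as the smallest at which binomial sampling error is negligible
relative to the 10% rule (pooled denominators of ~900 embryos put the
no-lethal hatch fraction ≈ 10 standard errors above threshold).

## Known limitations

* Planted loci are points; a real duplication may house several alleles,
  and the piercing count is by construction a lower bound.
* Semi-lethal alleles (partial viability reduction) are out of scope, as
  in the screen itself: the 10% rule detects complete lethality only.
* The band order needs no catalogue of bands per subdivision, at the cost
  of the `Inf` sentinel in completed right endpoints; formatted intervals
  are canonical (`"9C1-10B"`), not always byte-identical to loose input.
* Binomial thinning understates vial-to-vial variance in real data;
  threshold-adjacent calls on real tables deserve more replicates than
  the default three.
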