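---
title: "Designing and screening MRM transitions for modified nucleosides"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening MRM transitions for modified nucleosides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmscreen)
```

## The problem

Modified ribonucleosides are routinely quantified by LC-MS/MS on triple
quadrupole instruments in multiple reaction monitoring (MRM) mode: Q1
selects the protonated nucleoside (MH+) and Q3 the protonated nucleobase
(BH2+) produced by collision-induced cleavage of the N-glycosidic bond.
Because synthetic standards exist for only a fraction of the >160 known
natural modifications, many assays monitor transitions computed from
molecular formulas alone. At unit resolution (about 0.5 Da per
quadrupole) that practice exposes three distinct misidentification
mechanisms:

* **Type I — structural isomers.** Species with identical molecular
  formulas (e.g. the four base-methylated adenosines m1A, m2A, m6A, m8A)
  produce literally the same transition (282.1 → 150) and can only be
  told apart chromatographically.
* **Type II — mass-analogs.** Species with different formulas whose
  precursor and product masses each differ by less than the resolution.
  N6,N6-dimethyladenosine (C12H17N5O4, MH+ 296.1359) and
  N6-formyladenosine (C11H13N5O5, MH+ 296.0995) differ by 0.0364 Da and
  share the channel 296.1 → 164.
* **Type III — isotopic crosstalk.** A +1 or +2 heavy isotopologue
  (dominated by 13C and 34S at natural abundance) of one species lands in
  the channel of another species one or two nominal mass units up. The
  inosine channel 269.1 → 137, for instance, receives the +1
  isotopologue of adenosine whenever the two co-elute.

`mrmscreen` computes the transitions, detects all three conflict classes
in any panel, quantifies crosstalk intensities from first principles,
and simulates the resulting chromatographic traces.

## The model

### Masses and transitions

Monoisotopic masses are exact sums of lightest-isotope masses over the
molecular formula. The precursor is MH+; two adduct conventions are
supported and the difference between them is exactly the electron mass:

* hydrogen-atom addition, +1.00783 Da (default), and
* proton addition, +1.00728 Da.

The default was chosen because published nucleoside transition tables
round to values consistent with hydrogen-atom addition at four decimal
places; since the two conventions differ by 0.55 mDa, no nominal
(rounded) channel is affected by the choice.

Product ions follow a three-branch rule, in priority order:

1. **Overrides.** C-glycosides do not release a protonated base; the
   pseudouridine family instead shows ribose-internal fragments. These
   product ions are data, not a formula rule: pseudouridine is monitored
   at 245.1 → 209/179/155, its 1-/3-methyl derivatives at 179, the
   aminocarboxypropyl derivatives at 214 and 228. We deliberately did
   not invent a closed-form loss rule for this family because the
   printed ions do not determine one; a C-glycoside without overrides is
   reported un-monitorable rather than guessed at.
2. **2'-O-methyl sugars** lose C6H10O4 (146.0579 Da). This correctly
   keeps base modifications on the fragment: 1,2'-O-dimethyladenosine
   gives 296.1 → 150, while 2'-O-methyladenosine gives 282.1 → 136 and
   is thereby distinguishable from the base-methylated isomers.
3. **Ordinary N-glycosides** lose the ribose C5H8O4 (132.0423 Da).

Nominal values round half-up — precursor to one decimal, product to the
integer — matching the convention of published tables. Screening,
however, always compares *exact* masses against the resolution window:
two channels at x.44 and x.56 would round apart yet still overlap
physically.

### Isotopologue distributions

Distributions are aggregated by nominal shift k (unit-mass buckets),
matching the unit-resolution instrument model; fine isotopic structure
is out of scope. The per-element distribution of total shift for n
atoms is the multinomial over isotope assignments aggregated by shift;
formula distributions are polynomial convolutions of the element
distributions. Because isotope shifts are non-negative, truncating at
`max_k` is exact for every retained bucket, and the residual abundance
is carried explicitly as `truncation_bound` (so entries plus bound sum
to one by construction, to within floating error).

The default `max_k = 2` reflects that one- and two-unit shifts are the
ones that cause crosstalk in practice — +1 from 13C (and 15N), +2 from
34S and 18O. Two isotope tables ship with the package: the full stable
isotope table (default) and a two-isotope-per-element "minimal" table
with the heavy abundances commonly quoted in the nucleoside literature
(13C 1.11 %, 2H 0.0115 %, 15N 0.364 %, 18O 0.205 %, 34S 4.21 %). The
full table moves +1 abundances at the third significant digit; the
minimal table exists to reproduce literature calculations exactly.

### Crosstalk intensity

Crosstalk into the (precursor + k → product + k) channel requires every
heavy isotope to ride along into the retained base fragment, so the
observable fraction is

    crosstalk(k) = D_base(k) x D_loss(0)

where D are isotopologue distributions of the base fragment and the
neutral loss. This is always at most the whole-molecule D(k) — the
tests assert that conditioning can only reduce abundance. The mixed
configuration (heavies in the lost sugar: precursor shifted, product
not) is computed by the same machinery as `D_base(0) x D_loss(k)` and
reported under a separate "partial" heading, off by default, since no
published assay monitors precursor-shifted/product-unshifted channels.
Species monitored through overrides have no defined loss formula and are
therefore never treated as Type III *interferers* (their fragment
distribution is unknowable from the catalog); they remain Type I/II
participants and Type III targets.

When testing whether a shifted channel lands inside a target window the
per-unit shift is taken as the 13C−12C difference (1.003355 Da), the
dominant contributor; at a 0.5 Da window the sub-mDa differences between
heavy-isotope shifts cannot change any verdict.

## Screening semantics

All unordered species pairs are classified:

* Type I: identical formulas **and** a shared channel. Isomers whose
  products differ (m1A vs Am, uridine vs pseudouridine) are reported as
  *resolvable isomers* — informational, not findings.
* Type II: different formulas, both |Δprecursor| and |Δproduct| below
  the resolution (override products compared on nominal values).
* Type III: directional, both directions evaluated; requires the
  shifted channel to land within the window on **both** quadrupoles and
  the crosstalk abundance to clear `min_crosstalk_abundance`.

The default abundance floor of 0.1 % retains 13C +1 crosstalk (about 1 %
per carbon) and 34S +2 crosstalk (4.2 %) while suppressing 2H/17O noise;
the source material quotes no threshold, so this is a package choice,
and it is exposed as a parameter. Findings are grouped by shared nominal
channel; the classic five-standard demonstration panel (s2U, s4U, ho5U,
m5D, s2C) yields a single group at 261.1 → 129 with five members and all
three types at once. Thresholds are monotone: shrinking the resolution
or raising the floor never adds findings (property-tested), and on
panels of up to eight species the classifier is verified against an
independent brute-force double loop.

An optional retention table (measured times or ordinal ranks) flags
findings whose species elute within `rt_window` of each other. The
package never predicts retention: column fixtures carry only the
observed elution orders of the monomethyladenosines (HILIC:
m6A < m2A < m1A; PFP and ODS: m1A < m2A < m6A, with m2A/m6A not baseline
separated on PFP) and the 50-min run-time envelope.

## The bundled catalog and its validator

`builtin_catalog()` transcribes the published isomer/mass-analog/
crosstalk tables plus the seventeen commercial standards and the
canonical nucleosides (85 species). Printed precursor and product
values are stored verbatim next to the formulas, and
`validate_against_printed()` recomputes every transition and reports
mismatches as data. The bundled catalog intentionally reproduces the
source's internal inconsistencies rather than adjudicating them; the
stable reconciliation list (`known_discrepancies()`) comprises:

* three adenosine entries printed at precursor 269.1 whose formulas
  (C12H17N5O4, C11H13N5O5) compute to 296.1;
* one threonylcarbamoyl species printed 427.2 → 295 whose printed
  formula computes to 413.1 → 281;
* two uridine methyl esters printed with product 297 in one table and
  201 (the rule-consistent value) in another — both values are kept as
  primary/alternate.

## Chromatogram simulation

`simulate_chromatograms()` renders each panel species as a Gaussian peak
(area = amount × response factor) into its own channel with weight 1 and
into every reachable crosstalk channel with the fragment-conditional
weight. Response factors capture ionization-efficiency differences
(e.g. a formylated base that deprotonates rather than protonates can be
given a small factor); the shipped examples use placeholder ratios that
are illustrative, not physical. Peaks are Gaussian because interference
logic is shape-independent; tailing is not modeled. Noise is optional
and seeded, modeled as Poisson counting noise over the noiseless trace
plus a small baseline — this keeps intensities non-negative, and the
noise is carried as its own component so the per-channel total still
equals the sum of contributions exactly. Without a seed the simulation
is fully deterministic, which is what the property tests rely on:
linearity in amount, exact contribution bookkeeping, and crosstalk peak
areas that reproduce the isotope-engine factor to integration tolerance.

## Numerical choices and problem sizes

* Rounding is half-up (half away from zero), not banker's rounding; all
  decisive printed values agree under this rule.
* Formula arithmetic is exact integer arithmetic; mass additivity holds
  to 1e-9 Da and is property-tested on random formula pairs.
* Distribution correctness is established against an exhaustive
  multinomial-enumeration oracle (1e-10 agreement) and a decomposition
  identity D(a+b) = D(a) ⊛ D(b) on random formula splits.
* The test suite screens the full 85-species catalog (about 3,600
  pairs, a few seconds) and cross-checks twenty random panels of up to
  eight species against the brute-force classifier; these sizes exercise
  every code path while keeping the default check fast.

## Limitations

* Only [M+H]+ singly charged positive mode; no Na+/K+/NH4+ adducts, no
  negative mode.
* No fine isotopic structure or resolution-dependent peak shapes.
* No retention prediction — co-elution assessment requires user-supplied
  retention data, and the synthetic traces space ordinal ranks uniformly
  across the run for illustration only.
* The synthetic chromatograms demonstrate channel arithmetic, not
  matrix effects, in-source fragmentation, or detector saturation; a
  clean screen of a panel here does not guarantee clean biology, it
  only certifies the mass arithmetic of the method.
* The catalog is strictly what the source tables print; it does not
  track external modification registries.
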