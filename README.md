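# mrmscreen

Design and sanity-check multiple reaction monitoring (MRM) assays for
modified ribonucleosides analysed by triple-quadrupole LC-MS/MS.

Epitranscriptomics labs quantify modified nucleosides by monitoring the
transition from the protonated nucleoside (MH+, selected in Q1) to the
protonated nucleobase (BH2+, selected in Q3) released by cleavage of the
N-glycosidic bond. Standards exist for few of the >160 natural
modifications, so transitions are usually computed from molecular
formulas — which, at unit (~0.5 Da) resolution, invites three classes of
misidentification:

| Type | Mechanism | Example |
|------|-----------|---------|
| I | structural isomers share a channel | m1A/m2A/m6A/m8A all at 282.1 → 150 |
| II | mass-analogs differ by < 0.5 Da | m6,6A (296.1359) vs f6A (296.0995), Δ = 0.0364 Da |
| III | +1/+2 isotopologue crosstalk (13C, 34S) | adenosine +1 bleeding into inosine's 269.1 → 137 |

`mrmscreen` provides:

* an exact monoisotopic mass engine with formula parsing and the MH+
  protonation conventions (`parse_formula`, `protonated_mass`);
* isotopologue distributions by nominal shift, via multinomial
  convolution, including fragment-conditional crosstalk intensities
  (`formula_distribution`, `fragment_crosstalk_factor`);
* a bundled 85-species catalog of commonly monitored nucleosides with
  printed reference transitions and a validator that reconciles them
  against the computed ones (`builtin_catalog`,
  `validate_against_printed`);
* rule-based transition generation — ribose loss C5H8O4,
  2'-O-methylribose loss C6H10O4, data overrides for the pseudouridine
  family (`transitions_for_catalog`);
* pairwise panel screening for Type I/II/III conflicts with quantitative
  crosstalk evidence (`screen_catalog`);
* a synthetic chromatogram simulator for channel-sharing and
  bleed-through phenomenology (`simulate_chromatograms`);
* a CLI: `inst/cli/mrmscreen.R` with `transitions`, `isotopes`,
  `screen`, `simulate`, `validate` subcommands.

## Worked example

Screen the five-standard thiouridine panel that famously collapses into
a single MRM channel:

```r
library(mrmscreen)

cat5 <- builtin_catalog()
panel <- cat5[cat5$abbreviation %in% c("s2U", "s4U", "ho5U", "m5D", "s2C"), ]
rep5 <- screen_catalog(panel)
rep5$channel_groups
#>   precursor product n_members              members    types
#> 1     261.1     129         5 ho5U;m5D;s2C;s2U;s4U I;II;III
```

One channel, 261.1 → 129, collects all five species: s2U/s4U are
structural isomers (Type I), ho5U and m5D are mass-analogs of the
thiouridines (Type II, precursor deltas 0.018–0.054 Da), and the +1
isotopologue of s2C bleeds in directionally (Type III). The findings
table carries the evidence; for instance the s2C → s2U crosstalk row
reports `k = 1` and `crosstalk_abundance = 0.0529`, i.e. 5.3 % of the
s2C ion population appears in the shifted channel (a thionucleoside has
both a large 13C +1 and, at k = 2, a 4.2 % 34S route):

```r
subset(rep5$findings, type == "III" & target == "s2U")
#>   type target interferer shared_precursor shared_product ... k crosstalk_abundance
#>    III    s2U        s2C            261.1            129 ... 1          0.05287193
```

Validate the bundled catalog against its printed transitions — the
mismatches are themselves a stable, documented fixture:

```r
validate_against_printed(builtin_catalog())
#>   abbreviation     field printed computed
#> 1        m2,8A precursor   269.1    296.1
#> 2        m6,6A precursor   269.1    296.1
#> 3          f6A precursor   269.1    296.1
#> 4        m6t6A precursor   427.2    413.1
#> 5        m6t6A   product   295.0    281.0
#> 6       mchm5U   product   297.0    201.0
#> 7       mcmo5U   product   297.0    201.0
```

Or from the shell:

```sh
Rscript inst/cli/mrmscreen.R screen --catalog builtin --format json --out report.json
Rscript inst/cli/mrmscreen.R transitions --out transitions.tsv
Rscript inst/cli/mrmscreen.R isotopes --formula C10H13N5O4 --max-shift 2
```

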