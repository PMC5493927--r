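# paleopuna

Multi-proxy inference of hunter-gatherer highland land use.

High-elevation environments (above 2500 m a.s.l.) were among the last
places humans settled permanently, and for any one archaeological site
the competing explanations — logistical forays from a lowland base,
seasonal transhumance, or permanent highland residence — are hard to
separate from a single observation. `paleopuna` implements a
multi-proxy test battery that confronts a site with five independent
lines of evidence and scores three land-use models conjunctively:

* **H1** — drinking-water δ¹⁸O inferred from human bone carbonate via
  linear fractionation-correction chains, with collagen quality control
  (C ≥ 35 wt%, N 11–16 wt%, atomic C:N 2.9–3.6) and highland/lowland
  classification at the −8‰ meteoric-water threshold;
* **H2** — diet δ¹³C against per-model expectation windows, plus
  two-sample Kolmogorov–Smirnov comparisons with reference plant and
  camelid distributions;
* **H3** — terrain-adjusted least-cost travel from the site to the
  2500 m contour (Tobler hiking function over an elevation grid,
  anisotropic Dijkstra, isochrones, Arc/Info ASCII Grid I/O), with the
  ethnographic mobility rule: a round trip over 80 km refutes
  logistical use, over 1000 km refutes seasonal use;
* **H4** — age-at-death profiles from interval estimates (overlap
  apportionment into 10-year bins) and a χ² test of sex parity;
* **H5** — lithic raw-material tallies classifying non-local abundance.

A model must pass *every* evaluated line; the joint false-positive
probability of k convergent independent lines, each with false-positive
rate p, is p^k (two lines at 20% leave 4%). The package also provides
radiocarbon calibration with 95% highest-posterior-density intervals,
and synthetic generators (populations, assemblages, calibration curves,
terrains with closed-form travel-time oracles) that make the whole
pipeline testable end-to-end offline. A 16-burial sample table from a
3800 m Altiplano site ships as the worked fixture.

## Worked example

```r
library(paleopuna)

burials <- smp_burials()              # 16 individuals, corrected values
table(classify_zone(burials$d18O_mw_vsmow))
#> highland  lowland
#>       16        0

parity <- sex_parity_chisq(8, 5)      # determinate females vs males
sprintf("chi2 = %.2f, p = %.2f", parity$chi2, parity$p)
#> "chi2 = 0.69, p = 0.41"

h <- list(
  H1_d18o       = evaluate_isotope_hypothesis(burials, model_windows("table2"), "d18o"),
  H2_d13c       = evaluate_isotope_hypothesis(burials, model_windows("text"), "d13c"),
  H3_distance   = distance_rule_eval(244),   # 2 x 122 km one-way
  H4_demography = evaluate_demography(build_profile(burials)),
  H5_lithics    = evaluate_provenance(lithic_tally(n_total = 539, n_local = 534))
)
score_evidence(h)
#> evidence scorecard (5 hypotheses evaluated)
#>            H1_d18o H2_d13c H3_distance H4_demography H5_lithics
#> logistical no      no      no          no            no
#> seasonal   no      yes     yes         yes           no
#> permanent  yes     yes     yes         yes           yes
#> selected model: permanent (joint false-positive probability 0.00032 at p = 0.2 per line)
```

Every drinking-water value classifies highland, the sex ratio sits in
statistical parity, the 244 km round trip is three times the maximum
ethnographic logistical range, 99.1% of artefacts are local — and only
the permanent-use model survives every line, with the logistical model
supported by none.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full
study over the package functions and write their tables under
`results/`:

| script | step |
|---|---|
| `01_simulate_inputs.R` | synthetic input bundles per land-use model |
| `02_isotope_chemistry.R` | QC, zone classification, windows, KS tests |
| `03_radiocarbon.R` | calibration + 95% HPD ranges on a synthetic curve |
| `04_travel_cost.R` | travel-time surface, isochrones, contour route |
| `05_demography.R` | age profile and parity test |
| `06_provenance.R` | raw-material tallies |
| `07_evidence_scorecard.R` | scorecard + 200-run model recovery |

Run them in order with `Rscript analysis/01_simulate_inputs.R` etc.
The methods vignette (`vignettes/multiproxy-highland-occupation.Rmd`)
documents the models, parameter choices, numerical conventions and
limitations.

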