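---
title: "Methods: multi-proxy inference of hunter-gatherer highland occupation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-proxy inference of hunter-gatherer highland occupation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleopuna)
```

## The inference problem

When did hunter-gatherers begin to occupy high-elevation environments
(above 2500 m a.s.l.) on a permanent, year-round basis? For a single
site, three competing land-use models are on the table:

1. **Logistical use** -- task groups provisioned from a low-elevation
   base camp make targeted forays into the highlands.
2. **Seasonal use** -- whole residential groups move between low and
   high elevations with the seasons.
3. **Permanent use** -- the annual round is situated almost entirely in
   the highlands.

No single archaeological observation can separate these models
reliably. The approach implemented here confronts the site with five
*independent* lines of evidence -- drinking-water oxygen isotopes
inferred from human bone (H1), diet carbon isotopes (H2), least-cost
travel distance to the 2500 m contour (H3), the age/sex structure of the
burial population (H4), and the abundance of non-local lithic raw
materials (H5) -- and requires a model to pass *every* evaluated line
("across the board"). The value of convergence is quantified by the
joint false-positive probability: if each line alone has a false-positive
chance $p$, then $k$ independent lines all pointing at the same wrong
model has probability $p^k$ (`joint_false_positive()`; two lines at 20%
leave 4%). The per-line $p$ is illustrative, not estimated from data.

## H1/H2: bone chemistry

### Correction chains

Measured bone-carbonate values are linked to drinking water and diet by
chains of linear fractionation steps, each `v <- slope * v + intercept`
(`apply_chain()`). Chains compose associatively and the empty chain is
the identity, so project-specific equations can be substituted step by
step (`read_chain_config()`).

The packaged default oxygen chain (`default_d18o_chain()`) is the
canonical literature route -- VPDB-to-VSMOW scale conversion
($v \leftarrow 1.03091\,v + 30.91$), a $-8.5$ per-mil
carbonate-to-phosphate offset, and the inverted body-water fractionation
($v \leftarrow (v - 22.7)/0.78$). These are conventional stand-ins: the
exact equations behind any given published dataset vary, which is why
corrected values can be supplied directly in the sample table (the
packaged fixture does exactly that, and `read_samples()` records the
provenance of every value as `corrected_input` or `chain_applied`).
The named carbon constants (`d13c_corrections()`) are the Suess
(post-industrial fossil fuel) correction $+1.5$ per mil, trophic
enrichment $+5$, carbonization $+1$, and a conventional $-9.4$
apatite-to-diet spacing.

### Quality control

Diagenetic screening uses the standard collagen rectangle: carbon mass
fraction $\ge 35$ wt%, nitrogen 11--16 wt%, atomic
C:N $= (C/12.011)/(N/14.007)$ within 2.9--3.6, every boundary inclusive
(`collagen_qc()`).

### Classification and windows

Central-Andean surface waters below 2500 m produce meteoric-water
$\delta^{18}O$ above $-8$ per mil; Altiplano sources fall between $-25$
and $-8$. `classify_zone()` therefore calls a value *highland* when it
is strictly below the threshold ($-8$ by default): "consistently below"
reads most naturally as a strict inequality, and the boundary case then
conservatively counts as lowland. Window membership in
`evaluate_isotope_hypothesis()` is by contrast inclusive at both ends,
and a model is supported only when every sample with a value falls
inside its window; missing values are listed, never dropped.

Two window presets ship (`model_windows()`), because the per-model
expectations are stated twice in slightly different forms: a summary
table (`"table2"`, the default) and the hypothesis text (`"text"`). The
difference matters once: the table's permanent-use carbon window ends at
$-21$ per mil while the text's dietary range extends to $-19$, and the
packaged burial values (range $-24$ to $-20$) include two individuals
above $-21$. Under the strict all-inside rule the table preset would
therefore refute permanent use on H2 with data the source analysis
itself judged consistent with it (that judgement was distributional, by
KS comparison, not a membership test). The fixture analysis in
`analysis/07_evidence_scorecard.R` consequently evaluates H1 with the
table windows and H2 with the text windows; the model-recovery
simulations use the table preset throughout for both generator and
scorer, which is self-consistent. Users can pick either preset per
proxy.

### Distributional comparison

`ks_two_sample()` is the two-sample Kolmogorov-Smirnov comparison:
$D = \sup_x |F_a(x) - F_b(x)|$, with the p-value from the asymptotic
Kolmogorov distribution at effective size $n_a n_b / (n_a + n_b)$
(ties tolerated with the usual caveat). Small-sample exact p-values are
deliberately out of scope; $D$ is reported to two decimals in the
analysis drivers to match conventional reporting.

## Radiocarbon calibration

`calibrate()` implements the standard single-date calibration: with a
measured age $y \pm \sigma$ and curve mean $\mu(t)$, error
$\sigma_c(t)$ on a calendar grid, the posterior mass at $t$ is

$$ P(t) \propto \frac{1}{\sqrt{\sigma^2 + \sigma_c(t)^2}}
   \exp\!\left(-\frac{(y - \mu(t))^2}{2(\sigma^2 + \sigma_c(t)^2)}\right), $$

normalised over the grid. The $1/\sqrt{\cdot}$ total-variance factor is
included; some implementations omit it, which changes results slightly
wherever the curve error varies, so the choice is documented here for
comparability. The grid is the curve's native grid by default (no
hidden interpolation); `resolution =` refines it linearly. Input curves
may run ascending or descending -- they are canonicalised, so the
posterior is direction-invariant. Dates more than $5\sigma$ outside
curve coverage are rejected.

`hpd()` returns the smallest set of grid cells reaching the requested
level, merged into intervals; ties in cell mass are broken towards
older (larger cal BP) cells, making the output deterministic, including
on plateaux where the HPD is genuinely multi-interval. Reservoir
corrections and mixed-curve calibration are not implemented, and no
phase/sequence chronological modelling is attempted.

Because the underlying raw determinations for the motivating site are
unpublished, this module is validated by properties rather than value
reproduction: on an identity curve with vanishing curve error the
posterior recovers the input mean and sd within one grid step, HPD mass
always reaches its level, and halving the grid step moves the HPD
endpoints by at most one coarse step.

## H3: travel cost

Walking speed follows the exponential slope law
$s(m) = s_{max} e^{-k |m + c|}$ with Tobler's parameters
$(s_{max}, k, c) = (6\ \mathrm{km/h}, 3.5, 0.05)$ as defaults
(`hiking_function()`): the 6 km/h peak sits on a gentle 5% downhill and
level walking runs at 5.04 km/h. The published analysis says only
"terrain-adjusted", so all three parameters are exposed for drop-in
replacement of the actual cost function.

`build_cost_graph()` connects each cell to its 8 (queen) or 16 (queen
plus knight-move) neighbours with *directed* edges weighted
$\mathrm{distance}/s(\mathrm{slope})$ -- uphill and downhill differ, so
the surface is anisotropic. Planar grids use Euclidean cell-centre
distances; geographic grids use great-circle distances on the authalic
sphere ($R = 6371007.2$ m), which automatically contracts east--west
spacing with latitude. Cells are addressed (row, col) with row 1 at the
north edge and the origin at the lower-left corner, exactly matching
the Arc/Info ASCII Grid layout that `read_ascii_grid()` /
`write_ascii_grid()` parse bit-consistently. Walking is modelled
cell-centre to cell-centre with no off-path penalty multipliers.

`travel_time_surface()` runs Dijkstra over this graph (via igraph) and
keeps predecessor links; `time_to_contour()` takes the minimum over all
cells strictly below the contour elevation (2500 m by default),
reconstructs the route, and reports one-way and round-trip (twice
one-way) kilometres; `isochrones()` labels cells by
$\lfloor t/\mathrm{interval} \rfloor$ with a 10 h default interval.
8-connectivity is the default; 16-connectivity never increases any
travel time and reduces the metric distortion of grid routing (worst
case about 8% on 8 neighbours, 2.8% on 16). The synthetic terrains
(`synth_dem()`: inclined planes, cones, ridges) have closed-form
optimal times -- on a cone at exactly the optimal $-5\%$ grade, the
best descent runs along a pure radial at the full 6 km/h -- which is
what the travel tests check, to within the connectivity detour bound
(2%).

The published headline figures for the motivating site (122 km one-way,
41 h, 244 km round trip) depend on the specific 30 arc-second DEM tile
and the unpublished cost function; they are *not* reproduced from
terrain here. What the package reproduces is the derived logic: the
round-trip relation (twice one-way) and the distance rule -- a round
trip over 80 km refutes logistical use, over 1000 km also refutes
seasonal use (`distance_rule_eval()`, bounds inclusive). The summary
table states the same rules as one-way figures ("less than 40 km",
"less than 500 km"); both phrasings encode the same round-trip bounds,
which is the encoding used. Real DEM grids are supported through the
ASCII reader as an integration exercise.

## H4: demography

Osteological ages are interval estimates, so `build_profile()` spreads
each individual's unit mass uniformly over its age interval and
apportions it to 10-year bins by overlap (a midpoint mode is available;
the apportionment choice is an assumption and is recorded in the JSON
report). Total mass always equals the number of aged individuals.
Cohort flags use interval intersection: young children are intervals
meeting 4--8 years, old adults intervals reaching 50. The packaged
fixture closes one open-ended "50+" estimate at 70 years.

`sex_parity_chisq()` is the df-1 goodness-of-fit test of the determinate
female/male counts against 50:50, no continuity correction;
indeterminate individuals (typically subadults, whose skeletons cannot
be reliably sexed) are excluded. On the fixture's 8 females and 5 males
this gives $\chi^2_1 = 0.69$, $p = 0.41$. The asymptotic p tracks the
exact doubled-binomial p to within about 0.25 for totals of 10--20
(worst near even splits, where the doubled exact p saturates at 1); the
tests document this gap. Model scoring (`evaluate_demography()`):
logistical use is supported when children are absent *and* parity is
rejected at $\alpha = 0.05$; the residential models when children and
old adults are present and parity is not rejected. Burial-assemblage
bias is deliberately not corrected.

## H5: provenance

`lithic_tally()` reports the percentage of artefacts matched to local
raw-material sources (one decimal). `evaluate_provenance()` classifies
the non-local fraction $f$: *absent* when $f \le 0.02$, *abundant* when
$f > 0.20$, *present* between -- a value exactly on a threshold takes
the lower-abundance category. The published characterisation is
qualitative ("near absence"), so the thresholds are defaults chosen to
put the observed 0.9% in *absent*, and both are configurable.
Unmatched artefacts are counted non-local even though they may be
extremes of local material variation; the evaluation carries that note.

## The scorecard

`score_evidence()` takes named per-hypothesis support tables,
conjuncts them per model over the evaluated hypotheses, and selects the
unique surviving model (or reports "no unique model" with per-model
counts). Hypotheses with `NA` support are excluded and listed. The
hypothesis numbering follows the hypothesis sections (H3 distance, H4
demography); the summary table's column order swaps the two, which is
noted here so readers can map between them. A weighted or
partial-credit aggregation is deliberately out of scope.

## Synthetic data and what passing tests show

`simulate_population()` draws isotope values *uniformly* inside the
generating model's windows -- hard bounds, not merely in distribution --
because the source expectations are ranges, not distributions. Two
demographic modes mirror the model signatures:

* `full_spectrum` guarantees two young children and one old adult by
  stratified construction (burial populations of residential groups are
  U-shaped in age-at-death, so guaranteed presence at $n = 16$ is the
  realistic regime), draws the remaining ages from a broad mixture, and
  assigns adult sexes Bernoulli(0.5) with subadults recorded as
  indeterminate, matching osteological practice.
* `task_group` draws adults aged 18--45 with one sex in the majority at
  probability 0.85. The skew is an invented parameter; 0.85 makes the
  parity test reject in roughly 92% of draws at $n = 16$, i.e. the
  task-group signature is detectable at the excavated sample size
  without being deterministic.

Generating non-local artefact fractions are 0.30 / 0.08 / 0.005 and
round-trip distance scenarios 40 / 400 / 244 km for the logistical /
seasonal / permanent models ($n = 539$ artefacts, matching the examined
assemblage). `simulate_inputs_end_to_end()` additionally emits an
inclined-plane ASCII-grid terrain whose 2500 m crossing sits at the
scenario's one-way distance to within one cell, so the travel module
recomputes the scenario distance from terrain rather than taking it on
faith. Identical seeds give byte-identical bundles.

The end-to-end check is model recovery: 200 simulated studies per
generating model at $n = 16$, each scored blind with the same windows
the generator used. Recovery runs around 93% for permanent, 90% for
logistical and 95% for seasonal generation, with failures almost
entirely "no unique model" verdicts caused by sampling noise in the
parity test -- a conjunctive scorecard abstains rather than guessing.
A truncated-normal draw option is available for more realistic isotope
distributions but is off by default, because hard-bounded uniforms make
the window-membership properties exactly testable.

What passing these tests does *not* show: that real bone values follow
uniform window distributions, that real terrain behaves like synthetic
planes and cones, or that the published 122 km / 41 h figures are
recovered -- those require the original DEM and cost function. The
synthetic conditions validate the machinery and the inferential logic,
not the field measurements.

## Numerical choices and problem sizes

Tolerances: travel closed-form checks at 2% (the 8-connectivity detour
bound); Dijkstra-vs-relaxation equality at $10^{-9}$ h; calibration
recovery within one grid step; KS against its brute-force oracle at
$10^{-12}$. Degenerate inputs fail loudly: empty samples, zero
nitrogen, non-monotone calibration grids, nodata sources, empty
windows, levels outside $(0,1)$. Deterministic tie-breaks: HPD ties to
older cells; provenance thresholds to the lower category; `which.min`
route ties to the first (row-major) cell. Test problem sizes were
chosen to keep the full suite around ten seconds: shortest-path oracles
on grids up to $10 \times 10$ (the relaxation oracle is quadratic in
cells), invariant sweeps over 50 seeded $7 \times 7$ terrains, 200
recovery runs per model, and 50-instance KS/property sweeps.
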