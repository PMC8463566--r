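---
title: "Calling phosphosite functionality from growth and metabolome screens"
author: "PhosphoScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling phosphosite functionality from growth and metabolome screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhosphoScreen)
```

## The screening problem

Bacterial enzymes carry serine/threonine/tyrosine phosphosites whose
functional relevance is mostly unknown. A now-standard way to probe a site
is to mutate it to a phosphomimetic residue (S/T to E, imitating the
constitutive negative charge, a proxy for 100% occupancy) and to a
phospho-abolishing residue (S/T to A, Y to F, a proxy for 0% occupancy),
then to compare both mutants, the corresponding gene knockout and the wild
type across growth conditions. Two complementary readouts are used:

* **Growth phenotyping** — exponential growth rates from microplate OD600
  curves; a mutant whose rate differs from the wild type by at least 10%
  at Welch-test p < 0.05 in some condition has a growth phenotype.
* **Untargeted metabolomics** — flow-injection TOF-MS ion intensities.
  Ions are annotated to metabolites of a metabolic reconstruction by
  accurate deprotonated-ion mass ([M−H]⁻, 0.001 Da tolerance). Per mutant
  and condition, each ion's log2 fold change against the pooled wild-type
  replicates is tested (Welch on log2 intensities, Benjamini–Hochberg
  correction); an ion changes significantly when |log2 FC| exceeds a
  data-driven cutoff (the 95th percentile of all |log2 FC| of all annotated
  ions in all strains) and q < 0.05.

A phosphosite is called **functional** when any of its phosphomutants, in
any condition, shows (i) a growth phenotype, (ii) a *local* metabolic
change — a significantly changing metabolite within five reaction steps of
the mutated enzyme — or (iii) a metabolic profile that correlates with the
corresponding knockout (Spearman ρ > 0.4, p < 0.001). A *global-change*
flag (at least twice the cohort median number of changing metabolites) is
reported alongside but never suffices for the call. For functional sites a
phosphoregulation sign is inferred: if the abolishing mutant resembles the
knockout while the mimetic resembles the wild type, phosphorylation
activates the enzyme ("+"); the mirror pattern gives "−"; anything else is
undetermined.

This package implements every stage as composable, tested functions plus a
single-call pipeline, and ships a seeded synthetic-cohort generator with
planted ground truth so the whole chain is benchmarkable without any
external data.

## Reaction-step distances

The reconstruction is a bipartite metabolite–reaction graph
(`MetabolicNetwork`). Substrates and products of an enzyme's own
reaction(s) are at distance 1; each further reaction adds 1. Traversal is
undirected regardless of the reversibility flag — perturbations propagate
both with and against flux — with a directed mode behind a flag. For
enzymes catalyzing several reactions the distance is the minimum over
those reactions. Currency cofactors (ATP, NAD(H), CoA, ...) are removed
from the graph before traversal by default; otherwise every
ATP-consuming enzyme would be two steps from every other, and "local"
would lose its meaning. The list is configurable.

```{r distances}
net <- loadMetabolicNetwork(
  system.file("extdata", "ecoli_ccm_metabolites.tsv",
              package = "PhosphoScreen"),
  system.file("extdata", "ecoli_ccm_reactions.tsv",
              package = "PhosphoScreen"))
reactionStepDistance(net, "gnd", "r5p")
head(localNetwork(net, "gnd", maxSteps = 3))
```

## Accurate-mass annotation

An ion annotates to every metabolite whose deprotonated mass (neutral
monoisotopic mass minus 1.007276 Da) lies within the tolerance —
isobaric metabolites (glucose/fructose, the pentose phosphates, ...) are
kept as ambiguous sets and resolved only at the counting stage, where the
default policy counts every member of a set ("all"; "once" is available).
Masses are computed from elemental formulas with IUPAC monoisotopic atomic
masses; `neutralMonoisotopicMass("C6H12O6")` gives 180.06339 Da, so the
glucose ion is expected at 179.05611.

## Growth-rate fitting

Rates come from rolling regression on (t, ln OD): all windows of at least
12 consecutive readings (2 h at the standard 10-min sampling) spanning at
least 1 h are scored by R²; among windows within 0.01 of the best R², the
steepest is taken (ties to the earliest). The R² screen rejects windows
that straddle lag or stationary phase or are noise-dominated; the slope
criterion then picks the exponential phase itself. Selecting on R² alone
is a known trap: once the culture starts saturating, ln OD bends smoothly
and a low-noise saturating stretch is *more* linear than the genuinely
exponential but noisier early phase, biasing μ downward by up to ~20% on
logistic curves. On a noiseless exponential every window has R² = 1 and
identical slope, so the fit is exact. Readings at or below the OD floor
(default 0.01, blank-well noise) are dropped before the log transform.
Wells where the wild type grows but no mutant window can be fit are
flagged lethal (relative rate 0) — condition-specific lethality is the
strongest growth phenotype.

## The synthetic cohort generator

`cohortConfig()` + `generateIonTable()` / `generateGrowthCurves()` emulate
the screen's statistical structure; they are first-class, tested code and
every output is a pure function of the configuration seed.

* **Growth**: logistic curves `OD(t) = K·od0·e^{μt}/(K + od0(e^{μt}−1))`
  with additive OD noise (sd 0.005) and optional between-replicate rate
  noise; defaults: wild-type μ 0.65 h⁻¹ (typical E. coli glucose batch
  growth), od0 0.02, carrying capacity 1.2, 10-min sampling for 18 h, six
  replicates — the defaults a microplate screen would produce. Saturation
  is deliberate: it exercises the window-selection logic.
* **Metabolome**: one ion per model metabolite at its exact deprotonated
  mass plus 10% decoy ions ≥ 0.005 Da from any metabolite (exercising the
  no-annotation path); log2 intensities = per-metabolite baseline
  (U(10, 20)) + planted effect + N(0, 0.25). The noise sd 0.25 log2 units
  is a design choice — per-ion replicate variance is not published for
  this kind of data.
* **Planted truth**: a functional site perturbs every non-currency
  metabolite within its locality radius with |log2 FC| = effect size and
  random signs; the knockout carries the same effect vector and the
  knockout-like mutant (abolishing for "+" sites, mimetic for "−" sites)
  carries it scaled by the concordance factor; the other mutant is
  unperturbed. Knockout-like mutants grow at 0.85 of the wild-type rate,
  knockouts at 0.75, everything else at 1.0.
* **Reference pool**: the wild type defaults to six times the mutant
  replicate count. This reflects the screen's design — the reference
  strain is cultivated and measured with every mutant batch — and it
  matters statistically: two fold-change profiles computed against the
  *same* reference replicates share that reference's sampling noise and
  correlate at ρ = (1/n_wt)/(1/n_mut + 1/n_wt) even without any biology
  (0.5 at equal group sizes!). With the 6× pool the induced background is
  ~0.14, comfortably below the 0.4 correlation threshold — matching the
  observed situation in real screens, where the bulk of mutant–knockout
  correlations sits between 0 and 0.3 and the threshold is chosen above
  it.

`syntheticNetwork()` additionally generates a genome-scale-like model
(~420 metabolites in parallel pathway chains with sparse cross-links,
cofactor turnover on every third reaction, formulas drawn over C/H/N/O/P/S
inside the 50–1000 Da window). Benchmarks use it because locality only
means something at that scale: a five-step neighbourhood covers ~3% of a
genome-scale reconstruction but most of a 56-metabolite central-carbon
model. The packaged central-carbon fixture serves worked examples and the
demo pipeline.

What the generator does **not** emulate: raw spectra, isotope envelopes,
chromatography, batch effects, per-sample normalization errors,
heteroscedastic per-ion variances, and real biological covariance between
metabolites. Passing benchmarks therefore demonstrate the statistical
machinery under the stated noise model, not performance on any real
instrument's quirks.

## Numerical and procedural choices

* **Percentile definition** for the fold-change cutoff: linear
  interpolation between closest ranks (R type 7), with nearest-rank
  available; the pooled set {0.00, 0.01, ..., 0.99} gives 0.9405.
* **Welch test on log2 intensities** (variance stabilization for
  log-normal intensities); linear scale behind a flag. Degenerate inputs:
  both groups constant gives p = 1 when means agree and p = 0 when they
  differ. Note that Welch–Satterthwaite is anti-conservative in the far
  tail for very unbalanced designs (measured ~6× nominal at p = 10⁻³ for
  4 vs 24 by simulation); with hundreds of ions per profile this inflates
  per-profile family-wise error under the null, which is why the
  false-call budget is checked at cohort level rather than assumed from
  nominal test levels.
* **BH family**: all annotated, non-excluded ions of one strain ×
  condition profile. Ions with a zero group mean have no defined fold
  change and are excluded from that profile.
* **Spearman p-value**: t-approximation on average ranks; midranks for
  ties. Profile pairs with fewer than 10 shared annotated ions are
  flagged not determined.
* **Sign precedence**: knockout resemblance = correlation pass OR a
  significant growth defect in a condition where the knockout is also
  impaired; wild-type resemblance = something measured, no correlation
  pass, no growth defect. Rules are applied (a) "+", (b) "−", (c)
  undetermined, and are anti-symmetric under swapping the mutant roles. A
  single available mutant decides only when knockout-concordant. Missing
  measurements (n.d.) never act as evidence for or against anything.
* **Global-change flag**: n_changing at least twice the cohort median
  over all phosphomutant profiles, reported but excluded from ranking; on
  an all-null cohort the median is 0 and the flag stays off.

## Benchmarks and problem sizes

Three cohort-level benchmarks ship in the package (also driven by
`scripts/acceptance.R`):

* `benchmarkNullCohort()`: 30 null sites, 4 mutant replicates — the mean
  fraction of significant ions per profile and the false functional-call
  rate; run over 50 seeds.
* `benchmarkRecoveryCohort()`: 10 functional sites (effect 1.5 log2 units
  within 3 reaction steps, concordance 1.0, n = 6, σ = 0.25) + 10 null
  sites — sensitivity, false calls and sign recovery; run over 20 seeds.
  At genome scale the sign travels through the growth arm: even at full
  concordance, Spearman over ~430 ions of which ~25 are planted plateaus
  near 0.26, because rank correlation is insensitive to a small subset of
  extreme ions — growth concordance with the knockout carries the sign,
  as it does in real screens.
* `benchmarkGrowthScreen()`: planted 15% and 5% rate reductions with
  between-replicate rate noise 0.02 h⁻¹, n = 6; flag rates over 100
  seeds. Growth cohorts use 10 h of simulated cultivation; null and
  recovery cohorts use the generator defaults above. These sizes keep the
  full benchmark suite in the low minutes while leaving the Monte-Carlo
  error of each rate well below its decision margin.

## Known limitations

* The evidence OR-rule inherits the per-profile false-positive behaviour
  of the Welch/BH pipeline; on very small networks (where everything is
  "local") it degenerates — interpret local evidence only at realistic
  network scale.
* The sign rule codifies a comparative argument that is narrative in
  practice; contradictory or doubly-defective patterns are deliberately
  left undetermined rather than forced.
* SBML import is not provided; models load from the two documented TSV
  tables.
* No absolute quantification, raw-spectrum processing, flux analysis or
  kinase attribution.
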