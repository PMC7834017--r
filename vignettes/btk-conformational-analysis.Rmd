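---
title: "Mapping inhibitor allostery in full-length BTK: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping inhibitor allostery in full-length BTK: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(btkconf)
library(dplyr)
```

Full-length Bruton's tyrosine kinase (BTK) is a multidomain enzyme whose
regulatory PHTH, proline-rich, SH3 and SH2 regions pack against the kinase
domain in a compact autoinhibited conformation. Active-site inhibitors and
remote resistance mutations can shift this assembly without touching the
regulatory domains directly. `btkconf` implements the analysis chain used
to detect and quantify such long-range effects from two complementary
solution measurements:

* **differential HDX-MS** — peptide-level deuterium uptake differences
  between drug-bound (or mutant) and reference states, classified with
  fixed thresholds and localized to residues via overlapping peptides; and
* **two-state NMR population analysis** — active/inactive conformational
  fractions estimated from the two slow-exchange lines of the W395 indole
  NH reporter, including covalent-inhibitor titrations and the coupling of
  populations to autophosphorylation activity.

Because the package is built to be testable without any instrument data,
it also ships a synthetic-data generator whose ground truth has exactly
the statistical structure the analysis assumes. Every fixture used in the
examples and tests is produced by that generator at run time.

## The generative exchange model

Hydrogen/deuterium exchange at a backbone amide is modelled in the EX2
limit of Linderstrøm–Lang kinetics. Residue $r$ in conformational state
$s$ exchanges with rate $k_{\mathrm{int},r} / P_{s,r}$, where
$P_{s,r} = 10^{\log_{10}\mathrm{PF}_{s,r}}$ is the protection factor. For
an ensemble with mixing fractions $f_s$, the deuterium fraction of residue
$r$ at labeling time $t$ is

$$ d_r(t) \;=\; \sum_s f_s\,\bigl(1 - e^{-k_{\mathrm{int},r}\,t/P_{s,r}}\bigr), $$

and a peptide's relative deuterium level is the sum of $d_r(t)$ over its
exchange-reporting residues, scaled by $(1-\beta)$ for a uniform
back-exchange fraction $\beta$, plus additive Gaussian measurement noise.
Exchange-reporting residues exclude the peptide's first two positions and
all prolines beyond position 2 — the standard HDX-MS bookkeeping
convention (`max_exchangeable()`).

Deliberate simplifications, chosen to keep the ground truth analytic:

* **Intrinsic rates** default to a uniform $k_\mathrm{int} = 1\,$s$^{-1}$
  (configurable per residue). Sequence-dependent intrinsic-rate tables
  would add realism but no information relevant to testing the pipeline,
  which only ever consumes relative differences between states.
* **Mixing is linear**: the uptake of a mixture equals the
  fraction-weighted sum of pure-state uptakes. This is the EX2/fast-
  interconversion assumption on the HDX time scale; it makes planted
  effect sizes exactly computable (and is property-tested to $10^{-9}$ Da
  against a brute-force per-residue oracle).
* **Centroid-level simulation only.** No isotope envelopes and no
  EX1/bimodal spectra are generated, so the generator cannot exercise
  spectral deconvolution — which the analysis never performs.
* **Noise** is additive Gaussian on peptide deuterium, default
  $\sigma = 0.05$ Da, a typical replicate spread for a well-behaved
  peptide on a modern platform; blot band noise is multiplicative
  lognormal (intensities are positive and errors roughly proportional).

Labeling times default to 10, 60, 600, 3600 and 14400 s, a standard
five-point continuous-labeling ladder for this kind of platform. The
exact durations matter only in that the uptake curves must traverse the
dynamic range of the planted protection factors; the baseline
$\log_{10}\mathrm{PF}$ values are drawn once from $U[2.5, 5.5]$ so that
these times probe early, intermediate and near-saturated exchange.

## The packaged scenarios

The simulated protein is a deterministic 659-residue **synthetic**
BTK-like sequence (`synthetic_btk_sequence()`): residue identities are
random draws from globular-protein composition, with the landmark
residues pinned at their canonical positions (T316, W395, C481) and a
proline-enriched stretch across the proline-rich region. The domain map
(`btk_domains()`) uses round boundaries consistent with those anchors —
PHTH 1–170, PRR 171–214, SH3 215–280, SH2 281–380, SH2–kinase linker
381–396, kinase 397–659 — and is plain configuration that can be replaced
for other constructs.

`hdx_drug_panel()` builds the six-state experiment: apo plus five
drug-bound forms sharing one peptide map (~80 peptides of mean length 12,
minimum overlap 3). The conformational structure is a two-state
closed/open ensemble in which the open state loses
$\Delta\log_{10}\mathrm{PF} = 1.2$ across SH3 + SH2 + linker:

| state | open fraction | active-site protection |
|---|---|---|
| apo | 0.28 | — |
| ibrutinib-like | 0.60 | +1.0 on 430–520 |
| dasatinib-like | 0.85 | +0.8 on 430–470, −0.8 on 520–600 |
| GDC-like | 0.28 | +1.2 on 430–550 |
| CGI-like | 0.28 | +1.2 on 430–550 |
| CC-292-like | 0.28 | +0.6 on 430–480 |

The apo open fraction 0.28 matches the active-state population of the
wild-type protein measured by NMR, tying the two halves of the package to
one generative truth. The two regulatory-displacing drugs raise the open
fraction; the three kinase-local drugs leave it untouched and differ only
in their active-site footprint. The dasatinib-like state additionally
deprotects the kinase C-lobe, emulating the activation-loop exposure that
distinguishes that complex. `hdx_t316a_scenario()` uses the same
machinery with open fractions 0.28 (wild type and C481S) and 0.40
(T316A); at the default conditions this yields the characteristic small
0.5–1.0 Da regulatory increases for the mutant and *no* differences for
C481S.

What passing tests on these fixtures shows — and does not show. They
demonstrate that the analysis recovers effects of the assumed form
(two-state mixing, region-wise protection changes, Lorentzian lines,
lognormal band noise) at realistic noise levels. They cannot certify
behaviour under back-exchange gradients, EX1 kinetics, peptide
misassignment, overlapping charge states, or baseline drifts in real
spectra, none of which the generator emulates.

## Differential HDX-MS analysis

`difference_map()` subtracts replicate-mean uptake of the reference state
from the state of interest for every curated peptide and shared time
point. Curation (`curate_coincident()`) requires the exact
`(sequence, start, end)` triple in every table with records at every
shared time; charge states are assumed merged upstream, since charge is a
measurement artifact, not a peptide identity.

Differences are classified by fixed thresholds (`hdx_thresholds()`):
$|\Delta D| > 1.0$ Da is *major*, $0.5 \le |\Delta D| \le 1.0$ Da is
*modest*, below 0.5 Da is treated as no change. Two conventions needed a
decision:

* **Boundary values.** A difference of exactly 0.5 or 1.0 Da is
  *modest* — the band is read inclusively at both ends and *major*
  strictly. Both thresholds are configurable.
* **Time-course reduction.** A peptide's single category is taken at its
  strongest-$|\Delta D|$ time point: the strongest observed change is
  what structural color maps report. The full per-time classification is
  retained in the difference table for users who prefer per-exposure
  maps.

No significance testing or multiple-testing correction is applied: the
classification is purely descriptive, by design, and a hybrid
significance-test hook would be the natural extension point.

Residue-level localization (`consolidate_residues()`) uses the
overlapping-peptide rule: each covered residue inherits the category of
the *shortest* covering peptide, with ties broken by larger
$|\Delta D|$ and then lower start. Shorter peptides carry sharper
positional information, which is the entire value of overlapping
coverage; the deterministic tie-break makes the output reproducible.
The localization is only as sharp as the peptide map — an annotated
region can exceed the true perturbed segment by up to the length of the
shortest covering peptides, which is why the planted-region tests assert
confinement to the peptide-overlap *envelope* rather than to the exact
region.

`classify_inhibitor_response()` reduces the per-domain summary to the
two-category call: a drug is *regulatory-displacing* when at least 5
residues across SH3/SH2/linker carry an increase category, and
*kinase-local* when kinase-domain changes exist without that regulatory
signal. The threshold of 5 residues demands more than an isolated
single-residue artifact but is far below the ~180 regulatory residues a
genuine displacement annotates at default noise; classification outcomes
are insensitive to this choice over a wide range.

```{r panel, eval = FALSE}
panel <- hdx_drug_panel(seed = 1)
map <- attr(panel, "peptide_map")
peps <- curate_coincident(split(panel, panel$state))
dm <- difference_map(panel, "ibrutinib_like", "apo", peptides = peps)
plot_difference_map(dm)
ann <- consolidate_residues(dm, map)
classify_inhibitor_response(domain_summary(ann))
```

## Two-state NMR populations

The W395 indole NH resonance reports the kinase-domain conformation: the
downfield line corresponds to the active (αC-in) state, the ~0.2 ppm
upfield-shifted line to the inactive (αC-out) state, and slow exchange
between them makes the two integrals population-proportional.
`fit_two_peaks()` fits two Lorentzians plus a flat baseline by
Levenberg–Marquardt least squares; `estimate_populations()` converts the
closed-form areas ($\pi A w/2$) into fractions.

Numerical choices:

* **Areas, not heights.** Peak heights misreport populations whenever
  the two linewidths differ; integrals match the physical
  interpretation of slow-exchange intensities.
* **Lorentzian lineshape** is the slow-exchange limit for well-resolved
  solution lines; the flat baseline suffices because traces are short
  windows around the reporter.
* **Initialization** takes the two highest distinct local maxima of a
  lightly smoothed copy of the trace (running mean, ~0.5% of the window),
  which suppresses noise spikes on peak shoulders; explicit
  `init_centers` override this.
* **Linewidth floor.** Fitted widths are bounded below by two grid
  spacings so that a single noise spike cannot masquerade as a peak.
* **Degenerate traces.** When the two centers collapse onto one line the
  fit is redone as a single Lorentzian and a zero-area phantom partner is
  reported on the far side of the window, with a warning: a single-line
  trace cannot identify *which* state vanished without external
  information.

That last ambiguity matters in titrations, where the saturated endpoint
is single-line by construction. `analyze_titration()` therefore works in
two passes: unconstrained fits locate the two line positions across the
whole series, then every trace is refitted with those consensus centers
anchored (each within a quarter of the splitting), so a vanished line
keeps its label at its known position. For an irreversible one-site
covalent binder the bound fraction is `min(ratio, 1)`
(`stoichiometric_bound_fraction()`), and the recovered inactive fraction
tracks $f_0 + \min(r,1)(1-f_0)$.

```{r nmr, eval = FALSE}
trace <- nmr_state_fixture("wt_fl", seed = 7)
fit <- fit_two_peaks(trace)
autoplot(fit)
estimate_populations(fit)
```

The round-trip tests simulate traces at inactive fractions 0.28, 0.40,
0.60 and 0.72 with 1% noise and require recovery within ±0.02 absolute;
the acceptance checks require the packaged wild-type and T316A fixtures
to return their generating percentages within ±2 points.

## Coupling populations to activity

`normalize_blot()` divides each pY551 (activation-loop
autophosphorylation) band by its anti-His loading control and rescales so
the reference lane is exactly 1, making the result invariant to common
rescaling of either channel. `predict_activity_fold()` applies the
simplest coupling model — activity strictly proportional to the
active-state fraction, zero basal offset — and
`activity_consistency()` reports the prediction *next to* the measured
fold change rather than reconciling them: a measured fold exceeding the
population fold (e.g. 2.0 observed vs 0.40/0.28 ≈ 1.43 predicted for a
T316A-like shift) is evidence of coupling beyond the linear two-state
model (cooperative activation, substrate-level effects), and the package
deliberately does not absorb it. Whether residual activity persists as
$f_\mathrm{active} \to 0$ is not resolvable from these data; the zero
intercept is a modelling choice, not a finding.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale: a 659-residue protein, ~80 peptides × 5 times × 3
replicates × 6 states per panel replicate, 601-point NMR traces, 100
seeded replicates for the classification and localization properties and
100 random small instances for the simulator-vs-oracle bound. Every
random draw flows through an explicit integer seed, and fixed seeds
reproduce byte-identical tables and traces.

## Known limitations

* Relative deuterium only; no back-exchange correction, so absolute
  protection factors are not recoverable from the outputs.
* Residue localization inherits the peptide map's resolution; isolated
  single-residue changes inside long peptides are invisible.
* The two-peak NMR model handles exactly two states; broadened or
  undetectable reporter lines (as with some inhibitors) only surface as
  degenerate-fit warnings, not as quantitative estimates.
* Threshold classification is descriptive: no replicate-variance test,
  no global significance limit, no multiple-testing control.
* The inhibitor-response call depends on the domain map; constructs with
  different boundaries need their own `DomainMap` configuration.
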