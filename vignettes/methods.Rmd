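---
title: "Methods: from peak table to key aroma compounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from peak table to key aroma compounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aromakey)
```

This vignette is the package's own account of the statistical procedure it
implements, the assumptions behind each stage, the parameters a user may
reasonably want to move, and the design decisions that were genuinely open.

## The analytical chain

A multi-group GC-O-MS aroma study produces five tables: a per-sample peak
table, an n-alkane ladder, a compound library with odor thresholds, a GC-O
event log and a QDA sensory sheet. The pipeline composes eight stages:

1. retention-index identification,
2. internal-standard semi-quantitation,
3. rOAV screening,
4. GC-O consensus,
5. key-compound intersection,
6. hierarchical clustering of the full compound matrix,
7. PCA / OPLS-DA with VIP, permutation validation and CV-ANOVA on the key
   compounds,
8. PLSR against sensory attributes with jack-knife coefficient tests, and
   one-way ANOVA with Fisher-LSD letters per key compound.

## Retention indices

The GC program assumed here is temperature-ramped, so the linear
van den Dool–Kratz form is used rather than the isothermal logarithmic
Kovats form: between bracketing alkanes with carbon numbers $n$ and $n{+}1$,

$$RI(rt) = 100\left[n + \frac{rt - rt_n}{rt_{n+1} - rt_n}\right],$$

generalized to non-consecutive carbon numbers by interpolating over the
actual carbon span. Retention times outside the ladder are extrapolated on
the nearest segment's slope and flagged; extrapolated indices are served
with a warning because the linearity assumption weakens off the ladder.
Library matching accepts candidates within `ri_match_tolerance` (default
15 RI units, a common one-column matching window) ranked by $|\Delta RI|$
with lexicographic name order as a deterministic tie-break.

## Quantitation and rOAV

Semi-quantitation assumes a response factor of 1 against the internal
standard:

$$C_x = \frac{A_x \cdot C_s \cdot V_s}{A_s \cdot m_x} \quad [\mu g/g],$$

with the spike defaulting to 5 µL of 180 µg/mL sec-octanol in 3 g of
sample. This is a *relative* quantitation — adequate for screening and
multivariate contrasts, not for absolute concentrations (see Limitations).

rOAV divides the concentration by the compound's odor threshold in water.
The formula yields µg/g while thresholds are conventionally µg/kg, so
concentrations are multiplied by 1000 at rOAV time and in class totals;
the pipeline stores µg/g internally and converts only at reporting
boundaries. $C_i$ is the replicate-mean concentration within a sample
group, giving one rOAV per compound per sample. A missing threshold makes
rOAV *undefined* (never zero): such compounds are excluded from the rOAV
screen but can still enter the analysis through GC-O — collapsing them to
zero would silently delete exactly the compounds the sniff port exists to
rescue.

## The screen

A compound passes the rOAV screen in a sample when rOAV ≥ 1; the threshold
is inclusive by default (`roav_strict = TRUE` switches to a strict `>`,
since both conventions circulate in the literature). GC-O consensus
requires `gco_min_panelists` distinct panelists (default 2 of a 3-person
panel) to report the compound in at least one replicate session; detection
in any replicate counts, because sniffing panels conventionally record a
compound once a quorum of raters has ever confirmed it. The phrase
"more than two raters" in panel protocols is ambiguous for a 3-person
panel — read strictly it means all three — so the quorum is a visible
config parameter rather than a constant. The key-compound set is

$$\text{key} = \Big(\bigcap_{\text{samples}} \text{rOAV pass}\Big) \cap \text{GC-O consensus},$$

the strict all-samples reading: a key compound must be aroma-active
everywhere and human-confirmed somewhere. The exclusive Venn regions are
reported because they carry meaning of their own (potent but sub-threshold
odors; aroma-active compounds with poor sniff-port behavior).

## Chemometrics

All latent-variable models run on autoscaled data (mean-centered,
unit-variance) by default — the de-facto standard in metabolomics
software — with Pareto and center-only scaling available. Constant columns
get scale 1 and a flag instead of NaN.

PCA and PLS use NIPALS iteration (convergence at a squared relative score
change of 1e-24, i.e. ~1e-12 relative precision, tight enough that the test
suite can compare against SVD and eigendecomposition oracles at 1e-8).
Component signs are fixed so the largest-magnitude loading is positive,
removing the usual sign indeterminacy from outputs and tests.

OPLS-DA encodes the two classes (by default the wild-type sample versus the
mutant-fermented rest) as a centered 0/1 indicator, strips orthogonal
components by the Trygg–Wold filter, then fits exactly one predictive
component. `n_orth_components = "auto"` adds orthogonal components greedily
while cross-validated Q² improves, capped at 3 — beyond that, with a dozen
observations, additional components model noise. Each orthogonal score is
orthogonal to the class vector by construction (checked to 1e-8 in the
tests).

Cross-validation uses venetian blinds — observation $i$ in fold
$((i-1) \bmod k) + 1$, default `cv_folds = 7` — which is deterministic in
the row order and interleaves replicate structure across folds. Within
every fold both blocks are re-centered on the training split; Q² is
$1 - \mathrm{PRESS}/SS$. VIP is computed over the predictive component(s)
only, the common convention for OPLS (total-model VIP would dilute the
class-relevant signal with orthogonal variation); its normalization
$\sum_j VIP_j^2 = p$ is asserted for every fitted model.

The permutation test refits the model under `n_permutations` (default 200)
uniform label permutations, reporting $p = (1 + \#\{Q^2_{perm} \ge
Q^2_{obs}\})/(n+1)$ and the regression intercepts of permuted R²Y and Q² on
the |correlation| between permuted and original labels — the standard
validation-plot summary. CV-ANOVA compares mean squared cross-validated
residuals of the mean-only null against the model,
$F = (\mathrm{PRESS}_0/df_1)/(\mathrm{PRESS}/df_2)$ with $df_1 = N-1$ and
$df_2 = N-1-A$ ($A$ = fitted components including orthogonal ones), with
$p$ from the F distribution. This PRESS-ratio construction makes the
null-vs-null case land at $F \approx 1$ and is fully reproducible from the
CV residuals.

PLSR uses two factors (the biplot convention) of a PLS2 model; correlation
loadings are plain Pearson correlations of each original column with the
factor scores, plotted against circles at $\sqrt{0.5}$ and 1 (50 % and
100 % explained variance). Jack-knife uncertainty follows Martens:
$u_j = \sqrt{\sum_i \frac{n-1}{n}(b_{(-i)j} - b_j)^2}$, significance when
$|b_j| > u_j \, t_{1-\alpha/2, n-1}$.

## Univariate statistics

Fisher-LSD runs unprotected by default (every pair tested on the pooled
one-way-ANOVA error) with `protected = TRUE` gating the pairwise tests on a
significant omnibus F — the protected form mirrors the classical
ANOVA-then-LSD qPCR workflow, while the unprotected form matches how LSD
letters are usually attached to compound bar charts. Letters come from an
insert-and-absorb construction whose defining invariant — two groups share
a letter **iff** they are not significantly different — is audited
exhaustively in the tests. No multiplicity correction is applied beyond
LSD itself, deliberately matching field practice for these displays.

Hierarchical clustering uses Euclidean distance and average linkage on
per-compound (row) unit-variance scaled data — the common defaults of
heatmap tools — and both the sample and compound dendrograms are cut flat
(samples at $k=2$). Dendrograms export as Newick text.

## The synthetic generator

`generate_dataset()` emulates the study design the pipeline targets:

* 4 groups × 3 replicates, 99 compounds distributed over pyrazines (13),
  ketones (19), acids (6), alcohols (22), aldehydes (16), phenols (3) and
  assorted esters/furans/oxazoles/sulfides;
* base abundances log-normal per compound (median 0.05 µg/g, one log-unit
  spread), inter-replicate CV 15 % — a typical HS-SPME repeatability figure,
  and a modeling choice, since true replicate CVs are not knowable from a
  published summary;
* planted group effects mirroring the fermentation biology being emulated:
  pyrazines, guaiacol and 2,4,5-trimethyloxazole elevated in the
  mutant-fermented groups (strongest in the double-mutant group 4, roughly
  1.4–2.6×), 1-octen-3-ol and 3-hydroxy-2-butanone depressed (~0.6×) only
  there, ketones mildly elevated in groups 2–3 and acids in group 4;
* odor thresholds constructed from the planted concentrations so that the
  intended 12-compound key set passes rOAV ≥ 1 in every group with a
  log-uniform margin of 3–60×, background compounds stay below 0.3, three
  "rOAV-only" compounds pass everywhere but are practically undetectable at
  the sniff port, and a 15/15/16/18 per-group pass pattern emerges from two
  group-4-only and one group-3/4 partial compounds; the resulting rOAV
  values span roughly 10⁻³–10³;
* ~7 % of compounds carry no threshold, exercising the undefined-rOAV path;
* GC-O detections drawn per panelist × replicate with probability logistic
  in log10(rOAV) (midpoint −0.5, scale 0.3), so the rOAV and GC-O screens
  correlate without coinciding and the Venn regions are non-trivial;
  five sub-threshold compounds get a fixed high sniff-port detectability
  (odor release and matrix effects decouple sniffing from matrix rOAV);
* sensory scores: six latent attribute values per sample, linear in the
  log-abundances of their driving odor groups (roasted ← pyrazines,
  smoky ← guaiacol, buttery ← diacetyl+acetoin, …), plus panelist noise
  (sd 0.35), rounded half-up and clamped to 1–5. Rounding ties are fixed by
  the rule, not the random stream.

Peak areas are back-computed by inverting the quantitation formula, so with
zero noise the quantitation path is the exact inverse of generation — the
suite asserts this to 1e-9. All randomness flows from a single seed;
identical seeds give identical bundles.

`study_fixture()` is the same machinery at reduced noise (CV 5 %) with a
fixed internal seed and background sniff-port detections switched off, so
the screening arithmetic is pinned by construction: pass counts
15/15/16/18, intersection 15, GC-O set 17, key set 12.

What the generator does **not** emulate: co-elution and peak-picking
artifacts, mass-spectral ambiguity, response-factor variation between
chemical classes, panelist-specific sniffing sensitivity, session drift,
and correlated (compositional) concentration noise. Tests passing on this
generator therefore demonstrate the *statistical machinery* recovers
planted structure under idealized chromatography — not that any real
study's compound list is correct.

## Problem sizes and numerical choices

The test suite runs the full pipeline on 20 simulated studies (99
compounds, 12 observations each), 100-matrix oracle sweeps for the NIPALS
core, a 200-replicate calibration of the permutation p-value at 50
permutations per replicate, and 50 random Fisher-LSD designs — sizes chosen
to keep the default suite under a minute while leaving the statistical
assertions well-powered. Degenerate inputs are handled explicitly: constant
columns (flagged, scale 1), CV folds whose training split loses a class
(warned, zero-model prediction), zero model residuals in CV-ANOVA
(F = ∞, flagged), rank-deficient residual matrices in PCA (zero component,
flagged), and all-identical ANOVA groups (hard error, since the pooled MSE
is undefined).

## Limitations

Semi-quantitation with a unit response factor biases concentrations by
compound class; rOAV inherits that bias plus the literature variability of
odor thresholds, so rOAV magnitudes are indicative, not metrological.
OPLS-DA here is strictly two-class with a single predictive component; the
implementation aims for methodological fidelity, not numerical
bit-equality with commercial chemometrics suites. The compact-letter
construction guarantees its invariant but not minimality of the letter
count in pathological significance patterns. The GC-O consensus model
ignores intensity when deciding detection (intensity is reported, not
thresholded), and descriptor-based odor grouping is keyword-driven —
deterministic, but only as good as the descriptor vocabulary.
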