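---
title: "Methods: a tested pipeline for constitutive-UPR transcriptome and growth analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a tested pipeline for constitutive-UPR transcriptome and growth analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uprflow)
```

# Scope and study design

`uprflow` implements the analysis chain of a constitutive-UPR microarray
experiment: a strain expressing permanently active HacA (the fungal UPR
transcription factor) is compared with its wild type, with the mutant
sampled at three timepoints of a glucose batch culture. The default design
is therefore four conditions — `WT`, `CA1`, `CA2`, `CA3` — in independent
biological triplicates, 12 arrays in all, and the three contrasts of
interest are CA1−WT, CA2−WT and CA3−WT.

Because the original array platform is proprietary, the package ships a
synthetic-data generator for every input instead of raw data. The
generators are first-class, tested code: their planted truth is what every
downstream validation measures recovery against.

# Probe summarization

Probe intensities are modelled and processed on the log2 scale.

**Background correction** (off by default) uses the normal+exponential
convolution: observed X = S + B with S ~ Exp(α), B ~ N(µ_bg, σ²). The
corrected value is E[S | X = x] = a + σφ(a/σ)/Φ(a/σ) with
a = x − µ_bg − σ²/α, evaluated through log-scale Mills ratios so it stays
stable and strictly positive far below the background mean. When parameters
are not supplied they are estimated per array by method of moments around
the intensity histogram's mode. The synthetic generator adds no background
by default, which is why correction is opt-in.

**Quantile normalization** forces every array to the reference distribution
defined as the across-array mean of sorted columns. Ties receive the mean
of the reference values spanned by their ranks. Two consequences are worth
stating because they are occasionally assumed away: the transform is
idempotent on tie-free data, and rescaling *one* array does shift the other
arrays' values — through the shared mean reference only, by an identical
rank-wise amount. The per-column rank order is always preserved, and
rescaling all arrays by a common factor shifts all log2 expression by a
constant.

**Median polish** fits log2 x_pa ≈ overall + probe_p + array_a per probeset
by Tukey's alternating row/column median sweeps (rows first), stopping when
the total absolute residual changes by less than `tol` (default 0.01, at
most `max_iter = 10` sweeps — the defaults of the standard summarization
method). The reported expression is overall + array effect. The test suite
holds this to an independent iterative reference implementation at 1e-9.

**Replicate CV.** Reproducibility is summarized as the per-gene coefficient
of variation of anti-logged (2^x) replicate values, averaged over genes.
The probe-level noise default of the generator (`noise_sd_log2 = 0.6`) was
fixed once by Monte-Carlo calibration so that summarized triplicates show a
mean CV near 0.13 — the reproducibility level typical of the emulated
platform (0.12–0.14). Median aggregation over the default 11 probes per
probeset shrinks probe noise by roughly 1.253/√11, which is why the
probe-level value is much larger than the array-level scatter it produces.

# Moderated-t differential expression

The four conditions are fitted jointly as a one-way layout: per gene,
condition means and a pooled residual variance s²_g with
d = 12 − 4 = 8 degrees of freedom. This is equivalent, for this design, to
the linear-model-plus-contrasts formulation of the standard empirical-Bayes
machinery.

The variance prior (d₀, s₀²) is fitted by method of moments on
z = ln s²_g: var(z) = trigamma(d/2) + trigamma(d₀/2) and
E z = ln s₀² + digamma(d/2) − digamma(d₀/2) + ln(d₀/d). The trigamma
equation is inverted by Newton iteration (tolerance 1e-8, positivity-
preserving fallback); d₀ is reported as infinite when var(z) does not
exceed trigamma(d/2), and capped at 1e7 where a finite value is needed.
Two degenerate conventions: genes with exactly zero variance enter through
a floor of 1e-8 (log2 scale)² so ln s² stays finite; and when the observed
variances are all equal the prior scale is taken to be that common variance
itself rather than the bias-corrected exp(mean z − digamma(d/2) + ln(d/2))
— the corrected form is the right d₀ → ∞ limit under sampling noise, but
with literally zero dispersion the common value is the only defensible
estimate.

Posterior variances s̃² = (d₀s₀² + d s²_g)/(d₀ + d) always lie between s²_g
and s₀²; t̃ is referred to d₀ + d degrees of freedom (standard normal when
infinite). Genes with zero posterior variance are flagged degenerate and
excluded from all gene sets rather than assigned p = 0. Benjamini–Hochberg
adjustment is the standard step-up; classification uses a strict
q < 0.005 cut, sign taken from the log2 fold change, and deliberately *no*
minimal fold-change filter. Linear fold changes are reported with the
signed convention (−2^|lfc| for down-regulation) so magnitudes are never
below 1.

# Gene sets, promoter motifs, GO terms

**Sets.** Venn partitioning supports 2–3 sets (the shapes actually drawn
for timepoint comparisons); the 2^k − 1 regions are disjoint and tile the
union by construction, and the consistency sets (`up_all`, `down_all`) are
the genes classified the same way in every contrast.

**UPRE scanning.** The degenerate consensus 5'-CAN(G/A)NTGT/GCCT-3' is
normalized to the 11-mer IUPAC word `CANRNTGKCCT`, reading single-position
alternations in 5'→3' order ((G/A)→R, T/G→K). Promoters are the 400 bp
immediately upstream of the annotated coding start (windows truncated at
contig edges are flagged partial); minus-strand genes yield the reverse
complement so sequences always read toward the start codon. Both strands
are scanned by default — UPR elements are palindromic in origin and the
convention is exposed as a parameter (`strands`). An `N` in a promoter
matches no motif position (conservative). Enrichment contrasts the study
set against all remaining genes with retrievable promoters via the
hypergeometric upper tail P(X ≥ a); the scanner and the test are both held
to brute-force oracles (every offset × strand; exhaustive enumeration of
all tables with fixed margins).

**GO.** Annotations are propagated to all ancestors (true-path rule; `is_a`
and `part_of` edges are not distinguished). The tested universe is the set
of terms carrying at least one study gene — untestable terms are excluded
before FDR adjustment — and the population is the annotated genes only.
Both are documented, configurable conventions rather than claims about any
particular legacy tool. The enriched-term network is the transitive
reduction of the ancestor relation restricted to enriched terms.

The GO generator plants its enriched term as the *last* (leaf) term by
default: planting a term near the root is legal but propagation floods
root-adjacent terms with every gene's annotations, so an interior planted
term dilutes toward study_count = population_count and cannot dominate the
ranking. This is a property of the true-path rule, not of the generator.

# Growth kinetics

µ is the OLS slope of ln(signal) versus time. Two signals are supported:

* **biomass** — used directly;
* **cumulative alkali** — titrant added for pH control tracks biomass
  *formed*, A(t) ≈ c·(X(t) − x₀), so ln A is not linear in time. After
  removing any pre-detection baseline (observations below 3× the median of
  the earliest readings), the inoculum offset A₀ ≈ c·x₀ is estimated by
  minimizing the residual sum of squares of ln(A + A₀) ~ t. The SSE
  profile in A₀ can be multimodal, so a 200-point log-spaced grid precedes
  the local golden-section refinement. On noiseless proportional data this
  restores exact linearity, and the alkali-based µ equals the biomass-based
  µ to optimizer precision — the property that justifies using alkali as a
  growth proxy at all.

The exponential→linear shift is found by grid search over interior
observation times: exponential fit (log-scale OLS) before the candidate
break, a least-squares straight line *through the breakpoint value* after
it — the fit is continuous by construction — and total SSE evaluated on the
original scale. The two-phase model is only preferred when it reduces SSE
by more than 10% with at least 4 observations in each phase; this margin
guards against fitting a spurious break to noise, at the cost of missing
breaks very close to either end of the series. Yield on substrate is the
endpoint ratio Y_xs = ΔX/(−ΔS) over the exponential window, with endpoints
linearly interpolated and a culture density of 1 kg/L assumed so that g/kg
and g/L units cancel.

# Synthetic-data generators: what they emulate, and what they do not

* **Probe data** follow the additive log2 model the summarization assumes:
  intensity = 2^(θ_gc + φ_p + ε) with probe affinities zero-centred per
  probeset and i.i.d. Gaussian log-scale noise; an optional additive
  raw-scale background exercises the correction step. Planted effects are
  a fixed log2 offset (default 2), random sign, applied to all three CA
  conditions — emulating the observed pattern that constitutive-UPR
  responses largely persist across timepoints. Not emulated: probe-sequence
  affinity structure, spatial artifacts, intensity-dependent variance, or
  cross-hybridization; calibration passing on these data shows the
  statistics are implemented correctly, not that they are robust to every
  physical artifact of real arrays.
* **Promoters** are i.i.d. bases at a set GC content with one exact motif
  instance (drawn uniformly from the consensus expansion) written at a
  uniform position of each planted gene. Background hits still occur at the
  composition rate and are deliberately left in the truth's blind spot — an
  enrichment test must tolerate them. No fungal promoter grammar (TATA
  context, nucleosome exclusion, CpG structure) is modelled.
* **GO universes** are layered rooted DAGs (each later term picks 1–2
  earlier parents) with uniform direct annotations; the planted term is
  added to study genes with probability min(1, boost·p₀). Term-size
  distributions are therefore much more homogeneous than in the real
  ontology.
* **Cultures** follow x₀e^(µt) switching to a continuous linear segment at
  t_break, glucose by mass balance S = s₀ − (X − x₀)/Y_xs floored at 0, and
  alkali proportional to biomass formed. Noise is multiplicative lognormal
  (mean 1) so concentrations stay positive; cumulative alkali is kept
  non-decreasing. Defaults (µ = 0.22 h⁻¹, t_break = 21 h, Y_xs = 0.53,
  s₀ = 11.6 g/L, x₀ = 0.03 g/kg, 3% CV, hourly sampling from 2–30 h) are
  chosen so the synthetic cultures match the kinetic regime of the emulated
  experiment: roughly half the glucose consumed at the shift, ~3 g/kg
  biomass at the break.

Determinism: every generator is a pure function of its arguments and a
single integer seed; the pipeline driver derives per-stage seeds from one
root seed with an affine hash modulo 2³¹ − 1, so stages can be re-run
individually with identical results and two runs with the same inputs and
seed produce byte-identical manifests.

# Numerical and design choices

* Median of an even number of values is the mean of the central pair
  (everywhere medians appear).
* Quantile-normalization ties: mean of the reference values across the
  rank span. Other implementations interpolate at fractional ranks instead;
  the two agree except at ties spanning three or more values.
* Trigamma inversion: Newton with analytic derivative, halving fallback on
  negative iterates, tolerance 1e-8.
* Fisher tests use the log-stable hypergeometric survival function; odds
  ratios are the plain cross-product, reported as infinite on zero
  denominators rather than continuity-corrected.
* Breakpoint grid: candidate breaks are observation times (resolution =
  sampling interval); the SSE at the reported break is asserted to be the
  grid minimum.
* Degenerate genes (zero posterior variance) are excluded from gene sets;
  empty study sets, unknown GO terms, cyclic graphs, non-positive
  intensities and malformed designs all fail fast with typed conditions
  (`uprflow_invalid`, `uprflow_degenerate`, `uprflow_insufficient_data`).

# Validation strategy and problem sizes

The test suite checks each operation against an oracle that shares no code
with it: brute-force offset×strand scanning, exhaustive hypergeometric
enumeration (all 2×2 tables up to total 60), an independent median-polish
implementation, the literal BH step-up definition, numerical quadrature for
the background model, reachability closure by repeated edge expansion, and
pairs bootstrap for regression standard errors. Cross-checks against
independently maintained implementations of quantile normalization and
variance shrinkage run when those packages are installed, as corroboration
— never as the implementation.

Statistical validations run at deliberately moderate sizes chosen to keep
the full suite under a couple of minutes while leaving comfortable
statistical margins: null calibration uses 400-gene universes over 5 seeds
(KS uniformity at α = 0.01, ≥4/5 required); planted-effect recovery uses
1000 genes × 10 seeds (≥95% recall, realized FDR within 3 binomial
standard errors of the 0.005 target); prior recovery uses 20 000 genes;
breakpoint recovery uses 20 noisy cultures (±2 h in ≥90%).

# Known limitations

* Only perfect-match, single-probeset-per-probe designs are handled; no
  CEL parsing, mismatch probes, or detection calls.
* The DE model is the one-way layout with a single pooled variance — no
  arbitrary design matrices, array weights, or intensity-dependent priors.
* Venn partitioning is limited to three sets by design.
* The motif scanner is exact-consensus only (no PWM scores); a consensus
  that is too stringent will under-count true binding sites, which is a
  property of the consensus, not the scanner.
* GO results depend on the annotation's completeness; the package's
  conventions (tested-universe, annotated-population) are one defensible
  choice among several and are parameterized where they matter.
* The piecewise growth model fits one break at most; diauxic or multi-phase
  kinetics would need an extended grid.
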