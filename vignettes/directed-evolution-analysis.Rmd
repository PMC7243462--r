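---
title: "Models and methods: enrichment statistics, target size and additivity for transporter selections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: enrichment statistics, target size and additivity for transporter selections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abcselect)
```

This vignette is the package's account of its models: what each component
assumes, which parameters matter and why their defaults are what they are,
what the synthetic data emulates (and does not), and the numerical choices
behind the statistics.

## The experimental design being modeled

A weakly active transporter is mutagenized by error-prone PCR over one
contiguous transmembrane region of about 160 codons. Each library clone
carries a random number of nucleotide substitutions. Cells expressing the
clones carry a two-color readout: an autocrine reporter of export activity
(the cell responds to the pheromone it itself exports) and a fluorescent
tag on the transporter reporting expression. Libraries pass through
iterative FACS: cells clearing thresholds on both channels are sorted out,
expanded without selection, and re-sorted — four rounds in the canonical
protocol. Selected colonies are Sanger sequenced, and clone phenotypes are
measured as medians of ~30,000 cytometry events, normalized between an
empty-plasmid anchor (0) and a strong-exporter anchor (1).

## Library simulation

`simulate_eppcr_clone()` draws the substitution count from
Poisson(`mean_mutations_per_clone`), places substitutions uniformly without
replacement over nucleotide positions, and draws alternate bases from the
model's substitution weights. Defaults and rationale:

* **Mutation load.** The per-clone mean is a free parameter because the
  mutagenesis level is experimentally tunable (via Mn²⁺ concentration) and
  only coarse per-level estimates exist; 4.5 substitutions per ~480 nt is
  used throughout the tests as a realistic mid-level library. The mapping
  from mutagenesis condition to mean is deliberately user-supplied.
* **Substitution spectrum.** Uniform over the three alternate bases by
  default. Taq/Mn²⁺ mutagenesis has a transition bias, but no spectrum was
  available to calibrate against; a 4×4 weight matrix is accepted where a
  measured spectrum exists. The enrichment statistics downstream are
  spectrum-agnostic (they see only amino-acid changes), so this choice
  affects realism, not correctness, of the test bed.
* **Indels** are not simulated: Sanger analysis of substitution libraries
  treats length changes as suspect clones. `frameshift_suspected` exists
  only for real-data ingestion (length mismatch against the reference).
* **Reproducibility.** Per-clone seeds are a deterministic function of the
  master seed and clone index (kept below 2³¹), so libraries are
  reproducible and a one-clone library equals the single-clone simulator.

`plant_effects()` builds the ground-truth genotype–phenotype map: a chosen
number of "specificity" positions each receive one or two favorable mutant
amino acids with positive effects drawn from a gamma distribution
(mean 0.12, shape 4 — right-skewed, strictly positive, matching the scale
of observed strong single-mutation effects on the normalized signal, which
sit around 0.1–0.3). Favorable amino acids are drawn from the
non-synonymous single-base neighbours of the wild-type codon, so planted
effects are reachable by the mutagenesis process. All other substitutions
default to effect 0 (an optional small deleterious background is
available): the additive model is then exactly true by construction, which
is what makes the additivity tests sharp.

`genotype_signal()` is the additive phenotype: baseline + Σ effects +
Gaussian noise. Nonsense or frameshift clones get the empty-plasmid level
(0) regardless of effects — truncation ablates both transport and
expression. Signals are **not** clamped to [0, 1] by default; the anchors
are conventions (a mutant can out-export the positive control), and
clamping would silently break additivity, so it is opt-in.
`genotype_expression()` decays as (1 − penalty)ⁿ with n substitutions
(default penalty 0.05), reproducing the observation that median library
expression falls as mutation load rises.

`simulate_cytometry()` draws per-event fluorescence log-normally with the
median pinned to the latent raw value (meanlog = log(latent raw)), so the
population median — the statistic used for real samples — is an unbiased
estimate of the latent signal. The default per-event CV of 0.3 gives
population clouds of realistic width; `cv = 0` is the degenerate limit in
which every event equals the mean. Channels are independent per event:
observed autocrine–expression dependence is weak, so correlation enters
only through the clone's latent means.

### What the synthetic data does not emulate

No sequencing error or chromatogram noise; no PCR jackpots or lineage
structure (clones are iid); no growth-rate differences or pheromone-induced
arrest during expansion; no fluorescence spillover between channels; no
paracrine cross-stimulation (the blocking agent is modeled as perfect).
Passing tests therefore show that the statistics behave correctly under the
idealized generative model, not that they are robust to these artifacts in
real data.

## Mutation calling and spectra

`call_substitutions()` compares codon-by-codon, ignores synonymous changes,
reports positions in full-protein coordinates (1-based, inclusive — the
region "residues 199–359" convention), flags premature stops as nonsense,
and refuses non-ACGT input by record name. Clone identity for
`dedupe_clones()` is the *nucleotide* difference set: two clones reaching
the same amino acid through different codons are genuinely distinct library
members and Sanger data resolves them; an amino-acid mode is provided for
analyses keyed on protein genotype.

`per_position_counts()` tallies clones (at most one count per clone per
position), not raw events, by default — the spectrum then answers "how many
independent selected clones mutated this residue", which is the quantity
the Poisson null models; an event tally is available. Clones carrying a
nonsense change are excluded by default since truncated transporters cannot
have been selected for function.

`column_mean_pairwise_identity()` computes, per reference column of a
protein alignment, the fraction of identical unordered pairs among non-gap
rows. Gaps are non-participating rather than mismatches, matching the
reference-column filtering convention used to build such alignments;
columns with fewer than two non-gap residues are undefined (`NA`).

## Enrichment statistics

The null is Poisson with λ = total mutations / region length
(`fit_null()`). Two deliberate choices:

* **Chi-square pooling.** `chi_square_gof()` defaults to `pooling = "none"`
  over bins 0..max(observed) plus a closing tail bin. Unpooled, a single
  position observed at a count whose expectation is ~10⁻⁶ contributes an
  enormous term — that is the regime in which published statistics of order
  10⁷ arise, and the default reproduces that behavior. For calibrated
  inference the `min_expected` pooling (merge left-to-right until each bin's
  expectation reaches 5) gives a test whose type-I error at α = 0.05 sits
  in [0.03, 0.07] across 1,000 null replicates (verified in the acceptance
  suite). Degrees of freedom are bins − 2 (total and estimated mean);
  since the mean is estimated from ungrouped data the statistic lies
  between χ²(bins−2) and χ²(bins−1) in theory, but with the default
  binning nearly all information is retained and the bins−2 reference is
  empirically calibrated.
* **The fold rule.** The 10-fold enrichment rule is implemented on tail
  counts by default: m\* is the smallest m ≥ 1 with
  #{p : c_p ≥ m} ≥ fold · L · P(X ≥ m). A tail rule yields a well-defined
  "≥ m\*" threshold of exactly the published form ("≥6", "≥5"); a
  pointwise (exact-count) variant is provided since the printed rule does
  not disambiguate the two. Under the null the expected number of false
  enriched positions per region is below 0.1 at fold = 10 (simulated), and
  planted hotspots at ≥10× the null tail are recovered with sensitivity
  ≥ 0.95.

## The target-size model

All arithmetic is exact: `nchoosek()` uses the multiplicative formula whose
intermediates are integers, every value stays far below 2⁵³ (where doubles
are exact), and an integrality assertion guards each step. The chain is

```{r}
target_size_report()[c("combinations", "per_set", "space_rounded",
                       "hit_fraction", "favorable_rounded")]
target_size_report()$positions
```

Choices worth recording:

* The inversion rule is "smallest P with C(P,k)·a^k ≥ H". The source
  arithmetic states only approximate equalities; this rule is well defined,
  monotone in H and a, round-trips exactly for every P up to 200, and
  reproduces both printed answers (77 and 39).
* The default favorable-clone count uses the 3-significant-figure space
  (1.45 × 10⁸ → H = 72,500), following the published arithmetic; the
  exact-space alternative (H = 72,351.36) is reported alongside and yields
  the same inferred positions.
* s defaults to 6 (two non-synonymous codon positions × three alternate
  bases; third-position changes treated as synonymous). That simplification
  is conservative and slightly wrong per codon —
  `nonsynonymous_per_codon()` enumerates the true per-codon count (5–9 for
  most codons) for users who want the refinement.

## Additivity, epistasis and trajectories

Normalization is the two-anchor affine map; it is invariant to positive
affine transforms of all raw values (a cytometer gain change cancels), and
normalized values outside [0, 1] are legitimate. Replicates are aggregated
as the mean of per-population medians across biological replicates, and the
wild-type anchor for signal differences is the plate-matched control, since
every plate carries its own control triplicates.

`additive_prediction()` sums single-mutant deltas; `epistasis_residual()`
is the exact identity observed − predicted with root-sum-square error
propagation (validated against Monte-Carlo resampling). Genotypes missing a
single-mutant measurement are reported incomputable rather than silently
dropped.

`enumerate_trajectories()` enumerates all k! mutation orderings. The step
rule is "non-decreasing within ε" (a step may dip by at most ε, default
0.02 — the replicate-to-replicate uncertainty of normalized signal
medians): a trajectory is a plausible evolutionary path when no step loses
more signal than the measurement can resolve. A strict-increase variant is
provided; the within-ε rule is the default because measurement uncertainty
is part of the question being asked. The monotone count is non-decreasing
in ε by construction, and the full per-step audit trail is returned so
users can count failures per step or per trajectory as they prefer.

## FACS enrichment simulator

Gates are empirical quantiles of control populations: the expression
threshold passes ~5% of an autocrine-OFF control, the autocrine threshold
~1% of a negative-transport control; an event survives only if it strictly
exceeds both. Each round every cell emits one independent two-channel
event; survivors are expanded back to the working population size by
neutral multinomial resampling (no growth-rate differences). Consequences
that the tests verify: genotype richness never increases across rounds
(resampling cannot resurrect a lost genotype); with planted high-signal
clones at 0.05% starting frequency, the planted frequency rises every
round in expectation; and a constructed two-genotype separation (one
genotype passing the autocrine gate at ~20%, the other at ~1%) reproduces
a ~20-fold single-round enrichment. Sorted-event counts per round are
configurable through the composition's total count (the published protocol
collects 1–5× the library size; the simulator resamples to the working
population size, an equivalent neutral-expansion idealization).

## Problem sizes and determinism

The test suite uses 10⁴-clone libraries over 160-codon regions for the
round-trip and load-distribution checks, 1,000-replicate spectrum
simulations for calibration and power, 100 plate simulations for
additive-model recovery, and 100 seeded enrichment runs of 20,000 cells
over four rounds — sizes at which the binomial/Poisson standard errors the
assertions rely on are small relative to their tolerance bands. Every
stochastic function takes an explicit seed; nothing depends on the global
RNG state except through those seeds.

## Known limitations

* The Poisson null treats positions as exchangeable; real regions have
  conservation structure (the companion conservation profile exists
  precisely because observed spectra have more zero-count positions than
  Poisson predicts).
* The target-size model assumes exactly k required positions, independence
  across positions, and full library coverage of the k-mutant space;
  violations shift P in either direction, and the model is best read as an
  order-of-magnitude instrument.
* The additive phenotype is linear in effects on the normalized scale; if
  the reporter is a nonlinear transform of transport activity, apparent
  epistasis can be an artifact of the scale. The package takes the
  proportionality assumption as given and measures deviations from it.
* The enrichment simulator's neutral expansion ignores selection during
  growth, so it underestimates between-round drift for clones with growth
  phenotypes.
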