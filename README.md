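# abcselect

Analysis tools for directed-evolution selections on ABC-transporter mutant
libraries.

## The problem

ABC exporters move chemically diverse substrates across membranes, and their
substrate selectivity evolves readily. One way to probe how is to mutagenize
the transmembrane regions of a transporter that exports one substrate poorly
(for example, a distant fungal pheromone exporter confronted with a
non-cognate a-factor), run the error-prone PCR library through iterative
FACS enrichment on an autocrine reporter of export activity, sequence the
selected clones, and ask three questions:

1. **Which positions matter?** Sum non-synonymous mutations per residue over
   unique selected clones and compare the mutations-per-position spectrum to
   a Poisson null with the same mean, λ = total mutations / region length.
   Positions whose observed tail count exceeds the null prediction by a fold
   factor (default 10) are called enriched:
   `m* = min{ m ≥ 1 : #{p : c_p ≥ m} ≥ fold · L · P(X ≥ m) }`.
2. **How big is the mutational target?** If improving export takes mutations
   at k positions and each of L codons offers s non-synonymous single-base
   substitutions, the k-mutant space holds C(L,k)·s^k clones. An observed
   hit fraction f implies H = f·C(L,k)·s^k favorable clones, and the number
   of specificity positions is the smallest P with C(P,k)·a^k ≥ H, where a
   is the number of favorable amino acids per position.
3. **Do mutations interact?** On the two-anchor normalized reporter scale
   (strong exporter = 1, empty plasmid = 0), the additive model predicts a
   multi-mutant's signal difference as the sum of its singles' differences;
   the residual is epistasis, and all k! orderings of a clone's mutations
   can be audited for monotone (never dipping by more than the measurement
   uncertainty ε ≈ 0.02) evolutionary trajectories.

The package implements all three analyses plus a fully synthetic test bed:
an error-prone PCR library simulator (Poisson mutation load, uniform sites,
configurable substitution spectrum, planted additive effects, nonsense and
expression penalties), a two-channel log-normal cytometry event simulator,
and a quantile-gated sort-and-expand FACS enrichment simulator, so every
downstream statistic can be validated against planted ground truth.

## Worked example

```r
library(abcselect)
reg <- random_region(n_codons = 160, name = "TM4-6", start_residue = 199, seed = 7)
eff <- plant_effects(reg, n_specificity_positions = 12, favorable_per_position = 1,
                     effect_mean = 0.15, seed = 8)
lib <- simulate_library(reg, mutation_model(4.5), n_clones = 3000, seed = 9)
sig <- library_signals(lib, eff, baseline = 0.05)

# keep the clones a FACS selection would enrich (top 2% of autocrine signal)
sel <- lib[sig$autocrine >= quantile(sig$autocrine, 0.98)]
dd  <- dedupe_clones(sel, reg)
spec <- per_position_counts(dd$unique_clones, reg)
spec
#> <MutationSpectrum> TM4-6: 286 mutations over 160 positions (66 unique clones)

null <- fit_null(spec)                       # lambda = 1.788
chi_square_gof(spec)$statistic               # 3.21e7 (unpooled, heavy tail)
m_star <- enrichment_threshold(spec, null, fold = 10)
enriched_positions(spec, m_star)
#> threshold >= 7 -> 199, 210, 250, 302, 317, 332   (all 6 are planted positions)

target_size_report()
#> space 1.45e8, hit fraction 5e-4, favorable clones 72,500
#> a = 1 -> P = 77 positions;  a = 2 -> P = 39 positions
```

The spectrum's heavy tail relative to Poisson (huge unpooled chi-square) and
the recovery of planted specificity positions by the 10-fold rule are the
expected signatures of a selection that concentrates mutations at the
positions controlling substrate specificity. The target-size report inverts
the combinatorial model at the canonical study conditions (160 codons, 3
required mutations, 6 non-synonymous substitutions per codon, 50 hits in a
library of 1e5): 77 specificity positions if each admits one favorable
amino acid, 39 if each admits two.

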