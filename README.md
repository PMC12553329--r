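# protzoo

A desk-scale model zoo for protein property prediction in R. The package is
aimed at protein engineers and computational biologists who want to compare
embedding and zero-shot variant-scoring strategies on their own sequences
without stitching together one-off scripts: every model — from a one-hot
encoder to a marginal-likelihood variant scorer — follows the same
construct → `fit()` → `transform()`/`predict()` → `score()` contract, declares
its input requirements (needs an MSA, needs structures, needs a wild type) as
capability flags, and can be discovered through a registry that checks those
requirements against the data you actually have.

## What it computes

**Data types.** Validated `protein_sequence` / `protein_sequence_set` /
`aligned_family` objects over the canonical 20-letter alphabet (plus `X` for
unknown residues and `-` for gaps), FASTA/A2M input and output, deep
mutational scanning mutation notation (`"A2C"`, colon-separated multiples,
1-based on the ungapped wild type), saturation mutagenesis library
generation, and minimal PDB chain extraction for structure-requiring models.

**Independent-sites profile scorer.** From an MSA of width *W* it fits
per-column symbol frequencies over the 20 residues plus the gap,

  f_j(a) = (c_j(a) + α) / (n_j + 21α),

where c_j(a) counts symbol *a* in column *j*, n_j is the column's countable
depth (unknown residues excluded) and α ≥ 0 is a pseudocount (default 1). A
sequence is scored by its summed natural-log likelihood Σ_j ln f_j(s_j), and
a variant relative to a wild type by the delta

  Δℓ = Σ_i [ ln f_{j(i)}(mut_i) − ln f_{j(i)}(wt_i) ],

summed over mutated positions, higher = more favorable.

**Marginal scoring protocols.** The three standard conventions for turning a
conditional residue model p(a | context, position) into a variant score —
masked marginal, wild-type marginal and mutant marginal — implemented over an
abstract `residue_distribution()` contract. The built-in backend is the
context-free profile model, on which all three protocols provably coincide
with Δℓ above; language-model wrappers satisfying the same contract plug into
the identical scoring code.

**Embedders.** Fixed-length one-hot (20 channels per position), MSA-aligned
one-hot (21 channels per column including a gap channel; new sequences are
aligned to the training profile by a log-odds dynamic program), and k-mer
counts (k ≤ 3, lexicographic channel order).

**Registry and discovery.** `builtin_registry()` describes the whole zoo —
including capability-faithful stubs for GPU/externally-hosted models (ESM2,
SaProt, MSA Transformer, VESPA, EVE, SSEmb, EVmutation) — and
`available_models(bundle)` reports which models are installed and compatible
with your data.

**Synthetic ground truth.** `make_profile()` / `sample_family()` /
`labeled_variants()` generate alignment families and labeled variant sets
from known column profiles, so parameter recovery and rank consistency are
verifiable offline.

## Worked example

```r
library(protzoo)

prof <- make_profile(width = 12, concentration = 0.5, seed = 42)  # ground truth
fam  <- sample_family(prof, 200, seed = 43)                       # synthetic MSA
wt   <- profile_consensus(prof)                                   # "DHTRVDKSDTSR"

model <- fit(profile_scorer(alpha = 1), data_bundle(sequences = fam))
score_variants(model, wt, list("T3C", "T3C:K7W", ""))
#>           variant_id mutation_string  score
#>        consensus_T3C             T3C -4.190
#>    consensus_T3C:K7W         T3C:K7W -7.052
#>            consensus                  0.000

lv <- labeled_variants(prof, wt, 50, noise_sd = 0, seed = 44)
variants <- protein_sequence_set(lapply(lv$variants, \(m) apply_mutations(wt, m)))
score(model, data_bundle(variants, labels = lv$labels))
#> [1] 0.949
```

The variant scores are natural-log likelihood ratios against the wild type
under the fitted profile: `T3C` replaces a well-conserved threonine and is
penalized by −4.19 nats, the double mutant adds a second unfavorable
substitution, and the empty variant is exactly 0 by construction. The final
number is the Spearman rank correlation between the scorer (fitted on a
200-sequence sample) and noiseless labels from the generating profile — high,
but below 1 because the fitted frequencies carry finite-sample error.

Model discovery against bare sequences:

```r
available_models(data_bundle(protein_sequence_set(list(wt))))
# kmer and the one-hot embedders are compatible; MSA-, structure- and
# wild-type-requiring models are flagged with the unmet requirement.
```

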