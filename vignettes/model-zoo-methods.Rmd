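---
title: "Methods: the protzoo estimator contract, profile models, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the protzoo estimator contract, profile models, and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protzoo)
```

# The estimator contract

Protein property prediction methods differ wildly in what they need
(alignments, structures, a wild-type reference) and what they emit (feature
vectors, scalar scores). `protzoo` normalizes this behind one lifecycle:
models are constructed with hyperparameters only, `fit(model, bundle)`
returns the fitted model, embedders answer `transform()` with a numeric
matrix (one row per sequence, named finite channels) and scorers answer
`predict()` with one score per sequence. Calling `transform()`/`predict()`
before `fit()` is an error; refitting restarts from scratch, and refitting
on identical data reproduces outputs bit-identically — there is no hidden
state beyond what `get_params()` exposes, which is why
`clone_model()` (reconstruction from `get_params()`) is guaranteed to behave
identically after an identical fit.

Requirements are declared as immutable capability flags
(`requires_msa_for_fit`, `requires_structure`, `requires_wt`,
`requires_fixed_length`) and handled in two distinct ways:

* `check_compatibility(model, bundle)` *reports* every unmet requirement
  without raising or mutating anything; `available_models()` maps it across
  the registry. We count the MSA requirement as met only when the bundle
  carries an explicit alignment: a report should describe the data as given,
  not what remediation could manufacture.
* `fit()` *remediates* where a safe automatic step exists: ragged sequences
  are center-star aligned with a warning, sequences without structures fall
  back to the wild-type structure with one warning per fallback, and a
  missing wild type is an error. Two or more sequences of one uniform length
  are wrapped as an alignment unchanged, which makes the remediation
  idempotent.

All warnings and errors carry machine-readable condition classes
(`protzoo_<code>`), so pipelines can branch on event codes rather than
message text.

# Automatic alignment

The fallback aligner must be deterministic and dependency-free; competitive
alignment quality is explicitly not the goal (users with real MSAs should
supply them). We use center-star progressive alignment over pairwise global
dynamic programming with match +1, mismatch 0 and linear gap −1. The center
is the member maximizing the summed pairwise score (ties: lowest index);
pairwise center–member alignments are merged under "once a gap, always a
gap". Traceback ties prefer match, then a gap in the second sequence, then a
gap in the first, so identical inputs always give identical alignments.

# The independent-sites profile and its scores

The alignment-based zero-shot scorer assumes independent columns. For an
MSA of width $W$, column $j$ and symbol $a$ ranging over the 20 canonical
residues plus the gap:

$$f_j(a) = \frac{c_j(a) + \alpha}{n_j + 21\alpha}$$

with $c_j(a)$ the symbol count, $n_j$ the column depth after excluding
unknown residues (`X` contributes to no symbol, including the denominator),
and $\alpha \ge 0$ a pseudocount. The default $\alpha = 1$ (Laplace)
guarantees strictly positive frequencies and hence finite log-likelihoods;
$\alpha = 0$ gives raw empirical frequencies and is reserved for parameter
recovery, where any unseen symbol encountered at scoring time raises an
explicit zero-frequency error rather than silently returning $-\infty$.

A width-$W$ sequence scores $\ell(s) = \sum_j \ln f_j(s_j)$ (natural log,
gap scorable as the 21st symbol, `X` positions skipped with a warning); a
variant scores $\ell(\text{mutant}) - \ell(\text{wt})$, which for this model
reduces exactly to the per-site log-frequency ratios at mutated positions.
Scores are raw summed log-likelihoods: we deliberately do not
length-normalize or convert to E-value-like quantities, because the
package-wide convention is rank-scale comparison and within one profile the
normalization is a monotone shift. Likewise `score(model, bundle)` for every
predictive model is the Spearman rank correlation against the bundle's
labels: zero-shot outputs are only rank-comparable across methods.

Wild types whose length differs from $W$ are first aligned to the profile;
a mutation at a position consumed as an insertion maps to no column and is a
hard error rather than a silently dropped term.

# Marginal scoring protocols

Language models expose a conditional distribution over residues at a
position given a context. The three standard conventions for variant scoring
differ only in the context: masked (wild type masked at the site), wild-type
(unmasked wild type), and mutant (the full mutant sequence). `protzoo`
implements the three protocols once, over an abstract
`residue_distribution()` contract (non-negative named vector over the 20
canonical residues, summing to 1 within $10^{-12}$; violations raise a
contract error). The shipped backend is the context-free profile model,
whose prediction at position $i$ is column $j(i)$'s canonical frequencies
renormalized. Context-freeness makes the three protocols provably identical
— the renormalization cancels in the log-ratio — and equal to the direct
profile delta, which the tests verify to $10^{-9}$. That collapse is the
point: it gives an exact, offline-checkable reference for scoring code that
heavier backends then reuse unchanged. Marginal modes score canonical
residues only; the gap is not part of the conditional contract.

# Embedders and the profile-alignment dynamic program

*Fixed one-hot*: 20 indicator channels per position (`pos3_W`); `X` encodes
as an all-zero block, making the encoding a bijection on X-free sequences
with `onehot_decode()` as the inverse. *Aligned one-hot*: 21 channels per
column with the gap channel last (`col7_gap`), dimension $21W$; a
width-$W$ gapped input is encoded as-is, anything else is first aligned to
the training profile. *k-mer*: $20^k$ lexicographic count channels, windows
containing `X` skipped, optional division by the number of counted windows;
$k$ is capped at 3 so the dense output stays desk-scale (8000 columns).

Aligning a new sequence to the profile is a global dynamic program over
(query positions × columns). Placing residue $a$ in column $j$ scores the
log-odds $\ln(f_j(a) + \varepsilon) - \ln(1/20)$ against a uniform
background (the standard profile-match score; $\varepsilon = 10^{-9}$ only
floors the logarithm), an empty column emits a gap at −1.5, and a consumed
query residue (insertion) costs −1.5 and does not appear in the output, so
the output width is always $W$. Traceback ties prefer match, then deletion,
then insertion. The penalties are documented hyperparameters, chosen of the
order of a strong match score so single indels are placed where the profile
is weakest; the tests validate optimality not plausibility, by exhaustive
enumeration of all monotone column assignments on every instance with
$W \le 6$, $L \le 6$. `X` in a query takes match score 0 (uninformative
log-odds). The mechanism by which new sequences are mapped onto a training
alignment is an internal design choice of this package; swapping in an
external aligner would only need to preserve the output-width contract.

# Registry, tiers, and stubs

`builtin_registry()` describes 16 models in three dependency tiers: *base*
(the five implemented here: two one-hot embedders, k-mer, the profile
scorer, the profile-backed marginal scorer), *extra* (methods needing a
deep-learning stack: ESM2, SaProt, MSA Transformer, VESPA, EVmutation), and
*external_env* (tools run in their own environments: EVE, SSEmb). Non-base
entries are stubs carrying real capability metadata — e.g. the SaProt
entries require structures — so discovery over the full zoo is testable on a
laptop; instantiating a stub raises a not-installed error naming its tier.
Stubs are statically unavailable: this package does not probe Python
environments. MSA subsampling (`sample_msa`) is uniform without replacement
and order-preserving; no sequence reweighting scheme is applied.

# Synthetic ground truth

The generator exists so that every claim the tests make is checkable against
a known truth. `make_profile()` draws each column's canonical frequencies
from a symmetric Dirichlet (default concentration 0.5 — peaked, i.e.
conserved-looking columns, which keeps rank tests sharp; gap mass is a
constant per-column `gap_rate`, default 0). `sample_family()` draws every
column of every member independently from the profile, so
`fit_column_profile(alpha = 0)` is exactly the maximum-likelihood estimator
of the generating truth: with 2000 members and 30 columns the maximum
absolute frequency error is below 0.05 at the documented fixture seed 42.
`labeled_variants()` draws random single/double substitutions labeled with
their true profile delta plus optional Gaussian noise; at zero noise, rank
agreement with the profile scorer is 1 by construction, and the recovery
loop (generate → sample → fit → score) is the package's main end-to-end
surface.

What the generator does *not* emulate: epistasis (no pairwise couplings, by
scope), phylogenetic correlation between family members (rows are i.i.d.),
position-dependent gap structure, and alignment error. Passing tests
therefore demonstrate correctness of the estimators and protocols, not
predictive performance on real, correlated protein families.

# Numerical and degenerate-input choices

* Frequencies are validated to sum to 1 within $10^{-12}$ per column;
  conditional distributions likewise.
* All logarithms are natural; higher scores are more favorable; the empty
  variant scores exactly 0.
* Deterministic seeds: every sampling function takes a `seed` argument and
  restores the caller's RNG state, so library calls never perturb a user's
  stream.
* Degenerate inputs fail loudly with classed errors: all-gap sequences
  cannot be ungapped, a single unaligned sequence cannot be auto-aligned, a
  gapped wild type is rejected, mutating an `X` position is rejected, and a
  sequence shorter than `k` yields an all-zero k-mer row with a warning.
* Problem sizes used by the test-suite and acceptance script (families of
  50–2000, profiles of width 4–30, 200 enumeration instances) were chosen so
  the full loop runs in seconds on one core while keeping sampling error
  well inside the asserted tolerances.

# Known limitations

The center-star fallback aligner and the profile-alignment DP are
remediation tools, not competitive aligners. The profile model ignores
inter-column dependence, so it cannot express epistasis. Structure handling
extracts chain sequences only (CA-presence defines a residue, HETATM and
non-blank/non-A altlocs ignored) and reports numbering as found — it does
not renumber author numbering onto sequence coordinates. Stub registry
entries cannot be executed here by design.
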