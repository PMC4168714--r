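---
title: "Reactivity-guided ncRNA homology search: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reactivity-guided ncRNA homology search: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactscan)
```

## The model

`reactscan` searches for homologs of a structured ncRNA family in target
sequences that carry per-nucleotide structure-probing reactivities.  The
central modelling move is an asymmetry: on the **query** side the family's
specific pairing relationships are deliberately ignored — only a per-column
pairedness flag survives — while on the **target** side no structure is
predicted at all; the probing reactivities stand in for it.  This turns a
structure-alignment problem into a sequence-alignment problem with one extra
per-position term, and keeps the search at O(nm) time for a profile of n
columns and a target of m bases.

### Profile

From a Stockholm alignment with a consensus structure line we build
`Q = {P, S}`: frequency vectors `p_i` over `{A, C, G, U, X, -}` (X is any
unknown nucleotide; `.` and `-` are both gaps; T is normalized to U) and
flags `s_i` with 0 = paired, 1 = unpaired.  Columns whose gap fraction
strictly exceeds 0.5 are excluded (the threshold is a parameter bounded to
[0.5, 1]; a column at exactly the threshold is kept).  When one end of a
consensus pair is excluded, the surviving end is demoted to unpaired rather
than kept as a dangling "paired" flag: the per-site score only consumes
`s_i`, but the post-traceback consistency bonus walks the pair table, and a
pair pointing at a dropped column would corrupt it.  No pseudocount is
added by default; a Laplace pseudocount argument exists for profiles built
from very few sequences.

### Alignment

The alignment is semi-global ("glocal"): the whole profile must be
consumed, the target's flanks are free.  Three matrices (deletion,
insertion, match) with affine gap costs `e0 + k * ee` for a gap of length
k, initialized with `M[0,0] = 0`, `M[i,0] = e0 + i*ee`, `M[0,j] = 0` and
the gap matrices at negative infinity on their empty edges.  The match term
is `alpha * tau(s_i, r_j) + beta * sigma(p_i, b_j)`.  The final score is
`max_j M[n, j]`; since `M[0,j] = 0` makes the target prefix free, taking
the row maximum makes the suffix free as well, which is the standard
homology-search reading of the initialization.  Traceback starts at the
(smallest) argmax column and prefers match over deletion over insertion on
ties, so output is deterministic.

Reactivities are a property of the target: deleted profile columns consume
no reactivity, and inserted target bases skip theirs unscored — the
recursion's structure forces both.

### Structural similarity

`tau(s, r)` is 0 whenever r is undefined (sentinel -999 in reactivity
files, or positions absent from them), so unprobed regions fall back to
pure sequence alignment rather than being penalized.  Two scoring modes:

* **simplified** (default): `+1` when the reactivity agrees with the flag —
  `r > r_c` at an unpaired column, or `r <= r_c` at a paired one — and `-1`
  otherwise.  The boundary `r == r_c` counts as paired.  `r_c` defaults to
  0.3 (the conventional SHAPE threshold); for nuclease-based data with a
  different dynamic range a value of 0.5 is the usual adjustment.
* **protocol-specific**: the Bayesian log-ratio
  `log p(r | pi = s) - log p(r | pi != s)` under equal pairing priors,
  natural log.  The conditional densities `p(r | paired)` and
  `p(r | unpaired)` are configuration data, not constants: protocols and
  even normalization pipelines differ.  The shipped default
  (`inst/extdata/shape_densities.json`, loaded by `default_shape_model()`)
  uses Exponential(mean 0.15) for paired and Gamma(shape 1.8, scale 0.5)
  (mean 0.9) for unpaired sites — a repo default to be tuned per protocol,
  chosen so that paired mass concentrates below 0.3 and the log-ratio is
  monotone in r.  Densities are floored at 1e-12 before the log so scores
  saturate instead of overflowing.

Some probing pipelines emit an inverted signal (high value = protected);
`invert = TRUE` in `scoring_config()` (CLI: `--invert-reactivity`) flips
the convention.

### Structure-consistency bonus

After traceback, every consensus pair whose two columns are matched to
target positions earns `consistency_bonus` (default +1) if the two target
bases form a canonical pair (AU, UA, GC, CG, GU, UG; X never pairs).  The
bonus is added to the reported combined score *outside* the DP, which keeps
it a cleanly separable on/off term: toggling it can never change the
alignment itself, only the ranking.  Null calibration uses the same
`use_consistency` setting as the search, so scores and their null are
always on the same scale.

### Weights

`alpha = 0.7` and `beta = 2.6` are the default structural and sequence
weights, with the simplified scoring mode; they are the operating point
reported for SHAPE-style probing benchmarks, and both are plain arguments.
The substitution matrix defaults to +2 match / -1 mismatch, with X scoring
0 against everything and a profile gap scoring -1 against any base; any
6 x 5 matrix can be supplied as a whitespace-delimited labeled table.

## Significance

The null model asks: what combined scores does this profile produce against
random structured RNA?  Decoys are sampled from a stochastic context-free
grammar (`S -> aSu | uSa | gSc | cSg | gSu | uSg | aS | cS | gS | uS | eps`)
grown outside-in to a fixed length, with pair-type and single-emission
weights set so the expected GC content equals the requested value (pair
step probability 0.4, GU pairs 10% of pair steps — our choices, documented
here).  Each decoy is folded by Nussinov base-pair maximization (canonical
pairs including GU, minimum hairpin loop 3, deterministic tie-breaks) and
reactivities are simulated from the conditional densities given the
assigned structure.  Null scores come from independent fixed-length decoy
segments — `max(2 * profile length, segment_length)` — rather than sliding
windows, so the sample is i.i.d. for distribution fitting; 1,000 samples is
the default calibration size.

The scores are fitted with four candidates by maximum likelihood — normal,
Gumbel, GEV and a three-parameter (shifted) Gamma — and each candidate's
Kolmogorov–Smirnov statistic is recorded.  The Gamma fit is always the
operational null (the four-way comparison is a diagnostic only), and
p-values are its upper tail, clamped to [0, 1].

**Location estimation.** The shifted Gamma needs a location μ below the
sample minimum (alignment scores can be negative, and a Gamma supports only
positive values).  Anchoring μ a hair's breadth below the minimum is
tempting but wrong: the smallest observation then sits essentially at zero,
its log becomes an extreme outlier in the Gamma likelihood, and the shape
estimate is biased roughly 10% low (measured on Gamma(3, 2) samples at
n = 5000).  `fit_null()` therefore estimates μ by profile likelihood over
values strictly below the minimum, which recovers known parameters without
that bias and leaves tail p-values essentially unchanged.  A fixed anchor
1% of the score range below the minimum is the fallback if the inner fit
fails.

## The simulator

The package generates all of its own evaluation data:

* `simulate_family()` builds a stem-loop family (two helices, loop, spacer,
  tail) whose members diverge by whole-pair compensatory replacement at
  paired columns and random substitution at loops — the covariation
  signature of real families.  `pair_variation`/`loop_variation` near 0.25/0.2
  give a well-conserved family; 0.5/0.45 give the diffuse low-identity
  regime where sequence similarity alone struggles.
* `mutate_homolog()` derives a homolog from the profile consensus with
  i.i.d. substitutions and single-base indels; compensatory mode keeps
  every consensus pair canonical, so the true alignment's consistency score
  is exactly `bonus x |pair table|` by construction.
* `build_benchmark()` plants homologs between decoy flanks and simulates
  reactivities: decoy regions are probed concordantly with their assigned
  structure, the planted region concordantly with probability
  `concordance` per site (1 = ideal probing, 0.5 = uninformative — in
  simplified mode an exactly symmetric ±1 coin).
* `evaluate_roc()` scores ranked hits against the truth with a
  single-credit interval-overlap rule (≥ 50% of the shorter interval by
  default, configurable).

What the simulator does **not** emulate: transcript-level coverage biases,
position-dependent reactivity error, correlated noise along the molecule,
alternative structures/ensembles, and genomic repeat content.  Passing the
planted-benchmark tests therefore demonstrates the algorithm's behavior
under its own generative assumptions, not performance on any particular
experimental dataset.

## Study sizes and numerical choices

The test suite verifies DP optimality against exhaustive enumeration of all
semi-global alignments on 200 random instances (profile ≤ 6, target ≤ 8 —
small enough that enumeration is exact and fast), checks the alpha = 0
reduction against an independent affine-gap aligner
(`Biostrings::pairwiseAlignment`, global-local mode) on 50 instances, and
calibrates the null on 5,000 decoy scores (PIT uniformity) plus 2,000
fresh decoy trials (realized p < 0.01 rate).  The probing-benefit
experiment uses a diffuse family (pair/loop variation 0.5/0.45), three
pinned benchmark replicates of 20 positives and 60 decoys each, mutation
rate 0.25 with indel rate 0.12, and compares mean ROC areas under
concordance 1.0, concordance 0.5, and alpha = 0; the uninformative-probing
run is expected to land within noise of the no-probing run.  These sizes
keep the whole suite within a couple of minutes on one CPU while leaving
each stochastic check comfortably powered.

Numerical details worth knowing: DP scores are doubles and traceback
decisions use a 1e-9 tolerance; scan-level tie-breaks prefer the earlier
segment and smaller end coordinate; Nussinov tie-breaks prefer leaving the
right end unpaired, then the smallest pairing partner; the simplified
score's ±1 structure makes null scores partly discrete, which the
continuous Gamma absorbs (the PIT K-S on real null scores stays around
0.01–0.04).  All stochastic entry points take explicit seeds and restore
the caller's RNG state.

## Limitations

* The query side discards specific pairing during the DP; families whose
  identity rests on long-range pair geometry more than on pairedness
  patterns lose signal that a covariance model would keep (the consistency
  bonus recovers part of it, post hoc).
* Pseudoknot annotations in consensus structures are treated as unpaired.
* Targets are searched on the given strand only; probing data are
  strand-specific transcript measurements.
* The shipped reactivity densities are sensible defaults, not fitted to
  any particular protocol; for quantitative protocol-specific scoring they
  should be re-estimated from reference structures probed under the user's
  pipeline.
* p-values are per-alignment and uncorrected; genome-scale screens should
  apply their own multiplicity control downstream.
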