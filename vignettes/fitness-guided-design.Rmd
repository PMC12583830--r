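---
title: "Fitness-guided mutagenesis design and base-editing quantification with fitscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fitness-guided mutagenesis design and base-editing quantification with fitscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fitscan)
```

## The problem

Modern zero-shot variant-effect predictors summarize a protein's local
fitness landscape as an L x 20 matrix: for each residue position `t` of a
length-L protein, a probability distribution `p(x_t = a)` over the 20
canonical amino acids, conditioned on the rest of the sequence (and, for
structure-aware predictors, on the fold). fitscan takes that matrix as its
sole predictor interface and implements everything downstream of it in a
predictor-guided engineering campaign for a base-editing enzyme:

1. score and rank all single mutants of the protein,
2. ask which *mutation classes* (all substitutions into a given target
   residue, e.g. "X-to-K") are enriched among the top-ranked mutants,
3. select a panel of candidates for wet-lab testing using class quotas,
4. combine validated substitutions into a fixed background and search the
   astronomically large multi-site combination library for the top-N
   candidates, and
5. quantify the resulting editors' activity from amplicon sequencing reads.

## The fitness score

For a variant defined by a substitution set $T$ (pairs of position $t$,
wild-type residue $wt_t$ and mutant residue $mt_t$), the score is the sum of
log-probability differences, in nats:

$$s(v) \;=\; \sum_{t \in T} \Big[\log p(x_t = mt_t) - \log p(x_t = wt_t)\Big].$$

The empty set (wild type) scores exactly 0, and the score is additive over
disjoint substitution sets. Additivity is an assumption, not a theorem: it
ignores epistasis between the substituted positions. The package embraces it
deliberately, because it is what makes a $\sim 2.9\times10^{12}$-variant
three-site library searchable with a single matrix, and mitigates it the way
practitioners do — by re-conditioning: once a background of validated
substitutions is fixed, `make_background_matrix_request()` emits the mutated
sequence so the upstream predictor can be re-run on it, and all combination
scores are then computed on the *background-conditioned* matrix rather than
the wild-type one.

"Normalized" scores are min-max rescaled to [0, 1] over the enumerated
library. Ranked lists are unaffected by this choice (any strictly increasing
transform preserves ranks — a tested invariant); we chose min-max over
z-scores because it is scale-free and keeps the top variant at exactly 1.
When all scores are equal the normalization is degenerate and every entry is
reported as 1.

Ties in ranking are broken deterministically: raw score descending, then
position ascending, then mutant letter alphabetically. This makes every
ranked TSV byte-reproducible.

## Library enumeration

A k-site saturation library over a length-L protein with `n_fixed` excluded
positions has exactly $\binom{L-n_\mathrm{fixed}}{k}\,19^k$ members. For a
1368-residue Cas9, the single-mutant scan has $1368 \times 19 = 25{,}992$
members, and a three-site library over a 5-substitution background has
$\binom{1363}{3}\,19^3 = 2{,}888{,}288{,}965{,}699$. The count is returned
as a double and is exact whenever it is below $2^{53}$, which comfortably
covers these scales. The single-mutant scan is computed vectorized
(`scan_single_mutants()`), and a constant-memory iterator
(`enumerate_saturation()`) streams arbitrary k-site libraries without
materializing them.

## Class enrichment and quota selection

`class_enrichment()` reports, per target-amino-acid class, its
representation among the top fraction of the ranking (default 5%, with
boundary ties included so the cut never splits an equal-score run). Two
tests are reported side by side because "is class X enriched at the top?"
has two defensible readings:

* a two-sided t-test on the class members' *position-centered* scores
  (scores as the response), and
* a two-sided Fisher exact (hypergeometric) test on membership in the top
  set (membership as the response).

The centering deserves a note. Every mutant at position `t` shares the
term $-\log p(x_t = wt_t)$, so scores are strongly dependent within a
position. In a naive two-sample comparison of class scores against the
rest, these positional terms nearly cancel between the group means but
still inflate the pooled variance estimate, making the test badly
conservative (simulated type-I error under the package's null generator:
below 1% at a nominal 5%). Subtracting each position's mean score over its
19 substitutions removes the positional term exactly; the class members'
centered scores are independent across positions, and the one-sample
t-test against 0 is calibrated — a property the test suite verifies with a
1,000-simulation null sweep. Under a planted class bias the centered mean
shifts by 18/19 of the bias, so essentially no power is lost.

Both are Benjamini–Hochberg adjusted across the classes present. Fold
enrichment is invariant to monotone rescaling of scores; the t-test p-value
is not — this asymmetry is intentional and documented rather than hidden.

`quota_select()` implements hybrid selection: within the top-fraction pool,
take the q best-ranked mutants of each requested class (e.g.
`c(K = 6, C = 3, W = 3, M = 3, R = 3)` for an 18-candidate panel).
Under-filled quotas are reported in an attribute, never silently dropped or
fatally rejected, because a thin class pool is an expected outcome on small
proteins. The pool defaults to the top 5% but can be widened to the whole
library (`pool = "all"`).

After wet-lab validation, `dedup_positions()` collapses candidates sharing
a residue position, keeping the substitution maximal under a priority —
measured efficiency when supplied, predicted score otherwise (the
pre-experiment default, since measurements do not exist yet at design time).

## Exact lazy top-N combination search

`top_n_combinations()` finds the exact N best k-new-site combinations under
additive scoring without enumerating the library. Per mutable position the
19 substitution gains are pre-sorted; positions are ordered by their best
gain. A search state is a k-subset of positions plus one letter choice per
position; a max-heap pops states in non-increasing score order, expanding
each popped state to (a) single-step letter demotions and (b), from
letter-optimal states only, single-step position advances. Every state has a
predecessor under this scheme whose score is at least its own, so the n-th
pop is exactly the n-th best combination — the standard lazy k-best argument.
Cost is O(N·k·log) heap operations; the 2.9-trillion-variant design scope
resolves in milliseconds. Negative-gain substitutions are *not* pruned,
so the result stays exact even when fewer than k positions have beneficial
options. An exhaustive brute-force oracle in the test suite verifies
set- and order-exactness on 100 random small scopes.

## Base-editing quantification

`quantify_reads()` is a deliberately small, fully specified dialect of
amplicon editing quantification (it does not attempt feature parity with
full-scale tools):

* every read is globally aligned to the amplicon under unit mismatch/gap
  costs (match 0, mismatch −1, gap open 0, gap extend −1), with no
  quality weighting;
* a read whose alignment places a gap inside the quantification window
  (protospacer ± 10 nt by default) is an **indel read**, excluded from
  substitution calls — separating NHEJ-like outcomes from base-edited reads;
* gap-free reads contribute one base call per protospacer position 1–20
  (5′→3′ along the protospacer, PAM 3′-adjacent); conversion percent at a
  position is converted reads / substitution-eligible reads × 100;
* reads with gaps only outside the window are excluded from both tallies
  and counted separately; reads shorter than half the amplicon are
  discarded as unalignable. The counts obey
  `eligible + indel + gapped-outside = aligned` and
  `aligned + discarded = total` on every run — a tested conservation law.

Positions are treated independently (no haplotype phasing of multi-C
reads); callers wanting a "primary editing position" pick the
maximum-conversion C from the per-position table. For a minus-strand
protospacer, tallies are complemented and reversed; quantifying
reverse-complemented reads against the reverse-complemented amplicon
reproduces the forward result exactly (a tested invariant).

`product_purity()` gives, among converted reads at one position, the
fraction going to each alternative base. `window_profile()` averages
conversion across sites per protospacer position, excluding positions where
a site lacks the editable base (each position keeps its own denominator).
`normalize_efficiency()` sets the baseline editor's per-site replicate mean
to 1, computes per-site fold-changes, and summarizes across sites with an
arithmetic mean ± SD; zero-baseline sites are excluded and reported.

## Synthetic data generators

The three generators exist so every stage is testable end-to-end with known
ground truth:

* `gen_fitness_matrix()` draws per-row baseline log-scores
  (i.i.d. normal, SD `row_concentration`, default 0.4 nats), optionally
  adds a class-wide column bias, position-specific planted boosts and a
  wild-type preference, then renormalizes rows. The sub-nat default spread
  encodes that at a typical position the 19 alternative residues are
  comparably favored, so a planted boost of ~3 nats is a decisively
  beneficial substitution (it reaches the top percentile of a
  Cas9-scale scan), while unplanted scores center near 0 with both
  signs — a convenient null. Real predictors typically favor the wild
  type strongly; `wt_boost` emulates that when wanted (it shifts all
  scores down uniformly and changes no ranking among mutants).
* `gen_reads()` plants per-position conversions (independent Bernoulli
  draws per read), deletions of configurable size at protospacer position
  17 (the nick site, 3 nt 5′ of the PAM — the biologically standard indel
  hotspot), and uniform sequencing errors. A read receives an indel *or*
  conversions, not both.
* `gen_efficiency_table()` draws per-site baseline means uniformly
  (default 10–40%, a realistic untreated-editor range), then multiplies by
  the editor's true fold and a mean-one lognormal replicate noise with the
  stated CV (default 0.1, typical of three biological replicates), clamped
  to [0, 100].

All generators take an explicit seed, use an isolated RNG stream (the
caller's `.Random.seed` is untouched) and are bit-reproducible. What they
do **not** emulate: epistasis in the landscape, co-editing correlation
between nearby cytosines, quality-dependent or strand-biased sequencing
error, FACS enrichment effects, and amplicon-specific PCR bias. Passing
recovery tests on this synthetic data therefore demonstrates correctness of
the *quantification and search machinery*, not predictive validity on real
libraries — real-data performance is bounded by the upstream predictor and
assay, which are outside this package.

## Numerical and design choices

* Matrix columns are fixed in alphabetical one-letter order
  (`ACDEFGHIKLMNPQRSTVWY`); the TSV dialect is
  `pos res A C D ... Y`. Rows must exponentiate to 1 within 1e-6;
  raw logits are accepted behind `renormalize = TRUE` (row-wise
  log-softmax — which leaves all scores unchanged, since the score only
  uses within-row differences).
* The top-fraction cutoff is `ceiling(fraction * N)` entries, extended
  through boundary ties: deterministic and never empty.
* Welch's t-test on a constant-score library is undefined; the p-value is
  reported as `NA` (and can never be called significant), not coerced.
* Spearman's rho uses average ranks for ties; constant inputs are reported
  as undefined with an explanatory note, never as 0.
* Degenerate inputs (empty variant, empty library, k = 0, all-equal
  scores, zero baselines, no converted reads) each have a defined, tested
  behavior and a distinct error class where an error is the right answer.

## Problem sizes used in the test suite

The packaged tests run the complete machinery at reduced scale chosen to
keep the suite fast while leaving no code path untested: proteins of length
40–400 for scans and enrichment (the closed-form library sizes are checked
at the full 1368-residue scale, where only counting — not enumeration — is
needed), 100 random brute-force-verified combination scopes at L ≤ 8,
read sets of 10,000 for recovery checks, and 1,000 null simulations for the
type-I-error calibration of the class test.

## Known limitations

* Additive combination scoring cannot see epistasis; re-conditioning the
  matrix on each background recovers only background-to-new interactions,
  not interactions among the k new sites.
* The quantifier's unit-cost alignment has no affine gap model; a long
  deletion costs proportionally to its length. For the short indels typical
  of base-editor outcomes this is immaterial, but structural-variant-scale
  events would be misclassified as dense mismatches.
* Length-preserving insertion+deletion pairs in one read are classified by
  whichever gap placement the optimal unit-cost alignment chooses.
* The predictor itself — and hence any claim about which mutations are
  *actually* beneficial — is outside the package: the fitness matrix is
  trusted as given.
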