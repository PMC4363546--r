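---
title: "Ranking drug indications from chemical interactions and structural similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug indications from chemical interactions and structural similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`indirank` addresses drug-centric repositioning: given a query compound,
rank a fixed catalog of therapeutic indications $D_1, \dots, D_m$ from most
to least plausible. The model is a top-$k$ weighted nearest-neighbor vote
over a multi-label training collection, built on two guilt-by-association
assumptions:

* *interacting chemicals tend to share biological function* — so training
  drugs that interact with the query, weighted by the confidence of the
  interaction, are evidence for their own indications;
* *structurally similar chemicals tend to share function* — so 2D
  fingerprint Tanimoto similarity carries the same kind of evidence,
  more weakly.

For a query $d_q$ and candidate indication $D_j$ with training members
$S_j$, the interaction-path score is

$$R^i(d_q \Rightarrow D_j) \;=\; \sum_{l=1}^{k}\, w^i\!\left(d_q, d_{i_l}\right),$$

the sum of the $k$ largest interaction confidence scores between the query
and the members of $S_j$ (all of them when fewer than $k$ are positive;
an unreported pair has $w^i = 0$). The similarity-path score $R^s$ has the
identical form with Tanimoto similarities $w^s$ in place of confidence
scores. Two classical methods are limit cases: $k = 1$ is single
nearest-neighbor scoring, and $k = n$ (the training-set size) is the full
category sum. Indications with positive score are ranked in descending
order — the 1st, 2nd, ... order predictions; all-zero scores yield the
*trivial outcome*, an empty ranking.

The full (sequential) predictor applies the interaction path first and
falls back to the similarity path only on the trivial outcome, reflecting
the observation that interaction evidence, where it exists, is the stronger
signal (interaction confidence scores already integrate structural,
experimental and literature evidence, so the similarity channel is largely
redundant with them). An alternative *averaged* scheme scores every
indication by $\left(R^i + R^s\right)/2$ and ranks once; for queries with no
interaction partner at all both schemes reduce to the similarity-only
ranking (the averaged one with scores halved), a property the test suite
asserts exactly.

### Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_interaction` | 5 | summed top interactions per candidate indication |
| `k_similarity` | 2 | summed top similarities on the fallback path |
| `fingerprint` | `ECFP_4`, 2048 bits | similarity fingerprint family |
| dedup `threshold` | 0.7 | Tanimoto at or above which two drugs are near-duplicates |
| `min_size` | 8 | smallest retained indication category |

The `k` defaults are the operating point at which the two paths perform
best on the curated reference collection (interaction path peaking at
$k = 5$, similarity path at $k = 2$ under ECFP_4); they are configuration,
not re-derived by this package.

## Scoring conventions and numerical choices

* **Score scale.** STITCH-dialect files carry integer combined scores on a
  0–1000 scale; the reader divides by `scale = 1000` so stored weights lie
  in $(0, 1]$. Whether raw or rescaled scores enter the sum is
  ranking-invariant (a positive constant factor), so this choice only fixes
  reported magnitudes.
* **Ties.** The ranking requires a strict order but equal scores happen
  (e.g. two categories reached through the same single neighbor). Ties are
  broken by catalog order, which is fixed and explicit, making every
  evaluation deterministic. Any fixed rule can differ marginally from
  another implementation's implicit ordering on tied scores.
* **Zero scores.** Indications scoring 0 are excluded from the ranking
  rather than appended in arbitrary order; a drug can therefore receive
  fewer ranked predictions than the evaluation cutoff, and the missing
  orders count as incorrect (the accuracy denominator is always the full
  sample count).
* **Self-exclusion.** The query's own record never contributes a weight —
  self-similarity is identically 1 and would dominate the similarity path —
  and the evaluation harnesses remove the query from the training side
  before every call.
* **Multi-label neighbors.** A training drug tagged with several
  indications is an eligible neighbor for each of them independently; the
  category decomposition overlaps by construction.
* **Identifier hygiene.** Identifier matching is exact string equality.
  A `normalize_cid()` utility collapses zero-padded PubChem-style
  identifiers, but no reader applies it silently: coercing identifiers
  behind the caller's back hides join bugs.

## Fingerprints

ECFP (diameters 2/4/6), MACCS keys and the linear-path `PATH` family (the
Open Babel FP2 fingerprint: paths up to 7 atoms) are computed by Open
Babel. Circular fingerprints are emitted unfolded at 4096 bits and folded
by OR to 2048 bits; 2048 is the de-facto standard folded length, and
rankings can shift slightly under other foldings. MACCS is fixed at its
166 keys. `PATH` keeps its native 1024 bits — padding it to 2048 would add
dead bits and change no similarity.

FCFP (functional-class circular) fingerprints are implemented in this
package directly: atoms start from a 6-bit invariant (H-bond acceptor,
H-bond donor, negatively ionizable, positively ionizable, aromatic,
halogen) derived from the Open Babel MOL2 atom typing, and the standard
Morgan update rehashes each atom's identifier together with its sorted
(bond order, neighbor identifier) environment for `diameter/2` iterations;
all identifiers are folded modulo the bit length. The atom-class rules are
deliberately simple, deterministic approximations (implicit hydrogen counts
are estimated from standard valences, ionizability from charges and the
carboxylate/sp³-amine patterns). The result is a faithful member of the
FCFP family and is invariant to SMILES spelling — asserted in the tests
against a canonicalization oracle — but it is not bit-compatible with any
other toolkit's FCFP, so cross-toolkit similarity values will differ.
Bit-exact reproduction of any particular published fingerprint table is
out of scope. No salt stripping or structure standardization is applied by
default, because the reference procedure describes none.

## Dataset curation

Two procedures, applied in this order:

1. **Minimum category size.** Indications with fewer than 8 member drugs
   are dropped (too small to evaluate meaningfully), then drugs left with
   no label are dropped, iterating to a fixed point.
2. **Near-duplicate removal.** Build the graph joining drug pairs whose
   ECFP_4 Tanimoto is at least 0.7 ("at least" — the threshold itself is an
   edge) and retain a *maximal independent set*: no two retained drugs are
   near-duplicates, and every removed drug has a retained neighbor above
   the threshold. Without this step, families of trivially similar
   derivatives inflate accuracy. Maximal is not maximum: any maximal set
   satisfies the curation goal, and which one a given implementation finds
   is unknowable in general, so the retained *count* is not a contract.
   The greedy here picks vertices by ascending degree in the shrinking
   graph (ties by dataset order): deterministic, and biased toward larger
   retained sets. Consequently no specific retained cardinality is asserted
   anywhere — only the independence and maximality contracts, which the
   tests verify by brute force.

## Evaluation

* **Order accuracy** $\mathrm{ACC}_i$: the fraction of drugs whose $i$-th
  ranked indication is true. $N$ is all evaluated drugs; rankings shorter
  than $i$ contribute zero.
* **Recall/precision at $t$**: per-drug correct-in-top-$t$ divided by the
  drug's label count, respectively by $t$, averaged over drugs;
  $t = \lceil \mathrm{Average} \rceil$ where Average is the mean label
  count. $\mathrm{Precision}_1 = \mathrm{ACC}_1$ identically.
* **Per-category sensitivity** $SN^i$: the fraction of category $S_i$'s
  members that retrieve $D_i$ within their first two predictions, plus the
  Pearson correlation between category size and sensitivity.
* **Jackknife**: leave-one-out; deterministic, the least arbitrary scheme.
* **Repeated k-fold**: unstratified uniform partitions into near-equal
  folds (sizes differ by at most 1), re-drawn per repeat from
  `(seed, repeat index)`; per-repeat metrics are reported with their mean
  and sample (n−1) standard deviation across repeats. Stratification is
  deliberately not applied — the reference scheme divides "equally and
  randomly" — and at 5 repeats the sd convention is a sub-percent detail.
* **Random-ranking null**: a uniform random permutation of the catalog per
  drug scores $\mathrm{ACC}_1 = \mathrm{Average}/m$ in expectation (each
  drug's rank-1 tag is uniform over $m$ tags and hits with probability
  $N^j/m$). For the curated reference counts — 2,005 memberships over
  1,573 drugs, 56 categories — Average $= 1.27$ and the null is
  $1.27/56 = 2.27\%$, the benchmark against which recovered signal is
  judged.

## The synthetic benchmark

Real curated indication collections are proprietary, so the package ships
a generator that emulates exactly the statistical structure the method
exploits, with planted ground truth:

* a label-count distribution of 0.77/0.20/0.03 for 1/2/3 indications
  (the shape of the curated reference collection: 1,209 of 1,573 drugs
  single-label, 313 double);
* per-category prototype bit vectors (256 bits, 32 prototype bits per
  category by default); a drug's fingerprint is the union of its
  categories' prototypes with per-bit flip noise, so within-category
  Tanimoto exceeds cross-category Tanimoto by a margin controlled by
  `bit_noise`;
* interaction edges denser and higher-scoring (Beta(4,2) vs Beta(2,4))
  between same-label pairs than cross-label pairs. The default densities
  (0.03 same, 0.001 cross) leave roughly 40% of drugs with no interaction
  partner, mirroring the coverage split of real interaction databases
  (896 of 1,573 reference drugs interaction-covered, 677 not) so that both
  scoring paths — and the fallback logic between them — are actually
  exercised.

What passing tests on this fixture show: the implementation recovers
planted association signal well above the random null (the default
200-drug, 10-category benchmark scores $\mathrm{ACC}_1$ at 6–7× the null)
and degrades monotonically as the similarity signal is destroyed. What
they cannot show: performance on real pharmacology, where category sizes
are heavily skewed, fingerprint similarity within an indication is far
weaker and structured, and interaction evidence is correlated with
literature coverage rather than independent Bernoulli draws. The
generator's drugs also carry no SMILES — the predictor consumes pairwise
weights, not structures — so the chemistry module is tested separately on
a small panel of real drug SMILES.

### Problem sizes used by the shipped checks

The test suite and the acceptance script run, by design, at desk scale:
oracle-equivalence fixtures of at most 30 drugs (checked against exhaustive
brute-force reimplementations), curation contracts on at most 15 drugs
(checked exhaustively), the default 200-drug benchmark for signal recovery
(one jackknife per noise level across 10 generator seeds), and a
1,573-drug, 56-category fixture for the Monte-Carlo null (20 random-ranking
repeats). These sizes make every check exact or tightly
Monte-Carlo-bounded while keeping the whole suite in the low minutes.

## Known limitations

* Headline accuracies on the proprietary reference collection are not
  reproducible here: they require the original commercial drug list and a
  full interaction dump. The package reproduces the method, its
  self-contained arithmetic, and its behavior on planted-signal data.
* Whether raw or rescaled confidence scores entered the reference
  implementation's sums is undocumented; as noted above the ranking is
  invariant, so the package fixes `scale = 1000` and reports weights in
  $(0, 1]$.
* The FCFP implementation is package-specific (see above); the `PATH`
  family approximates the Open Babel FP2 design and both are excluded from
  default benchmarks, which use ECFP_4.
* No probabilistic calibration, no learned weights, and no disease-centric
  direction: scores are evidence sums, comparable within one query's
  ranking, not across queries.
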