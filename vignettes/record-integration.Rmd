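---
title: "Integrating person records from multiple sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating person records from multiple sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reclink)
```

## The problem and the model

Given person records from several datasets with no shared identifier,
we want a partition of all records into person-clusters. Treating each
record as a point and clustering sidesteps the two classic failure modes
of pairwise linkage on 3+ sources: non-transitive pair decisions
(A≈B, B≈C, A≉C) and the combinatorial blow-up of record tuples across
sources.

The distance between records is additive over their common non-missing
attributes: RD(R₁, R₂) = Σᵢ dᵢ. Attributes missing in either record are
excluded from the sum — a record with no date of birth is neither
rewarded nor punished on that attribute — and a pair with *no* common
non-missing attribute is incomparable: it never merges at any finite
threshold. Addition is deliberately unweighted; attribute weighting
would be a one-line extension but is not part of the method.

Single-linkage agglomeration over this distance, cut at threshold t,
yields the output clusters. Single linkage is the right linkage here for
a structural reason: the cut partition equals the connected components
of the graph joining pairs with RD ≤ t, which is what "the same person,
possibly through a chain of intermediate versions" means operationally.
That identity is also the backbone of the test suite — three different
algorithms (full dendrogram + cut, truncated agglomeration, direct
component growth) must return identical partitions on random inputs,
and the component grower is additionally checked against an independent
graph library.

## Attribute distances and what they forgive

The base measure is unit-cost Levenshtein distance. Name attributes can
be compared by distances that forgive structured, realistic errors:

* **reversal** — `min(ed(f₁,f₂)+ed(l₁,l₂), ed(f₁,l₂)+ed(l₁,f₂))`; a pure
  first/last swap costs 0.
* **nickname** — smallest edit distance over both names' variant sets
  from a symmetric nickname table; the table is applied to first names
  only by default (`nickname_last_names = FALSE`), since surname
  "nicknames" are not a documented error mode; the flag widens it.
* **truncation** — edit distance of the length-L prefixes, L = 5 by
  default; "christopher" vs "chris" costs 0.
* **name distance** — the minimum of straight edit, reversal, nickname
  (on firsts, plus edit on lasts) and truncation (on both names). The
  joint first+last combination is this package's convention: the
  ingredient distances are defined per name, and we take the global
  minimum over the four pairings listed.
* **phonetic** — 0 if the Metaphone codes agree, else the edit distance
  of the codes. The encoder is pluggable (`encoder_fn`); the bundled
  default is an original-Metaphone implementation written from the
  published rule set. Its conformance is pinned in tests by rule-derived
  codes (smith/smyth → `SM0`, knight → `NT`, philip → `FLP`) and by the
  purity and equivalence properties the method actually relies on.

Six record-level modes assemble these (see `?distance_spec`). When a
joint name mode (`rded`, `nded`) finds only one of the two names
comparable, it falls back to plain edit distance on the comparable one.

## Thresholds

A **constant** threshold is an absolute edit budget t (integer). A
**proportional** threshold is a fraction p of the record length; "record
length" is not uniquely defined for a pair, so the package uses the
mean of the two records' summed compared-attribute lengths (symmetric,
bounded by the longer record; `proportional_base` offers min/max/sum).
Under proportional thresholds the dendrogram is built over
length-normalized distances RD/base so that a single cut level p exists;
the component-growing algorithms use the equivalent per-pair test
RD ≤ p·base. This choice is what preserves the exact three-way
equivalence of the algorithms across both threshold kinds.

Proportional budgets are converted to integer band widths via floor(t):
distances are integers, so `RD ≤ t` and `RD ≤ floor(t)` accept the same
pairs.

## The bounded distance machinery

Every comparison inside the clustering algorithms runs through a banded
edit distance with three short-circuits: (1) the length-difference lower
bound rejects a pair before any table work; (2) the dynamic programme
only fills the band of width 2t+1 around the diagonal, O(t·l) instead of
O(l²); (3) it terminates as soon as every cell of the current band row
exceeds t, which is sound because values along any diagonal of the
edit-distance table never decrease. Whatever one attribute spends is
subtracted from the budget available to the next ("threshold minus the
distance already used"), so the accept/reject decision is identical to
comparing the full record distance against the threshold — a property
tested on 10⁴ random pairs against the full dynamic programme, and
independent of the attribute comparison order. The over-budget outcome
is a distinct OVER sentinel (`NA` + `is_over()`), never a large magic
number that could leak into sums. A Four-Russians-style table speedup
was considered and rejected: person-record attributes are far too short
for the block-table amortization to pay off.

## Blocking

The two-phase algorithm indexes every record under each distinct l-mer
(length-l substring) of its last name — 26^l possible keys; "rueckl"
lands in 4 blocks for l = 3 — clusters each block independently, and
merges clusters sharing records by union-find. Two conventions cover
corner cases the indexing rule leaves open: last names shorter than l
are indexed under the whole name (skipping them would orphan such
records silently), and records with an empty last name stay singletons.
Merged clusters are not re-checked against the threshold afterwards;
merging is by shared membership only. The output always refines the
unblocked partition — blocking can only remove candidate pairs — and
equals it exactly when every same-entity pair shares at least one
l-mer, both of which are property-tested.

## The synthetic cohort generator

No public corpus with per-record ground truth accompanies the method, so
the package ships a seeded generator (`generator_params()`,
`generate_datasets()`) that emulates the error taxonomy the distances
target. Entities draw names from bundled pools (~160 first names with a
nickname table, ~290 surnames — small enough that occasional tautonyms
occur, as in real registries), a date of birth uniform over 1940–2005, a
gender and a 5-digit zip. Each entity yields 1–3 records; each record
may suffer, independently: a first/last swap (p = 0.05), a nickname
substitution (p = 0.1), a name truncation to 5 characters (p = 0.05), a
homophone rewrite such as ph→f (p = 0.05), and per-field
single-character typos (p = 0.2 per field, at most 2 edits per record).
The typo and structured-error rates are the package's own declared
parameters, chosen as a "mildly corrupted registry" regime in which a
small trained edit budget separates entities. The RNG stream is split
per entity, so growing a cohort never perturbs earlier entities, and a
fixed seed reproduces output byte-for-byte.

What passing tests on this generator do **not** show: real registries
have correlated errors (household members sharing typos), missingness
that is informative, OCR-specific confusions, and name distributions
with heavier tails than the bundled pools. Results on synthetic cohorts
bound the method's behaviour under the modelled error types only.

## Numerical and determinism conventions

* Values are normalized on ingestion: lowercase, trimmed; name
  attributes keep only a–z (so name distances operate on the 26-letter
  alphabet the 26^l block count assumes); date-like values become
  YYYYMMDD digit strings; other values keep letters and digits. The
  normalization rules are declared package conventions, not part of the
  method.
* Agglomeration ties are broken by cluster label: among minimum-distance
  pairs, merge the pair whose (smaller label, larger label) is
  lexicographically least; a cluster's label is its smallest member
  record id. This makes dendrograms — not just partitions — independent
  of record order.
* The component grower seeds each new cluster with the smallest
  unassigned record id; the resulting partition is seed-independent
  anyway (components are), only traversal order is fixed.
* Cluster ids in output are the smallest member record id; cluster CSV
  rows are sorted, so equal clusterings produce identical bytes.
* Incomparable pairs (no common attribute) sit at +Inf and merge, if
  ever, above every finite level; `as.hclust` conversion flattens those
  levels to max+1 only for plotting.

## Problem sizes in the test suite

The suite exercises: 10⁴ random string pairs for the bounded-distance
oracle check; 200 random cohorts (most 6–50 records, a few up to ~180)
for the three-way algorithm equivalence; 50 cohorts for blocking
refinement/equality; and one 500-entity (~1,000-record) cohort for the
end-to-end trained-threshold run, where a threshold trained on 200
records by re-cutting a single dendrogram is applied to the held-out
~800 records. These sizes were chosen so the full suite documents the
method's behaviour at realistic small-registry scale while running
comfortably on a laptop.

## Limitations

* Accuracy degrades in name-only modes when tautonyms (distinct persons
  with identical names) are common; add attributes (`ed_all`, `pded`)
  rather than raising thresholds.
* The dendrogram-based algorithms hold an O(n²) matrix; the package
  warns above 20,000 records and the matrix-free algorithms are the
  default advice there.
* Blocking misses same-entity pairs whose last names share no l-mer
  (heavy surname corruption); that loss is the documented price of its
  speed.
* No probabilistic match weights (Fellegi–Sunter style) and no pairwise
  precision/recall reporting: the unit of evaluation here is the
  cluster, not the pair.
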