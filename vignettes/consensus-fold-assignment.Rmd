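---
title: "Consensus fold assignment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus fold assignment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldcons)
```

## The problem and the model

Remote-similarity surveys of uncharacterized protein domain families run
several search engines with complementary strengths — sequence searches in
linker-enriched and natural SCOP sequence databases, scans against an HMM
library, profile–profile alignment, HMM–HMM comparison, and threading —
and gain reliability where the engines converge. `foldcons` implements the
downstream half of such a survey as a deterministic pipeline over the
engines' hit tables:

1. **Filter** each method's hits with its own significance rule.
2. **Resolve** each method's surviving hits to at most one SCOP
   superfamily per domain region of each query, using a per-method
   decision tree.
3. **Merge** per-method verdicts across methods by region overlap,
   excluding ambiguous regions, and tier confidence by method agreement.
4. **Annotate** retained assignments with GO terms, candidate EC numbers
   and member-kingdom distributions.
5. **Benchmark** against families of known structure at fold level.

The underlying assumptions are those of the survey design: queries are
globular domains; agreement between independent detection strategies at
superfamily level is strong evidence of true homology; fold-level
agreement alone is suggestive but not sufficient for retention.

## Parameters, units and defaults

All thresholds live in one place (`default_thresholds()`) and are
boundary-inclusive, evaluated exactly as decimal comparisons — a hit at
E = 0.001 or Z = 7.5 passes. They are contracts of the survey design, not
tuning knobs, which is why no epsilon is applied.

| parameter | default | meaning |
|---|---|---|
| `evalue` | 0.001 | full-sequence E-value cutoff for HMM-based searches |
| `coverage` | 0.60 | query-length coverage, required for nrichd and supfam_plus |
| `zscore` | 7.5 | profile–profile Z-score cutoff |
| `pvalue` | 1e-5 | threading P-value cutoff, jointly with the `CERTAIN` tag |
| `link_zscore`, `link_coverage` | 9, 0.80 | family–family link qualification |
| `evalue_margin` | 10 (exclusive) | frequency margin for cross-fold E-value groups |
| `z_fold_margin`, `z_class_margin` | 4, 6 (inclusive) | best-Z margins across folds / classes |
| `overlap` | 0.60 | region identity: overlap ≥ 60 % of either region |
| `ic` | 1.5 | minimum information content of transferred GO terms |

The asymmetry between the strict `> 10` frequency margin and the inclusive
`≥ 4` / `≥ 6` Z margins is deliberate: the rules are implemented exactly as
stated for each method, not harmonised.

The full-sequence E-value, not the per-domain conditional E-value, is the
filtering score for HMMER tables; per-domain lines each yield their own
hit, with no merging at read time. For the iterative sequence search only
the final-iteration table is consumed. HHsearch hits are taken per summary
row, not best-per-template — the more conservative reading, since repeated
rows of one template then weigh in the frequency rules exactly as the file
reports them.

## Decision-tree details and tie-breaks

Where the cascade is underdetermined, `foldcons` resolves ties
conservatively:

* Rule "lowest E-value and maximum coverage" can conflict; E-value is
  primary (it is the method's significance measure), coverage secondary,
  lexicographic hit id tertiary, making resolution order-independent.
* A tie for the modal superfamily leaves the region unresolved — no
  adjudication rule exists for it, and discarding is the conservative
  choice.
* Groups whose superfamilies span both shared and unshared folds fall to
  the most general applicable rule (the cross-fold margin), reading each
  cascade step as an "all hits" condition.
* In the Z-score tree, class homogeneity is tested over all hits: any
  cross-class pair routes the group to the ≥ 6 margin.

The consensus stage applies one tolerated disagreement: exactly four
agreeing methods with one dissenter retain the majority superfamily, with
the dissenter recorded. Three-versus-one is excluded; so is every
two-method conflict, even within one fold (same-fold conflicts are only
flagged for reporting). The merged region is the min-start/max-end
envelope of the agreeing assignments — the merge rule never defines a
boundary narrower than its evidence. Chained overlaps (A–B and B–C but not
A–C) join by single linkage, matching the "same region" pooling used
within methods. Ambiguity is counted at both granularities — per excluded
region and per family — since either convention is defensible.

Indirect assignments inherit one hop only through qualifying links: a
family linked to directly mapped partners gains their superfamily when the
partners agree, and nothing otherwise. Transitive chaining is not applied;
one hop is the minimal reading of "direct or indirect" relationships, and
each extra hop would compound profile-drift risk.

## Degenerate inputs and numerical choices

* Hits whose structural template has no SCOP mapping are dropped before
  filtering, with counts logged (`n_unmapped`), mirroring the exclusion of
  unmapped threading templates.
* An empty region group is a programming error, not an outcome; readers
  raise errors naming the offending line.
* With zero predictions, precision and error rate are undefined and
  reported `NA`, never 0; success is 0.
* Reference families spanning several folds count a prediction correct if
  it matches any of them; queries with a reference but no prediction lower
  success but not precision.
* Scores are written as shortest ≤ 6-significant-digit decimals so that a
  write–read–write cycle is byte-stable; threshold comparisons operate on
  the parsed decimals directly.

## What the synthetic bundles emulate — and what they do not

`fixture_spec()`/`generate_fixture()` emit complete bundles whose
per-method hit counts, cross-method agreement patterns, conflict ledgers,
tier histograms and link topology are controlled exactly, with a manifest
stating the outcome the pipeline must reproduce per family. Each file's
content is drawn from a pseudo-random stream keyed by (seed, label), so a
given spec regenerates byte-identically and adding one file never shifts
another. The generated catalog spans 4 classes × 3 folds × 3 superfamilies
so every lineage relation the decision trees branch on is representable.

Generated bundles place one passing hit per (family, method): pre-filter
hit counts then equal the specified assignment counts, which is what the
bookkeeping checks need. Consequently the standard bundles exercise
decision-tree rule (i) only; the multi-hit branches, margins and
tie-breaks are covered by exhaustive oracle-equivalence sweeps (about
8,000 generated hit groups of up to 15 hits and 3 superfamilies per run,
checked against a brute-force rule interpreter) and by targeted
perturbations (`perturb_fixture()`): E-value inflation, region shrinkage
and dissenter flipping, each with a manifest-predicted effect.

What passing these tests shows is that the bookkeeping, the rule cascades
and the merge semantics are implemented exactly. What it cannot show is
performance on real data: synthetic scores carry no alignment information,
sequence content is absent, score distributions are only placed relative
to the thresholds, and region boundaries are cleaner than real domain
parses. Benchmark percentages on synthetic bundles therefore validate the
equations, not any method's real-world accuracy.

Where a published survey's own marginals are used as generator inputs
(tier histogram 15/39/50/89/421; per-method assigned/conflicting ledgers
245−24, 384−30, 173−23, 68−18, 205−22; 5,002 direct plus 278 indirect
mappings), the per-method retention fixtures are generated one method at a
time: the tier histogram and the per-method ledgers are marginals of
different tables and are not jointly realisable in a single dataset (the
tier histogram implies 980 method-slots, the ledgers 958). Conflict
quotas are consumed by pairing the two largest remaining quotas; a last
unpaired quota is matched with a round-robin partner, which adds one
assignment *and* one conflict to the partner, leaving every method's
retained count exact.

The built-in taxonomy is a minimal four-kingdom tree (a superkingdom rank
with species leaves); "kingdom" in outputs means the superkingdom-rank
ancestor, with Viruses as its own division. Phylum-level reporting is
possible from the same tables but carries no set semantics in the outputs.

## Problem sizes

The shipped tests and the acceptance script run the pipeline end-to-end on
bundles of up to 614 families (~1,000 hits), sweep ~8,000 oracle groups,
derive indirect mappings over a 5,280-row mapping table, and verify
manifest fidelity across 100 random bundle specifications of ~5–20
families each — sizes chosen so the full suite completes in a few minutes
while still covering every rule branch exhaustively.

## Known limitations

* The artifact consumes search output; it never invokes the engines, so
  input quality (profile drift, alignment truncation) is inherited.
* One SCOP catalog per run: reconciling hit identifiers across catalog
  versions is out of scope.
* Exclusions are never re-adjudicated by score magnitude, and clan
  information is not used computationally.
* GO transfer is a flat IC-thresholded lookup; ontology-graph reasoning
  and IC computation belong upstream.
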