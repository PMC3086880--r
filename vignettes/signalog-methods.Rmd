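---
title: "Orthology-based transfer of signaling pathway membership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orthology-based transfer of signaling pathway membership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalogr)
```

## The problem and the model

Curated signaling-pathway maps are uneven across species: the same
pathway is often known in far more detail in one organism than in
another. When pathway membership has been curated with uniform rules
across several species, that asymmetry becomes exploitable — a protein
with no known signaling role, whose ortholog in another species is a
curated member of a pathway, is a strong candidate for the same role.
`signalogr` implements this transfer systematically. A predicted novel
(protein, pathway) membership is called a **signalog**; the protein
carrying it is a signalog protein. The default configuration covers
the three metazoans with deeply curated maps — *C. elegans* (`CEL`),
*D. melanogaster* (`DME`), human (`HSA`) — and eight canonical
pathways (EGF/MAPK, TGF-beta, IGF/insulin, Notch, WNT, Hedgehog,
JAK/STAT, NHR), but both sets are configurable.

The transfer rule is deliberately simple and fully deterministic. For
a target species $t$, every protein $p$ of $t$ that appears in an
ortholog cluster is a candidate. For every ortholog $o$ of $p$ (in any
source species) and every curated membership $(o, P)$, the pair
$(p, P)$ is emitted unless $(p, P)$ is already curated in $t$. All
supporting orthologs are merged into one record per $(p, P)$ with
full provenance. There is no probabilistic model: confidence lives in
the inparalog scores of the provenance and in the downstream novelty
classification, not in a fitted score.

## Orthology model and the inparalog threshold

Orthology comes from InParanoid-style clusters: each cluster links
proteins of one species pair, anchored by one *seed ortholog* per
species with score exactly 1.0; additional *inparalogs* (post-speciation
duplicates) carry scores in (0, 1]. The `threshold` parameter
(default **0.3**, the value used in the original analysis) filters
ambiguous many-to-many orthology: when a protein has more than one
counterpart in its cluster, only counterparts with inparalog score
*strictly above* the threshold are used; a sole counterpart is kept
regardless of score, and seeds always pass.

Two choices here were genuinely open:

* **Strictness.** "Higher than 0.3" is read as a strict inequality;
  a counterpart scoring exactly 0.3 is dropped.
* **Sidedness.** The filter could be applied from the perspective of
  the query protein only, or from both ends of a link. We apply it
  from both ends (a link survives only if each endpoint retains the
  other), which makes the ortholog map symmetric by construction —
  `orthologs_of()` then satisfies the natural reciprocity property
  exactly. The one-sided variant would keep slightly more links
  (those where a low-scoring inparalog is the *sole* counterpart of
  its partner but one of several counterparts the other way). On the
  packaged fixtures the two variants coincide, since all fixture
  clusters are seed–seed pairs.

Thresholding is monotone: raising the threshold never adds links, and
therefore never adds predictions; at threshold 1.0 only seed–seed
links (and sole counterparts) remain. These invariants are enforced by
property tests against an independently written brute-force
per-cluster filter.

## Candidate universe and novelty

Only proteins present in some ortholog cluster can become signalogs:
the method transfers through orthology and makes no claim about
un-clustered proteins. A protein already curated into one pathway can
still receive a *different* pathway (its `is_new_protein` flag is then
`FALSE`); this mirrors the rare but real case of a known pathway
member gaining an additional membership. The precondition "no known
signaling role" is operationalized as "that (protein, pathway) pair is
not curated"; the stricter reading — the protein participates in no
curated interaction at all — is available as
`require_no_interactions = TRUE`.

The novelty of each prediction is graded into five classes from the
literature flags in the attribute table (`orthologs_known`,
`function_known`, plus whether the protein had any prior pathway
annotation). The published wording of class 1 ("no orthology
information and/or no biochemical function") overlaps classes 2 and 3;
we resolve the overlap by evaluating most-specific-first, so class 1
means *both* unknown and the five classes partition all eight flag
combinations. Note that `orthologs_known` is literature-documented
orthology, not cluster membership — the method's whole point is to
predict roles for proteins whose orthology nobody had discussed.

## Interologs, coverage, and reference overlap

Three supporting computations contextualize the predictions:

* `derive_interologs()` predicts an interaction between two target
  proteins whenever their orthologs interact in another species.
  Direction and sign are dropped (external interolog resources are
  undirected) but preserved in provenance; self-pairs are suppressed,
  while a source self-interaction mapping to two distinct inparalogs
  is kept. `compare_interolog_sets()` reports the overlap of two sets
  as distinct unordered pairs; because published overlap percentages
  rarely state their denominator, it reports the percentage of the
  union and of either set.
* `coverage_stats()` asks, per species, what fraction of *known*
  signaling proteins has an ortholog at all, an ortholog with a known
  signaling role, and an ortholog in an identical pathway. The latter
  two fractions use proteins-with-at-least-one-ortholog as the
  denominator ("of these"); cross-species summaries are unweighted
  means of the per-species percentages. All percentages are rounded
  to one decimal with round-half-even so printed values are
  reproducible across platforms.
* `compare_to_reference()` measures novelty against a
  KEGG/Reactome-like export. Sub-pathway names (ErbB, JNK, MAPK, ...)
  are folded into the canonical vocabulary through a user-editable
  synonym map *before* comparison; a protein listed in the reference
  under an unmapped pathway still counts as "present" (presence is
  pathway-agnostic), with a warning.

Per-pathway percentages in `summarize_predictions()` are reported
against both plausible denominators (annotations and proteins), since
published breakdowns do not always state which was used.

## Drug-target relevance and orthodisease reporting

The drug-target relevance score of `relevance_score()` is the count of
four boolean properties — membrane localization, enzymatic activity,
kinase domain, disease relatedness — that characterize established
drug targets. It is deliberately a transparent 0–4 count, not a
weighted model. `candidate_table()` ranks signalog proteins by this
score (ties broken lexicographically by id, for determinism) and
flags those not currently targeted by any drug as novel candidates.
`orthodisease_report()` lists signalogs whose ortholog in a chosen
species (typically human) is disease-linked, aggregating the
orthologs' disease names.

## The synthetic generator

`generate_dataset()` draws datasets with the statistical shape of the
curated inputs: per species pair, seed-anchored clusters with a
Poisson number of extra inparalogs per side (scores uniform on (0, 1),
rounded to 3 decimals and capped at 0.999 so seeds stay unique);
sparse annotations over clustered proteins, a fraction of which carry
a second pathway; directed interactions among annotated proteins; and
Bernoulli attribute flags. Defaults — 60 proteins per species, 80%
clustered, 0.4 extra inparalogs per cluster side, 40% of clustered
proteins annotated, 15% multi-pathway, 1.5 interactions per annotated
protein, disease rate 0.25 — were chosen once to resemble curated
signaling maps at desk scale (the multi-pathway and disease rates
match the shares observed in the curated data the method was developed
on). A single `set.seed()` at entry with a fixed stage order makes
output a byte-identical function of the config.

What the generator does *not* emulate: realistic inparalog score
distributions (real scores cluster near 1), sequence-level orthology
errors, correlated pathway structure (real pathways share components
non-uniformly), and literature-coverage bias between species. Tests
passing on generated data therefore demonstrate algorithmic
correctness — agreement with brute-force oracles, invariant
preservation, determinism — not biological performance on real
curated databases.

Alongside the generator, `load_fixture()` ships small hand-encoded
datasets reproducing published worked examples (the six
experimentally validated worm Notch signalogs with their fly/human
orthologs; the 19-row drug-target table; the worm and fly
orthodisease tables; the genome-scale summary breakdown). Attribute
flags those tables do not print are synthetic placeholders, documented
as such, chosen only to reproduce the printed derived quantities.

## Numerical and degenerate-input choices

* Identifier comparison is case-insensitive after trimming (gene
  symbol casing differs across the three species); original casing is
  preserved in output. Normalization is idempotent.
* Percentages: one decimal, round-half-even, everywhere.
* A species pair covered by no cluster yields an empty map, not an
  error; an unknown query protein yields an empty result with a
  warning.
* Proteins referenced without an attribute record receive all-false
  flags and empty lists (with a warning) rather than failing:
  attribute sources are incomplete in practice, and prediction must
  not crash on them.
* Duplicate annotation rows are collapsed with their PubMed ids
  unioned; all outputs are sorted, so identical inputs give
  byte-identical outputs.

## Problem sizes in the test suite

The property suites run against brute-force oracles on random
instances of up to ~12 proteins per species (200 instances for
ortholog mapping, 100 for prediction and interolog derivation), with
generator-level checks at up to 1000 proteins per species for the
sampling-rate bound. These sizes were chosen as the smallest at which
every structural case (multi-member clusters, multi-pathway proteins,
cross-species provenance merging) occurs routinely; the algorithms
themselves are join-based and scale far beyond them.

## Known limitations

* Transfer fidelity degrades under rapid evolution: orthologs may no
  longer share pathways, and the method has no way to detect this.
* The method cannot propose pathway members without orthologs in a
  curated species, and inherits any curation bias of its inputs.
* The interolog and reference comparisons depend on identifier
  agreement between resources; the synonym registry handles pathway
  names, but protein identifier mapping beyond case normalization is
  the caller's responsibility.
* The relevance score treats the four drug-target properties as
  exchangeable and unweighted.
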