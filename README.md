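# signalogr

Orthology-based transfer of signaling pathway membership between
species.

Curated signaling maps are uneven: a pathway deeply characterized in
one organism is often sparsely annotated in another. When pathway
membership has been curated with uniform rules across species,
orthology makes that asymmetry exploitable. `signalogr` predicts
**signalogs** — proteins assigned to a signaling pathway because an
ortholog in another species is a known member of that pathway — and
provides the supporting computations a study of such predictions
needs: interolog derivation, orthology-coverage statistics, novelty
classification, reference-database overlap, drug-target relevance
scoring and orthodisease reporting. It is written for computational
and systems biologists working with cross-species pathway curation
(worm / fly / human by default; any ≥2-species set is supported).

## The method

Orthology comes from InParanoid-style clusters: each cluster links
the proteins of one species pair, anchored by a *seed ortholog* pair
(inparalog score 1.0), with additional inparalogs scoring in (0, 1].
For a protein with more than one counterpart in its cluster, only
counterparts with inparalog score **> 0.3** (configurable) are used;
a sole counterpart is kept regardless of score. The transfer rule for
target species *t* is then:

> for every protein *p* of *t* in some cluster, every ortholog *o* of
> *p*, and every curated membership (*o*, *P*): predict (*p*, *P*)
> unless (*p*, *P*) is already curated in *t*.

All supporting orthologs are merged into one prediction per
(*p*, *P*) with full provenance. The same ortholog maps also yield
**interologs** — predicted interactions between two proteins of *t*
whose orthologs interact in another species. Predictions are graded
into five novelty classes (orthology known / function known / pathway
known) and, for drug-target work, scored 0–4 by counting four key
properties: membrane localization, enzymatic activity, kinase domain,
disease relatedness.

## Worked example

The packaged `table1_notch` fixture encodes six *C. elegans* genes
with no curated pathway role whose fly and (where present) human
orthologs are curated Notch members:

```r
library(signalogr)
ds <- load_fixture("table1_notch")
preds <- predict_signalogs(ds, "CEL")
preds
#> # A tibble: 6 × 5
#>   species protein_id pathway is_new_protein provenance
#>   <chr>   <chr>      <chr>   <lgl>          <chr>
#> 1 CEL     aqp-6      Notch   TRUE           DME:bip:1
#> 2 CEL     crb-1      Notch   TRUE           DME:crb:1;HSA:NOTCH2:1
#> 3 CEL     D1009.3    Notch   TRUE           DME:sca:1
#> 4 CEL     F10D7.5    Notch   TRUE           DME:neur:1;HSA:NEURL:1
#> 5 CEL     nsh-1      Notch   TRUE           DME:sno:1;HSA:SBNO1:1
#> 6 CEL     num-1      Notch   TRUE           DME:numb:1;HSA:NUMB:1
```

Each row is one predicted membership: `crb-1` is predicted into the
worm Notch pathway because both its fly ortholog `crb` and its human
ortholog `NOTCH2` are curated Notch members (the provenance column
lists each supporting ortholog with its inparalog score);
`is_new_protein` records that the gene had no prior pathway annotation
at all. All six genes were subsequently validated experimentally as
Notch-pathway interactors, which is why they make a good worked
example.

The same surface scales to generated data:

```r
sim <- generate_dataset(generator_config(seed = 1))
glance(predict_signalogs(sim, "CEL"))
#> # A tibble: 1 × 6
#>   species n_signalog_proteins n_annotations n_multi_pathway_proteins ...
#> 1 CEL                      44            80                       22
glance(coverage_stats(sim))
#> # A tibble: 1 × 3
#>   mean_with_ortholog mean_ortholog_signaling mean_identical_pathway
#> 1               98.2                    62.3                   26.2
```

`tidy()` expands provenance to one row per supporting ortholog;
`autoplot()` / `plot_pathway_counts()` / `plot_relevance_scores()`
draw the standard summaries. A thin command-line front end wraps the
same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/signalog.R", package="signalogr"))')" \
  predict --data data_dir --target CEL --out predictions.tsv --deterministic
```

with subcommands `predict`, `orthomap`, `interologs`,
`compare-interologs`, `annotate`, `compare`, `simulate`, `export`
(SIF/GraphML) and `stats`.

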