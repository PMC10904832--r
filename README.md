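# orthoid

Analysis pipeline for **dual-orthogonal proximity-labeling proteomics** of
organelle contact sites, with a fully ground-truthed synthetic benchmark.

## The problem

Proteins at mitochondria-associated ER membranes (MAM) sit between two
organelles and are hard to catalogue: single-enzyme proximity labeling
reports everything near one membrane face, and streptavidin enrichment is
confounded by endogenously biotinylated carboxylases. The dual-orthogonal
strategy expresses two enzymes on opposite faces of the interface — a
biotin ligase on the cytosolic face of the outer mitochondrial membrane and
a peroxidase on the luminal face of the ER membrane — and identifies
labeled proteins *by the modification mass shift on the labeled residue*:

* **Bt** (biotin) on cytosol-exposed lysines: Δm = +226.078 Da
  (C₁₀H₁₄N₂O₂S), streptavidin (SA) enrichment arm;
* **Ad** (adamantane-phenol) on ER-lumen-exposed tyrosines:
  Δm = +414.252 Da (C₂₄H₃₄N₂O₄), cucurbit[7]uril (CB7) enrichment arm.

A protein identified reliably (≥ 2 of 3 biological replicates) in **both**
arms, with an ER/mitochondria GO-style annotation and labeled sites
consistent with its membrane topology, is a MAM candidate. Comparing a
perturbed condition (the mitophagy inducer CCCP) against untreated cells by
per-site PSM counts reveals residues that become labelable when membranes
draw closer — e.g. intermembrane-space tyrosines of inner-membrane
proteins.

`orthoid` implements the full chain: elemental-composition mass calculus,
tryptic digestion and b/y fragment generation, a topology-aware simulator
of proteomes/labeling/enrichment/MS2 spectra (MGF with ground-truth
titles), a modification-aware search engine with reverse-decoy FDR control
(10 ppm / 0.02 Da, q ≤ 0.01 at PSM and protein level), parsimony protein
inference with LFQ, and the decision layer (replicate consensus,
annotation filter, arm intersection, topology validation, differential
sites).

## Worked example

```r
library(orthoid)

cfg <- pipeline_config(seed = 42, n_proteins = 80)
run <- run_pipeline(cfg, outdir = "orthoid-out", quiet = TRUE)
print(run$report)
```

```
OrthoID run report
==================
NT: SA reliable 7 (ER 3 / mito 4 / both 0), CB7 reliable 10 (ER 9 / mito 1 / both 0)
    intersection (dual) 2; precision 1.000 recall 1.000; topology violations 0
CCCP: SA reliable 6 (ER 2 / mito 3 / both 1), CB7 reliable 17 (ER 9 / mito 7 / both 1)
    intersection (dual) 1; precision 1.000 recall 0.500; topology violations 0
dual sets: 2 NT-only, 1 CCCP-only, 0 shared
differential sites: 154 total, 23 CCCP-gained, 15 NT-only
PSMs: 343 total, 343 accepted at FDR, decoy fraction 0.0000
```

Reading it: per condition, the number of reliable proteins in each
enrichment arm split by annotation class; the arm intersection is the
dual-labeled MAM-candidate set, compared against the simulator's ground
truth (precision/recall); "CCCP-gained" sites are residues with ≥ 2 PSMs
under CCCP and none untreated. Every number is recomputable from the TSV
tables the run writes next to `report.json` (`psms.tsv`, `detections.tsv`,
`calls_*.tsv`, `differential_sites.tsv`, ground truth in `truth_*.tsv`).

The individual stages are ordinary functions if you want only a part of
the chain — e.g. `digest()`, `fragment_ions()`, `build_search_space()` +
`search_spectra()` on your own MGF via `read_mgf()`, or
`topology_check()` on an external topology table. A thin CLI with
`simulate` / `run-all` / `report` subcommands ships in
`inst/scripts/orthoid-cli.R`.

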