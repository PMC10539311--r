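# chartographer

Statistical analysis of RNA–DNA contact maps from proximity-ligation
assays (ChAR-seq, GRID-seq, RADICL-seq and kin), for researchers asking
where chromatin-associated RNAs (caRNAs) sit on the genome, which of
them spread beyond their transcription locus, and whether their
contacts relate to gene regulation.

Each sequenced chimera links one RNA to one genomic locus; aggregated,
these form a sparse RNA × genomic-bin contact map per sample. On such
maps the package implements:

* **Delocalization screening.** Per RNA, the far-contact count is
  modeled as beta-binomial given the total,
  `E[N_far | N] = πN`, `var = π(1−π)N(1+(N−1)γ)`, with
  `logit(π) = η_chr + η_e ln N` fitted on mRNAs as a neutral training
  class. The fitted null acts as an empirical-Bayes prior
  (`a+b = 1/γ − 1`); the calibrated score is the posterior-vs-model
  log2 odds ratio `Δ = [logit(π_post) − logit(π_model)]/ln 2`, and the
  tail probability `P(prior draw ≥ posterior draw)` — combined across
  replicates by Fisher's method and BH-corrected — flags delocalized
  and ultralocalized RNAs in *trans* (off the source chromosome) and
  in *cis* (beyond a travel-distance threshold, 1 Mb or 10 Mb).
* **A generative null of contact placement.** Cis contacts follow a
  multinomial with probabilities ∝ DNA-locus bias × distance-decay
  kernel summed over source positions; trans contacts follow the bias
  alone, conditioned on per-chromosome totals (which simulated maps
  therefore preserve exactly). Kernel and bias are estimated from mRNA
  contacts. Observed-vs-model comparisons flag contacts not explained
  by diffusion from the locus (candidate affinity-driven peaks).
* **Interactome-space differential testing.** A per-interaction
  negative-binomial GLM engine (median-of-ratios size factors,
  moderated method-of-moments dispersion, Wald or likelihood-ratio
  tests, normal-prior LFC shrinkage) drives ES-vs-DE contact dynamics,
  relocalization screening against expression-only maps, and per-gene
  chromatin-association scores from paired contact and RNA-seq counts.
* **Classification of unannotated transcribed loci (UTLs)** by a
  seven-class priority rule over TE k-mer annotations, cis-regulatory
  elements, readthrough geometry, and antisense overlap.
* **caRNA–gene networks** over 100 kb proximal regulatory regions
  (10 kb upstream to 90 kb downstream of each TSS), with edge signs
  against gene expression dynamics and bootstrap-CI enrichment of
  positive edges over a shuffled-label null; metagene profiles around
  arbitrary feature sets.
* **A synthetic-data generator** producing pairs files, gene models,
  paired RNA-seq counts and a planted-truth table with the exact
  statistical structure above — delocalized, ultralocalized,
  XIST-like and peak-bearing RNAs — so every stage is testable end to
  end without external data.

The methods vignette (`vignettes/chartographer-methods.Rmd`) documents
the models, parameter defaults and numerical choices in detail.

## Worked example

Simulate the default study design — 3 × 30 Mb genome, 500 RNAs, two
cell states × two replicates at 2 × 10⁵ contacts each — and screen for
trans-delocalized RNAs:

```r
library(chartographer)

sim <- simulate_dataset(sim_config(), seed = 42)
res <- score_delocalization(sim$records, sim$gene_models, sim$genome,
                            sim$sample_info, mode = "trans")
table(res$per_state$category, res$per_state$state)
```

```
                  DE  ES
  delocalized     10  10
  neither        415 415
  ultralocalized  11  11
```

The dataset plants 10 trans-delocalized RNAs (logit offset +2.5), 10
trans-ultralocalized (−2.5) and one XIST-like RNA (trans mass ×10⁻³):
the screen recovers 10 delocalized and 11 ultralocalized (the planted
ultralocalized set plus the XIST-like RNA) in both states, with no
false positives among the 415 neutral RNAs scored —
`truth_report()` confirms recall = precision = 1 for every class.
Running the cis-mode screen as well identifies exactly one RNA that is
simultaneously cis-delocalized and trans-ultralocalized — the planted
XIST-like RNA (`gene0397` under this seed), which spreads over its own
chromosome while being excluded from the others.

The full workflow lives in `analysis/` as numbered drivers:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the synthetic dataset into `results/data/` |
| `02_delocalization.R` | trans/cis screens, truth report, XIST-like check |
| `03_generative_model.R` | kernel + bias fits, model maps, peak flags |
| `04_differential.R` | contact dynamics, relocalization, chromatin association |
| `05_network.R` | caRNA–gene interactome, edge-sign enrichment, metagene |

Run them in order (`Rscript analysis/01_simulate.R`, ...); each prints
its findings and writes tables under `results/`. Highlights from the
default run: the deviation detector tests 5,156 interactions and flags
0.58%, catching 4 of 5 planted 5× peaks (all of those carrying ≥200
contacts); the relocalization screen flags 0 of 2,578 interactions (by
construction nothing relocalizes); chromatin-association labels
recover all 25 planted 8×-enriched and 25 depleted genes with no false
labels; and the caRNA–gene interactome shows a 1.91× positive-edge
excess (95% CI 1.60–2.24) — an emergent consequence of contacts
concentrating near the caRNA's own locus, whose dynamics follow its
expression.

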