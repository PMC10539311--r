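---
title: "Statistical models behind chartographer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical models behind chartographer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

chartographer analyses RNA-DNA contact maps from proximity-ligation
assays (ChAR-seq and kin), in which each sequenced chimera links one
chromatin-associated RNA (caRNA) to one genomic locus. This vignette is
the package's account of its statistical machinery: the models, their
assumptions, the tunable parameters, the numerical choices, and what
the synthetic-data validation does and does not establish.

## Data model and conventions

A contact is a record with an RNA side (gene of origin, mapping
coordinate, strand) and a DNA side (chromosome, coordinate, strand).
Internally all coordinates are 0-based half-open, matching BED; the
on-disk pairs dialect is 1-based (pairs-format convention) with a
`#columns:` header naming the ten fields, RNA side first. Contacts are
aggregated into sparse RNA x bin count matrices over either a uniform
tiling of the genome (100 kb and 1 Mb are the working resolutions) or
explicit windows such as gene-proximal regions. Bin assignment is by
the DNA coordinate's containing bin: the DNA side is a point, not an
interval. Records on chromosomes outside the declared genome (scaffold
contigs) are skipped with a warning rather than an error.

The signed travel distance of a cis contact is
$\delta = d - r$, the DNA coordinate minus the RNA coordinate; only
$|\delta|$ enters the models, the sign is kept for profile plotting.

## Delocalization scores

The screen asks, per RNA and per sample, whether the RNA contacts
chromatin far from its locus more (or less) often than a neutral RNA
of the same expression and chromosome of origin would.

**Counts.** In trans mode, $N_i$ is the RNA's total contact count and
$N_{\mathrm{far},i}$ the count on chromosomes other than its own. In
cis mode only same-chromosome contacts enter, split at a travel
distance threshold $D$ (default 1 Mb; 10 Mb is exposed for
chromosome-scale spreading, and both conventions appear in the
literature — neither is privileged here). A contact at exactly
$|\delta| = D$ counts as near.

**Null model.** Conditional on $N_i$, the far count is modeled as
beta-binomial,
$$\mathrm{E}[N_{\mathrm{far},i}\mid N_i] = \pi_i N_i, \qquad
\mathrm{var} = \pi_i(1-\pi_i)N_i\,(1 + (N_i-1)\gamma),$$
with a logit-linear mean
$\mathrm{logit}(\pi_i) = \eta_{\mathrm{chr}(i)} + \eta_e \ln N_i$
(one intercept per chromosome, no global intercept) and a single
overdispersion $\gamma$ shared by all RNAs. The model is fitted by
maximum likelihood on a training class — mRNAs, on the premise that
bulk mRNA has no specific far-targeting — after removing RNAs with
fewer than 50 contacts. $\gamma$ is the beta-binomial intraclass
correlation, so the implied Beta prior concentration is
$a+b = 1/\gamma - 1$; this mapping is the package's choice of
parameterization, fixed throughout. Optimization is BFGS with
$\gamma$ on the logit scale, initialized from a binomial GLM plus a
method-of-moments overdispersion estimate, with three random restarts
on failure; standard errors come from the numerical Hessian.
Chromosomes without training RNAs inherit the mean fitted intercept,
with a warning.

**Empirical-Bayes update.** The fitted null provides, at each RNA's own
covariates, a conjugate prior
$\mathrm{Beta}(\pi_i(1/\gamma-1),\,(1-\pi_i)(1/\gamma-1))$; adding the
observed far/near counts gives the posterior and the shrinkage
estimate $\pi_{\mathrm{post},i}$ (its mean), which always lies between
the model prediction and the empirical proportion. If $\gamma$
degenerates to zero the prior collapses; the implementation then falls
back to a unit pseudo-count prior around the model prediction and says
so.

**Calibrated score.** The score is the posterior-vs-model log odds
ratio in log2 units,
$$\Delta_i = \left[\mathrm{logit}(\pi_{\mathrm{post},i}) -
\mathrm{logit}(\pi_{\mathrm{model},i})\right] / \ln 2 .$$
This reading reconciles "difference of logits" with "log2-transformed
ratio of the shrinkage estimate over the model prediction": it is both,
on the odds scale. A natural-log variant is available via a flag.
Rates are clipped to $[10^{-12}, 1-10^{-12}]$ before the logit.

**Tail probability.** Significance compares a draw $X$ from the
posterior with a draw $Y$ from the prior at the same covariates.
The exceedance $P(X > Y)$ is computed by deterministic quadrature of
$\int f_X(x) F_Y(x)\,dx$ to absolute tolerance $10^{-8}$ (a flagged
Monte-Carlo fallback with $10^6$ draws covers quadrature failures).
The p-value for the delocalized side is defined as
$p_{\mathrm{deloc}} = 1 - P(X>Y) = P(Y \ge X)$, small when the
posterior sits above the prior, and $p_{\mathrm{ultra}} =
1 - p_{\mathrm{deloc}}$ for the other tail. The direction convention
matters: the exceedance itself is near 1 for a strongly delocalized
RNA, so it is its complement that plays the role of an upper-tail
p-value. Under null data either tail is uniform, so the caller cuts
off the expected 5% of the training-class distribution at the 0.05
level — the package ships `null_tail_calibration()`, which verifies
exactly this end to end.

"A draw from the model" is interpreted as a draw from the prior at the
RNA's own covariates, not a draw over the mRNA roster; this is the
calibrated choice (covariate-matched comparisons), and the one under
which the uniformity above holds.

**Replicates and classification.** Per cell state, replicate p-values
are combined with Fisher's method ($-2\sum\ln p$, $\chi^2$ with
2 x replicates df), separately per side; p-values are floored at
$10^{-300}$ before the log. Benjamini-Hochberg correction is applied
across RNAs within each (state, side) family, and an RNA is called
delocalized or ultralocalized below FDR 0.05. $\Delta$ is summarized
as the arithmetic mean over replicates. Fisher combination is per
state (df = 4 with two replicates), not pooled across states.

## The generative contact-map model

The null for peak detection is a fully generative model of where an
RNA's contacts land, given how many it makes per chromosome:

* cis, for RNA $i$ with source positions $\{r_{i,k}\}$:
  $\mathrm{Multinomial}\!\left(N_{i,\mathrm{cis}},\;
  p_j \propto b_j \sum_k \rho(d_j - r_{i,k})\right)$ over the source
  chromosome's bins, $d_j$ the bin midpoint;
* trans, per chromosome $c$:
  $\mathrm{Multinomial}(N_{i,c},\; p_j \propto b_j)$ renormalized
  within the chromosome.

Because the model conditions on the observed per-RNA per-chromosome
totals, simulated and observed totals agree exactly — this is asserted,
not approximated.

The distance kernel $\rho$ is estimated as a histogram of $|\delta|$
from mRNA cis contacts over log-spaced bins (25 per decade from 100 bp
to the longest chromosome, plus a linear bin below 100 bp), converted
to per-bp density and mixed with a small uniform floor (weight 0.01 by
default) so unobserved distances keep non-zero probability; the
density integrates to 1. The kernel is symmetric in $\delta$; strand
or orientation asymmetry is not modeled. The DNA-locus bias $b_j$ is
the coverage at bin $j$ summed over mRNAs whose source chromosome
differs from the bin's chromosome (so no cis structure leaks in), plus
a pseudocount of 0.5 per bin, normalized genome-wide. Kernel binning,
the floor, and the pseudocount are package defaults — the histogram
resolution is a bias/variance trade-off, and the pseudocount guards
zero-probability bins.

Source positions for prediction default to the gene midpoint; callers
can supply per-gene position sets (e.g. sampled from the observed
RNA-side coordinates) where gene bodies are long relative to the bin
size. Exact per-position convolution is what `cis_probabilities()`
computes; at the working resolutions midpoint evaluation is the
operative approximation.

## Interactome-space differential testing

Differential questions — ES vs DE dynamics, observed vs model, observed
vs expression-only, contact vs RNA-seq abundance — are all posed as
per-interaction count regressions, with (RNA, locus) pairs as rows and
samples as columns, mirroring differential-expression practice.
Interactions with fewer than 10 reads in fewer than 2 samples are
dropped, the filter being evaluated on the observed samples only when
synthetic comparison columns (model or expression-only maps) are
present.

The engine is deliberately simple and fully specified. Per row:

1. **Normalization.** Median-of-ratios size factors, optionally from a
   row subset (the chromatin-association analysis restricts the
   reference to well-covered rows so that length/representation biases
   do not leak into the factors); factors are rescaled to geometric
   mean 1 and enter the GLM as offsets.
2. **Dispersion.** A method-of-moments estimate conditional on the
   design cells, floored at $10^{-8}$, shrunk 50/50 toward the trimmed
   mean (trim 0.1) dispersion of rows in the same mean-quantile
   stratum, and then floored at that stratum trend. The final floor is
   asymmetric on purpose: the Wald statistic plugs the dispersion in
   as known, so per-row underestimates inflate it, while overestimates
   merely cost power. Without the floor the null type-I rate at
   $\alpha = 0.05$ with two replicates per condition sits near 0.09;
   with it, 0.058-0.069 across simulation seeds.
3. **Test.** A negative-binomial log-link GLM with the dispersion
   plugged in; Wald z-test with information-based standard errors by
   default. The observed-vs-model and relocalization contrasts use a
   likelihood-ratio test on the same fits instead, because those
   designs routinely contain all-zero cells (an RNA absent from a
   locus in one map type), where the Wald statistic degenerates
   (Hauck-Donner collapse) and the LRT does not.
4. **Shrinkage.** Shrunken log2 fold changes from a zero-centered
   normal prior whose scale is the empirical SD of the raw LFCs —
   a one-parameter analogue of heavier-tailed shrinkage estimators.
   Calibration and recovery of this engine are what the test suite
   certifies; it does not attempt to reproduce any other
   implementation's numbers.

Flag thresholds follow the source conventions: deviations from the
generative model require shrunken LFC $> \log_2(1.3) \approx 0.379$
and adjusted p $< 0.05$ (the alternative reading, a threshold of 1.3
on the LFC value itself, is available by argument); relocalization
requires only the interaction-term adjusted p; chromatin-association
labels require adjusted p $< 0.05$ and |score| $> \log_2 3$ (again
with the threshold exposed, as the fold-change-of-3 convention can be
read on either scale). Reference-level switching (refitting with the
other state as baseline) produces per-state coefficients rather than
recombined contrasts.

## UTL classification

Unannotated transcribed loci are classified by a priority rule over
four tags: dominant transposable-element family and TE-score (the
dominant family's reads over *all* the locus's reads, unlabeled
included; ties break lexicographically and are logged), proximity of
the 5' end to an ATAC-active cis-regulatory element (within 300 bp;
subtype from the ES annotation when active in ES, else DE), a
readthrough window around annotated 3' ends, and antisense overlap
(at least 10% of the UTL covered by opposite-strand gene bodies,
union across genes). The priority order is: tRNA (score > 0.10),
small-RNA families (score > 0.10), readthrough, CRE-derived,
repeat-derived (score > 0.50), antisense, intergenic — first match
wins, so every locus gets exactly one class.

Two geometric conventions are decisions, not reproductions: the
readthrough window runs from 200 bp inside the gene body to 100 bp
past the 3' end, oriented by the gene's direction of transcription,
and the UTL must continue on the gene's own strand (readthrough
transcription does); an any-strand variant is exposed.

## caRNA-gene networks

Each gene's proximal regulatory region (PRR) is the 100 kb window from
10 kb upstream of the TSS to 90 kb into the gene, strand-oriented and
clipped at chromosome ends — the only reading of "+10 kb upstream and
-90 kb downstream" that yields the stated extents. Contacts landing in
overlapping PRRs count once per containing gene, since density is
defined per gene.

Differential caRNA-gene contacts are classified against the expression
dynamics of both partners: positive when contact and target gene move
up in the same state, negative when opposite, neutral when the gene is
stable; stable contacts yield no edge. On the subset of edges whose
caRNA is itself differentially expressed, the positive-edge fraction
is compared with a null in which gene labels are shuffled across genes.
The null mean averages 1,000 permutations (the mean is linear in label
proportions, so this estimates a closed form; the permutations are
kept for transparency and for the permutation p-value). The confidence
interval of the fold comes from resampling edges with replacement —
10,000 times by default — with the per-resample null computed from the
resample's label and contact-class composition; enrichment is declared
when the 95% CI excludes 1.

Metagene profiles average an RNA's contacts in fixed windows around a
feature set and divide by the RNA's genome-wide mean contacts per bin,
so flat background reads 1.

## The synthetic-data generator

Every analysis above is validated on data from `simulate_dataset()`,
which draws contacts from the same statistical structure the models
assume: multinomial totals from log-normal expression weights (two
states, log-fold-changes planted for 20% of RNAs at |ln FC| = ln 4),
a beta-binomial cis/trans split on the logit-linear null
($\gamma = 0.02$, chromosome intercepts at rates 0.30-0.40,
$\eta_e = 0.1$), bin-level multinomial cis placement under a truncated
power-law kernel ($\rho(\delta) \propto (|\delta| + 5\,\mathrm{kb})^{-1.2}$
with a 5% uniform floor — a parametric stand-in for the empirical decay,
chosen so recovery can be checked against a closed form) times a
log-normal DNA bias, and bias-proportional trans placement. Planted
effects: logit offsets of ±2.5 for trans/cis delocalized and
ultralocalized RNAs; one XIST-like RNA whose trans mass is multiplied
by $10^{-3}$ (kept positive to avoid degenerate likelihoods) and whose
cis far mass is tilted up; five RNAs with 100 kb peak regions 0.5-1.5 Mb
from their TSS at 5x placement probability. Paired RNA-seq counts are
drawn so each gene's contact:RNA-seq abundance ratio equals its planted
chromatin-enrichment factor (8x for 25 genes, 1/8 for 25).

The default scale — 3 chromosomes x 30 Mb, 500 RNAs, 2 x 10^5 contacts
per sample, 2 states x 2 replicates — is a desk-scale design chosen so
the full pipeline runs in minutes while every detector operates in its
intended regime. Two abundance conventions serve that regime: RNAs
carrying planted delocalization effects get a 4x expression multiplier
and peak-bearing RNAs 25x, because a detector specified for RNAs with
hundreds of contacts (or peaks carrying hundreds of reads) cannot be
exercised by RNAs drawn at the roster median — in the real data, too,
the detectable broad-pattern and peak-bearing RNAs are the abundant
ones. Source positions within gene bodies are drawn uniformly per
contact, emulating fragmentation; placement probabilities integrate
the kernel over 15 evenly spaced source positions per gene.

What the generator does *not* emulate — and therefore what passing
tests cannot certify on real data: 3D genome structure (TADs, loops,
A/B compartments) that correlates contacts across loci; sequence- or
mappability-driven artifacts; chromosome-scale heterogeneity of the
distance decay; intron/exon structure within genes; and any coupling
between an RNA's delocalization and its expression dynamics. The
validation establishes internal correctness and calibration of the
statistics under their own assumptions, not robustness to the ways
real chromatin violates them.

## Numerical choices, in one place

* Beta exceedance: quadrature between the $10^{-12}$ and $1-10^{-12}$
  quantiles of $X$, absolute tolerance $10^{-8}$, 500 subdivisions;
  Monte-Carlo fallback with $10^6$ draws, flagged by a warning.
* Fisher combination: p floored at $10^{-300}$.
* Logit clipping at $10^{-12}$.
* Beta-binomial MLE: convergence by relative tolerance $10^{-12}$ in
  BFGS; three jittered restarts; error with diagnostics afterwards.
* Dispersion floor $10^{-8}$; stratum count 20; trim 0.1.
* Bias pseudocount 0.5; kernel floor weight 0.01 (estimation) and
  0.05 (simulation truth).
* Test-suite problem sizes: the shared synthetic dataset above;
  2,000-RNA cohorts for GLM recovery and tail calibration; 5,000-row
  null simulations for engine calibration; 50 repeats of 5,000-edge
  bootstrap recovery.

## Known limitations

The beta-binomial GLM assumes a single $\gamma$ across RNAs; strongly
class-dependent overdispersion would miscalibrate the tails for the
affected classes. The NB engine's Wald test with plugged-in dispersion
is mildly anticonservative at two replicates (0.06-0.07 at nominal
0.05) — by design it trades exactness for simplicity, and the
calibration band in the test suite reflects that. Model deviations are tested per bin;
peaks split across bin boundaries lose power, and peaks whose location
coincides with high model density (close to the locus, or in
high-bias bins) are intrinsically harder to flag. The edge-sign null
conditions on label counts but not on genomic position, so spatial
autocorrelation of expression would inflate apparent enrichment on
real data.
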