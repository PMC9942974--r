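---
title: "Quantifying escape from X-inactivation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying escape from X-inactivation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciescape)
```

## The inference problem

A bulk RNA-seq sample from a female tissue is a mosaic of cells, each with
one of the two parental X chromosomes inactivated. Let $p$ denote the
fraction of cells in which the haplotype-A X is active. A gene with escape
ratio $e$ (expression from the inactive X as a fraction of expression from
the active X, $e \in [0, 1)$) contributes haplotype-A and haplotype-B
expression proportional to

$$m_A = p + (1 - p)\,e, \qquad m_B = (1 - p) + p\,e,$$

so its expected allelic fold change is
$\mathrm{aFC} = \min(m_A, m_B) / \max(m_A, m_B)$. Two consequences drive the
whole design:

* At $p = 0.5$ (random XCI), $\mathrm{aFC} = 1$ for every gene — escape is
  invisible in bulk. Only samples with skewed XCI are informative, which is
  why the pipeline classifies samples by skew first and scores escape only
  in skewed ones.
* Even within skewed samples, $\mathrm{aFC}$ of a silenced gene depends on
  the degree of skew ($\mathrm{aFC} = (1-p)/p$ at $e = 0$, for $p > 0.5$).
  Comparing raw aFC values across samples of different skew therefore
  biases escape estimates; the escape score removes this dependence by
  regressing aFC on skew and working with residuals.

`expected_afc()` exposes the closed form above; the test-suite uses it as an
independent oracle for the simulator.

## Pipeline stages

**Allelic observations and QC.** From haplotype read counts, `apply_qc()`
computes $\mathrm{ASE} = AC/TC$ and
$\mathrm{aFC} = \min(AC,BC)/\max(AC,BC)$ and applies two filters: total
allelic depth $\ge 8$ reads (boundary inclusive), and detection of both
haplotypes in the RNA at least once. The depth threshold bounds the
worst-case aFC granularity (at depth 8 the smallest non-zero aFC is 1/7)
while keeping typically expressed genes. Zero-depth records are dropped
with a logged count rather than raising an error, and the attrition table
attached to the output partitions every input record into
zero-depth / low-depth / single-haplotype / retained.

The both-haplotype rule exists to guard against mis-genotyped (homozygous)
sites, whose RNA is perfectly monoallelic in every sample. Its natural
scope is ambiguous: applied per sample it would also discard genuinely
silenced genes in strongly skewed samples — observations the method must
score near 0, not discard. The default therefore pools all samples of an
individual (heterozygosity is a property of the genotype, not of one
library); a strict per-sample mode is available via
`xci_config(both_haplotype_scope = "sample")`.

**Skew calling.** `call_skew()` uses the *XIST* observation of each sample:
$DS = |0.5 - XIST_{ASE}|$, skewed iff $DS \ge 0.3$ (equivalently
$XIST_{ASE} \le 0.2$ or $\ge 0.8$). The *XIST* record must pass the depth
filter but is deliberately exempt from the both-haplotype rule: a
completely skewed sample shows monoallelic *XIST* by construction, and
requiring both haplotypes would discard exactly the most informative
samples. Samples without a usable *XIST* record are carried as
`unavailable` and excluded from scoring.

**Escape model and score.** `fit_escape_model()` pools every retained
observation of every skewed sample — all tissues, including any excluded
from downstream calls — and fits one OLS line of aFC on DS. Residuals are
min–max rescaled over the fitting set:
$\mathrm{EscScore}' = (\mathrm{EscScore} - \min)/(\max - \min)$. OLS
orthogonality guarantees zero correlation between the rescaled scores and
DS; the tests assert this at $10^{-10}$. The *XIST* gene itself is excluded
from the fit and the scores: it is the skew instrument, and regressing it
on its own allelic ratio would be circular.

Design choices here that were genuinely open:

* *Pooling.* One global regression rather than per-tissue fits: the score
  is meant to be comparable across tissues, and the aFC–DS dependence is a
  property of the mosaic arithmetic, not of the tissue. A per-tissue mode
  (`per_tissue_fit = TRUE`) exists for sensitivity analysis.
* *Rescaling scope.* A single global min–max over the fitting set. The
  extremes are sensitive to outlier residuals; faithfulness to the plain
  min–max definition is the default, with an optional quantile-based
  rescale (`rescale_quantiles = c(0.005, 0.995)`) as the robust variant.
* *Out-of-cohort scoring.* `score_new_samples()` scores additional skewed
  samples (e.g. purified immune cell types) against the persisted line and
  extremes, clipping to $[0,1]$ with a `clamped` flag, rather than
  refitting — so scores stay on the cohort scale. The persisted model is
  five plain-text numbers (`write_escape_model()`).
* *Degenerate inputs.* All-identical DS values and all-identical residuals
  (a perfectly linear fitting set) raise errors rather than producing a
  zero-width rescale; the residual-width test uses an absolute tolerance of
  $10^{-12}$ so that float noise in an exactly-linear synthetic set is
  still recognised as degenerate.

**Calls.** `call_gene_tissue()` takes the median EscScore per gene and
tissue over skewed samples (all samples pooled, including co-twins and
repeat samples of an individual), requires $\ge 3$ samples, and calls
escapee at median $\ge 0.36$ (boundary inclusive). Whole-blood samples are
excluded from calls and downstream analyses by default while still
supporting the model fit, reflecting their typically sparse overlap with
other tissues; the exclusion list is configuration. The 0.36 default sits
where benchmarking against an annotated XCI catalogue
(`benchmark_thresholds()`) balances concordance, and the benchmark sweep is
exposed so users can re-derive a cutoff for their own data. Ties need no
special handling anywhere: medians at exactly the cutoff are escapees by
the $\ge$ rule, and equal counts give $\mathrm{aFC} = 1$ by formula.

**Variability and twins.** `intra_donor_summary()` restricts to donors
with scored skewed samples in every analysed tissue and bins each
fully-scored gene by the number of tissues in which it escapes.
`consistency_call()` labels a gene consistent in a tissue when $\ge 80\%$
of individuals (one median score per individual, $\ge 10$ individuals) lie
within one standard deviation of the gene's mean; the population standard
deviation (divisor $n$) is the default since the band is descriptive, not
inferential — a zero standard deviation trivially places everyone inside
the band. `group_difference_test()` wraps the Kruskal–Wallis test with
mid-ranks and tie correction. `twin_pair_stats()` requires complete pairs
(both co-twins skewed in the analysis tissue), correlates co-twin score
vectors over $\ge 5$ shared genes, and computes the discordance rate (gene
escaping in exactly one co-twin). Spearman correlation is the default —
scores are bounded and the rescaling makes only ranks comparable with
confidence — with Pearson behind a flag; the zygosity comparison uses a
Welch t-test on the per-pair coefficients, optionally after a Fisher-z
transform.

## The simulator

`simulate_dataset()` inverts the inference model generatively:

* Per sample, a skew fraction $p$; per gene–tissue–individual, an escape
  ratio $e$; haplotype-A reads are Binomial (optionally beta-binomial)
  around $\pi_A = (p + (1-p)e)/(1+e)$ at negative-binomial total depth
  (defaults: mean 50, size 5 — no published per-gene allelic depth
  distribution exists for this setting, so these are package choices,
  exposed in the configuration). *XIST* is drawn with expected haplotype-A
  fraction $1 - p$.
* Escape ratios are hierarchical on the logit scale: class-specific gene
  baselines (silenced concentrated near 0; escape on roughly 0.3–0.8,
  since tissue-level escape ratios above 0.8 are rarely observed; variable
  wide), a gene-by-tissue effect shared across individuals
  (`tissue_effect_sd`, default 0.4), and a gene-by-individual perturbation
  (`individual_sd`) whose variance is split by `heritability_weight`
  (default 0.6) into a genetic part — identical in MZ co-twins, correlation
  0.5 in DZ co-twins — and an independent environmental part. Genes of the
  `variable` class get both perturbations inflated
  (`variable_sd_factor = 3`). The logit parameterisation keeps
  $e \in [0, 1)$ without truncation artifacts.
* `individual_sd = 1.75` was calibrated so that complete twin pairs in the
  simulation show co-twin score correlations in the regime reported for
  adult twin cohorts (monozygotic around 0.6, dizygotic around 0.45); it
  encodes substantial inter-individual escape variability.
* The skew distribution is a symmetric two-component Beta mixture: weight
  0.3 on a U-shaped near-extreme component (`Beta(0.35, 0.35)`) and the
  rest on a central component (`Beta(8, 8)`). A single U-shaped Beta
  cannot simultaneously be U-shaped and leave skewed samples in the
  minority at the 0.2/0.8 rule; the mixture reproduces the 14–32%
  per-tissue skew rates seen in adult cohorts while keeping genuinely
  extreme samples present. Skew is drawn per sample by default
  (`skew_by_individual = TRUE` shares one draw across an individual's
  tissues).
* Per gene and individual, heterozygosity (measurability) is Bernoulli
  (`het_prob = 0.7`); *XIST* is always measurable so that skew can be
  called. Genes with reads on only one haplotype arise naturally, so QC
  paths are exercised without special-casing.
* The default cohort is 17 MZ pairs, 10 DZ pairs and 46 singletons across
  LCL, adipose and skin (availability 1 / 0.8 / 0.8), and the derived
  reference annotation simply maps the true gene classes — it is a
  synthetic stand-in for a published catalogue, not a copy of one.

What the simulator does **not** emulate: mapping bias and phasing switch
errors, genotyping error beyond missingness, dependence of depth on
expression level or of *XIST* expression on skew, cell-type composition
within a tissue, age effects on skew, and linkage between neighbouring
genes' escape (each gene is independent given its class). Passing
recovery tests therefore demonstrates that the estimator inverts its own
generative assumptions at realistic noise levels — not that those
assumptions exhaust real data.

## Validation problem sizes

The test-suite checks, among others: exact boundary behaviour of every
threshold (depth 8, DS 0.3, cutoff 0.36, 3-sample gate, 80%/10 consistency
rule, 5-gene twin gate); the analytic score–skew orthogonality at
$10^{-10}$; agreement of the hypergeometric overlap p-value with exhaustive
tail summation and of the Kruskal–Wallis statistic and p-value with a hand
rank-sum formula and a permutation null; ground-truth recovery on the
default cohort (200 genes, around 60 skewed samples: rank agreement between
true mean escape ratios and median scores, and separation of simulated
silenced from escape genes at the 0.36 cutoff); and twin heritability
recovery over 100 replicate cohorts of 17 MZ + 10 DZ complete pairs
(all-skewed configuration, mirroring a complete-pair selection) with a
matched null at zero heritability. These sizes keep the full suite within a
few minutes on a single core while leaving Monte-Carlo margins wide.

## Known limitations

* Min–max rescaling ties the score scale to the two most extreme residuals
  of the fitting cohort; scores from different cohorts are not directly
  comparable unless scored against the same persisted model.
* The escape score is relative: 0 and 1 are anchored at the cohort's
  extremes, not at biological silencing/escape, so the escape cutoff should
  be re-benchmarked when cohort composition changes substantially.
* With few complete twin pairs the zygosity comparison is underpowered and
  reported means are noisy; the per-pair table carries `valid` flags so
  users can apply stricter gates.
* Whole-blood exclusion, the analysis tissue for twins, and the XIST gene
  identifier are configuration, not detection — mislabelled sample sheets
  propagate silently.
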