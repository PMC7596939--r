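---
title: "metaRegulon: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{metaRegulon: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaRegulon)
```

# The problem

MicroRNAs and transcription factors regulate overlapping target sets, and
which of their potential interactions are *active* depends on the disease
context. metaRegulon infers context-specific regulation in two stages:

1. **Static potential.** Interactome evidence — CLASH chimeric reads for
   miRNA–mRNA binding, ChIP peaks near transcription start sites for TFs —
   is converted into a regulatory score RS per (regulator, gene) pair, then
   competitively normalized to RS′ so each regulator's total influence is
   partitioned across its targets.
2. **Context-specific activity.** For every gene, its per-sample log2
   expression change is regressed on the RS′-weighted expression changes of
   its candidate regulators, adjusting for copy-number and methylation
   background. Subset selection, FDR pruning and resampling-based consensus
   yield the final interaction calls.

# Interactome confidence and filtering

Each binding site with chimeric support $C_{ijk}$ out of a grand total
$C_{all}$ receives the upper-tail binomial p-value

$$p_{ijk} = \sum_{c=C_{ijk}}^{C_{all}} \binom{C_{all}}{c}\,
  \pi^{c}(1-\pi)^{C_{all}-c},$$

followed by a Bonferroni gate at 0.05, removal of the bottom 10% of
low-confidence survivors, and a hard floor of 12 supporting reads.

**The null rate.** Taken verbatim, $\pi = C_{ijk}/C_{all}$: a null centred
on the observation itself. Its tail probability never drops much below 0.4,
so under the verbatim rate the Bonferroni gate removes *every* site —
`bindingSitePValue()` implements it as the default for fidelity, but it is
a degenerate test. The pipeline therefore defaults to an expectation-based
rate, `null_rate = "independence"`, which sets
$\pi_0 = (C_i/C_{all})(C_j/C_{all})$ — the chance that a random chimeric
read pairs this miRNA with this mRNA if reads combined independently. Sites
are then significant when their support exceeds that expectation. The
verbatim behaviour remains reachable with `null_rate = "observed"`, and any
fixed numeric rate may be supplied.

**Ranking for the bottom-10% stage.** Confidence is defined only through
the p-value, so survivors are ranked by adjusted p-value (largest = worst),
ties broken by ascending read support and then site id; the number dropped
is `floor(0.10 * n)` — deterministic and conservative. Whether this stage
should run before or after the significance gate is ambiguous; it runs
after, matching the reading that the two extra filters are "additional".

# Regulatory scores

For miRNAs, the per-site binding probability combines chimeric and single
(unbound) read totals,

$$P_{ijk} = \frac{C_{ijk}^2}{(C_i + M_i)(C_j + M_j)},$$

and the pair score averages probability-weighted duplex stability over the
pair's $K$ sites, $RS_{ij} = \frac1K \sum_k |MFE_k| P_{ijk}$ (MFE in
kcal/mol; more negative = more stable, hence the absolute value).

For TFs the score decays exponentially with peak-to-TSS distance $d$ (bp):
$RS_{tjk} = e^{-(0.5 + 4d/10^5)}$, i.e. $e^{-0.5}\approx 0.607$ at the TSS
with a 25-kb e-folding scale, and sites combine by noisy-OR,
$RS_{tj} = 1-\prod_k (1-RS_{tjk})$. Distances use the unstranded peak
*midpoint*, the least biased single point given no shape information, and
candidate pairs are enumerated within a ±100 kb window — beyond it the
score is below $e^{-4.5}\approx 0.011$ and contributes nothing while
keeping enumeration linear. Overlapping peaks of the same TF are *not*
merged; each contributes a site.

Normalization divides by the regulator's score total,
$RS'_{ij} = RS_{ij}/RS_i$ — the explicit formula, preferred over a count
interpretation of its accompanying description — so per-regulator RS′ sums
to exactly 1 (a class invariant of `RegulatoryScoreTable`).

# The per-gene meta-regression

For gene $j$ across the $S$ disease samples of a condition, with
$\Delta g_{js} = \log_2(g_{js}/\bar g_{j,ctrl})$:

$$Y = X_1\beta_1 + X_2\beta_2 + \epsilon,$$

where $X_1$ holds the gene's CNV and methylation changes (cancer cohorts;
empty otherwise) and $X_2[s,r] = \Delta reg_{rs}\, RS'_{rj}$ is the
score-weighted regulator-change design, TFs first then miRNAs. The
background is projected out by the Frisch–Waugh–Lovell annihilator
$M = I - B(B'B)^{-1}B'$; since every fitted model carries an intercept, the
intercept is part of the background block, $B = [\mathbf 1\; X_1]$, which
makes the residualized coefficients exactly equal the $X_2$-block of the
joint fit. The degrees of freedom absorbed by $B$ are carried forward so
residual variances and t-tests remain exact after the transform.

**Subset selection.** Candidate subsets are scored by Mallows's
$C_p = SSE_p/\hat\sigma^2 - S + 2p$ with $\hat\sigma^2$ from the full
candidate model and $p$ counting the intercept. Search is exhaustive up to
15 candidates (32,768 subsets; the enumeration works on the Gram matrix in
compiled code, so each subset costs one small symmetric solve) and greedy
forward beyond that, keeping the best $C_p$ seen along the path.

**Guards.** Exact duplicate design columns are dropped (first kept) before
fitting. When the candidate count approaches the sample count
($R \ge S-3$), a prescreen keeps the $\lfloor S/3\rfloor$ candidates most
correlated with the residualized response, keeping the full-model variance
estimate well defined. A perfect full-model fit ($\hat\sigma^2 = 0$)
degenerates to the full model with a warning rather than an undefined
$C_p$.

**Significance.** Regulators are pruned by Benjamini–Hochberg adjusted
coefficient t-tests at Q < 0.05, per gene. Two inference modes exist:

* `inference = "full"` (default): p-values come from the *full* candidate
  model, BH runs across all of the gene's candidates, and the reported set
  is the intersection of the Cp selection with the q-gate. Because the
  p-values are not conditioned on selection, a gene with no true regulators
  emits any call with probability at most the nominal level — the null
  behaviour a screening tool must have.
* `inference = "selected"`: t-tests inside the Cp-selected model, BH across
  the selected set only. This is the textbook post-selection fit, but
  Cp-selected null columns have |t| > √2 by construction, so their
  "p-values" concentrate below 0.16 and the procedure is strongly
  anti-conservative under the null (in the package's own null benchmark it
  calls regulators for roughly a third of truly null genes, versus ~3% for
  the default mode). It is retained for comparison, not recommended.

# Consensus over randomized datasets

Twenty randomized datasets are generated and refit; a (gene, regulator)
pair's **consistency** is the fraction of splits in which its coefficient
is nonzero, i.e. the regulator entered the split's selected model. The
final call set keeps pairs that are in the original-dataset call set *and*
reach consistency ≥ 0.7. The threshold is taken as operative over the
stricter "detected in all splits" phrasing; that reading is exactly
`consistency = 1` and remains available. Split-level detection uses the
selected model's nonzero coefficients without the q-gate — the q-gate
expresses significance in the original fit, while consistency measures
selection stability — and the summarized coefficient is the median of the
nonzero split coefficients (robust to the occasional unstable refit), with
the original-fit coefficient reported alongside.

What the 20 "randomized datasets" randomize is a genuine design choice:

* `strategy = "subsample"` keeps a without-replacement 80% of disease
  samples per split (all controls retained);
* `strategy = "oversample"` augments the cohort with multiplicative-noise
  copies (below);
* `strategy = "auto"` (default) oversamples cohorts with fewer than 30
  disease samples — the regime that motivates augmentation — and
  subsamples larger ones.

# Over-sampling small cohorts

A new sample is an existing disease profile multiplied elementwise by a
variation vector with i.i.d. Uniform(0.95, 1.05) entries; originals are
retained. The symmetric ±5% band is the default — it perturbs without
biasing the mean profile downward — and a one-sided Uniform(0.95, 1)
variant is a configuration away (`noise_high = 1`). Source samples are
drawn uniformly
with replacement, preserving the empirical distribution in expectation.
CNV/methylation columns of a synthetic sample are copied from its source.

# The synthetic-data generator

`simulateGroundTruth()` + `simulateCondition()` implement the generative
counterpart of the regression model: regulator log2 changes are i.i.d.
standard normal, backgrounds (when enabled) standard normal with fixed
per-gene coefficients (0.5 for CNV, −0.5 for methylation), and

$$\Delta g_{js} = X_1\beta_1^* + \sum_r RS'_{rj}\,\Delta reg_{rs}\,
  \beta^*_{2,rj} + N(0,\sigma).$$

Changes are exponentiated around a constant control baseline of 100, so
the preprocessing recovers them exactly. Defaults: 10 scored candidates
per gene of which 3 carry true effects with magnitudes uniform in
[0.5, 1.5] and random sign, noise sd σ = 0.2, and a regulator pool sized
so each regulator targets about 3 genes. That target multiplicity keeps
normalized scores in roughly [0.1, 0.5] — at desk scale (a handful of
genes) it plays the role that target-set dilution plays genome-wide, and
it fixes the signal-to-noise ratio of the benchmark: a true effect of 0.5
on a pair with RS′ ≈ 0.2 has a t-statistic near 4 at S = 60.

`simulateInteractome()` emulates chimeric-read tables: true sites draw
counts of `ceiling(depth/2) + NegBin(mu = depth/2, size = 8)` (an
overdispersed draw whose floor guarantees read-support survival at
sufficient depth), decoys draw `1 + Poisson(2)`, MFE is uniform in
[−25, −5] kcal/mol, and single-read totals are drawn per entity so the
abundance identities hold by construction.

What the generator does **not** emulate: regulator–regulator correlation
(co-expression of miRNAs in a cluster), non-Gaussian and heteroscedastic
expression noise, measurement error in the regulator profiles, mismatched
interactome and expression contexts, and realistic genome geometry beyond
what distance scoring needs. Passing the recovery benchmarks therefore
shows the inference machinery is correct and calibrated under its own
model assumptions — not that real cohorts will behave as cleanly.

# Numerical and reproducibility choices

* All TSV writers emit numerics with 17 significant digits, so write/read
  round trips are bit-exact and reruns are byte-identical.
* Every random stage derives a child seed from the master seed by a
  polynomial string hash of the stage name, folded into [0, 2^31 − 2]; no
  two stages share a stream and a single integer reproduces a whole run.
* Score tables validate per-regulator RS′ sums at tolerance 1e-9;
  regression problems validate `X2 = P · diag(RS′)` at relative 1e-12.
* Degenerate inputs are first-class: empty candidate sets skip the gene
  with a logged reason, zero-variance responses return empty calls,
  zero-residual-df fits set all q-values to 1 with a warning.

# Benchmark problem sizes

The shipped tests and the acceptance script use 50 replicates of a
benchmark condition with 5 genes, 10 candidates per gene (3 true), 60
disease and 10 control samples — large enough that the Monte-Carlo error
on sensitivity/FDR is about a percentage point, small enough to run on a
laptop in about a minute. The FWL and Cp correctness checks run against
independent brute-force oracles (joint OLS; naive per-subset enumeration)
on hundreds of random instances.

# Known limitations

* The verbatim binomial null is degenerate (above); any real use needs the
  independence rate or an externally supplied one.
* With `inference = "full"`, a regulator can be Cp-selected yet fail the
  q-gate on full-model evidence when candidates are strongly collinear;
  the package reports only the intersection.
* Forward stepwise above 15 candidates does not guarantee the Cp optimum
  (it does agree with exhaustive search on orthogonal designs, and the
  identifiability guard keeps candidate counts modest in practice).
* Pathway enrichment is hypergeometric over-representation on membership
  lists; it is not a ranked GSEA and carries no permutation null.
* The consensus procedure stabilizes selection; it is not a formal
  stability-selection error-control bound.
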