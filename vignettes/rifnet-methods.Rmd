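---
title: "Methods: mixed-model normalization, RIF scoring and PCIT networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mixed-model normalization, RIF scoring and PCIT networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rifnet` implements a classical systems-biology workflow for two-state
bovine RNA-seq designs — the kind of experiment in which a dozen animals
are sampled in two physiological states (pre- and post-pubertal heifers
being the motivating case), several tissues are collected per animal,
and the analysis asks three questions in sequence: which genes change
expression between states, which transcription factors (TFs) appear to
drive those changes, and how do the changed genes and candidate drivers
wire together in a co-expression network.

This vignette documents the model, the estimators, the tunable
parameters, the synthetic-data generator that backs the test suite, and
the numerical and design choices that were genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. Normalization model

Raw input is a gene x library read-count matrix with per-gene exon
lengths (kb) and per-library mapped-read totals (millions). Counts are
first converted to RPKM,

$$\mathrm{RPKM}_{js} = \frac{\text{counts}_{js}}
  {\text{mapped reads}_s\,[\mathrm{M}] \times \text{exon length}_j\,[\mathrm{kb}]},$$

genes with mean RPKM below 0.2 across all samples are dropped (the
boundary is inclusive; the aggregation across samples is by the mean,
one of the open choices — the rule is stated per gene without an
aggregation rule, and the mean is the least surprising choice), and
values are transformed to `log2(RPKM + 1)`. The +1 offset keeps zeros
at zero and is monotone; the offset is a parameter of
`log2_transform()` for users who prefer a smaller pseudo-count.

The log-scale values are then normalized with the additive mixed model

$$Y_{ijkpt} = \mu + L_i + G_j + \mathrm{GAPT}_{jkpt} + e_{ijkpt},$$

where $L_i$ is the fixed effect of library $i$ (sequencing depth and
batch nuisance), $G_j \sim N(0, \sigma^2_G)$ is the random gene effect,
$\mathrm{GAPT}_{jkpt} \sim N(0, \sigma^2_{GAPT})$ is the random gene x
animal x state x tissue interaction — the term that carries all
biological signal of interest — and $e \sim N(0, \sigma^2_e)$ is the
residual. Because every gene is observed in every library and genes are
conditionally independent given the fixed effects, the covariance of
one gene's sample vector collapses to the small matrix
$\Sigma = \sigma^2_G J + \sigma^2_{GAPT} A A^\top + \sigma^2_e I$
($A$ = sample-to-combination incidence), and REML estimation by EM
iterates entirely on $\Sigma$ (n_samples x n_samples) instead of the
full Henderson system. The solutions are nevertheless the exact
BLUE/BLUP of the full system; the test suite verifies this against an
independently coded solver (`lme4::lmer`) and against an explicitly
assembled Henderson mixed-model-equation system on a small case.

Numerical choices:

* EM-REML convergence: relative change of every variance component
  below `tol = 1e-6`, at most `max_iter = 500` iterations; a fit that
  runs out of iterations is returned with `converged = FALSE` and a
  warning, never silently.
* Variance components are floored at zero; for matrix inversion the
  residual component is floored at `1e-8` — EM near a zero boundary
  otherwise drives the condition number of $\Sigma$ past what double
  precision supports (this floor is what lets noiseless data be
  reproduced to `1e-6`).
* Identifiability: library effects are constrained to sum to zero. The
  original analysis used a proprietary solver with its own constraint
  convention; all downstream quantities ($G + \mathrm{GAPT}$,
  differences, correlations) are invariant to this choice.
* Constant input (zero total variance) short-circuits to the exact
  answer ($\mu$ = the constant, all effects and variances zero).
* Separating $\sigma^2_{GAPT}$ from $\sigma^2_e$ requires replicate
  libraries within at least one animal x tissue combination; without
  replication the fit warns that the two are confounded.

The normalized per-animal expression of gene $j$ in the analysis tissue
is $x_{jk} = \hat\mu + \hat G_j + \widehat{\mathrm{GAPT}}_{jk}$.
Including $\hat\mu$ is a deliberate choice: the solutions then sit on
the log2-RPKM abundance scale (published normalized means for this
design are in the 0.4-7.7 range), which the RIF abundance weights
require; fold changes, t-tests and correlations are invariant to the
constant.

## 2. Differential expression

Per gene, the fold change is `FC = mean(post) - mean(pre)` on the
normalized log2 scale — a *difference*, reported without antilog
conversion, reproducing the published table arithmetic exactly. The
test is the pooled-variance two-sample Student t (the design is
balanced, 6 vs 6 animals; the source describes only "a t-test", and
pooled is the classical default for balanced groups; the slaughter-day
pairing is deliberately not guessed). DE genes are called at nominal
`p < 0.05` with no multiple-testing correction, matching the original
analysis' argument that the strict normalization and the downstream
filtering (RIF, network membership) carry the burden of stringency.
"Top" genes additionally satisfy `|FC| >= 3` and `p <= 0.01`.

Degenerate inputs are fixed by contract: zero pooled variance with
equal means gives `t = 0, p = 1`; with unequal means it gives `p = 0`
with a warning. Volcano output caps `p = 0` at `1e-300` so the
ordinate stays finite.

## 3. Regulatory impact factors

For each expressed TF $i$ and the DE gene set $j = 1..n_{de}$, with
per-state means $e1_j, e2_j$, average abundance $a_j = (e1_j+e2_j)/2$,
differential expression $d_j = e2_j - e1_j$, phenotypic impact factor
$PIF_j = a_j d_j$, and within-state Pearson correlations $r1_{ij}$
(pre) and $r2_{ij}$ (post) computed across the 6 animals of each state:

$$\mathrm{RIF1}_i = \frac{1}{n_{de}} \sum_j PIF_j\,(r1_{ij} - r2_{ij})^2,
\qquad
\mathrm{RIF2}_i = \frac{1}{n_{de}} \sum_j (e1_j r1_{ij})^2 - (e2_j r2_{ij})^2.$$

RIF1 rewards differential connectivity to abundant, strongly changing
genes; RIF2 rewards TFs whose condition-wise "predictive product" of
abundance and correlation changes. Both are z-standardized across TFs
and a TF is a key regulator when either $|z| \ge 1.96$. The threshold
is read as two-sided magnitude because published RIF results include
large negative scores. $d_j$ uses post minus pre to stay
sign-consistent with the DE module.

Correlations come from the per-animal normalized values of the analysis
tissue (the correlation input is not stated in the source; the
normalized solutions are the only quantity the model declares as "the
currency of downstream analysis"). Zero-variance vectors yield r = 0
with a degeneracy flag rather than NA.

**A calibrated warning about 6-animal designs.** A Pearson correlation
estimated from 6 points has null standard deviation about
$1/\sqrt{5} \approx 0.45$, so a null TF's differential wiring
$r1 - r2$ fluctuates with sd $\approx 0.63$ while the largest
*plantable* signal with a wiring change of 1.0 is itself about 1.0.
With ~50 TFs competing, chance alignment of some null TF with a
regulator's 6-dimensional expression profile regularly produces
RIF scores comparable to genuinely wired regulators. The synthetic
recovery experiment in the acceptance suite measures exactly this (a
~10% success rate for "all 3 planted regulators in the top 5" across
20 runs) and is left failing by design: it quantifies a real
limitation of the published design size rather than a software defect.
On such designs RIF rankings should be read as enrichment evidence,
not as a reliable top-k list.

## 4. PCIT network inference

The co-expression network is built over DE genes plus significant TFs
(plus any user-supplied extra nodes) from Pearson correlations across
all 12 animals of the analysis tissue, both states pooled — one network
is inferred for the two conditions jointly. The PCIT screen then visits
every unordered trio $(x, y, z)$: with first-order partial correlations
$r_{xy\cdot z}$ etc., the information-theoretic tolerance is

$$\varepsilon = \frac{1}{3}\left(\frac{r_{xy\cdot z}}{r_{xy}} +
 \frac{r_{xz\cdot y}}{r_{xz}} + \frac{r_{yz\cdot x}}{r_{yz}}\right),$$

and edge $(x,y)$ is flagged non-significant in the context of $z$ when
$|r_{xy}| \le |\varepsilon\, r_{xz}|$ and
$|r_{xy}| \le |\varepsilon\, r_{yz}|$. An edge survives iff **no**
third node flags it — the single-sufficient-explainer quantifier, fixed
here because PCIT is an indirect-association filter. Ratios whose
direct correlation is below `1e-12` in magnitude, or whose partial is
undefined (a unit correlation in the denominator), are excluded from
the tolerance mean; a trio with no defined ratio imposes no flag. The
flag comparison is non-strict (`<=`), documented for reproducibility.
The screen is implemented in C++ (O(n^3) trios) and is verified
edge-for-edge against an independently coded R brute-force oracle.

Two properties worth knowing:

* The edge set is invariant to negating any single variable's data.
  It is *not* invariant to negating the whole correlation matrix — the
  signed tolerance ratios change — which the oracle confirms.
* At 12 samples the null retention rate is substantial (roughly 6-15%
  of noise edges depending on network size, measured in the test
  suite). PCIT's sparsification strength grows with both the number of
  samples and the number of candidate explanatory genes; published
  networks built from >1,000 nodes are much sparser than desk-scale
  replicas. Tests therefore assert relative enrichment of planted
  edges, not absolute hub dominance.

## 5. Trio selection

Among the TFs present in the network, all $\binom{n}{3}$ trios are
enumerated (deterministically, lexicographic order) and scored by
**coverage** — the number of distinct nodes adjacent to at least one
member, open neighborhoods, so a TF never covers itself — and
**redundancy**, the sum of the three pairwise neighborhood
intersections. The winner maximizes coverage with ties broken by
minimum redundancy and then lexicographic order; "minimum redundancy"
as a tie-break (rather than a weighted objective) is the package's
concrete reading of the qualitative "spans most of the topology with
minimum redundancy" objective, fixed and documented. The trio-centered
subnetwork (trio, neighborhoods, induced edges) is exported for
visualization. Exhaustiveness is verified against a set-arithmetic
oracle.

## 6. The synthetic world

`sim_config()` / `simulate_experiment()` generate the world the
analysis assumes, with known ground truth:

* **Design**: 6 + 6 animals, 5 tissues (named liver, hypothalamus,
  pituitary, ovary, uterus for the default 5), 72 libraries — one per
  animal x tissue combination plus 12 replicate libraries assigned
  round-robin (the published model reports 72 library levels against
  60 combinations; the surplus is modeled as replication, which is
  also exactly what identifies $\sigma^2_{GAPT}$ vs $\sigma^2_e$).
* **Expression**: log2 RPKM drawn from the additive model above with
  defaults $\mu = 5$ (a moderately expressed gene, RPKM ~32),
  $\sigma^2_G = 1$ (genes differ a lot), $\sigma^2_{GAPT} = 0.5$
  (animal-level biology), $\sigma^2_e = 0.1$ (technical noise of
  deeply sequenced libraries), library effects with sd 0.1.
* **DE planting**: a fraction `prop_de` of genes (default 5%) gains
  `de_effect` (default +2 log2 units) in post-state interaction terms.
* **Wiring planting**: `n_planted_regulators` TFs are each wired to a
  disjoint block of DE targets at correlation `r_pre` (default 0.95)
  pre-state and `r_pre - wiring_shift` post-state (the + direction is
  used if the - direction leaves [-1, 1]; configs where both leave the
  interval are rejected). The wiring is planted as the **exact
  empirical** correlation within each state x tissue animal group
  (latents standardized and orthogonalized within groups): with only 6
  animals per group, a population-level plant would make the realized
  correlation itself fluctuate by +-0.2, i.e. the ground truth would
  be random. When `wiring_shift = 0` the groups merge across states so
  pooled correlations are exact too.
* **Counts**: RPKM = 2^Y is inverted through the RPKM formula with
  log-uniform gene lengths (0.2-20 kb) and library sizes (40-80 M
  reads, bracketing the ~63 M per library of the motivating study) and
  rounded half-to-even. Short, weakly expressed genes therefore carry
  visible rounding noise — as in real data — which is why exact
  noiseless-limit tests use the latent log matrix carried in the
  ground-truth object.
* **Reproducibility**: one master seed; every stream (lengths, library
  sizes, library effects, gene effects, interactions, residuals) draws
  from a documented fixed offset of it. Identical config implies
  bit-identical output.

What the generator does **not** emulate: read-level sampling
(negative-binomial overdispersion beyond the mixed-model noise),
isoforms, GC or length biases within a gene, batch structure beyond
the library effect, and non-Gaussian tails. A green test therefore
establishes correctness of the estimators under the stated model, not
robustness to real-data pathology.

## 7. Pipeline

`run_pipeline()` chains normalize -> DE -> RIF -> network -> trio from
three input files (counts TSV, design TSV, TF list) and a YAML-able
configuration whose defaults are the published thresholds (RPKM >= 0.2,
p < 0.05, |FC| >= 3 & p <= 0.01, |z| >= 1.96). Every stage writes TSV
(plus SIF for networks, YAML for the fit report and manifest); reruns
are byte-identical. When fewer than 3 TFs reach the z threshold the
trio stage falls back to the top-|z| TFs, with a warning and a manifest
flag — small inputs routinely produce fewer than 3 significant TFs and
a hard error would make the tail of the pipeline unreachable.

## 8. Known limitations

* The 6-animals-per-state correlation noise floor discussed in section
  3 bounds what any wiring-based score can resolve on this design.
* EM-REML converges linearly near variance boundaries; fits with a
  true zero component may need more than the default 500 iterations to
  reach tight tolerances (the fit reports `converged` honestly).
* PCIT here is the first-order (trio) screen only; higher-order
  partial correlations and graph post-processing (communities, layout)
  are out of scope.
* The fold change is a log-scale difference by the published
  convention; users wanting ratios must antilog themselves.
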