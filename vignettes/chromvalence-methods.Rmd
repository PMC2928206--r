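---
title: "Methods: multivalent histone-mark models of gene expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multivalent histone-mark models of gene expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

chromvalence predicts log2 gene expression from histone-modification
ChIP-Seq enrichment in four stages.

**Templates and amplitudes.** Each mark $j$ has a characteristic spatial
profile across genes. We summarise it as a *template* $t_{i,j}$: every gene is
laid out as a 2 kbp 5' flank, a gene body scaled to a fixed number of bins
(8138 by default, the median human gene length in bp), and a 2 kbp 3' flank;
profiles are aligned at the TSS and TES, averaged position-wise across genes,
and rescaled so the template's mean over all positions is exactly 1. A gene's
enrichment for the mark is then a single scalar, the least-squares amplitude

$$A_j^k = \frac{\sum_i y_i^{j,k}\, t_{i,j}}{\sum_i t_{i,j}^2},$$

the closed-form minimiser of $\sum_i (y_i - A\,t_i)^2$. Because the template
has mean 1, $A_j^k$ is interpretable as the mark's effective per-bin read
density at gene $k$; for a uniform template it reduces to the simple bin
average. Fit quality is tracked per gene by
$\mathrm{CV(RMSD)} = \sqrt{\tfrac1n\sum_i (y_i - A t_i)^2}\,/\,A$.

**Enrichment significance.** Per mark, a Gaussian null is fitted to the left
tail of the amplitude distribution: the mean is the distribution's mode
(half-sample mode by default; a Freedman-Diaconis histogram mode is the
fallback) and the SD is the root mean square deviation of the amplitudes at
or below the mode. Upper-tail p-values are BH-adjusted per mark across genes
and flagged at FDR 0.05. Genes with alternative start/stop sites take the
candidate with the most significantly enriched marks (ties: most upstream
start; stop ties: longest body, a deterministic stand-in for an arbitrary
pick).

**Multilinear model.** Expression is regressed on all mono-, bi- and
trivalent amplitude products ($\binom{n}{1}+\binom{n}{2}+\binom{n}{3}$ terms;
1561 for 21 marks). Selection is stepwise with partial F-tests at 0.05 in
both directions, wrapped in the two-round protocol: (1) 100 randomly seeded
stepwise runs on the full data; terms surviving in at least 35% of the
converged models seed round two; (2) 10-fold cross-validation, several runs
per fold seeded with the survivors plus random extras, each converged model
pruned by a backward-only pass on the fold's held-out rows, the lowest
held-out-MSE model kept per fold, terms retained if present in at least 5 of
the 10 kept models, and final coefficients taken as trimmed means (single min
and max dropped) of per-fold refits. Reported per term: coefficient, Z-score,
and the impact factor $\beta \times \mathrm{IQR}$ of its regressor.

**MARS.** The spline model sums products of hinge functions
$h(x-k)=\max(0,x-k)$, added greedily in symmetric pairs by maximal RSS
reduction under hierarchy constraints (a bivalent basis must extend a
monovalent one, a trivalent a bivalent one; no mark repeats within a basis;
degree at most 3), then pruned backwards against the GCV score
$(\mathrm{RSS}/N)/(1-\mathrm{enp}/N)^2$.

**In-silico knockout.** A mark is knocked out by setting its amplitude column
to zero and re-evaluating the model - hinge bases are recomputed at zero, not
dropped, so $h(k-0)=k$ can stay positive. The per-gene log2 fold change is
$\hat y_{WT} - \hat y_{KO}$ (both already log2 expression). A negative median
classifies the mark as globally repressive. Quintile stratification ranks
genes by the knockout effect with QU1 the 20% most up-regulated by the
knockout (the largest de-repression, i.e. the most negative
$\hat y_{WT}-\hat y_{KO}$).

# The synthetic world

Real tag-level compendia are large downloads; the generator replaces them
with a stated world whose ground truth is known.

* **Gene models**: one synthetic chromosome, log-normal body lengths (median
  about 8 kbp), Bernoulli(0.5) strands, 0-based half-open coordinates, and
  (at rate 0.15 per site class) alternative internal start/stop sites.
* **Templates**: four smooth shapes (TSS peak, 3'-increasing body ramp,
  uniform body, bimodal TSS/TES) defined as functions of normalised gene
  position, so base-pair and scaled-bin evaluations are mutually consistent.
* **Counts**: bin counts are Poisson around $A_j^k\, t_{i,j}$ (rank-1
  noiseless profiles when noise is off). Poisson is this generator's choice;
  no count-noise family is implied by any reference data. A BED-emitting mode
  samples tag 5' starts proportional to the template for I/O tests.
* **Expression**: $Y_k = c_0 + \sum \text{planted terms} + \varepsilon$, with
  planted mono/bi/trivalent products and a hinge-saturated mono term. The
  residual SD is derived from the realised signal variance to hit a true
  $R^2$ of 0.5 by default.
* **The confounded repressor**: the default 8-mark panel plants a mark
  $R = s + a z + \eta$ on the latent activity $z$, entering expression with
  coefficient $-c_r$ alongside an activity-coupled activator
  ($A = c + \lambda z + \epsilon$, coefficient $c_a$). The loading $a$ solves
  $c_r a^2 - c_a \lambda a + c_r \sigma_\eta^2 = 0$, which makes
  $\mathrm{Cov}(R, Y)$ exactly zero: the mark shows no marginal trend with
  expression (|Spearman| < 0.05 at n = 2000) yet is strongly repressive
  conditionally - the synthetic analogue of an arginine methylation whose
  repressive role appears only in multivariate models. These two marks use
  shifted-Gaussian amplitudes precisely so this cancellation is exact and
  analytic; the other six marks keep the skewed log-normal marginals typical
  of enrichment data. With log-normal marginals here the conditional mean
  E[Y|R] would curve and the cancellation would be approximate only - we
  traded marginal-shape fidelity for an exact defining property.
* **Planted-coefficient balance**: in the three-term recovery scenario the
  coefficients (+4 mono, +2 bivalent, -1.5 trivalent) are chosen once so each
  term contributes comparable signal variance; log-normal products grow
  heavy-tailed with valency, and a dominant trivalent term would test the
  arbitrary coefficient choice rather than the selection protocol.

What a green test does *not* establish: realism of read-level noise
(fragment sizes, mappability, duplicates, input controls are out of scope),
inter-mark normalisation, or any quantitative claim about real ChIP-Seq
compendia - fitting real data requires the original downloads and is a user
exercise, not a test target. The synthetic tests establish that the
machinery recovers known structure under its own assumptions.

# Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_body_bins` | 8138 real / 300 synthetic | bins | median gene length; synthetic runs scale down for speed |
| `flank_bp` | 2000 | bp | promoter/terminator context |
| `flank_bin_bp` | 1 (10 in robustness scans) | bp/bin | per-nucleotide flanks are the dominant memory cost; aggregation is a knob |
| `fdr_cutoff` | 0.05 | - | BH flag level |
| `n_runs`, `survival_cutoff` | 100, 0.35 | - | round-1 survival filtering |
| `folds`, `runs_per_fold`, `retention` | 10, 10, 5 | - | CV protocol (tests use `runs_per_fold = 5`) |
| `extra_random_terms` | 60 (30 in the 8-mark tests) | terms | exploration in round 2 |
| `max_degree`, `penalty` | 3, 3 | - | MARS interaction depth and GCV penalty |
| `max_knots` | 20 | knots/mark | quantile-spaced candidate cap (<= 100 by design; 20 chosen for speed) |

# Numerical choices

* **Stepwise engine**: forward entry uses vectorised partial-F scans against
  an orthonormal basis of the current model, extended by Gram-Schmidt per
  accepted term; backward elimination downdates $(X'X)^{-1}$ by rank-one
  updates, so a whole backward pass costs one QR factorisation. Entry ties
  break by larger F, then canonical term order; aliased columns are dropped
  with a warning. An oscillation guard caps forward/backward alternation
  (entry and removal both at 0.05 can cycle).
* **Trimmed mean**: drop the single smallest and largest of the 10 fold
  values (20% total trim).
* **Retention reading**: the protocol keeps one lowest-test-MSE model per
  fold and counts retention across the 10 kept models; the alternative
  reading (5 of the 10 models *within* a fold) is recorded in model metadata
  as the road not taken.
* **GCV effective parameters**: enp = T + penalty x (number of distinct hinge
  pairs), pairs identified by their factor set ignoring direction; the exact
  printed form of the penalty is not recoverable, so the formula is carried
  in model metadata.
* **Binning rounding**: bin boundaries use round-half-up so a base bisected
  by a boundary goes wholly to the bin holding its majority; genes shorter
  than the bin count repeat the base under each bin midpoint.
* **Degenerate inputs**: all-zero aggregate profiles, zero-spread nulls and
  constant design columns raise classed errors (`cv_degenerate_template`,
  `cv_degenerate_null`) or are dropped with a message; CV(RMSD) at
  non-positive amplitude is reported as missing rather than fabricated.
* **Seeding**: every stochastic function takes one seed; child seeds are
  derived by hashing stage labels, keeping all values below $2^{31}$.

# Known limitations

* Stepwise p-values are post-selection and nominal; no selective-inference
  correction is attempted (regularised and Bayesian alternatives are
  non-goals).
* The site-selection wrapper caps candidate (start, stop) pairs at 10 per
  gene and scores candidates against raw-p thresholds implied by the
  dataset-level BH flags - a pragmatic one-gene-at-a-time surrogate.
* Significant-site proportions substitute internal enrichment flags for
  external peak calls; they are a stated stand-in, not a reproduction.
* Flank windows may overlap neighbouring genes; no masking is applied.
* Tags are counted at their 5' start with no fragment-shift model.
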