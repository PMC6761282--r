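---
title: "Methods: integrative miRNA-mRNA analysis of age-associated expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative miRNA-mRNA analysis of age-associated expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the design

`agemir` analyses paired small-RNA and mRNA sequencing count matrices
from a cohort of 12 human atrial tissue samples spanning four age
groups — SR40 (38–42 y), SR50 (48–52 y), SR60 (58–62 y), SR70
(68–72 y), three samples each — to find miRNAs and genes whose
expression changes with age, and to connect them into a miRNA–mRNA
regulatory network. The central design idea is *reciprocal
replication*: rather than one old-versus-young comparison, two
disjoint contrasts are tested (SR60 vs SR40 and SR70 vs SR50), and a
feature is only called age-associated when the signal appears in both,
with the same direction. With n = 3 per group this sacrifices some
power for a substantially lower false-positive burden.

# Differential expression model

Counts for feature $f$ in sample $s$ are modelled as negative binomial,

$$y_{fs} \sim \mathrm{NB}(\mu_{fs}, \phi), \qquad
\log \mu_{fs} = \log L_s + \beta_{0f} + \beta_{1f} x_s,$$

where $L_s$ is the raw library size (column total; no TMM-style
between-sample factor is applied, though `library_sizes()` accepts
plug-in normalization multipliers), $x_s$ indicates the older group,
and the variance is $\mu + \phi\mu^2$. Each feature is fitted by IRLS
with the canonical log link (at most 50 iterations, convergence when
the relative deviance change falls below $10^{-8}$; start values are
the log of prior-augmented library-size-scaled group means). The group
effect is tested by the likelihood ratio
$\mathrm{LR} = 2(\ell_{\text{full}} - \ell_{\text{null}})$, clipped at
zero and referred to $\chi^2_1$; the test is two-sided, with direction
carried by the sign of the logFC. Features with all-zero counts across
a contrast's six samples are skipped and counted, not tested.
Non-converged fits are flagged with `NaN` p-values rather than
reported silently.

Two reporting conventions follow the established practice for count
models at small n: abundances are log2 counts-per-million with a 0.5
prior count ($\mathrm{logCPM} = \log_2\!\frac{y + 0.5}{L + 1}\,10^6$),
and the *reported* logFC comes from a refit with 0.5 added to every
count, which shrinks fold changes of near-zero counts to finite,
stable values. The likelihood-ratio test itself always uses raw
counts.

## Dispersion

A single common dispersion is shared by all features of a contrast —
with three samples per group there is far too little information for
per-feature dispersions, and a common $\phi$ keeps the test's null
behaviour easy to audit. $\phi$ maximizes the Cox–Reid adjusted
profile likelihood summed over features,
$\sum_f [\ell_f(\hat\beta_f; \phi) - \tfrac12 \log\det(X^\top W_f X)]$,
evaluated on a 41-point grid in $\log_{10}\phi \in [-4, 1]$ and then
refined by golden-section search inside the bracketing interval (the
adjustment compensates the downward bias of plugging in estimated
means). On simulated data the estimator recovers the generating
$\phi$ closely and agrees with the reference Cox–Reid implementation
in the test suite's cross-checks. A method-of-moments estimate and a
fixed override are available for sensitivity analysis.

# Meta-analysis and selection

Per feature, the two contrast p-values are combined by Fisher's
method, $S = -2\sum_i \ln p_i \sim \chi^2_{2k}$ with $k = 2$
contrasts (df = 4), and BH-adjusted across *all* tested features.
Two selection paths mirror the two feature classes:

* **miRNAs** (`nominal_both`): $p < 0.05$ in both contrasts and equal
  logFC signs. miRNA counts are few enough that the replication
  requirement itself is the multiplicity control.
* **genes** (`fdr_meta`): BH FDR $< 0.05$ on the combined p over all
  tested genes, *then* the direction-consistency filter. The order is
  fixed — FDR first, consistency second — so the FDR threshold refers
  to the full tested universe.

Features passing every filter except direction consistency are
returned in a separate *discordant* table: a reproducible record of
the boundary cases, never silently merged into the main list.
Numerical guards: p-values of exactly zero (underflow) are floored at
$10^{-300}$ before the logarithm with a warning; a zero logFC
contributes direction "+" with a warning (a zero effect cannot pass
the significance filters, so the tie-break is cosmetic).

# Correlation and the valid-pair rule

Each selected miRNA is correlated against every tested gene on the
logCPM scale (prior 0.5) with the Pearson coefficient and its exact
t-based two-sided p-value, $t = r\sqrt{n-2}/\sqrt{1-r^2}$, df
$= n - 2$ (n = 12 here). No multiplicity adjustment is applied to
these correlations — the downstream rule filters at nominal
$p < 0.05$, which is a known, documented limitation rather than an
oversight: the pair list is a screen, not a confirmatory test.

A (miRNA, gene) pair is a **valid interaction** when

1. both members were selected as age-associated;
2. the correlation is significant at $p < 0.05$;
3. the correlation sign equals the product of the two features' effect
   signs, $\operatorname{sign}(r) =
   \operatorname{sign}(\mathrm{logFC}_{\text{miR}}) \cdot
   \operatorname{sign}(\mathrm{logFC}_{\text{gene}})$ — the
   operationalization of "directions of effect consistent with the
   correlation". An exact $r = 0$ cannot pass condition 2; it is
   rejected with a warning should it arise.

A valid pair is a **direct** interaction when the gene is a
database-predicted target of the miRNA *and* $r < 0$ (the repression
signature); otherwise it is **indirect**. Database-predicted pairs
with positive correlation are deliberately labelled indirect and
flagged `predicted_positive`, so the direct list never contains a pair
whose sign contradicts the repression mechanism. Pairs whose gene has
no entry in an optional annotation alias table are excluded and
counted. The four correlation types (up-up, up-down, down-up,
down-down) follow from the two direction signs.

# Enrichment

Per miRNA, the overlap $k$ between its target set (size $n$) and the
$K$ selected age-associated genes is summarized by the fold change
$(k/n)/(K/N)$ and the upper-tail hypergeometric $P(X \ge k)$ with
universe $N$ = all tested genes (the 42-of-23,346 background
reproduces the published fold-change column; the universe is
configurable). The indirect scope uses the miRNA's significantly
correlated non-target genes. Pathway over-representation of the
network genes uses the same hypergeometric and the same BH routine
across user-supplied GMT sets; the default universe is the union of
set members intersected with tested genes, the clusterProfiler-style
convention. Empty target sets yield fold change 0, p = 1 and a flag.
Published hypergeometric p-values and pathway p/q-values depend on an
unstated test universe and a specific annotation release, so the
package documents and tests its own definitions instead of chasing
those numbers.

# The synthetic cohort generator

`simulate_aging_cohort()` generates the statistical structure the
analysis assumes, so every stage is verifiable without the original
(restricted) sequencing data:

* **Design**: 12 samples, four groups, ages fixed at the
  representative decade values 40/50/60/70 (optional jitter), one
  female and two males per group.
* **Abundances**: baseline CPM log-normal with $\sigma_{\log} = 1.5$
  and mean CPM $10^6/\text{n features}$; planted features draw from a
  moderate-abundance distribution (1.5× average CPM,
  $\sigma_{\log} = 0.8$) so the planted truth is detectable at
  n = 3 — mirroring that the study's reported features are not at the
  detection floor.
* **Age effects**: planted features get multipliers
  $2^{d \cdot \mathrm{logFC} \cdot s_g}$ with zero-centered monotone
  group scores $s = (-0.75, -0.25, 0.25, 0.75)$, so each decade-pair
  contrast has true logFC equal to `planted_logfc` (default 2) while
  planted mass stays balanced across samples.
* **Compositionality**: expected proportions are renormalized to sum
  to one per sample before scaling by the library size (log-uniform
  per sample), because sequencing depth is set by the instrument, not
  by the biology. Realized post-normalization mean CPMs are stored in
  the ground truth; at study scale the renormalization perturbs
  planted logFCs negligibly, at desk scale by a documented small
  attenuation.
* **Couplings**: each planted direct pair multiplies the target
  gene's mean by $2^{-c \cdot \tilde\ell_s}$ where $\tilde\ell_s$ is
  the regulator's centered latent (noise-free) log2-CPM and $c$ is
  `coupling_strength` (default 0.8). Acting through the latent
  expression, not the noisy count, keeps the planted truth
  well-defined. The target database contains all planted pairs plus
  10× uniformly sampled decoys; counts are NB with the same $\phi$
  (default 0.1), drawn Poisson when $\phi = 0$.

All randomness flows from the single mandatory seed, and the global
RNG state is restored afterwards. What the generator does **not**
emulate: batch effects, sequence-driven target prediction, GC or
length biases, within-group age spread (by default), and sample
quality variation — so passing recovery tests demonstrates
correctness of the statistical machinery under the assumed model, not
robustness to real-data artefacts.

# Problem sizes and numerical choices

The test suite and the acceptance script run the generator at desk
scale — typically 60–500 miRNAs and 400–5,000 genes with 5–20 planted
features per class — which preserves every qualitative property of
the study-scale design (the per-feature model is identical; only the
multiplicity landscape shrinks). The analysis drivers under
`analysis/` use 500 miRNAs and 5,000 genes. Other fixed choices:
prior count 0.5 (edgeR-style convention, configurable); dispersion
grid bounds $[10^{-4}, 10]$; IRLS linear predictor clamped to
$\pm 30$ to avoid overflow on degenerate features; BH via
`stats::p.adjust`; chi-square/t/hypergeometric tails via the
corresponding `stats` distributions; deterministic output ordering
everywhere (miRNA then gene id; enrichment by ascending p with set-id
tie-break).

# Known limitations

* Common dispersion only — no trended or tagwise shrinkage; with
  n = 3 per group this is a deliberate bias-variance trade-off, but it
  will under-fit datasets with strong mean-dispersion trends.
* Library-size-only normalization; composition shifts between samples
  (one highly induced transcript class) would bias logFCs, which the
  hook for plug-in normalization factors can mitigate.
* The 163k-scale correlation screen is unadjusted by design; its
  output should be read as candidate ranking, not inference.
* Identifier handling is deliberately opaque-string; cross-annotation
  reconciliation (e.g. differing genome builds between the miRNA and
  mRNA quantifications) is out of scope.
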