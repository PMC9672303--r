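---
title: "Models and methods in plasmasig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in plasmasig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmasig)
```

plasmasig dissects CD138-selected single-cell RNA-seq samples from the
multiple-myeloma disease spectrum (healthy donor bone marrow, MGUS, SMM,
MM) into their normal and clonal plasma-cell components, and characterises
the clonal component with within-patient differential expression,
signature discovery by automatic-relevance-determination NMF, and
signature-level statistics. This vignette explains each model, its
assumptions, the tunable parameters, and the design decisions behind the
implementation.

## The light-chain purity model

A clonal plasma-cell population descends from a single B-cell progenitor
and therefore expresses exclusively the kappa or exclusively the lambda
immunoglobulin light chain ("light-chain restriction"). Normal plasma
cells mix both chains, with a kappa fraction that is similar across
healthy individuals. The tumor purity $\rho$ of a sample — the fraction of
abnormal cells among its plasma cells — is therefore identifiable from
light-chain counts alone:

$$
\kappa_n \sim \mathrm{TruncNormal}(\mu, \sigma^2, 0, 1), \quad
\kappa_t \sim \mathrm{Bernoulli}(0.5), \quad
\rho \sim \mathrm{Beta}(1, 1),
$$
$$
p = \rho\,\kappa_t + (1 - \rho)\,\kappa_n, \qquad
n_\kappa \sim \mathrm{Binomial}(N, p),
$$

where $N$ counts the cells assigned a chain (a cell is kappa when its
IGKC expression exceeds IGLC2, lambda in the reverse case; exact ties are
excluded from both counts because the model assumes every counted cell is
informative) and $\mu, \sigma$ are estimated from the healthy-donor
samples, using the sample standard deviation with a floor of
`sigma_min = 0.01` so that a handful of closely agreeing donors cannot
make the likelihood singular.

The posterior over $\rho$ is evaluated on 100 equally spaced grid points
in $[0, 1]$; $\kappa_t$ is marginalised by summation and $\kappa_n$ by a
1001-point trapezoid rule on $[0, 1]$ with the truncated-normal density.
The trapezoid rule is effectively spectrally accurate here because the
integrand's derivatives vanish at the interval ends for any
$\sigma \ge 0.01$; the package's tests compare the posterior against a
dense $10^4$-point quadrature written independently and observe
total-variation distances around $10^{-8}$ or better. We report the grid
mode as the purity estimate and the 2.5%/97.5% points of the linearly
interpolated cumulative distribution as the 95% interval, clamped to
contain the mode (the clamp matters only for near-degenerate posteriors
concentrated on a boundary grid point).

```{r purity-example}
post <- purity_posterior(N = 200, n_kappa = 155, prior = kappa_prior(0.55, 0.02))
glance(post)
```

An intrinsic accuracy limit is worth stating: the data constrain only
$p = \rho \kappa_t + (1-\rho)\kappa_n$, so every $\rho$ on the ridge
$\rho + (1-\rho)\kappa_n = p$ (for a kappa clone) is nearly equally
supported, and the ridge has width $\sigma (1 - \rho) / (1 - \mu)$. With
$\mu = 0.6, \sigma = 0.05$ this is about $0.125\,(1-\rho)$: at
intermediate purity no estimator can localise $\rho$ to better than about
$\pm 0.1$ from a single sample, however many cells are sequenced. The
posterior's 95% intervals remain calibrated (coverage around 95% in the
package's simulations); the point estimate inherits the ridge width.

## Automated cell labeling and the conjugate interval

The second, orthogonal purity estimator labels each cell. Cells of one
sample are clustered on highly variable genes with immunoglobulin genes
excluded (so clonal chains cannot drive the clustering); the default
community-detection backend is an igraph Louvain pass over a
15-nearest-neighbour graph on 10 principal components, and is pluggable —
any per-cell cluster labels can be supplied. A cluster is called abnormal
when its dominant light-chain fraction exceeds 0.9 *and* departs from the
normal-cell expectation $\mu$ by more than 0.2, or when configured driver
genes (e.g. CCND1 in t(11;14) tumors) exceed the other clusters by 2
pooled SDs. These thresholds replace a manual curation step; each
cluster's evidence is returned for audit. With $n$ of $N$ cells labeled
abnormal and a uniform prior, the purity posterior is
$\mathrm{Beta}(n+1, N-n+1)$, whose 2.5%/97.5% quantiles give the interval.

Because the two estimators share almost no assumptions, their agreement
on real or simulated cohorts is a meaningful check; `label_cohort()`
returns both per sample and `plot_purity_comparison()` draws them against
each other.

## Within-patient differential expression

For each sample containing both populations, every analysis gene is
tested abnormal-vs-normal with a two-sided Wilcoxon rank-sum test (normal
approximation with tie and continuity correction — the package's tests
check it against exact enumeration for small groups), followed by
Benjamini-Hochberg correction across genes within the patient. Effect
sizes use an offset-regularised fold change on log-normalized expression
$e = \log(10^4 n_{g,c}/N_c + 1)$ (natural log; $N_c$ excludes genes
holding more than 20% of any cell's UMIs):

$$
\mathrm{FC} = \frac{\exp(\bar e_A) - 1 + \delta}{\exp(\bar e_B) - 1 + \delta}.
$$

The printed expression for this statistic typesets the $-1$ ambiguously;
we place it outside the exponential, i.e. `expm1(mean) + offset`, because
only that reading reduces to the single-cell convention it modifies when
$\delta \to 10^{-9}$. The offset $\delta$ defaults to half the minimum
nonzero log-normalized value in the dataset at hand (0.126 in the reference cohort this package's defaults emulate, available
as a fixed override). A gene is a
DEG when $q < 0.1$ and $|\log \mathrm{FC}| > \log 1.5$. Genes recurring
across patients are summarised by the maximum $q$ across patients
multiplied by the number of patients with DEGs (capped at 1) — a
conservative cross-patient correction — separately for up- and
down-regulated instances.

The cross-patient pseudosample comparison (limma-voom with TMM) is
deliberately out of scope; the package produces its
exact inputs — summed counts per (sample, population) pseudosample, the
CPM $\ge 5$ / expressed-in-$\ge 5$% / non-immunoglobulin gene filter, and
the covariate table with mean-imputed missing donor age.

## ARD-NMF signature discovery

UMI counts of analysis genes are modelled as
$V \approx \hat V = WH$ with a Poisson likelihood, an exponential (L1)
prior on $W$, a half-normal (L2) prior on $H$, and a relevance weight
$\lambda_k$ per component shared between $W$'s column and $H$'s row. The
MAP objective is

$$
D_{KL}(V \Vert WH)
+ \sum_k \frac{1}{\lambda_k}\Big(\sum_g w_{gk} + \tfrac12 \sum_c h_{kc}^2 + b\Big)
+ \Big(G + \tfrac{C}{2} + a + 1\Big) \sum_k \log \lambda_k ,
$$

with $a = 10$ and $b = \sqrt{(a-1)(a-2)\,\overline V / K_{init}}$.
Irrelevant components see their $\lambda_k$ collapse toward the floor
$b/M$ ($M = G + C/2 + a + 1$), which drives their weights to zero — the
rank is discovered, not chosen.

Implementation choices that matter:

* **Updates.** $H$ uses the exact minimiser of the KL majoriser under the
  L2 prior — a quadratic root, not the common ratio heuristic — and $W$
  the exact minimiser under the L1 prior; $\lambda$ has a closed form.
  Each block update provably decreases the objective, so the recorded
  trace is non-increasing to floating-point precision, a property the
  test suite asserts on every fitted run. The inner loop is compiled
  (RcppArmadillo) with BLAS matrix products.
* **Convergence** is declared when the relative L2 change of the
  $\lambda$ vector drops below `tol` (default $10^{-5}$), capped at
  `max_iter` (default 7000).
* **Component death.** Dying components approach the $\lambda$ floor only
  asymptotically (sub-1% per iteration), so an exact floor test needs
  thousands of extra iterations. A component is instead counted dead when
  its data mass $S_k = \sum_g w_{gk} + \tfrac12\sum_c h^2_{kc}$ falls
  below the prior pseudo-mass $b$ (equivalently $\lambda_k < 2b/M$) —
  prior-dominated components are dying by construction — or when its $W$
  column holds under $10^{-8}$ of the total weight. On the package's
  recovery fixtures this matches floor-based pruning run to full
  collapse.
* **Model selection.** 20% of cells are held out once; each restart is
  scored by the KL divergence of the held-out cells projected onto the
  fitted $W$ (H-only updates, same priors). Among restarts whose final
  rank equals the modal rank (ties break toward the smaller rank, for
  parsimony), the lowest validation divergence wins. The full-scale
  default of 100 restarts is configurable; the package's tests use 10.

After fitting, $W$'s columns are normalized to sum 1 with the weight
shifted into $H$ (the reconstruction is unchanged), and activities are
divided by each cell's total counts. Signatures are classified:
*patient-specific* when one patient's mean activity exceeds the other
patients' means by more than 4 SDs of those means (we read "standard
deviations" as the SD across the other patients' means, the scale on
which the comparison is made); *single-gene* when the top normalized gene
weight exceeds the runner-up by at least 0.5; otherwise *interpretable*,
described by top genes ranked by weight times specificity
$s_{gk} = [H\mathbf 1]_k w_{gk} / \sum_{k'} [H\mathbf 1]_{k'} w_{gk'}$.

## Signature-level statistics

Population means (per sample, per normal/abnormal population) carry a
bootstrap SEM — the SD of the means of 10,000 multinomial resamples,
which is the bootstrap's exact resampling distribution and vectorises
cleanly. Group differences across the seven groups (NBM plus
normal/abnormal at each disease stage) use Kruskal–Wallis with Dunn's
post-hoc z-tests on pooled ranks, Bonferroni-corrected over the
comparisons actually performed, significant at family-wise error rate
0.1. Whether the reference analysis corrected over all 21 pairs or only
disease-vs-NBM contrasts is not documented; we default to all performed
pairs (the more conservative reading) and accept an explicit comparison
list. Ordered trends across stages use the Jonckheere–Terpstra statistic
(sum of pairwise Mann–Whitney counts over ordered group pairs),
two-sided, with a tie-aware normal approximation and continuity
correction, switching to full permutation enumeration automatically when
the total sample size is at most 12.

Intratumor heterogeneity of a signature within one tumor is declared when
the coefficient of variation of its per-cluster mean activities exceeds
1, using the population SD (divisor $n$), matching the reference
implementation's default. A consequence worth knowing: with population
SD, a two-cluster tumor has CV $= (a-b)/(a+b) < 1$ always, so only
tumors with at least three clusters can be flagged. Single-cluster
samples return an undefined CV and no flag.

The batch screen tests, on normal cells only (where no biological
activity differences are expected), each signature's per-sample mean
activity against each covariate: rank-sum for binary covariates,
Kruskal–Wallis for multi-level batch, Pearson and Spearman for age, at a
0.05 screening threshold. Sample-level means are used because cells of
one sample share its covariates and are not independent replicates.

Bulk projection of a signature onto an external cohort uses
median-of-ratios size factors, per-million scaling, `log1p`, per-gene
z-scores across samples, and the mean z over the signature's top genes
(for the normal plasma-cell signature: CD27, CD79A, RNU12, JSRP1, SAT1,
CTSH, HCST). "log-tpm" here means size-factor-normalized counts scaled
to per-million then log-transformed — without gene lengths, counts-based
TPM and normalized CPM coincide up to the size factors, which is how we
read the reference description.

## The synthetic cohort generator

Because the cohorts this kind of analysis targets are access-restricted,
the package
ships a generator that emulates the assumed data structure with full
ground truth: per-sample mixtures of normal and abnormal plasma cells
(abnormal fraction = purity, clonal chain Bernoulli(0.5)); normal-cell
kappa fractions drawn TruncNormal($\mu, \sigma^2$) on $[0,1]$ by
inverse-CDF sampling (exact, no rejection); expected counts as
library-size-scaled shares $W h_c$ from `k_true` latent signatures with
exclusive high-weight marker blocks; abnormal cells drawn around 1–3
subclone profiles, each concentrated on its own tumor signature on top of
a moderate core program common to all subclones of that tumor (subclones
descend from one clone and share its program), normal cells around a
shared normal program (this is what makes the normal-PC signature and
both halves of the heterogeneity analysis — private signatures flagged,
shared ones not — recoverable); dedicated
high-mean Poisson components for the clonal light-chain gene (5% of the
library, against a $5\times 10^{-4}$ cross-chain background, so chain
assignment is nearly noiseless, as in real plasma cells); log-normal
library sizes (median 5000 UMIs), reproducing per-cell total
overdispersion while keeping counts Poisson conditional on the rate; and
optional planted fold changes. Planted genes get signature-flat baselines
so their expression is identical in both populations before the effect,
and the applied multiplier is solved so the *post-renormalisation* fold
change equals the requested one.

Cohort defaults mirror the reference design: 9 NBM, 6 MGUS, 12 SMM, 8 MM samples;
per-stage purity ranges NBM 0, MGUS 0–0.81, SMM 0.58–1, MM 0.98–1;
$\mu = 0.6, \sigma = 0.05$. The gene panel defaults to 500 genes — a
desk-scale stand-in for a highly-variable-gene subset — and `k_true = 5`
latent signatures; tests and the acceptance script state their sizes
explicitly (e.g. 500 genes × 2000 cells with 10 NMF restarts from
`K_init = 10`, and a 12-sample end-to-end fixture). What passing tests on
these cohorts do *not* show: robustness to doublets, ambient RNA,
batch effects on expression (batch labels are generated exchangeable),
UMAP-realistic manifold geometry, or gene–gene correlation beyond the
low-rank structure — the generator is a model of the analysis
assumptions, not of a sequencer.

## Pipeline and reproducibility

`run_pipeline()` chains the stages (simulate, QC, normalize, purity,
label, DE, NMF, signature stats, report), writing plain TSV/JSON
artifacts plus a parameter log per stage; a thin command-line wrapper
ships in `inst/scripts/`. One global seed is fanned out to stages through
named substreams (`substream_seed()`), so any stage is reproducible in
isolation and reruns are byte-identical. Degenerate inputs are handled
explicitly: empty QC survivors warn rather than error, cells whose
adjusted totals vanish are dropped with a warning, all-tie genes get
p = 1, zero-weight signature columns are pruned with a warning, and
single-cluster heterogeneity is reported as undefined rather than false
precision.
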