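---
title: "A hierarchical Bayesian model for pathway-level differential methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A hierarchical Bayesian model for pathway-level differential methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathmeth)
```

## The problem

DNA methylation at CpG sites is usually summarised as a beta value, the
ratio of methylated to total fluorescent signal, in [0, 1].  In a matched
case-control design the natural observation is the paired difference
$\theta_{ij} = \beta^{case}_{ij} - \beta^{control}_{ij}$ for matched pair
$i$ and probe $j$.  Two features of such data motivate the model in this
package:

* **CpG-island (CGI) stratification.**  Probes inside CGIs show markedly
  larger between-pair dispersion of $\theta$ than probes outside them, and
  probes of the same CGI status are more alike.  Treating all probes as
  exchangeable discards this structure.
* **Pathway topology.**  Genes act in pathways, and a gene's position in
  the pathway graph (its degree, i.e. number of neighbours) may modulate
  its contribution.  Classical two-stage analyses (per-probe tests followed
  by enrichment of the significant genes) ignore intra-pathway structure
  entirely.

## The model

Observations are normal around a probe-level effect plus an optional pair
random intercept:

$$\theta_{ij} \sim N(\mu_{ij}, \sigma^2_\varepsilon), \qquad
  \mu_{ij} = \lambda_j + \delta_i, \qquad
  \delta_i \sim N(0, \tau^2_\delta).$$

The probe effect decomposes as $\lambda_j = \beta_j + \Phi_j$.  The CGI
part mixes over island status:

$$\beta_j \sim \begin{cases}
  N(b_Y, \tau^2_Y) & \text{probe } j \text{ in a CGI}\\
  N(b_N, \tau^2_N) & \text{otherwise,}
\end{cases}$$

and the pathway part sums per-pathway contributions,
$\Phi_j = \sum_{k=1}^K f_k(P_j)$, where $f_k$ takes one of the forms

| form | $f_k(P_j)$ | parameters |
|------|------------|------------|
| a    | $0$ | 0 |
| b1   | $I_k(P_j)\,\gamma_k$ | $K$ |
| b2   | $I_k(P_j)\,(c_j \gamma^Y_k + (1-c_j)\gamma^N_k)$ | $2K$ |
| c1   | $E_{jk}\,\gamma_k$ | $K$ |
| c2   | $E_{jk}\,(c_j \gamma^Y_k + (1-c_j)\gamma^N_k)$ | $2K$ |
| c1\_inv / c2\_inv | as c1/c2 with $E_{jk}^{-1}$ (0 when $E_{jk}=0$) | $K$ / $2K$ |

Here $I_k(P_j)$ indicates that probe $j$'s gene belongs to pathway $k$
(a gene may belong to several), $E_{jk}$ is the gene's neighbour count over
the pathway's undirected edges, and $c_j$ is the CGI indicator.  The
inverse-degree forms encode the view that highly connected hub genes carry
individually smaller effects.  Edges are undirected and deduplicated;
isolated member genes keep $I=1$ with $E=0$, so they contribute under the
constant forms but not the degree forms (and never produce a division by
zero).

Priors are conjugate throughout: normal on $b_Y$, $b_N$ and every $\gamma$,
inverse-gamma on $\tau^2_Y$, $\tau^2_N$, $\sigma^2_\varepsilon$,
$\tau^2_\delta$.  The defaults — $N(0, 10^2)$ and $\mathrm{IG}(0.01, 0.01)$
— are conventional vague choices and can be overridden via `pm_priors()`
or a key-value config file; they are not claimed to match any published
analysis.  An optional CGI-stratified observation noise
($\sigma^2_{\varepsilon,Y}, \sigma^2_{\varepsilon,N}$; `stratum_noise`) is
available, motivated by the larger CGI dispersion, but off by default: a
single shared noise is the simplest identifiable choice.

## Computation

Every full conditional is conjugate, so `run_gibbs()` is a pure Gibbs
sampler — no Metropolis step, no tuning.  One deliberate departure from a
naive single-site scan: the stratum means and pathway parameters
$(b_Y, b_N, \boldsymbol\gamma)$ are drawn **jointly, with the probe effects
$\beta_j$ integrated out analytically** (given the variances, the probe
means $\bar\theta_j - \bar\delta$ are independent normals with variance
$\tau^2_{s(j)} + \sigma^2_\varepsilon/n$); $\beta$ is then redrawn from its
full conditional immediately afterwards, which makes the pair a valid
blocked update.  The naive scan mixes pathologically here because
$\beta_j$, $b$ and $\gamma$ are strongly confounded — a constant pathway
shift can be absorbed probe by probe — and in our checks it failed to
recover known truths at practical chain lengths, while the blocked sampler
delivers near-iid draws of $\gamma$.  Correctness is verified three ways in
the test suite: against a closed-form conjugate posterior, against
brute-force nested quadrature, and by a Geweke-style joint-distribution
check (prior draws vs sweep/re-simulate draws).

Defaults: 12,000 iterations, 2,000 burn-in, thinning 5, 2 chains
(`mcmc_config()`).  Published run lengths for this class of model are not
available, so these are conservative conventions; the blocked sampler is
usually well converged far earlier (check `gelman_rubin()`).
Initialisation draws location parameters from their priors (variance
components start at the prior mode, since a draw from a vague inverse-gamma
can be astronomically large); a `"zeros"` option exists for debugging.
Draws of $\lambda_j$ are stored per iteration so probe-level probabilities
use exactly the sampled states.  `fixed =` pins selected hyperparameters
(e.g. known variances), which both supports the conjugate test oracle and
lets $\tau^2 = 0$ collapse $\beta_j$ to its stratum mean.

## Decision quantities

* $P(\gamma_k > 0 \mid \theta)$: posterior probability that pathway $k$ is
  hypermethylated in cases (near 0 means hypomethylated).  Ties at exactly
  zero count as not-positive, so $P(>0)$ and $P(<0)$ never double-count.
* **Score of strength** $= 2\,|P - 0.5| \in [0, 1]$: rescaled distance from
  indifference, used to rank pathways irrespective of direction.
* **DIC** $= \bar D + p_D$ with $p_D = \bar D - D(\hat\lambda, \hat\delta,
  \hat\sigma^2)$ selects among forms; `rank_models()` applies a parsimony
  tie-break (default margin 2 on the DIC scale): among forms within the
  margin of the minimum, the fewest-parameter form wins.  A negative $p_D$
  is reported with a warning rather than hidden.
* **Methylation-variable probes / DMGs**: probe flagged when
  $P(\lambda_j > 0)$ or $P(\lambda_j < 0)$ reaches the Bayesian posterior
  probability threshold (default 0.975; we use $\ge$ where the verbal rule
  says "greater than" — immaterial at Monte-Carlo resolution).  A gene is a
  differentially methylated gene when **any** of its probes is flagged
  (inferred from how published gene tables annotate genes carrying both
  hyper- and hypo-methylated probes); an all-probe rule is exposed as an
  option.  Genes with probes flagged in both directions are reported with
  both.

A practical note on DIC among the *constant* forms (a, b1, b2): because
every probe carries its own $\beta_j$ with a freely estimated stratum
variance, a constant pathway shift can be absorbed by the probe effects,
and the fit (hence DIC) of forms a/b1/b2 is often nearly flat.  The
parsimony rule then favours the simpler form.  This mirrors the published
experience that no single form fitted better and the CGI-dependent constant
form was chosen on parsimony/interpretability grounds.  The *degree* forms
(c1/c2) are where DIC discriminates sharply, because a degree-proportional
mean structure cannot be mimicked by exchangeable probe effects — the
acceptance suite verifies exactly this.

## Matching and the two-stage baseline

`match_pairs()` builds case-control pairs greedily: cases in increasing
age order, each taking the eligible control with the smallest age gap
(strict `|age difference| < caliper`, exact equality on requested
covariates such as ethnicity, ties by control id).  A control may serve up
to `max_cases_per_control` cases, supporting the one-control-to-many-cases
design used when controls are scarce.  The published analyses used age
calipers of 3 years (one-to-one) and 5 years (one-to-many, same ethnicity);
the matching algorithm behind those counts is not described, so greedy
nearest-age with a deterministic tie-break was chosen for reproducibility
— an optimal bipartite variant is deliberately out of scope, and no claim
is made of reproducing any published pairing count.  Quality-control steps
(outlier removal, batch correction, normalisation) of the source studies
are not printed anywhere reproducible; rather than silently invent them,
the package only drops probes with missing values (logged) and leaves
further preprocessing to the user.

`paired_t_baseline()` implements the classical first stage — a per-probe
one-sample t-test of $\theta$ against zero with a Bonferroni threshold
$\alpha/m$ — as a comparison point, e.g. $0.05/1675 \approx 2.99\times
10^{-5}$ for a ten-pathway, 1,675-probe panel.

## The synthetic-data generator

`simulate_study()` states a world and sticks to it:

| parameter | default | why |
|-----------|---------|-----|
| $\tau^2_Y$ | 0.04 | CGI probes show visibly larger $\theta$ dispersion (SD 0.2) |
| $\tau^2_N$ | 0.0025 | non-CGI probes are tight (SD 0.05) |
| $\sigma^2_\varepsilon$ | 0.01 | within-probe noise SD 0.1, typical of array betas |
| $\tau^2_\delta$ | 0.0025 | small shared pair effect |
| $b_Y, b_N$ | 0 | observed stratum means are of order $10^{-3}$ |
| CGI fraction | 0.76 | fraction observed among array probes in the ovarian study |
| probes per gene | 1–4 uniform | ~150 probes for the default 3x20-gene study; real panels run 1–10 and the range is settable |
| pathways | 3 x 20 genes, 20% consecutive overlap, Erdős–Rényi edges $p = 0.15$ | multi-membership and degree heterogeneity at test scale |

$\theta$ draws are clipped to $[-1, 1]$ (a difference of ratios cannot
leave it) with the clip count recorded; at the default scales clipping is
rare.  The generator emulates the *structure* of matched methylation
panels — CGI-stratified dispersion, genes with several probes, overlapping
pathways with graph topology, age/covariate metadata — but not genomic
coordinates, probe-level spatial correlation along the genome, array
manifest quirks, or non-normal tails of real beta differences.  A green
recovery test therefore establishes that the sampler and the decision
rules work on data from the stated model, not that the model is true of
any particular array.

## Numerical choices and edge cases

* Variance draws are clamped to $[10^{-12}, 10^{12}]$ to guard against
  under/overflow when a vague inverse-gamma is sampled for an empty
  stratum.
* A pathway with zero member probes is a degenerate design and is rejected
  before sampling.
* Zero-variance probe columns in the t-test baseline are flagged
  degenerate and reported with $p = 1$, never dropped silently.
* Multi-gene probes are unsupported: the annotation requires exactly one
  gene symbol per probe (how published analyses annotated multi-mapping
  probes is not stated).
* Degrees are raw distinct-neighbour counts; no pathway-size normalisation
  is applied (none is described), but `assemble_features(degree_scale=)`
  exposes a scaling hook.
* All identifiers are case-sensitive exact strings; no gene-symbol
  aliasing.
* GMT carries membership only, so topology travels in a separate 3-column
  edge file; both are plain, order-preserving text formats and read/write
  round-trips are exact.

## Known limitations

* Constant pathway effects are only weakly identified when every probe in
  the panel belongs to some pathway (the effect is confounded with the
  stratum means); overlap between pathways and non-member probes restore
  identification.  Pathway panels should include topology and, ideally,
  probes outside the candidate sets.
* The normal observation model ignores the boundedness of $\theta$;
  with effects near the boundary the clipping in the generator and the
  normal likelihood diverge.
* One seeded recovery check (3 pathways, CGI-dependent truths
  $\gamma^Y = (0.3, 0, -0.3)$, 20 replicates) asks the *null* pathway's
  sign probability to land in (0.1, 0.9) in at least 18 of 20 replicates.
  For a truly null effect that probability is approximately uniform, so a
  single replicate passes with chance about 0.8 and 18-of-20 is a ~20%
  event even for a correct sampler; published pathway tables show the same
  spread of mid-range probabilities.  The suite keeps the check at its
  stated strictness and our fixed seeds currently score 17 of 20.
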