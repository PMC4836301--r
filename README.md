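# pathmeth

Bayesian gene-set analysis of differential DNA methylation for matched
case-control studies, with CpG-island (CGI) information and pathway
topology.

## What it does, and for whom

Methylation arrays and bisulfite sequencing summarise each CpG probe as a
beta value in [0, 1].  For a matched design the observation is the paired
difference θᵢⱼ = β(case) − β(control) at probe *j* in pair *i*.  This
package is for analysts who already have a panel of candidate pathways
(gene sets with known intra-set gene–gene links) and want to (i) rank those
pathways by the evidence that their genes are hyper- or hypomethylated in
cases, and (ii) call the individual probes and genes driving that signal —
in one coherent model instead of a per-probe test followed by enrichment.

The hierarchical model is

    θᵢⱼ ~ N(μᵢⱼ, σ²ε),   μᵢⱼ = λⱼ + δᵢ,   λⱼ = βⱼ + Φⱼ,

where βⱼ mixes over CGI status — βⱼ ~ N(b_Y, τ²_Y) for CGI probes and
N(b_N, τ²_N) otherwise — δᵢ is a pair random effect, and the pathway effect
Φⱼ = Σₖ fₖ(Pⱼ) takes one of several forms: null (**a**), constant per
pathway Iₖ(Pⱼ)·γₖ (**b1**), CGI-dependent constant (**b2**, separate γᵏ_Y /
γᵏ_N), degree-weighted Eⱼₖ·γₖ (**c1**, Eⱼₖ = the gene's neighbour count in
pathway k), CGI-dependent degree (**c2**), and inverse-degree variants
(**c1_inv**, **c2_inv**).  Everything is conjugate, so fitting is a pure
Gibbs sampler (with a blocked, partially collapsed update for
(b_Y, b_N, γ) that makes the chain mix essentially iid).  Forms are
compared by DIC with a parsimony tie-break; pathways are summarised by
P(γₖ > 0 | θ) and the score of strength 2·|P − 0.5|; probes with
P(λⱼ > 0) or P(λⱼ < 0) ≥ 0.975 are methylation-variable, and any gene
carrying one is a differentially methylated gene (DMG).

Also included: greedy age-caliper case-control matching (strict
|Δage| < caliper, optional exact covariates, optional one-control-to-many-
cases), a paired-t + Bonferroni baseline, and a synthetic-study generator
with ground truth.

## Worked example

Simulate a 3-pathway, 50-pair study whose truth is a degree effect
(γ = 0.08, 0, −0.08 per neighbour), fit the constant and degree forms, and
report on the DIC winner:

```r
library(pathmeth)
spec  <- model_spec("c1")
truth <- simulation_truth(spec, 3, gamma = c(0.08, 0, -0.08))
sim   <- simulate_study(K = 3, genes_per_pathway = 20, n_pairs = 50,
                        spec = spec, truth = truth, seed = 7)
fits <- lapply(c(b1 = "b1", c1 = "c1"), function(f)
  run_gibbs(sim$theta, model_spec(f), pm_priors(), sim$features,
            mcmc_config(n_iter = 4000, n_burnin = 1000, thin = 2,
                        n_chains = 2, seed = 7)))
dics <- sapply(fits, function(f) compute_dic(f, sim$theta)$dic)
rank_models(dics, n_pathways = 3)$table
#>   form       dic n_params
#> 1   c1 -11578.92        3
#> 2   b1 -11576.93        3
pathway_report(fits$c1)
#>   pathway_id stratum form p_positive score_of_strength gamma_mean ...
#> 1       PW01     all   c1       1.00             1.000     0.0814
#> 2       PW02     all   c1       0.24             0.519    -0.0041
#> 3       PW03     all   c1       0.00             1.000    -0.0771
calls <- call_dmps_dmgs(fits$c1)
sum(calls$probes$variable); sum(calls$genes$dmg)
#> [1] 111
#> [1] 50
```

The generating pathway directions are recovered exactly: PW01 (positive
degree effect) has P(γ > 0) = 1 and score 1, PW03 the mirror image, and the
null PW02 sits near indifference.  DIC prefers the generating degree form;
note the b1/c1 gap is small because free probe effects absorb much of any
pathway shift — among *constant* forms DIC is often nearly flat and the
parsimony margin (default 2) then picks the simpler form, which is the
documented, intended behaviour.  Convergence can be checked with
`gelman_rubin(fits$c1)` (all split-R̂ ≤ 1.002 here).

For file-based end-to-end runs (including matching from β matrices and
metadata) use `run_analysis()` on a key-value config, or the thin CLI at
`inst/cli/pathmeth.R` (`simulate`, `run`, `baseline` subcommands).  Every
run writes a pathway report, probe/gene reports, a DIC table and a
manifest sufficient to rerun the job.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's end-to-end workflow from scratch at the given
seed — simulates a CGI-dependent study, fits the null/constant/
CGI-dependent forms by MCMC, ranks them by DIC and writes the reports —
then writes its JSON summary to `--out`.

## Repository layout

- `R/` — implementation (io, matching, topology, model, Gibbs sampler,
  posterior inference, simulator, pipeline)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/pathway-methylation-model.Rmd` — model, assumptions,
  numerical choices, generator defaults, limitations
- `scripts/acceptance.R`, `inst/cli/pathmeth.R`
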