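# mdsn

MiRNA Dysregulational Synergism Networks: miRNA module discovery from
differential miRNA–target correlation, and module-regularized cancer-stage
classification.

## The problem

MicroRNAs repress their target mRNAs, but *which* targets a miRNA represses
can change between tumor subtypes of a heterogeneous cancer. A miRNA
biomarker selected from a single normal-vs-tumor differential-expression
analysis may therefore fail on subtypes in which that miRNA regulates a
different target set. `mdsn` implements a pipeline that works from the
*changes in miRNA–target regulation* between sample subgroups instead:

1. **Dysregulation testing.** For every miRNA *i* and mRNA *j*, Pearson
   correlations r_A and r_B are computed in two sample groups and compared
   through Fisher's transformation, z = ½·ln((1+r)/(1−r)):

       z_AB = (z_A − z_B) / sqrt(1/(n_A − 3) + 1/(n_B − 3))

   with a two-tailed normal p-value. A pair is a *dysregulation* when
   p < 0.001 and the pair is negatively correlated in at least one group
   (miRNAs repress targets, so inverse correlation is a prerequisite).
   A permutation test on the raw correlation difference
   Dys = r_A − r_B is provided as a nonparametric companion.
2. **Association matrix.** Repeating the test over all subtype pairs gives
   a binary miRNA × (target, analysis) matrix **A** whose rows profile each
   miRNA's dysregulated targets across analyses.
3. **Synergism network.** Functional similarity of two miRNAs *p*, *q* is
   the cosine similarity s(p,q) = A_p·A_q / (‖A_p‖‖A_q‖) of their rows —
   shared dysregulated targets normalized by total connections. The
   resulting weighted miRNA–miRNA network (the MDSN) is pruned with a hard
   threshold chosen as the smallest grid value whose degree distribution
   keeps a scale-free fit R² = cor(log10 k, log10 p(k))² ≥ 0.8.
4. **Modules.** Louvain modularity optimization (two-phase greedy, weighted)
   partitions the pruned MDSN into miRNA modules; partitions from
   independent analyses are compared with normalized mutual information.
5. **Classification and biomarkers.** A one-vs-rest logistic classifier of
   cancer stage is fitted to miRNA expression with the Sparse Group Lasso
   penalty over the discovered modules,

       min_W (1/s) Σ log(1 + exp(−c_i·Wᵀx_i)) + λα‖W‖₁ + λ(1−α) Σ_g √|g|·‖W_g‖₂

   so that if one module member is selected, its co-members are favored
   too. Nonzero coefficients rank candidate biomarkers, evaluated by
   precision/recall at k against a user-supplied known-marker list.

A synthetic-cohort generator (`simulate_cohort()`) plants subtype-specific
dysregulation modules and stage signal with known ground truth, and backs
the validation suite.

## Worked example

```r
library(mdsn)

sim <- simulate_cohort(effect_size = 8, noise_sd = 0.5, seed = 42)

cfg <- read_config()
cfg$threshold   <- 0.3    # planted-clique networks are not scale-free
cfg$seed        <- 42L
cfg$sgl_lambda  <- 0.05

res <- mdsn_pipeline(sim$mirna, sim$mrna, sim$design, config = cfg,
                     known_set = names(which(sim$truth$module_of == 1)),
                     k_list = c(5, 10))
res
#> <mdsn_result>
#>   dysregulations: 639 across 1 analyses
#>   network: threshold 0.3, 40 non-isolated nodes
#>   modules: 4 (modularity 0.7499)
#>   SGL macro-AUROC: 0.620

nmi(res$partition, ground_truth_partition(sim$truth))
#> [1] 1

res$biomarkers
#> # A tibble: 2 × 4
#>       k n_hits precision recall
#>   <dbl>  <int>     <dbl>  <dbl>
#> 1     5      5       1      0.5
#> 2    10      8       0.8    0.8
```

The cohort plants four miRNA modules (10 miRNAs each) whose targets are
repressed (ρ = −0.8) in subtype A and unregulated in subtype B. The
pipeline finds 639 significant dysregulations in the A-vs-B analysis
(600 planted pairs plus the expected false positives at p < 0.001),
builds the MDSN on the 40 miRNAs found dysregulated, and recovers the
planted partition exactly (NMI = 1, modularity 0.75 — four equal-weight
cliques). Module 1 carries the stage signal; with it as the "known" set,
all top-5 and 8 of the top-10 ranked SGL candidates are module-1 members.
Per-class AUROC is strongest for the extreme classes (normal, IV ≈ 1.0)
and weak for intermediate stages, as expected for a linear one-vs-rest
score on an ordinal latent signal at n = 24 per stage.

`tidy()`, `glance()` and `autoplot()` methods are available for the
association matrix, network, partition and fitted model, and
`write_mdsn_results()` writes deterministic TSV/JSON outputs. A thin CLI
lives at `inst/cli/mdsn.R` (`simulate`, `dysreg`, `pipeline` subcommands).

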