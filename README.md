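# ppea

Per-transcript predictive power estimation for two-class expression
studies, by iterative two-way bootstrapping.

## The problem

Expression studies that try to predict a binary phenotype — a compound
treatment causing liver toxicity or not, for instance — typically have
thousands of transcripts and only tens of samples. Classifiers trained in
that regime overfit: they describe the training cohort perfectly and
generalise poorly, and the gene lists they select are unstable across
studies. `ppea` is for analysts who want a *ranking of individual
transcripts by predictive power* rather than one fragile multivariate
signature, and then a minimal signature built from the top of that
ranking.

## The method

Per-transcript counters are accumulated over many randomised iterations:
`T_i` — times transcript `i` was drawn; `S_i` — times it took part in a
model that passed an honest hold-out test; `R_i = S_i / T_i` — its
estimated predictive power. Each iteration:

1. draws `p` transcripts at random and, per class, a random
   `floor(beta * M_k)` training samples (remainder = disjoint test set),
   keeping `p` below the training sample count so no individual model can
   overfit by dimensionality alone;
2. fits a nearest shrunken centroid (PAM) classifier, with the shrinkage
   threshold Δ chosen by stratified 10-fold cross-validation ("lowest
   error with fewest genes"); if no Δ reaches CV error ≤ α the hold-out
   test is skipped;
3. otherwise scores the disjoint test samples: test error `e < α` makes
   the iteration a success, and the transcripts surviving shrinkage are
   credited in `S`.

Transcripts are ranked by decreasing `R`; every `checkpoint_every`
iterations the rank vector is snapshotted, and the run stops when the
Spearman correlation between consecutive snapshots reaches `rho_stop`.
Around the loop the package provides the standard preparation steps
(informative-transcript filtering against vehicle controls; ridit analysis
of ordered severity grades with positive/negative/excluded treatment
labeling), minimal top-n signature construction with confusion-matrix
metrics, a synthetic two-class generator with planted markers, and a CLI
(`inst/cli/ppea.R`).

## Worked example

```r
library(ppea)
library(dplyr)

sim <- standard_recovery_fixture()   # 500 genes x (20+20), 10 planted at 3 SD
sim$matrix
#> <ppea_matrix> 500 genes x 40 samples (20 positive / 20 other)

cfg <- ppea_config(alpha = 0.2, beta = 0.5, genes_per_iter = 8,
                   max_iters = 20000, checkpoint_every = 5000, seed = 1)
fit <- run_ppea(sim$matrix, cfg, keep_log = FALSE)
fit
#> <ppea_fit> 500 genes, 20000 iterations (2858 success / 1202 tested-fail / 15940 no-model)
#>   stopped: FALSE; last rho: 0.88589

tidy(fit) |> head(5)
#> # A tibble: 5 × 5
#>   gene_id     T     S     R  rank
#>   <chr>   <int> <int> <dbl> <int>
#> 1 g0009     281   281 1         1
#> 2 g0005     302   300 0.993     2
#> 3 g0007     346   342 0.988     3
#> 4 g0003     283   277 0.979     4
#> 5 g0010     335   326 0.973     5
```

After 20,000 iterations every planted marker (`g0001`–`g0010`) sits in the
top 10 ranks: their `R` values (0.88–1.00) say they took part in a
successful, independently tested model in nearly every draw, while noise
transcripts succeed only as occasional passengers (median `R` ≈ 0.01). `plot_rank_stability(fit)` shows the Spearman trace the stop
criterion watches; `autoplot(fit)` shows `R` against rank.

A minimal signature from the finished ranking:

```r
sig <- build_signature(sim$matrix, fit)
sig
#> <ppea_signature> 10 genes, CV error 0.000 (delta = 4.747)
#>   g0009, g0005, g0007, g0003, g0010, g0001, g0008, g0004, g0006, g0002

evaluate(sig, sim$matrix)   # resubstitution metrics; use held-out data when you have it
#> # A tibble: 1 × 9
#>      TP    FN    FP    TN sensitivity specificity   ppv   npv error_rate
#>   <int> <int> <int> <int>       <dbl>       <dbl> <dbl> <dbl>      <dbl>
#> 1    20     0     0    20           1           1     1     1          0
```

The 10-transcript model meets the ≤20% cross-validated error bound
immediately (here: error 0), so no expansion to 15 or 20 transcripts is
needed.

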