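# prsbils

Polygenic risk scores (PRS) with a **bilevel continuous shrinkage prior**:
half-Cauchy shrinkage scales on individual variants *and* on functional
annotation groups (gene categories, pathways — overlapping or not), fitted by
a blocked Gibbs sampler from GWAS summary statistics and an external LD
reference panel. For statistical geneticists who have marginal association
results, a reference panel, and a variant→annotation mapping, and want
annotation-aware effect-size shrinkage plus group-weighted scores.

## The model

With standardized genotypes and phenotype, marginal effects
`β̂ = Gᵀy/N` (i.e. `z/√N`) and block-diagonal LD `D = GᵀG/N`:

```
y = Gβ + ε,     ε ~ MVN(0, σ²I),          p(σ²) ∝ 1/σ²
β | σ², δ², λ² ~ MVN(0, (σ²/N) V_δ V_λ)
δ_k ~ C⁺(0,1)   per annotation group k    (group shrinkage)
λ_j ~ C⁺(0,1)   per variant (copy) j      (local shrinkage)
```

Because the half-Cauchy is an inverse-gamma scale mixture, every conditional
is conjugate and the posterior is explored by a Gibbs sampler whose β-update
works block-wise on the LD partition:

```
β | ·  ~ MVN( (N/σ²) Σ β̂ , Σ ),   Σ = (σ²/N) [D + (V_δ V_λ)⁻¹]⁻¹
```

A variant in several groups is expanded into one *copy* per membership (M′
copies in total), each with its own effect and local scale. Group-wise scores
`PRS_k = Σ_{j∈k} G_j β̃_j` are combined with weights `α_k` fitted by tenfold
cross-validation on individual-level validation data, optionally hybridised
with a conventional PRS (`+ γ·PRS_conv`). The package also ships the
single-group continuous-shrinkage benchmark (`prscs_auto` mode, gamma-gamma
local prior, sampled global scale) and an annotation-informed posterior-mean
comparator with L ranked effect-size bins, plus a synthetic-data engine and a
benchmark driver that reproduces the method comparison end to end.

## Worked example

Simulate a study with a sparse group architecture — four annotation groups
explaining 0%, 0%, 10% and 90% of a total heritability of 0.7 — then fit the
bilevel model and score a disjoint test panel:

```r
library(prsbils)
st    <- sim_setting(1)                  # q = (0, 0, 10, 90)%, h² = 0.7
study <- simulate_study(st, seed = 42)   # GWAS, test and LD-reference panels
post  <- run_gibbs(study$ss, study$ld, study$annot, prsbils_config(seed = 42))
post
#> prsbils_posterior: 2000 effect copies, 4 groups; mode bils ; 100 kept draws
round(post$delta2_mean, 3)
#> [1] 0.764 0.771 0.834 0.767

res <- fit_method(study, "bils", bils_post = post, cv_seed = 42)
round(unlist(res$overall), 3)
#>   AUC    R2
#> 0.851 0.700
round(res$fit$alpha, 3)
#>     g1     g2     g3     g4
#>  0.065 -0.017  0.822  1.941
```

The cross-validated combination weights tell the story: the two
zero-heritability groups get weights near 0, the 10% group 0.82, the 90%
group 1.94 — annotation information concentrated into the score. The
single-group benchmark on the same data:

```r
cs <- fit_method(study, "prscs", cfg = prsbils_config(seed = 42), cv_seed = 42)
round(unlist(cs$overall), 3)
#>   AUC    R2
#> 0.782 0.479
```

AUC here is computed after labelling the top decile of the quantitative
phenotype as the at-risk class; R² is the squared correlation between the
held-out prediction and the phenotype.

A command-line front end wraps the same functions:

```sh
exec/prsbils simulate --setting 1 --seed 3 --out simdir
exec/prsbils sample --sumstats simdir/sumstats.tsv --n-gwas 2000 --dialect z \
    --ld-ref simdir/test --annot simdir/annotations.tsv --seed 3 --out weights.tsv
exec/prsbils score --weights weights.tsv --panel simdir/test \
    --pheno simdir/phenotype.tsv --seed 3 --out metrics.tsv
```

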