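# drmsim

Tools for studying **false recognition in the Deese–Roediger–McDermott
(DRM) paradigm** with vector-space models of prior knowledge. The package
is aimed at memory and psycholinguistics researchers who want to build
similarity-graded DRM stimulus lists from embedding spaces, simulate
recognition behaviour with known structure, and run the trial-level
mixed-model analysis that separates vision-based from language-based
similarity effects.

## The model

Every category has two vector representations: a **visual prototype**
(the centroid of many image-exemplar embeddings) and a **distributional
word vector**. For a lure item *i* presented at recognition after
studying list *S*, each modality contributes one predictor

```
sim_m(i, S) = cos( v_m(i), mean_{j in S} v_m(j) ),   m in {vision, language}
```

and the probability of falsely calling the lure "old" is modelled by a
binomial GLMM with crossed random intercepts for participant *p* and
list *l*:

```
logit P(old) = b0 + b_v * z(sim_vision) + b_l * z(sim_language) + u_p + u_l
u_p ~ N(0, s_p^2),  u_l ~ N(0, s_l^2)
```

The two predictors enter **hierarchically**: a baseline model with one
predictor is compared with the test model containing both via AIC,
Akaike weights (`w_i ∝ exp(-Δ_i/2)`) and the likelihood-ratio χ²;
ΔAIC = 2 corresponds to an evidence ratio of e ≈ 2.7. Collinearity is
checked with VIF = 1/(1−R²), effects are reported as odds ratios with
Wald intervals, and descriptives (pHit, pFA, and the nonparametric
sensitivity index A′) summarise performance per participant × category.

Because the real inputs (ImageNet-derived CNN prototypes, Italian
fastText vectors, participant responses) are external data, the package
ships a first-class **synthetic-data generator**: coupled
vision/language spaces built from a shared latent layer whose mixing
weight is calibrated so the two lure-similarity metrics rank-correlate
at ρ ≈ .58, plus a Bernoulli response simulator that inverts the GLMM
above.

## Worked example

```r
library(drmsim)

cfg <- run_config(n_participants = 40, master_seed = 2026,
                  output_dir = "runs/demo")
bundle <- run_pipeline(cfg)
```

The pipeline logs one line per stage:

```
[generate] 1687 items; vision d=128, language d=300, alpha=0.190
[filter] 1687 of 1687 catalog items retained
[lists] 12 lists x (30 studied, 10 targets, 10+10 lures)
[similarity] 240 lure rows; cross-modal rho = 0.636 (p = 0)
[simulate] 40 participants, 14400 rows (9600 lure rows)
[compliance] 0 participant(s) excluded; 14400 rows analyzed
[glmm] baseline AIC 7621.0, test AIC 7603.2, dAIC 17.74, w(test) 1.000
[interaction] dAIC favouring interaction = -1.99
```

12 lists are built from the vision space (30 studied items each, 10
returning as targets, plus 10 close and 10 far lures); the two
similarity metrics correlate at ρ = .64 on this seed (the seed-averaged
default is ρ ≈ .58); 40 simulated participants contribute 240 lure
observations each (9,600 analysis rows). Adding language-based
similarity to a vision-only baseline improves fit (ΔAIC = 17.7), the
interaction term does not earn its parameter (ΔAIC = −1.99), and the
test model recovers the simulation's slopes:

```r
bundle$test
#> <glmm_fit: 9600 obs, logLik -3796.61, AIC 7603.2, 5 params>
#>             term       b      se      z          p
#> 1    (Intercept) -1.5331 0.17976 -8.528  1.484e-17
#> 2   sim_vision_z  2.1230 0.05726 37.075 7.188e-301
#> 3 sim_language_z  0.1747 0.03944  4.430  9.418e-06

sapply(bundle$effects, function(e) sprintf("OR %.2f [%.2f, %.2f]", e$or_, e$ci_low, e$ci_high))
#>                  vision                language
#> "OR 8.36 [7.47, 9.35]" "OR 1.19 [1.10, 1.29]"

bundle$collinearity$vif
#>   sim_vision_z sim_language_z
#>       1.579814       1.579814
```

`b` is the change in log-odds of a false alarm per SD of similarity
(the simulation used 2.046 and 0.210); the VIF of 1.58 is far below the
conventional threshold of 5. All artifacts (`.vec` spaces, lists, trial
table, results JSON, manifest) land in `output_dir`, and
`replay("runs/demo/manifest.json")` reproduces the run byte-for-byte.

A thin command-line wrapper with subcommands (`run-all`, `replay`,
`calibrate-alpha`, `generate-spaces`, `build-lists`, `simulate`,
`analyze`) is installed at `inst/cli/drmsim`.

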