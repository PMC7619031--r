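---
title: "Modelling false recognition from vision- and language-based similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling false recognition from vision- and language-based similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In the Deese–Roediger–McDermott (DRM) paradigm, people study a list of
related items and later falsely recognise unstudied *lures* that resemble
the studied set. When the items are images with word labels, two distinct
sources of prior knowledge can drive that resemblance: visual experience
(how similar the things *look*) and linguistic experience (how similarly
the words are *used*). Both can be quantified from data: a category's
visual representation as the centroid of many image-exemplar embedding
vectors, and a word's linguistic representation as its distributional
(word-embedding) vector. For every lure, cosine similarity to the centroid
of the studied items — computed once in each space — yields two continuous
predictors of false recognition, whose joint contribution can be separated
in a single trial-level model.

`drmsim` implements this framework end to end: embedding-space containers
and similarity primitives, a similarity-driven DRM list generator, a
calibrated synthetic-data generator that stands in for the real embedding
spaces and participants, the recognition GLMM with its hierarchical model
comparison, and signal-detection descriptives.

## Similarity primitives and list construction

Similarity is always `cosine(u, v) = u·v / (‖u‖‖v‖)` on the stored
vectors; cosine supplies the normalisation, so vectors are never
re-scaled at load time. Zero vectors are legal in a container (catalogs
may carry items that are later filtered out) but rejected at similarity
time. Category prototypes are unweighted exemplar means
(`build_prototype()`), and the per-lure predictor is the cosine between
the lure and the unweighted mean vector of the studied items
(`centroid_similarity()`).

`build_lists()` turns one embedding space into `k` DRM lists (default
12). The space is partitioned by **spherical k-means** — ordinary k-means
on length-normalised vectors, which on the unit sphere minimises
within-cluster cosine dispersion — with 10 restarts. No particular
clustering algorithm is canonical for this step; spherical k-means is the
natural cosine-consistent choice, and the partition is exposed so any
alternative assignment can be passed in. For each cluster the builder
takes the 50 not-yet-assigned items most similar to the cluster centroid
(the *close pool*; ties broken by item id), draws 30 studied items from
it (10 of which return at recognition as targets), selects as *close
lures* the 10 remaining close-pool items nearest the **studied-set**
centroid, and draws 10 *far lures* from 50 random unassigned items
outside the close pool. Distances during selection use cosine throughout,
matching the similarity index used for the predictors.

Two scoping decisions deserve note, since the construction recipe leaves
them open. First, the close-lure candidate pool is the list's own
unassigned close-pool items (20 after studied selection); only if that
pool ran short — impossible under the default counts — would the builder
fall back to the nearest unassigned items space-wide, with a logged
message. Second, lists are fully disjoint: only assigned items (30
studied + 20 lures = 50 per list) are consumed, unused pool candidates
return to the pool, and no stimulus is encountered twice across blocks.
With 1,687 items and 12 lists of 50, capacity is ample.

Each lure is annotated with both similarity metrics against the same
studied ids (`similarity_table()`, 240 rows by default), and
`cross_modal_correlation()` reports their Spearman correlation. The
recognition phase also contains the 120 targets;
`similarity_table(include_targets = TRUE)` covers that 360-item
accounting, but the correlation and the GLMM operate on the 240 lures,
whose responses are the quantity of interest. Catalog filtering
(`filter_catalog()`) retains items with Zipf frequency ≥ 2 in both the US
and Italian norms (the exclusion rule is "lower than 2", so exactly 2
survives) and ≥ 100 exemplars.

## The synthetic-data generator

`generate_coupled_spaces()` emulates the one property of the real
vision/language spaces that the analysis leans on: their similarity
geometries overlap partially. Each item draws a latent core around one of
12 cluster centers (centre SD 1, within-cluster SD 0.5 — clusters well
separated but overlapping, so close pools are meaningfully graded); each
modality observes an orthonormal random projection of the core mixed with
independent Gaussian noise, `x = α·signal + (1−α)·noise`, both parts
scaled to unit coordinate spread. Orthonormal projections preserve inner
products exactly, so `α = 1` reproduces the latent geometry in both
spaces (cross-modal correlation 1) and `α = 0` decouples them.

The default `α` is **calibrated, not assumed**: the cross-modal overlap
of real embedding spaces is an empirical fact, so the packaged
`calibrate_alpha()` routine bisects on `α` until the default pipeline's
lure-similarity Spearman correlation averages .58 (±.02 over 10 seeds).
Because the per-seed correlation has SD ≈ .05, the frozen default
(`default_alpha()` = 0.190) was then confirmed on wider seed pools
(30–60 seeds per value), giving a seed-population mean of ρ ≈ .58.
The ρ(α) curve is steep near the default — raising `α` by .01 moves ρ by
roughly .1 — which is worth knowing before editing the mixing weight.

Defaults mirror the reference design: 1,687 items, 12 centers, language
dimension 300. The vision space is generated at 128 rather than 4096
dimensions: downstream stages consume similarity structure, and the
extra dimensions would only add runtime. The synthetic catalog draws
Zipf frequencies around the reference means (US 4.2 ± .85, IT 3.6 ± .86)
truncated to pass the familiarity filters, and exemplar counts in
100–200, because the 1,687-item catalog it emulates is *already
filtered*; `filter_catalog()` in the pipeline is therefore an audited
pass-through on synthetic runs. Cluster centers take the seven
descriptive category labels round-robin so category-level summaries are
exercisable.

`simulate_responses()` is the generative inverse of the analysis model:
lure endorsements are Bernoulli with logit
`β₀ + β_v·z_v + β_l·z_l + u_participant + u_list`, target endorsements
use a fixed hit log-odds, and each participant gets a truncated-normal
go/no-go compliance score. Defaults are declared choices, documented and
overridable, since no variance components or baseline rates are
available to copy: `β₀ = −1.7` (~15% false alarms at average similarity,
inside the descriptive false-alarm range .05–.25), `hit_logit = 1.1`
(~75% hits, inside .68–.81), both random-intercept SDs 0.5, compliance
.92 ± .05. Slope defaults are the image-task test-model estimates
(vision 2.046, language 0.210). `paper_scale_design()` wires generator,
list builder and simulator together at the planned scale: 40
participants × 240 lure observations = 9,600 analysis rows.

### What the generator does *not* emulate

Item content, word-frequency distributions, the Italian lexicon, image
typicality, and the real spaces' fine-grained geometry are all out of
scope. Passing tests therefore show that the *pipeline* recovers what it
simulates under the assumed statistical structure — not that the
substantive conclusions would replicate on the real stimuli and
participants, which require the original data.

## The inference module

Predictors are standardized (`standardize()`) over the analyzed
observation rows — the lure rows, since only responses to new stimuli
enter the model. In the balanced design this equals standardizing the
240 unique item values and broadcasting, up to the Bessel factor
`sqrt((Kn−1)/(K(n−1)))` ≈ 1.0016 at `K = 40`; the tests pin down this
exact relationship.

`fit_glmm()` estimates a logit-link Bernoulli GLMM with crossed Gaussian
random intercepts for participant and list by Laplace-approximated
maximum likelihood (`lme4::glmer`, the reference implementation's
default regime; adaptive quadrature is impractical for crossed factors).
Wald z and p values are reported per fixed term, `n_params` counts fixed
effects plus variance components (so adding one predictor moves AIC by
`2 − χ²`), and the AIC identity `AIC = 2k − 2ℓ` is asserted in tests.
Convergence reporting is honest: any optimizer complaint or singular
fit flips the `converged` flag and raises a warning; a slope that
diverges with an enormous standard error raises a complete-separation
error instead of returning garbage.

`compare_hierarchical()` implements the AIC machinery: Akaike weights
`w_i ∝ exp(−Δ_i/2)`, evidence ratio (for two models `exp(ΔAIC/2)`, so
ΔAIC = 2 ↔ ratio `e ≈ 2.7`), and the likelihood-ratio χ². `vif()` is the
textbook `1/(1−R²)` on the analyzed rows (for two predictors,
`1/(1−r²)` exactly); the two reported experiment-specific VIF values in
the reference analysis are not reproducible from the shared items alone
and are not attempted. `test_interaction()` refits with the product of
the standardized predictors and returns the same comparison, and
`odds_ratio_ci()` recovers `se = |b/z|` to turn any reported `(b, z)`
pair into an odds ratio with Wald bounds.

## Memory metrics

`recognition_summary()` computes per-participant × category hit and
false-alarm rates and the nonparametric sensitivity index
`a_prime()` — the Pollack–Norman A′ in its signed generalization, with
A′ = .5 at `h = fa`. The formula is stated in the function
documentation; it reproduces published descriptive cells at two decimals
when fed their mean rates (e.g. h = .76, fa = .05 → .92). Category
aggregates are means of per-participant A′, not A′ of mean rates — the
two differ by Jensen's inequality, and only the former matches
participant-averaged descriptive tables. `fa_above_zero_test()` uses a
one-sample Wilcoxon signed-rank test (exact for n ≤ 25 without zeros)
because rates are bounded and skewed and no parametric test is implied
by the design; `compliance_filter()` drops participants with go/no-go
accuracy strictly below 60%.

## Reproducibility

Every stage seed is derived from one master seed by the documented
counter scheme in `derive_seed()`, so `run_pipeline()` is fully
determined by its `run_config()` and any stage can be replayed in
isolation. The run manifest records package version, all parameters, all
derived seeds and a content checksum; `replay()` re-executes the run and
errors on any checksum mismatch. The two analysis orders
(`vision_first`, `language_first`) differ only in which predictor enters
the baseline model; their two-predictor test models are identical, which
the pipeline tests assert.

## Numerical choices and problem sizes

* `.vec` files are written with 8 significant digits — diffable yet
  lossless at every tolerance used in the package.
* k-means uses 10 restarts, 100 iterations; close-pool ties break
  lexicographically so list construction is reproducible even under ties.
* GLMM convergence follows `glmer` defaults; tests that deliberately
  simulate zero variance components tolerate the resulting (honest)
  singular-fit warnings.
* Monte-Carlo test sizes were chosen for tight feedback loops at
  desk scale: recovery checks average 20 seeds at the full 9,600-row
  design; interaction power/null checks run 4 seeds at 15 participants;
  calibration checks average 20 generator seeds. The vignette-stated
  population figures (e.g. ρ ≈ .58 ± .005 at the default `α`) come from
  the wider calibration pools described above.

## Known limitations

* The GLMM is intercepts-only on the random side — no random slopes,
  REML, or Bayesian alternatives — matching the target analysis exactly.
* A′ and the Wilcoxon test are conventions chosen here; other
  sensitivity indices (d′, A_z) and tests would slot into the same
  summary shape.
* The generator couples modalities through a single shared latent layer;
  real vision/language spaces share structure in more heterogeneous ways
  (e.g. category-dependent overlap), which the calibration deliberately
  collapses into one number.
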