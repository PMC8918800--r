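# fishcat

Analysis pipeline for visual object categorization in two-alternative
choice experiments with archerfish.

Archerfish report visual decisions by shooting a jet of water at one of
two images on a screen, which makes them a rare non-mammalian model for
studying object recognition behaviourally. In a paired-presentation
task they learn to categorize objects at the superordinate level —
animal (spider, insect) versus plant (leaf, flower) — and keep doing so
across changes in size, contrast and rotation, and for novel images.
`fishcat` is for researchers who want to model and dissect that
behaviour computationally: which image features could carry the
decision, how much of the error is perceptual versus execution noise,
and how per-fish success rates should be evaluated statistically.

## The model

The behavioural model is a three-stage cascade applied to each trial's
two stimuli:

1. **Perception.** Each grayscale object-on-white image is reduced to
   18 classical descriptors: area, convex-hull area and hull/area ratio
   (reciprocal solidity), perimeter, roundness
   (P²/4πA), the number and mean curvature of sharp contour sections,
   object and hull eccentricity (√(1−(b/a)²) of the second-moment
   ellipse), intensity entropy, standard deviation and skewness,
   checkerboard and star template correlations, grayscale and
   silhouette mirror symmetry, and mean and total image energy.
   A linear soft-margin SVM categorizes the descriptor vector; greedy
   forward selection orders features by their contribution to a
   repeated random 75/25 split protocol.
2. **Decision.** If exactly one branch reports the rewarded category,
   the choice follows it; if both agree, the choice is Bernoulli(0.5).
3. **Execution noise.** The decided response is flipped with
   probability `(model − target)/(2·model − 1)`, calibrated so the
   post-noise success rate matches a fish's observed rate (0.65–0.8).

Per-fish success counts are evaluated with a hierarchical beta-binomial
model: k<sub>fish</sub> ~ Binomial(n, p<sub>fish</sub>),
p<sub>fish</sub> ~ Beta(ω, κ) in mode/concentration form
(a = ω(κ−2)+1, b = (1−ω)(κ−2)+1) with broad uniform priors, sampled by
Metropolis-within-Gibbs (3 × 10,000 draws), and summarized by 95%
highest-density intervals against a ±0.05 region of practical
equivalence around chance.

Because the original photographic stimuli are not redistributable, the
package includes a parametric generator of animal-like (star-polygon
body with radial limbs) and plant-like (smooth leaf ellipse) stimuli
whose shape and texture statistics are dialled explicitly, rendered at
the five object-area levels used on the experimental screen. All
numbers below are computed on this synthetic material.

## Worked example

```r
library(fishcat)

# 1. synthetic stimuli: 30 animals + 30 plants at two area levels
set <- gen_stimulus_set(n_per_class = 30, size_levels = c(10000, 50000),
                        separation_profile = "shape_dominant", seed = 7)

# 2. the 18 descriptors per object
feats <- extract_features(set$images, labels = set$manifest$category)

# 3. categorization under the repeated 75/25 split protocol
X <- as.matrix(feats[, feature_names()])
evaluate_protocol(X, feats$label, seed = 7)
#> protocol result: svm on 60 images, 20 iterations
#>   mean success 1.000 (sd 0.000)

# shape pair vs texture pair: shape carries the signal here
evaluate_protocol(X[, c("hull_ratio", "eccentricity")],
                  feats$label, seed = 7)$mean_success   # 1.0
evaluate_protocol(X[, c("entropy", "intensity_std")],
                  feats$label, seed = 7)$mean_success   # 0.387

# 4. behavioural simulation with execution noise targeted at 0.72
model <- train_categorizer(feats)
noise <- calibrate_flip_probability(
  model_rate = mean(predict_categorizer(model, feats) == feats$label),
  target_rate = 0.72)
noise$flip_prob                                         # 0.28
trials <- simulate_experiment(feats, model, rewarded = "animal",
                              noise = noise, n_trials = 1000, seed = 7)
mean(trials$correct)                                    # 0.725

# 5. hierarchical Bayesian evaluation of a simulated 6-fish cohort
cohort <- simulate_fish_cohort(omega_true = 0.72, kappa_true = 40,
                               n_fish = 6, n_trials_per_fish = 200,
                               seed = 7)
fit <- fit_hierarchical(cohort, chains = 3, samples = 5000,
                        burn_in = 1000, seed = 7)
posterior_summary(fit)
#>   parameter   mean hdi_lower hdi_upper  rhat rope_decision
#> 1     omega  0.764     0.716     0.816 1.001         above
#> 2    fish01  0.806     0.754     0.857 1.002         above
#> ...
#> 8     kappa  176.2     6.054     639.2 1.006          <NA>
```

Reading the output: the perfect protocol success says the synthetic
classes are separable from the descriptors; the 0.387 texture-pair
result says texture alone carries no class signal in a shape-dominant
set. The calibrated flip probability 0.28 takes a perfect classifier
down to the target 0.72, and the simulated cohort's group-level mode ω
has a 95% HDI of [0.716, 0.816], entirely above the ROPE — the cohort
performs credibly above chance, as the decision `above` states. The
wide κ interval is typical: six fish say little about the concentration.

## The analysis workflow

`analysis/01_generate_stimuli.R` through `analysis/06_report.R` run the
full study as numbered stages — stimulus generation, feature
extraction, recognition protocol and greedy ordering, behavioural
simulation on full / silhouette-only / texture-only stimuli, the
hierarchical fits, and a markdown report — writing their tables under
`results/`. Each stage reads only the previous stages' files and a
fixed seed, so any stage can be re-run in isolation and reproduces its
output exactly.

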