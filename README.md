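# mitomix

Bayesian classification of OXPHOS-deficient single muscle fibres.

## The problem

Mitochondrial disease produces a mosaic of healthy and dysfunctional cells
within the same tissue. In skeletal muscle, single-fibre imaging (IMC or IF)
yields, for every myofibre, an average abundance for each protein channel:
a mitochondrial-mass surrogate (VDAC) and one or more OXPHOS subunits
(NDUFB8, CYB, MTCO1). In healthy tissue, log OXPHOS abundance is linear in
log mitochondrial mass. The clinical quantity of interest is the proportion
of a patient's fibres whose OXPHOS abundance is *not like* that of healthy
controls.

The prevalent approach pools all control fibres, fits one regression line,
and flags every patient fibre outside the 95% prediction interval. Because
it ignores inter-subject variability — a healthy patient's fibres may sit on
their *own* line, with a different slope and intercept than any control —
this classifier can arbitrarily bisect a perfectly healthy fibre population
and misclassify most of a sample.

`mitomix` implements a Bayesian hierarchical two-component mixture model
that fixes this, together with the legacy frequentist classifier, a
control-data-driven prior pipeline, a ground-truth synthetic-data
generator, and the evaluation protocol used to compare them.

## The model

For the data of one 2Dmito plot (subjects `i = 1, …, k`, controls first,
patient last; fibre `j`), with `X` log mass and `Y` log OXPHOS abundance:

    controls:  Y_ij | m_i, c_i, tau        ~  N(m_i X_ij + c_i, 1/tau)
    patient:   Y_kj | m_k, c_k, tau, gamma ~  (1 - pi) N(m_k X_kj + c_k, 1/tau)
                                            +      pi  N(m_k X_kj + c_k, 1/gamma)
    membership: Z_j | pi ~ Bernoulli(pi)

    hierarchy: m_i | mu_m, tau_m ~ TN(mu_m, 1/tau_m, 0.1)   (left-truncated)
               c_i | mu_c, tau_c ~ N(mu_c, 1/tau_c)

The second mixture component shares the patient's line but has a fixed,
very small precision `gamma = 1e-4`: a broad catch-all for any aberrant
fibre, which also rules out label switching. Priors are elicited from
per-control-subject line fits: `mu_m ~ N(am, 0.25²)`, `mu_c ~ N(ac, 0.25²)`
with `am`, `ac` the mean control slope/intercept; `tau ~ Ga(g, h)` with its
mode at the mean control precision and variance 10; `tau_m, tau_c ~
Ga(51.981, 1.020)` (shape/rate, mode 50, variance 50); `pi ~ U(0, 0.5)`.

Inference is by a Z-augmented Gibbs sampler (conjugate block updates; exact
Metropolis correction for the slope-truncation constant). Per-fibre
deficiency probabilities are reconstructed at every retained draw by Bayes'
rule, and a fibre is called not-like-control when its posterior mean
probability reaches 50%.

## Worked example

```r
library(mitomix)

truth <- sample_ground_truth(config = list(pi = 0.2), seed = 1)
sim   <- generate_dataset(truth, n_per_subject = c(250, 250, 250, 250, 500),
                          seed = 2)

freq <- classify_frequentist(sim$data)
fit  <- fit_mixture(sim$data, config = mcmc_config(chains = 2,
                                                   iterations = 5000,
                                                   burn_in = 2000, seed = 3))
cls  <- classify_bayes(fit)
```

which prints (via the objects' `print` methods):

```
Frequentist classification: 86/500 patient fibres flagged (17.2%) at level 0.95
Hierarchical mixture fit: 5 subject(s), 500 patient fibres
  2 chain(s) x 3000 retained draws; selected chain 2
  posterior median deficiency proportion: 0.201
Bayesian classification: 100/500 fibres not-like-control (20.0%)
  pi posterior median 0.201, 95% HDI [0.167, 0.238]
```

The generator's true deficiency proportion was 0.2: the posterior median is
0.201 with a 95% HDI of [0.167, 0.238]. Against the generator's true fibre
labels,

```r
misclassification_rate(confusion_matrix(freq$fibres$z,    sim$labels$label))
#> 3.4
misclassification_rate(confusion_matrix(cls$fibres$label, sim$labels$label))
#> 0.2
```

the mixture model misclassifies 0.2% of fibres against 3.4% for the
prediction-interval rule — and the frequentist gap widens dramatically when
the patient's healthy fibres deviate from the pooled control line (see the
vignette). `tidy()` and `glance()` return per-fibre tables and one-row
summaries; `autoplot()` and `plot_classification()` draw the 2Dmito
scatters and posterior predictive bands.

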