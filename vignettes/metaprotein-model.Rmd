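---
title: "Metaprotein factor models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaprotein factor models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Label-free LC-MS proteomics quantifies peptides as *isotope groups*: the
set of chromatographic peaks belonging to one peptide at one charge state
and retention time, summarized by area-under-the-curve (AUC) intensity.
Rolling isotope groups up to proteins is harder than it looks:

* a percent or so of MS/MS identifications are simply wrong;
* post-translationally modified peptides can track a different abundance
  trajectory than the rest of their parent protein;
* instrument sensitivity drifts between batches ("runblocks") and shifts
  every feature at once;
* half or more of the features never get an identification at all, yet
  still carry quantitative information;
* low-intensity features drop below the detection limit, so missingness is
  intensity-dependent.

This package groups isotope groups into **metaproteins**: latent factors
driven jointly by co-expression across samples and by identifications,
with the identifications treated as informative but fallible.

# The model

For $P$ isotope groups by $N$ samples of natural-log intensities $X$,

$$X = \mu 1_N' + B H' + A \Lambda' + \epsilon$$

* $\mu_i \sim N(\mu_0, \phi_0)$ — per-row mean log intensity;
* $B$ ($P \times J$, $b_{i,j} \sim N(0, v_0)$) and $H$ ($N \times J$,
  $h_{n,j} \sim N(0,1)$) — *dense* systematic factors for sample-wide
  structure such as batch sensitivity shifts;
* $A$ ($P \times K$) and $\Lambda$ ($N \times K$,
  $\lambda_{n,k} \sim N(0,1)$) — *sparse* metaprotein factors: each row of
  $A$ has a single non-zero entry $a_{i,z_i} \sim N(0, v_0)$ selected by
  the membership indicator
  $z_i \sim \mathrm{Mult}(1, q_i)$,
  $q_i \sim \mathrm{Dir}(\alpha_0, \dots, \alpha_k, \dots, \alpha_0)$;
* $\epsilon_{i,n} \sim N(0, \tau_i^{-1})$,
  $\tau_i \sim \mathrm{Gamma}(\nu_0, \delta_0)$ — row-specific noise.

There is one labeled factor per protein with at least two identified
isotope groups, plus `K_noise` unlabeled factors that absorb features
fitting no protein's pattern. An identified row's Dirichlet prior puts
pseudocount $\alpha_k$ on its annotated protein's factor and $\alpha_0$
everywhere else; unidentified rows get a flat prior. All priors are
conjugate and the model is fit by Gibbs sampling (`run_mcmc()`).

An optional *overlapping peaks* extension replaces the single-membership
constraint with an independent point-mass mixture on every entry of $A$,
$a_{i,k} \sim (1-q_k)\,\delta_0 + q_k\,N(0, v_0)$ with
$q_k \sim \mathrm{Be}(\nu_0^{mix}, \gamma_0^{mix})$, so one isotope group
(e.g. two co-eluting peptides in one peak, or a peptide shared between
homologues) may load on several metaproteins (`mp_hyper(mixture = TRUE)`).

# Default constants, with units and reasons

| constant | default | meaning |
|---|---|---|
| `mu0`, `phi0` | 8, 100 | row means in ln(AUC counts); two-sigma interval $(-12, 28)$, deliberately overdispersed |
| `v0` | 100 | loading prior variance; admits fold changes beyond $10^8$ |
| `nu0`, `delta0` | 0.001, 0.001 | precision prior with mean 1, variance 1000 — close to scale-free |
| `alpha0`, `alphak` | 1, 500 | membership pseudocounts: 500:1 prior odds toward the identified factor |
| `J` | 3 | systematic factors (one is usually enough for a single batch split) |
| `K_noise` | 10 | unlabeled factors |
| `n_iterations`, `n_burnin`, `thin` | 2000, 1000, 2 | chain defaults |

Two of these deserve comment.

**The identification pseudocounts.** Only the *ratio*
$\alpha_k / \alpha_0$ enters the membership update, and we set it to 500:1.
There is a hard information budget behind this choice: for a row observed
in $n$ cells, once its residual precision $\tau_i$ has adapted to a wrong
assignment, the marginal-likelihood advantage of the correct factor
saturates near $n/2$ nats. At $n \approx 18$ (a small spike-in study) that
cap is $\approx 9$ nats; $\log(500) \approx 6.2$ leaves co-expression
evidence able to overrule a wrong label, while a ratio of $5 \times 10^4$
($\approx 10.8$ nats) would make relabeling mathematically impossible at
that sample size. Corrected identifications are exactly the behavior the
model exists to provide, so the 500:1 reading is the one implemented.

**The precision prior.** Gamma(0.001, 0.001) is near scale-free and lets
$\tau_i$ follow the data almost unconstrained. With `>100` samples that is
harmless; in very small studies it permits a pathology where a row with
few observed cells overfits, acquires a huge $\tau_i$, and hijacks its
factor's scores. For studies with tens of samples a more informative prior
(e.g. `nu0 = delta0 = 2`) is advisable.

# Sampler design

The Gibbs cycle is: row means, systematic factors, membership (or
spike-and-slab loadings in mixture mode), metaprotein loadings, factor
scores, precisions. Numerical and design choices that matter:

* **Collapsed membership update.** $z_i$ is drawn with the loading
  integrated out analytically under its $N(0, v_0)$ slab; conditioning on
  a stale loading would essentially freeze the current assignment. $q_i$
  is then drawn explicitly from its Dirichlet posterior.
* **Missing cells** (zeros/blanks in the raw export) are excluded from
  every likelihood sum, not imputed: non-detections at the low end would
  otherwise bias loadings downward. This is a missing-at-random
  approximation of what is really left-censoring.
* **Initialization.** Labeled factors start from the standardized mean
  centered pattern of their identified members; random starts invite
  sign-cancelled local modes in which half a protein's peptides push the
  factor one way and half the other.
* **Sign identifiability.** After each sweep, each factor column's sign is
  fixed so its members' summed loading is non-negative; otherwise
  sign-switching corrupts posterior means of $\Lambda$.
* **Rotation identifiability of the systematic part.** $BH'$ is identified
  only up to rotation of its $J$ columns, so reported systematic scores
  are the right singular vectors of the posterior-mean $BH'$, ordered by
  singular value and scaled by $\sqrt N$. The leading column is therefore
  the dominant sample-wide pattern — with a planted batch effect, the
  runblock indicator.
* **Factor-score prior.** The i.i.d. $N(0,1)$ form is used for conjugacy.
  The uniform-on-the-sphere reading (columns of norm $\sqrt N$, on which
  i.i.d. normals concentrate anyway) is available as
  `sphere_constraint = TRUE`, implemented as a post-draw rescaling;
  neither reading is asserted as the intended one since they disagree only
  at $O(1/\sqrt N)$.
* **Divergence detection.** The unnormalized log joint is evaluated every
  sweep; a non-finite value aborts with the iteration number.
* **Mixture-mode defaults** `mixture_nu0 = 1, mixture_gamma0 = 99` expect
  about 1% inclusion per factor, matching the sparsity of the
  single-membership model; the Beta constants are otherwise unidentified
  a priori.

# What the synthetic-data generator emulates

`generate_dataset()` samples the model forward at a realistic scale
(defaults: $P = 6729$, $N = 96$, 109 labeled proteins, 3 runblocks; the
`small` preset $P = 300$, $N = 48$, $K = 10$ is what the test suite runs).
Choices that are *modeling decisions*, not fits to any dataset:

* **Loadings are half-normal** ($|N(0, \text{snr}^2)|$, default snr 5):
  peptides from one protein co-express with a common sign, because
  ionization sensitivity scales, but does not invert, the shared
  concentration signal.
* **Misidentification** (default 1%) relabels a row to a uniformly chosen
  wrong protein. **PTM divergence** (default 2%) keeps the (correct)
  label but moves the row's true factor — label says protein $k$,
  abundance tracks factor $k'$ — which is the statistical signature of a
  modified peptide, without simulating any chemistry.
* **Missingness is logistic in true log intensity** (midpoint 5, slope 1
  on the ln scale), giving intensity-dependent non-detection; the
  mechanism is a modeling choice since real censoring curves are
  instrument-specific.
* **Batch structure**: the first systematic factor is the runblock
  indicator (+1 for the first blocks, −1 for the last) with positive
  loadings around `batch_effect` (default 0.5 ln units, a moderate
  sensitivity shift).

`generate_latin_square()` emulates a spike-in benchmark: six non-human
proteins spiked into a constant background at six concentrations in a
cyclic latin square, three replicate blocks, 18 analyses. Its calibration
is derived from the physics of AUC quantitation rather than from the
factor model: AUC is linear in concentration, so a spike row's
log intensity tracks the log-concentration profile with slope near 1
(loadings are sensitivity jitter in $[0.8, 1.2]$), the design spans a
32-fold range ($2^5$, about 3.5 ln units), and replicate noise is 20% CV
for spikes against 50% for the biological background. An earlier draft of
this generator scaled loadings like the co-expression simulator
(snr-times-standardized profiles); that implied million-fold intensity
swings whose low ends were entirely censored by the missingness mechanism,
deleting whole conditions and making adjacent cyclic-shift profiles
indistinguishable — a physically wrong emulation, not a hard dataset.

What passing recovery tests on these generators does **not** show:
robustness to non-Gaussian noise, to correlated (structured) missingness,
to retention-time misalignment within a dataset, or to proteins whose
true expression genuinely spans several correlated factors. Real-data
performance depends on those.

# Downstream analyses

* `protein_summation()` and `protein_top3()` are the classical baselines.
  Summation operates on raw counts (the natural scale for adding AUC
  areas; whether to re-log afterwards is a flag) with missing cells
  contributing zero; Top-3 ranks by mean intensity with ties broken by
  input row order.
* `dominant_metaproteins()` finds, per protein, the factor holding a
  strict majority of its identified groups; `motif_enrichment()` builds
  the 2×2 table of motif presence (Q, N, S, T, negative controls P and H,
  sequons NxS/NxT with an optional x ≠ P flag) against sitting outside
  the dominant metaprotein, reporting the sample cross-product odds ratio
  and a two-sided Fisher exact p. Peptides of proteins lacking a dominant
  metaprotein are excluded — there is no "outside" without a dominant
  pattern to be outside of.
* `anova_association()` does per-factor one-way ANOVA against a binary
  phenotype with Bonferroni correction (the simplest defensible
  family-wise procedure).
* `fit_predictor()` is stochastic variable-selection search with model
  averaging for the $K > N$ regime: add/delete/swap moves over subsets of
  factor columns, each model scored by the closed-form Zellner g-prior
  marginal likelihood ($g = n$) of the centered 0/1 outcome under a
  model prior uniform over sizes up to `max_size`. A probit link was
  considered and rejected: with strongly separating factors at these
  sample sizes the probit likelihood degenerates (perfect separation),
  whereas the Gaussian g-prior score is closed-form, stable and
  rank-equivalent for classification. Scores are monotone in class
  probability, which is all that ROC evaluation needs.
* `roc_with_random_null()` draws null predictors trained on
  covariance-matched Gaussian factor scores with a *permuted* outcome and
  scores them against the actual labels, where exchangeability pins their
  AUC distribution at 0.5. (Scoring a null predictor against its own
  permuted training labels would instead measure how far a flexible
  search can overfit noise — a different and less interpretable
  quantity.)

# Alignment of datasets

Features measured in a second experiment are modeled as Gaussian around a
per-dimension shift-and-scale transform of their (RT, m/z) coordinates,
with a full 2×2 residual covariance. Parameters are initialized by
maximum likelihood on anchor features identified in both datasets
(per-dimension least squares; the residual covariance is floored to stay
invertible when anchors are exact), matching is greedy best-first under a
one-to-one constraint, and a pair is accepted only while its posterior
odds against a uniform background density over the observed coordinate
bounding box exceed 1 at prior odds `prior_match/(1-prior_match)`
(default prior 0.5). The uniform background is what turns that prior into
an operational stopping rule. Parameters are refit once from the accepted
matches and matching is redone; further iteration is declined because the
likelihood surface is extremely peaked and re-iteration mostly re-ranks
ties. The one-to-one constraint prevents intensity double-counting in the
merged matrix. Retention-time warping (nonlinear drift) and use of
intensity profiles are out of scope.

# Problem sizes used by the tests and the acceptance script

Simulation sizes are chosen so the full suite exercises every claim at
meaningful power: conditional-correctness checks run on 1–3 row instances
against grid integration (relative error $10^{-6}$); the
joint-distribution (Geweke-style) check runs $10^4$ successive-conditional
sweeps on a 5×4 instance with moderate constants, because the
scale-free default precision prior has effectively unestimable
fourth moments; recovery experiments use the `small` preset (300×48,
500-sweep chains), three 18-sample latin squares for relabeling, and 20
replicates of an 80-sample, 51-factor predictor problem. Each is a
deliberately scaled-down analog of the corresponding full-size analysis,
with the scaling documented here as the package's own choice of test
conditions.

# Known limitations

* Missing data are treated as missing-at-random; the true mechanism is
  left-censoring, and fold changes of analytes near the detection limit
  are underestimated.
* Single-site Gibbs updates mix slowly between well-separated membership
  modes; a corrupted identification held by an extreme prior ratio can
  persist for many sweeps. The collapsed z-update mitigates but does not
  eliminate this.
* $K$ is fixed by the labeled-protein rule plus `K_noise`; there is no
  model selection over the number of noise factors.
* The predictor's g-prior linear score is calibrated for ranking, not for
  probability estimates.
* The alignment model is linear in RT; gradient nonlinearity between very
  different chromatographic setups would need warping upstream.
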