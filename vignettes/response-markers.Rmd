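---
title: "Longitudinal plasma-proteomics response markers and trial endpoint statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal plasma-proteomics response markers and trial endpoint statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`protrial` re-implements, as a tested and reusable pipeline, the two
analytical arms of a randomized two-arm oncology trial with paired
pre/post-treatment plasma proteomes:

1. an exploratory **response-marker analysis**: per-protein linear mixed
   models, four contrast families, Benjamini–Hochberg adjustment, compound
   decision rules that call arm-unique response markers and treatment
   targets, and single- or multi-protein panel ROC prediction of response;
2. the **trial-design and endpoint statistics**: composite mRECIST response
   over intra- and extrahepatic lesion compartments, ORR/DCR with exact
   intervals and chi-square/Fisher comparison, Kaplan–Meier estimation,
   the log-rank test with an O/E hazard-ratio approximation, and the
   Freedman log-rank sample-size design.

Patient-level data of the motivating study are not public, so a
synthetic-data generator with known spike-in ground truth stands in for
them; every downstream stage is validated against that truth or against
independent oracles.

## The mixed model and its contrast families

Each protein's normalized log2 expression \(y_{ij}\) (patient \(i\),
sample \(j\)) is modeled as

\[ y_{ij} = \mathbf{x}_{ij}^\top \beta + b_i + \varepsilon_{ij}, \qquad
   b_i \sim N(0, \tau^2), \quad \varepsilon_{ij} \sim N(0, \sigma^2), \]

with fixed effects for response evaluation (PD/SD/PR/CR; NE samples are
excluded), treatment arm, and time point (pre/post), and a per-patient
random intercept for the paired samples. Estimation is REML via `lme4`.
Reference levels default to PD, placebo, pre.

The published formula lists main effects only, but two of the four
contrast families are interactions, which a main-effects model cannot
carry. How the original analysis parameterized them is not stated; this
package fits the **saturated cell-means model**
`~ response * arm * time + (1 | patient)` once and derives every family as
a difference of design-cell rows:

* **pairwise_pre** — response pair differences at pre-treatment within
  each arm (12 contrasts for 4 response levels);
* **interaction_arm_response** — the arm-by-response
  difference-in-differences of every response pair at pre-treatment
  (6 contrasts; pairs against the reference level coincide with the
  interaction coefficients);
* **pre_post_within** — post minus pre within each response-by-arm cell
  (8 contrasts);
* **interaction_arm_time** — the arm-by-time difference-in-differences
  within each response (4 contrasts).

A single saturated fit keeps the families mutually consistent (every
estimate is a cell-mean difference, verified in the test suite against an
explicitly inverted cell-means system) at the cost of a few more
parameters; with two or more patients per design cell this is harmless,
and empty cells are reported as per-protein non-converged records rather
than errors. Inference is the large-sample Wald *z* test
(\(z = c^\top\hat\beta / \sqrt{c^\top \hat\Sigma c}\), two-sided normal
*p*), matching the simultaneous-testing convention of the tooling the
original analysis used; no degrees-of-freedom approximation is attempted.
When the random-intercept variance is estimated at the boundary
(\(\hat\tau^2 = 0\)), the reported covariance coincides with the OLS
covariance and the fit carries a `boundary` flag instead of failing.

Benjamini–Hochberg adjustment is applied per contrast family, pooled over
all proteins and contrasts within the family (the source states only that
*p* values were adjusted; `adjust_scope` exposes `"global"` and
`"per_label"` alternatives).

## Marker and target decision rules

A protein is **differential** in a family if any contrast has raw
*p* < 0.05. It is an **arm-unique response marker** if, for some
pre-treatment response contrast in the target arm,

> raw *p* < 0.05 **and** (adjusted *p* < 0.05 **or** |coefficient| > 1.5)
> **and** the arm-by-response interaction *p* < 0.05,

and an **arm-unique treatment target** by the same structure over the
pre/post families with |coefficient| > 1.2 and the arm-by-time gate. Two
readings were open:

* *Which interaction gates a given contrast?* The rule speaks of "its"
  interaction *p*. Here each pairwise contrast is gated by the interaction
  of the **same response pair** (e.g. CR−PD in the treatment arm is gated
  by arm × (CR−PD)), which is exact for every pair including those not
  involving the reference level. This is why the interaction family
  enumerates all pairs rather than only the three coefficients.
* *Raw or adjusted interaction p?* The rule names a bare "*p* value"
  where it says "adjusted" explicitly elsewhere, so the gate is raw by
  default (`interaction_scale = "adjusted"` switches it).

The called **cell** of a pairwise contrast is the response group in which
the protein is higher; for pre/post contrasts the cell is the response
evaluation and the direction is the sign of the post-minus-pre estimate.
Calls are monotone in every threshold (tested property), and unique calls
imply the corresponding differential call by construction.

## Panel prediction

Markers are pre-treatment predictors: scoring uses pre-treatment samples
with a non-NE response. Undetected panel proteins are **zero-imputed
before standardization** — deliberately reproducing the published
convention, whose cost the test suite demonstrates (heavy dropout with
zero imputation degrades the AUC of a truly spiked protein). The default
combination rule is the mean per-protein *z* score over the scored
samples (`mean_z`); the source does not state its rule, and `mean_z`
implies no fitted model. AUC is the pairwise concordance (rank-sum)
statistic with ties counted one half, and the ROC curve is a threshold
sweep — both checked against an \(O(n^2)\) enumeration oracle.

## Trial endpoints and design

The composite response rule over (intrahepatic, extrahepatic) lesion
evaluations is: PD in either compartment dominates; otherwise any needed
NE makes the overall NE; CR requires CR everywhere; PR requires at least
one PR with the rest CR/PR; SD requires all in CR/PR/SD with at least one
SD; single-compartment patients take that compartment's value. The full
input grid is verified against an independently written priority-encoded
truth table.

ORR = (CR+PR)/n and DCR = (CR+PR+SD)/n use the intention-to-treat
denominator (NE stays in `n`), with exact Clopper–Pearson intervals.
Between-arm comparison collapses to responder/non-responder and uses the
continuity-corrected chi-square, or Fisher's exact test when any expected
cell is below 5. The motivating report prints Cochran–Mantel–Haenszel
*p* values with unstated strata; those are not reproducible and are not
targets (the uncorrected chi-square, `correct = FALSE`, lands close).

Kaplan–Meier estimation, the unstratified log-rank test, and the
\((O_1/E_1)/(O_2/E_2)\) hazard-ratio approximation with a
\(\sqrt{1/E_1 + 1/E_2}\) log-scale CI are hand-implemented and verified
against worked examples, `survival::survfit`/`survdiff`, and a
permutation null. An optional Cox fit (`cox = TRUE`) is delegated to the
`survival` package.

The sample-size calculator uses the **Freedman** event formula
\(d = (z_{1-\alpha/2} + z_{\mathrm{power}})^2\,((1+HR)/(1-HR))^2\) with
\(HR\) the ratio of exponential medians, rounding up at each stage:
total events, per-group events (1:1 allocation), then inflation by event
probability and loss to follow-up. Freedman rather than Schoenfeld
because it reproduces the published 53/group under the stated parameters
(medians 8.2 vs 14.9 months, two-sided \(\alpha = 0.05\), power 80%, 10%
loss, full event probability); Schoenfeld is available via `method`.
Event probability defaults to 1, appropriate to an advanced-disease
setting and the source's silence on the matter.

## The synthetic-data generator

`generate_cohort()` defaults **are** the published trial's stated world:
53 vs 55 patients, the observed response frequencies per arm
(ATRA 4/9/14/19/7 over CR/PR/SD/PD/NE, placebo 1/4/12/31/7), median OS
16.2 vs 10.7 months, median PFS 7.1 vs 4.2 months, and a 10% censoring
probability mirroring the design's loss-to-follow-up assumption. Survival
is exponential (only medians are published). Lesion-level compartment
pairs are drawn uniformly from the preimage of the sampled overall
response under the composite rule, so the endpoint pipeline can start
from lesion-level inputs. Numerical choices worth knowing:

* **Censoring** is an independent exponential follow-up limit per patient
  with rate calibrated so P(censored before death) equals `censor_prob`.
  An earlier draft censored at a uniform fraction of the event time;
  that is *informative* censoring and visibly biases the product-limit
  median, which is exactly why the generator does not do it.
* **PFS is capped at OS** (progression cannot be observed after death),
  so the marginal median of observed PFS is
  \(1/(1/m_{\mathrm{pfs}} + 1/m_{\mathrm{os}})\), not the configured
  latent value; recovery tests use that analytic truth.

`generate_proteome()` emulates a label-free spectral-count experiment:
per-protein log2 baselines \(N(5, 2)\), protein-specific patient random
intercepts (a shift shared across all proteins would scale the whole
sample and vanish under total-count normalization), Gaussian residuals,
scaling of each sample to a drawn library size (default 50k–150k total
spectra), rounding to counts, and Bernoulli dropout (optionally
intensity-dependent, logistic in log-abundance). Effects are on the
**log2** scale (the source says only "log-transformed"; base 2 is the
field's convention and is recorded in the matrix state). Four spike-in
archetypes mirror the reported marker classes, each restricted to one
arm, response group, and time point: `pre_CR_up`, `pre_PR_up`,
`post_CR_up`, and `post_responder_down` (CR+PR, post, downshift).

Two deliberate realism choices:

* **Spiked proteins are mid-abundance** (baseline log2 sd 1 instead of
  2). The heavy lognormal tail otherwise lets a single protein carry
  ~20% of total spectra; spiking such a protein 4-fold shifts the
  affected samples' totals enough that, after total-count normalization,
  dozens of null proteins acquire spurious arm interactions. The plasma
  markers being emulated are SOD3/TTR-class proteins, not albumin-class
  dominants, so the restriction is the realistic case — but it means a
  green spike-in test does **not** establish robustness of the caller to
  compositional distortion by dominant proteins.
* **Dropout is abundance-independent by default** (the source gives no
  detection model); the intensity mode exists for realism but is not what
  the operating-characteristic tests use.

What a green test establishes, and what it does not: the simulation
validates the *pipeline* — design construction, REML fitting, contrast
arithmetic, multiplicity handling, rule logic — under a data-generating
process that matches the model. It cannot validate the published protein
lists (80 differential, 17 unique markers, 184 pre/post, 13 targets) or
the published AUCs (e.g. 0.941 for the CR marker), which depend on the
unreleased cohort; those counts are explicitly not targets. Likewise the
operating-characteristic simulations use a **balanced response mix**
(0.25 per category, no NE) rather than the published frequencies: the
placebo arm's observed CR probability (1/55) leaves the CR×placebo design
cell empty in most moderate-size replicates, which makes arm×CR
interactions inestimable — a property of the real design worth knowing,
and the reason the trial's own frequencies remain the generator default
while the caller's sensitivity/specificity is measured where it is
identifiable.

## Known limitations

* Inference is asymptotic (*z*, not *t*): raw per-contrast *p* values are
  mildly liberal in very small cells.
* No empirical-Bayes variance moderation, random slopes, or non-Gaussian
  families; no batch correction or imputation beyond the panel module's
  explicit zero rule.
* The stratified log-rank of the source is implemented unstratified (its
  strata are unstated); `survival::coxph` is available for covariate
  adjustment but multivariate prognostic modeling of the real cohort is
  out of scope.
* The generator does not simulate raw DIA spectra, retention times, or
  peptide-to-protein rollup.
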