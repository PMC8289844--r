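---
title: "Longitudinal network analysis of paired questionnaire item panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal network analysis of paired questionnaire item panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longnet)
```

## The model

`longnet` analyses a panel of questionnaire items answered by the same
subjects at two waves — typically a battery of binary depression and
anxiety items plus a handful of ordinal social-isolation items. Each wave
is modelled as a Gaussian graphical model over the items: the estimand is
the matrix of *partial correlations*

$$\omega_{ij} = -\frac{K_{ij}}{\sqrt{K_{ii}K_{jj}}},$$

where \(K\) is the precision (inverse covariance) matrix. An edge
\(\omega_{ij} \ne 0\) is the association between items \(i\) and \(j\)
conditional on every other item, which is what makes these networks
readable as direct symptom–symptom dynamics rather than marginal
co-occurrence.

Estimation is the standard psychometric-network recipe:

1. **Spearman correlations with pairwise deletion.** Item responses are
   ordinal, so each entry of the input matrix is the rank correlation over
   the subjects observed on *both* items of the pair (`spearman_matrix()`).
2. **Positive-definite repair.** Pairwise deletion can produce an
   indefinite matrix; eigenvalues are clipped at `1e-8` and the matrix
   rescaled to unit diagonal (`nearest_pd_repair()`). The repair is
   idempotent and a no-op on PD input.
3. **Graphical lasso.** The penalized likelihood
   \(\log\det K - \mathrm{tr}(CK) - \lambda \sum_{i\neq j} |K_{ij}|\)
   is maximized by blockwise coordinate descent in compiled code, with the
   diagonal unpenalized. Solutions carry exact off-diagonal zeros and are
   verified in the test suite against the subgradient (KKT) conditions at
   tolerance `1e-4`, and against the direct matrix inverse at
   \(\lambda = 0\).
4. **EBIC model selection.** A descending log-spaced path of 100 penalties
   from \(\lambda_{\max}\) (the largest absolute correlation) down to
   \(0.01\,\lambda_{\max}\) is fit with warm starts, and the extended BIC
   \(-2L + E\log n + 4E\gamma\log p\) selects \(\lambda\); ties resolve to
   the sparser model. \(\gamma = 0.5\) by default — the conventional
   choice, erring toward discovery of robust edges only. Under pairwise
   deletion the \(n\) handed to EBIC is the number of subjects (an option
   switches to the minimum pairwise count).

## Network description

From the estimated network the package computes what longitudinal symptom
studies report: **global strength** (sum of `|edge|` over unique pairs),
**node strength**, and **bridge strength** — per node, the absolute edge
mass reaching a *different* community, with the affective items (depression
and anxiety) and the isolation items forming the two default communities.
Block summaries average `|edge|` within and between questionnaires over
*all* pairs of the block, zero edges included in the denominator; that
convention is what makes sparse between-questionnaire blocks average near
zero (values of order 0.002–0.01) while within-questionnaire blocks sit an
order of magnitude higher, and it is the only denominator consistent with
the magnitudes such studies print. `top_edges()` ranks edges by absolute
weight with deterministic lexicographic tie-breaks.

## Stability: case-dropping bootstrap and the CS coefficient

`case_drop_bootstrap()` re-estimates the network after dropping a growing
proportion of subjects (10 equally spaced levels from 5% to 75% by
default, the bootstrap budget split equally with remainders to the
shallowest levels) and correlates each re-estimate's statistic vector with
the full-sample one. The **CS coefficient** is the deepest drop proportion
at which at least 95% of replicates still correlate at least 0.70 with the
full sample, with monotone enforcement: every shallower level must also
pass, so sampling noise at one depth cannot manufacture a deep CS. Values
of 0.25 are conventionally the floor for interpreting metric orderings and
0.50 is preferred.

## Comparing the two waves

`nct_paired()` is a paired permutation network-comparison test. The null
hypothesis is exchangeability of the two waves *within subject*; the
resampling scheme therefore swaps each subject's wave-1 and wave-2 response
vectors independently with probability 1/2 and re-runs the *entire*
estimation pipeline — Spearman, repair, glasso path, EBIC selection — on
both permuted waves, so model-selection variability propagates into the
null distribution. Four families of statistics are tested: the global
strength difference, the structure statistic \(\max_{ij}|\Delta\omega_{ij}|\),
per-edge differences over the union of edges nonzero in either observed
network, and per-node strength and bridge-strength differences. P-values
use the add-one convention \(p = (1 + \#\{|T^{(b)}| \ge |T|\})/(1 + B)\),
so no p-value can be zero and the test is valid at finite \(B\). Edge and
centrality p-values are uncorrected by default (the convention in the
applied literature for displayed edges), with an optional Holm adjustment.

A design choice worth making explicit: permutation re-estimation reuses the
λ-path *settings* but re-selects λ by EBIC in every replicate. Freezing the
selected λ would understate the null variability of the sparsity pattern.
Raw response vectors are swapped, not residualized scores; with only two
exchangeable waves the raw swap is the natural group action.

## The synthetic-data generator

Real item panels of this kind are rarely shareable, so the generator is a
first-class, tested component rather than a fixture. It emulates a
two-wave geriatric battery: 15 binary depression items, 20 binary anxiety
items, and 6 five-point isolation items (41 items), answered by 419
subjects, with missing cells planted completely at random at rate
24/34,358 so a default panel carries about 24 missing of its 34,358 cells.

The truth is a sparse block-structured Gaussian graphical model. Target
partials are drawn per block (`within_density = 0.10` within a
questionnaire, `between_density = 0.015` across, weights uniform on
0.4–0.6), the precision \(K = I - P\) is repaired to positive definiteness
by the smallest ridge on a 0.01-spaced grid achieving a minimum eigenvalue
of 0.05, rescaled to unit diagonal — and the *realized* partials are then
recomputed from the repaired precision and stored as the truth, so recovery
tests compare against what was actually planted, not what was wished for.
The repair attenuates: realized maxima land near 0.3, the magnitude of the
strongest edges such item networks exhibit. Wave 2 starts from the wave-1
target with planted perturbations (by default +0.10 on existing
affective–isolation edges and +0.05 within isolation, mirroring the
qualitative lockdown finding the package's motivating literature reports)
applied before its own repair.

Responses arise through a latent Gaussian copula: each subject draws a
\(2p\)-dimensional normal whose per-wave blocks are the correlation-scale
inverses of the true precisions and whose cross-wave block is diagonal with
per-item test–retest correlation (0.5 by default). Latents are cut at
per-item thresholds \(c_k = \Phi^{-1}(k/C) + \Phi^{-1}(1-\pi)\), which
makes binary endorsement exactly \(\pi\) and shifts ordinal mass
monotonically with \(\pi\). Default endorsement probabilities are anchored
to realistic geriatric scale means (depression ≈ 1.0/15 at wave 1 rising to
≈ 2.1/15 at wave 2; anxiety ≈ 1.1/20 to ≈ 1.4/20; isolation worsening
slightly), so synthetic panels worsen across waves in the documented
directions. Binary items are emitted keyed (higher = worse); isolation
items raw (higher = better) with `keyed_direction = -1` recorded, so
scoring reproduces the opposite directions of real batteries.

What the generator does *not* emulate: item-response-theory discrimination
structure, non-MCAR missingness, more than two waves, and respondent-level
heterogeneity beyond the latent copula. Passing tests therefore certify the
pipeline's statistical machinery on data with this structure, not the
substantive conclusions of any particular real panel.

### Numerical and degenerate-input choices

- The diagonal cross-wave coupling can make the assembled \(2p\) joint
  covariance indefinite when the coupling exceeds the smallest eigenvalue
  of the within-wave covariance; it is repaired by eigenvalue clipping at
  `1e-8` with unit-diagonal rescale, and a warning is raised (and captured
  in the pipeline manifest) when the repair moves any entry by more than
  0.05. The copula-fidelity property (latent correlations within 0.01 of
  the truth at \(n = 10^5\)) holds exactly in the regime where no clipping
  occurs.
- `spearman_matrix()` refuses items with zero variance on their complete
  cases and pairs with fewer than 3 complete observations, naming the
  offenders.
- An input with no off-diagonal correlation short-circuits to the empty
  network for every \(\gamma\).
- Identical waves in `paired_t()` return the degenerate \(t = 0, p = 1\)
  rather than erroring; zero-variance differences with nonzero mean error.
- Scale totals require 80% of a scale's items observed and prorate the
  rest (total = observed sum × items/observed), rounded to 2 decimals —
  scale-level missing handling is rarely specified in the applied
  literature, so the rule is exposed as an argument.

## Problem sizes used by the test suite

The statistical checks run at deliberately reduced scale chosen as the
smallest sizes at which the properties are sharp: chain-recovery at
\(n = 5000\) over 10 nodes; type-I-error calibration of the paired test
with 200 replicates × 200 permutations over 15 nodes at \(n = 300\)
(rejection counted at \(\alpha = 0.05\) against the 99% binomial band),
using a 50-value penalty path in the resampling-heavy checks — path
resolution beyond that changes selected models negligibly at these sizes;
planted-edge power across 5 seeds at \(n = 800\); copula fidelity at
\(n = 10^5\) over 8 items. The bundled acceptance script runs the full
default-scale pipeline (419 × 41 × 2) with a reduced bootstrap (200) and
permutation count (300).

## Known limitations

- Polychoric/tetrachoric input correlations are out of scope; Spearman
  attenuates latent associations for rare binary items, so synthetic
  networks estimated from low-prevalence items are sparser than the latent
  truth.
- The permutation test inherits the conservatism of add-one p-values at
  small \(B\).
- CS coefficients are reported on the bootstrap grid; a CS of 0.44 means
  "the level 0.44 passed and 0.52 failed", not a continuously estimated
  breakdown point.
- Between-subject networks say nothing about within-person dynamics; the
  package deliberately implements no cross-lagged or temporal (VAR)
  models.
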