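---
title: "Tree-based association tests for longitudinal microbiome data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-based association tests for longitudinal microbiome data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmat)
```

This vignette is the package's account of its statistics: the model behind
the genus-level test, the assumptions it rests on, what the synthetic-data
generator does and does not emulate, and the numerical choices that were
genuinely open. Nothing here states an empirical result that the test suite
or `scripts/acceptance.R` does not itself compute.

## The testing problem

A longitudinal 16S study observes counts $c_{ijm}$ of taxon $m$ for subject
$i$ at visit $j$, a binary phenotype $y_{ij}$, and a rooted binary phylogeny
over the taxa. The question per genus: is the genus's abundance profile
associated with the phenotype, accounting for within-subject correlation
and for the compositional nature of sequencing counts (library size is an
instrument artefact, not biology)?

## Covariates from the phylogeny

Counts are normalised to log2 counts-per-million with a per-sample
pseudo-count $c_{ij\cdot}$:

$$r_{ijm} = \log_2\!\left(\frac{c_{ijm} + c_{ij\cdot}/2}
  {\sum_m c_{ijm} + c_{ij\cdot}} \times 10^6 + 1\right).$$

The pseudo-count is not pinned down by the transform itself; the package
implements two policies. The default, `prior = "constant"`, sets
$c_{ij\cdot} = 1$ (prior count one half, the convention of edgeR-style
log-CPM). `prior = "library_scaled"` sets $c_{ij\cdot} = L_{ij}/\bar L$,
which makes a single sample's log-CPM nearly invariant to rescaling that
sample's depth — the better choice when sequencing depth varies wildly and
zero cells are common (see *Compositional robustness* below).

A genus with $M_1$ leaves has $M_1 - 1$ internal nodes in its subtree,
numbered $k = 1, 2, \dots$ in pre-order from the subtree root; node $k$
splits its leaves into the left set $L_k$ (first-listed child in the Newick
string) and right set $R_k$. The node covariate is the natural-log ratio of
pooled log-CPM values over $L_k$ and $R_k$; swapping children only flips its
sign, which the quadratic statistics ignore, so child order affects the sign
of reported effect estimates but never p-values. The pooled node
$x^{(0)}$ compares the whole genus against a reference: the pooled log-CPM
of **all other taxa** (default), of one **reference genus** (the additive
log-ratio, ALR), or the **geometric mean of all genus-level sums** (the
centered log-ratio, CLR).

The rationale for pooling along the tree: nearby species share ecology, so
a real signal tends to appear coherently in a subtree; pooling aggregates
sparse counts (fewer zeros at the pooled level) and the log-ratio removes
the common library-size scale.

## The marginal model and its tests

Each covariate $x^{(k)}$ is modelled marginally,

$$E(x^{(k)} \mid Z, y) = Z\alpha_k + y\beta_k,\qquad
  \mathrm{var}(x^{(k)} \mid Z, y) = \Sigma^{(k)},$$

with $\Sigma^{(k)}$ block-diagonal over subjects,
$\Sigma^{(k)}_i = \sigma_{kk} D_{ik}^{1/2} R_i D_{ik}^{1/2}$. $R_i$ is a
working correlation: identity, exchangeable (`cs`), first-order
autoregressive in the visit index (`ar1`, gaps decay as
$\rho^{|j-j'|}$), or unstructured (`un`, balanced designs only). By default
$D = I$: per-visit variance heterogeneity is absorbed into $\sigma_{kk}$,
with an optional `visit_var` estimate of a per-visit diagonal. Inference is
robust to misspecification of $R_i$ through the sandwich construction, so
the choice of structure affects efficiency, not validity.

Two statistics test $H_0: \beta_k = 0$:

* the **generalized score statistic**, evaluated at the null GLS fit, with
  robust middle matrix $\tilde B = \sum_i U_i U_i^\top$ or, with the
  small-sample adjustment (default), each subject's residual inflated by its
  inverse leverage $(I - \tilde P_{ii})^{-1}$, where the leverage accounts
  for the tested contrast;
* the **robust Wald statistic** $\hat\beta_k^2 / \hat V_k$, where
  $\hat\beta_k$ comes from the joint GLS fit (it equals
  $(y^\top\hat\Sigma^{-1}y)^{-1} y^\top\hat\Sigma^{-1}(x - Z\hat\alpha)$,
  the solution of the marginal estimating equation) and $\hat V_k$ is the
  $(\beta,\beta)$ entry of the sandwich on the joint design $[Z\ y]$ with
  the same inverse-leverage inflation (the Mancl–DeRouen correction).

Both are referred to $\chi^2(1)$; an arbitrary contrast matrix $L$ on
$(\alpha_k, \beta_k)$ is accepted for joint group/time/interaction tests.
A note on the Wald variance: the sandwich must be built on the joint design
so that $y$ is implicitly orthogonalised against the covariates. A variance
built from $y$ alone (no $Z$-projection) underestimates
$\mathrm{var}(\hat\beta)$ by roughly $n/n_0$ — a factor 2 in balanced
designs — and makes Wald p-values disagree with score p-values even in
large samples; the package therefore uses the projected form, which the
test suite checks against both a dense-matrix transcription and the
classical cluster-robust sandwich.

**Estimation.** The paper-level model leaves the nuisance estimators open;
the package uses standard moment estimators from Pearson residuals
($\sigma_{kk}$ with denominator $n - q$, $q$ mean parameters; exchangeable
$\rho$ from within-subject cross-products; AR1 $\rho$ from lag-one products
of consecutive visits; unstructured $R$ from the average residual outer
product, spectrum-floored at 0.05 — with few subjects or tie-degenerate
responses the raw estimate can be near-singular, which visibly inflates the
type-1 error). Coefficients and correlation parameters are alternated to
tolerance $10^{-8}$ (up to 200 iterations; the fixed point converges only
linearly on some small datasets). After convergence the coefficients are
recomputed once at the final parameters, so every reported statistic is an
exact function of (data, $\hat\sigma$, $\hat\rho$).

## Combining nodes: minimum p-value under Beta(1, M1)

The node statistics of one genus are asymptotically independent, so under
the genus-level null the minimum of the $M_1$ node p-values (the pooled node
always included) is Beta(1, $M_1$) and

$$p_{\text{genus}} = 1 - (1 - \min_k p_k)^{M_1}$$

is again uniform. With a single-taxon genus, $M_1 = 1$ and the genus is
still testable through the pooled node — an advantage over kernel methods
that need at least two taxa. In finite samples the node statistics share
taxa and are positively dependent, which makes the combination mildly
conservative; the suite therefore checks the rejection *level*, not exact
uniformity, on pipeline nulls. If a node fails numerically (e.g. a covariate
degenerates to a constant in a small subsample) the default policy drops it
and uses the realized node count as the Beta parameter; `keep_m1` keeps the
nominal count, which is conservative.

The `IM` variant applies the rank-based inverse normal transform
$z_i = \Phi^{-1}((\mathrm{rank}_i - 0.5)/n)$, average ranks for ties, to
each covariate vector (all subject-visits pooled) before testing. On sparse,
heavy-tailed data this is what keeps small-sample type-1 error at its
nominal level; it also makes genus p-values invariant to any strictly
monotone distortion of a covariate. The `M` variant tests raw covariates
and its effect estimates live on the log-ratio scale.

## The synthetic-data generator

`generate_synthetic()` emulates the structure of a filtered, species-level
longitudinal 16S cohort:

* **Composition**: 24 genera of 1–20 species (168 taxa), each genus a clade
  on a random rooted binary tree. Libraries are log-normal
  ($e^{\mu} = 10^4$, sdlog 0.5, roughly 3000–30000 reads), so typical
  per-taxon counts are in the tens — the regime in which hundreds of
  species share a few thousand reads.
* **Abundances**: a per-taxon baseline $z_m \sim N(0, 1)$ scaled by a
  temperature $s$, plus unit-variance within-taxon log-noise with the chosen
  within-subject structure (independent, exchangeable, or AR1), pushed
  through a softmax and Poisson-thinned to the library size. The temperature
  is calibrated by root-finding so the expected zero fraction equals the
  `sparsity` target (default 0.64, the median of the cohort regime this
  emulates; 0.52 and 0.73 are the quartile scenarios). Only the baseline is
  scaled: zeros arise from rare taxa, while within-taxon temporal dispersion
  stays at about one log unit, as in real 16S series. An earlier design that
  scaled the noise as well produced count dispersion far beyond anything
  observed in practice.
* **Phenotype**: subject-level Bernoulli, independent of the counts — the
  generator produces *null* data; association is introduced only by
  [spike_in()].

What it does **not** emulate: taxon-taxon ecological interactions,
phylogenetic signal in abundances (abundance is independent of tree
position), batch effects, or visit-level covariates. Calibration and power
results on this generator therefore speak to the statistical machinery —
correlation handling, small-sample behaviour, compositional pooling — not to
any particular ecosystem.

## The experiment harnesses

`run_type1_power()` implements the permutation spike-in design: each
replicate draws `n_subjects` without replacement from the (filtered,
complete-case) base table, assigns case status at random at the requested
ratio (cases rounded down, controls up), draws a multi-taxon genus and a
test node within it, makes `p_causal` of the node's leaves causal, and adds
$\delta = \beta\,\hat\sigma_{mm}$ (taxon count variance over the whole base
table, rounded half-up) to case samples. $\beta = 0$ gives type-1 error;
power uses adjusted thresholds (empirical null quantiles) via
`rejection_rates(..., null_p = )`. Because $\delta$ grows with the square
of a taxon's abundance scale, abundant causal taxa saturate power quickly;
the informative regime is the ordering across $\beta$, which the acceptance
suite checks, not the absolute level.

`run_bias_experiment()` isolates compositional leakage: the tested genus is
spiked ($\beta = 0.15$, half the node's leaves), one random external taxon
is made phenotype-associated with case-sample shift $\mathrm{sd}_m \times$
multiplier, and the pooled-node effect is re-estimated under each reference.
The bias estimate is the *paired* difference against the same replicate
without the external effect, so its mean and IQR isolate the leakage. In
this generator the ALR reference (a single random genus) shows the largest
mean bias and IQR at high multipliers, and bias grows with the multiplier
for every reference; the default-versus-CLR ordering is close and varies
with the base composition, because once the external spike is large enough
to move case library sizes the $\log_2(\cdot + 1)$ transform responds
sublinearly for low-abundance cells and each reference's bias is driven by
how well its abundance profile matches the tested genus rather than by the
size of the reference pool.

**Problem sizes.** The suite and the acceptance script run the desk-scale
versions of these experiments: type-1 error with 2000 replicates per
working correlation at $N = 50$, power with 500 replicates per effect size
against a 1000-replicate null, the bias experiment with 1000–2000
replicates, and oracle equivalence on 100 random small instances. These
sizes put Monte-Carlo standard errors near 0.005 on rejection rates, which
is the resolution at which the calibration claims are stated.

## Compositional robustness and the pseudo-count

Exact invariance of the covariates to per-sample depth rescaling holds only
where counts dominate the pseudo-count: for a zero cell the numerator of the
CPM ratio is the pseudo-count itself, which does not scale with the sample
factor under the constant policy, so a sample's zero cells shift by up to
$|\log_2 s|$. The library-scaled policy cancels the factor for single-sample
rescaling (unit tests check a shift below $10^{-2}$ on the node covariate at
sparsity 0.55), but a *global* random rescaling still moves the shared mean
library and with it every zero cell. On zero-free tables with libraries
$\ge 10^4$ the genus p-values are invariant to random per-sample factors in
$[0.5, 2]$ to well below $10^{-2}$ under either policy — the acceptance
suite checks exactly this, and the sparse-data caveat is the reason the
robustness fixture is dense.

## Degenerate inputs and edge cases

Constant phenotype, rank-deficient designs, zero library sizes, empty
genera, non-binary trees, and non-monophyletic genera (strict error or
lenient pruning of foreign leaves) all raise informative errors; a subject
carrying all the phenotype information makes the leverage correction
singular and is reported as such. Ties in a covariate map to one
transformed value; an all-tied covariate is identically zero after the
transform and the node is dropped under the failure policy.

## Known limitations

* The Beta(1, $M_1$) null leans on asymptotic independence across nodes;
  at small $n$ the combination is conservative rather than anti-conservative.
* The unstructured working correlation needs balanced visit grids and a
  spectrum floor; with many visits and few subjects it remains the least
  stable choice.
* Effect estimates $\hat\beta_k$ are on the (possibly transformed)
  log-ratio scale; they order effects but are not directly interpretable as
  fold changes.
* The generator's realism limits are listed above; conclusions about real
  cohorts require the real tables.
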