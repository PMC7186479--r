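---
title: "Methods: compositional ordination, diel periodicity, and virus-host network inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compositional ordination, diel periodicity, and virus-host network inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microts)
```

# Scope

`microts` analyses taxon-by-sample count tables collected as a time series —
the typical output of an amplicon survey sampled repeatedly over days. It
covers three workflows: (i) normalizing compositional counts and ordinating
or clustering samples and taxa; (ii) screening every taxon for a diel
(24-hour) periodic signal with a non-parametric rank test under false
discovery rate control; and (iii) simulating virus–microbe communities and
inferring their weighted infection network from sampled dynamics. All inputs
needed for development and testing come from the package's own seeded
generators; no downloads are involved.

# Compositional normalization

Sequence counts are compositional: each sample's reads sum to its sequencing
depth, so only relative information is present and naive covariances acquire
a built-in negative bias. The package provides the standard log-ratio ladder:

* `focal_log_ratio()` — log abundances relative to one focal taxon,
  $\mathrm{LR}_i = \ln x_i - \ln x_{\mathrm{focal}}$. Simple, but every value
  is relative to an arbitrary reference.
* `clr()` — log abundances centred on the sample's geometric mean. CLR
  columns sum to zero (still sum-constrained), which the test suite asserts
  to $10^{-9}$ on random compositions, along with invariance to per-sample
  rescaling.
* `ilr()` — an orthonormal contrast basis applied to CLR, mapping $n$ taxa
  to $n-1$ unconstrained coordinates. Distances between samples are
  identical under CLR and ILR (isometry, asserted to $10^{-9}$). The default
  basis is a Helmert-type sequence of contrasts in taxon input order; no
  canonical sequential binary partition exists for these data, so the basis
  is documented as order-dependent and overridable.

Zeros must be handled before taking logs; `add_pseudocount()` (default
$c = 1$) makes all entries positive. A pseudocount disproportionately
perturbs rare taxa whose between-sample differences are comparable to $c$;
this caveat is inherent to the approach, not an implementation detail.
`started_log()` ($\ln(x + c)$) is the variance-stabilizing step used before
clustering: it behaves like a plain log for large counts and remains defined
at zero. It is a deliberate, simple stand-in for model-based
variance-stabilizing transforms that fit a mean–dispersion trend; cluster
memberships obtained with it will not exactly reproduce analyses based on
such fits. `zscore()` uses the sample ($n-1$) standard deviation, and
`detrend_linear()` removes each taxon's ordinary-least-squares line on time
(idempotent; residuals have zero mean and slope).

# Dissimilarity and ordination

`euclidean_dist()`, `jaccard_dist()` (presence = count > 0),
`bray_curtis()`, and `aitchison_dist()` (Euclidean on CLR) feed the
ordination and clustering steps. Bray–Curtis is flagged non-metric:
`bray_curtis_counterexample()` constructs three samples violating the
triangle inequality, and the suite verifies both the violation and its
downstream symptom — negative PCoA eigenvalues.

`pca()` eigen-decomposes the covariance matrix of the observations. `pcoa()`
applies the Gower double-centring $-\tfrac12 J D^2 J$ and eigen-decomposes;
coordinates are eigenvectors scaled by $\sqrt{\lambda}$. Negative
eigenvalues are reported as-is with zero coordinate contribution and a
warning — no Cailliez/Lingoes correction — because surfacing non-metricity
is more informative than silently repairing it. Variance fractions are taken
over positive eigenvalues only. On Euclidean input, PCoA reproduces PCA
variance fractions to $10^{-9}$ (asserted).

`mds()` minimizes the metric least-squares objective
$\sum_{i<j} (d_{ij} - d'_{ij})^2$ and reports the normalized stress
$\sqrt{\sum (d - d')^2 / \sum d^2}$. This is deliberately *metric* MDS;
Kruskal's monotone-regression NMDS is out of scope, and the function is
named for what it optimizes. Defaults: PCoA initialization plus 20 seeded
random restarts, BFGS with analytic gradient, relative tolerance $10^{-8}$,
2000 iterations per start. Identical seeds give identical coordinates.

# Clustering taxa by temporal profile

The intended pipeline is `taxon_profiles()`: started-log, per-taxon z-score,
Euclidean taxon-by-taxon distances. `pam()` is a from-scratch BUILD + SWAP
k-medoids (steepest improving swap, lowest-index tie-break, hence
deterministic); it is cross-checked against an independent reference
implementation and against brute-force partition enumeration on small
instances. `agglomerative()` cuts a standard hierarchical tree at $k$.

Three quality indices are provided. `sse()` is the centred within-cluster
sum of squares (the usual elbow quantity). `calinski_harabasz()` is
$[B/(k-1)]/[W/(n-k)]$; on the hand-worked four-point instance
(0, 0.1, 10, 10.1 split at the gap) it equals 20000 exactly.
`silhouette_widths()` ships two variants because two definitions circulate:
`"extrema"` scores each item by
$(\min d_{\text{out}} - \max d_{\text{in}})/\max(\cdot,\cdot)$ — positive
iff the item is closer to its farthest in-cluster neighbour than to any
outside item — while `"standard"` is Rousseeuw's mean-based
$(b - a)/\max(a, b)$. Neither is asserted as *the* silhouette; both are
bounded in $[-1, 1]$ and singletons score 0. `sweep_k()` tabulates all
three indices over a range of $k$ and flags the CH argmax, but selects
nothing automatically: the table, inspected for an elbow, is the
deliverable. A caution learned from the test fixtures: for very tight
Gaussian blobs CH keeps rewarding splits of true clusters, so the CH argmax
recovers the planted $k$ reliably only when within-cluster scatter is
non-negligible relative to separation.

# Diel periodicity screening

Each taxon's detrended series is tested for a single rise-and-fall per
period. Sampling times map to $C = \text{period}/\Delta t$ phase classes
(default $24/4 = 6$). For a candidate peak class, observations are ordered
by circular distance from the peak, and the umbrella statistic counts,
Mann–Whitney style, the concordant pairs among all pairs whose classes are
strictly ordered (ties count one half). The per-peak p-value comes from a
seeded permutation null — shuffling observation order — as
$p = (1 + \#\{T_{\text{perm}} \ge T_{\text{obs}}\})/(1 + n_{\text{perm}})$,
and the reported p-value is the minimum over the $C$ candidate peaks times
$C$ (Bonferroni over shapes), capped at 1. Only symmetric umbrellas are
candidate shapes. Design notes:

* The exact analytic null of the published rank-based rhythmicity method is
  replaced by a permutation null: assumption-light, seeded, and directly
  testable. Validity is asserted by simulation: across 1000 null series,
  $P(p \le \alpha) \le \alpha + 2/\sqrt{n_{\text{perm}}}$.
* Because the statistic is rank-based, the permutation null for a tie-free
  series depends only on the class layout, so `periodicity_screen()`
  computes it once and shares it across taxa; taxa with tied values fall
  back to permuting their own values. This is exactly equivalent for
  continuous (CLR-detrended) data and makes community-wide screens cheap.
* At least two full periods must be sampled (the test assumes stationarity
  across periods); the default design — 19 samples at 4-h intervals over
  72 h — provides three.
* A peak lying exactly between two phase classes (e.g. hour 14 on a 4-h
  grid) is genuinely ambiguous between the flanking classes; the reported
  class is the p-value argmin with ties broken low.
* Default $n_{\text{perm}} = 10000$; p-values are floored at
  $1/(n_{\text{perm}}+1)$ before the shape correction.

`bh_fdr()` applies the Benjamini–Hochberg step-up rule across taxa and is
verified against both an exhaustive threshold scan and the stock adjusted
p-value routine. Calibration and power are measured, not assumed: on
pure-noise tables (1000 taxa) the screen's rejected fraction at
$\alpha = 0.05$ is essentially zero, and on planted 24-h cosines with
amplitude twice the noise standard deviation the screen recovers at least
80% of planted taxa (medians over 25 seeds; these runs use
$n_{\text{perm}} = 2000$, which changes p-value resolution, not validity).

The companion demonstration `gen_random_walks()` /
`spurious_correlation_summary()` shows why detrending/differencing matters:
independent random walks, tested pairwise for Pearson correlation, appear
"significant" far above the nominal rate, while their first differences sit
at it (asserted: residual fraction within [0.03, 0.07] and raw fraction at
least three times larger, medians over 25 seeds).

# Virus–host dynamics

The community model couples $N_H$ hosts and $N_V$ viruses:
$$\dot H_i = r_i H_i\Big(1 - \tfrac{1}{K}\sum_{i'} H_{i'}\Big)
  - H_i \sum_j M_{ij}\phi_{ij} V_j, \qquad
\dot V_j = V_j \sum_i M_{ij}\phi_{ij}\beta_{ij} H_i - m_j V_j,$$
with binary infection network $M$, adsorption rates $\phi$ (ml/h), burst
sizes $\beta$, host growth rates $r$ (1/h), shared carrying capacity $K$
(cells/ml) and virus decay rates $m$ (1/h). Integration is adaptive-step
(lsoda) at relative tolerance $10^{-8}$; the closed-form limits (aggregate
logistic growth without viruses, pure exponential decay without hosts,
equilibrium invariance) are asserted to $10^{-6}$ relative.

`sample_community()` builds nested networks (virus $j$ infects hosts
$1..j$). Drawing all traits at random and rejecting until a positive
equilibrium appears works only for very small communities — the acceptance
probability collapses with dimension — so the sampler instead draws $\phi$,
$\beta$ and *target equilibrium abundances* $H^\ast \in [10^4, 10^5]$,
$V^\ast \in [10^6, 10^7]$ per type, and derives
$m = (M \circ \phi \circ \beta)^{\mathsf T} H^\ast$ and
$r = (M \circ \phi)\, V^\ast / (1 - \sum H^\ast / K)$, which are positive by
construction. Candidates whose derived rates leave broad plausibility bounds
($r \in [0.01, 10]$/h, $m \in [10^{-3}, 1]$/h) are redrawn. Trait scales are
marine-virus orders of magnitude: $\phi \in [10^{-9}, 10^{-7}]$ ml/h,
$\beta \in [10, 100]$, $K = 10^7$ cells/ml. Feasibility, not local
stability, is guaranteed; `vh_stability()` reports the Jacobian spectral
abscissa at the equilibrium for users who want the latter.

# Network inference

The virus equations imply that the per-capita derivative
$W_j = \mathrm{d}\ln V_j/\mathrm{d}t$ is linear in host densities:
$W_j = \tilde M_j^{\mathsf T} H - m_j$ with
$\tilde M_{ij} = M_{ij}\phi_{ij}\beta_{ij}$. `percapita_derivatives()`
estimates $W$ by central log-differences (exact for exponentials; forward
differences by flag), dropping endpoints. `infer_network()` solves, per
virus row,
$$\min_{\tilde M_j \ge 0,\; m_j \ge m_{\min}}
  \|W_j - \tilde M_j^{\mathsf T} H + m_j \mathbf 1\|_2^2
  + \lambda \|\tilde M_j\|_1 .$$
Numerical choices:

* The residual is squared (standard lasso form) rather than an unsquared
  norm; the minimizer family is identical and the problem far better
  conditioned.
* Strict positivity is relaxed to $\tilde M \ge 0$ and
  $m \ge m_{\min} = 10^{-6}$/h: closed sets are required for attainment and
  sparsity requires exact zeros.
* The solver is an active-set non-negative least-squares method with the L1
  term folded into the normal equations. Host trajectories from
  perturbed-equilibrium simulations are highly collinear, which stalls
  first-order methods; the active-set method terminates finitely at machine
  precision (scaled KKT residuals around $10^{-14}$, asserted below
  $10^{-6}$), and is checked against an independent box-constrained
  quasi-Newton optimizer.
* `select_lambda()` cross-validates over *contiguous time blocks* (default
  5), never a random scatter — time series are autocorrelated and random
  folds would leak. The smallest $\lambda$ attaining the minimal mean
  held-out squared residual (relative tolerance $10^{-10}$) is selected.

`recovery_metrics()` scores an inferred network against the generating
community: support precision/recall/F1 with an edge called present above
`support_threshold` times the largest inferred weight, relative Frobenius
error over the true support, and relative decay-rate error. The default
threshold is $10^{-3}$: true weights $\phi\beta$ span $10^{-8}$–$10^{-5}$
(three decades), so a 1%-of-max threshold would by construction miss the
weakest true edges no matter how good the fit.

The reference experiments, run by the acceptance suite with $\lambda$
chosen by blocked CV over $10^{-8} \ldots 10^{3}$:

* *Noiseless:* 10x10 nested community, equilibrium perturbed by ±20%,
  150 h sampled every 0.1 h. Median support F1 over 5 seeds is 1.0 and
  median relative Frobenius error is below 0.05. The dense sampling keeps
  central-difference truncation below the smallest edge weights.
* *Noisy:* 1% multiplicative log-normal observation noise on all densities,
  ±50% perturbation, 600 h sampled hourly. Median support F1 over 5 seeds
  is at least 0.9. Coarser, longer sampling trades truncation error for
  noise averaging; the larger perturbation enriches the dynamics that
  identify weak edges.

# Synthetic diel tables

`gen_diel_table()` emulates the structure the screening pipeline assumes: a
3-day campaign sampled every 4 h (19 time points). Latent log-abundance of
taxon $i$ is baseline + optional cosine + linear trend + Gaussian noise;
counts are a per-sample multinomial over the softmax of the latent vector,
so columns sum exactly to the depth and carry the compositional negative
correlation of real data. Defaults, chosen once: 100 taxa, 20% periodic,
noise sd 0.5 (log scale), amplitude 1 (twice the noise sd), baselines
N(0, 2) (a realistic spread of rare and dominant taxa), trends N(0, 0.01)/h,
depth 50000 reads. What it does *not* emulate: overdispersion beyond the
multinomial (a log-normal noise layer stands in), taxonomic structure,
sequencing error, or zero-inflation mechanisms beyond sampling; passing
tests therefore demonstrate correctness of the statistical machinery, not
performance on any particular real community.

# Known limitations

* The ILR basis is order-dependent by default; analyses that interpret
  individual ILR coordinates should supply a meaningful basis.
* Metric MDS only; rank-based NMDS is intentionally absent.
* Only symmetric umbrella shapes are tested; asymmetric rise/fall profiles
  lose power.
* The coexistence sampler targets square ($N_H = N_V$) nested communities;
  other network architectures must be supplied manually via
  `vh_community()`.
* $\phi$ and $\beta$ are inferred only as their product with $M$; the
  factors are not separately identifiable from these data.
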