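---
title: "Structural-functional coupling analysis: models, conventions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural-functional coupling analysis: models, conventions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfcoupling)
```

## The scientific question

Structural connectivity (SC, white-matter connection probabilities from
probabilistic tractography) constrains functional connectivity (FC,
inter-regional correlations of resting-state BOLD signals). The degree to
which individual functional networks track their structural scaffold —
SC-FC *coupling* — is a candidate marker of network-level damage in
cerebral small vessel disease (CSVD) and related conditions: with
increasing lesion burden, coupling is expected to fall, and the drop to
track cognitive decline.

This package implements the full analysis chain used in such studies:

1. build FC from regional time series (`build_fc()`), symmetrize raw
   directed SC (`symmetrize_sc()`);
2. sparsify the FC network over a series of proportional thresholds
   (`threshold_proportional()`, `threshold_scheme()`);
3. at each threshold, correlate retained FC edge weights with their SC
   counterparts, whole-brain and per functional module
   (`coupling_profile()`);
4. compute weighted graph metrics of the sparse FC networks — global,
   local and nodal efficiency and characteristic path length
   (`topology_profile()`);
5. summarize every per-threshold curve by a range-normalized AUC
   (`auc_summary()`);
6. compare groups with covariate-adjusted ANCOVA and LSD post hoc tests,
   correlate metrics with cognition by partial correlation, and control
   discovery with Benjamini-Hochberg FDR (`ancova_group_test()`,
   `partial_correlation()`, `bh_fdr()`);
7. validate every stage against a synthetic cohort generator with known
   ground truth (`sim_config()`, `generate_cohort()`).

## The coupling statistic

At sparsity $s$, the sparse functional network retains the
$k = \mathrm{round}(s \cdot n(n-1)/2)$ strongest edges (upper triangle;
round-half-away-from-zero; ties broken by ascending row/column index so the
retained sets are nested across $s$). Writing $f_{ij}$ for the retained FC
weights and $w_{ij}$ for the SC weights of the *same* edges, the coupling
at $s$ is the Pearson correlation

$$ r(s) = \mathrm{cor}\big(\{f_{ij}\},\ \{w_{ij}\}\big),
   \qquad (i,j) \in E(s). $$

Structural zeros are kept as-is; no structural-edge filtering is applied.
Modular coupling restricts $E(s)$ to edges with both endpoints inside one
functional module. Pearson correlation makes the statistic invariant to any
positive affine rescaling of SC, so waytotal-normalized and raw
tractography outputs give identical coupling.

Fewer than 3 surviving edges, or zero variance of either vector, make the
value undefined; the two conditions carry distinct marker codes. The
statistic is carried raw (not Fisher-z transformed) into the group
statistics, matching the convention of ANCOVA on the metrics directly;
a z-transform can be applied by the caller if desired.

### Threshold series and AUC

The default scheme sweeps $s$ from 8% to 60% in steps of 2% (27 levels),
the range in which sparse brain graphs stay connected enough to be
comparable yet free of the weakest, least reliable correlations. Each
metric's curve is summarized by the trapezoidal integral over $s$ divided
by the width of the range, so the summary lives on the metric's own scale
(a constant curve summarizes to that constant; published whole-brain
coupling AUCs around 0.27 are directly comparable to per-threshold
couplings). Up to 10% of undefined points are filled by linear
interpolation (constant extension at the ends); beyond that the AUC is
reported undefined rather than guessed.

## Weighted topology metrics

Metrics operate on the sparse FC network with weights divided by the
network maximum, so normalized weights lie in $(0, 1]$ and edge *lengths*
$\ell_{ij} = 1/\tilde w_{ij}$ are $\geq 1$. Shortest-path distances
$d_{ij}$ come from Dijkstra's algorithm (via igraph). Then

- global efficiency $E_{glob} = \mathrm{mean}_{i \neq j}\, 1/d_{ij}$,
  with disconnected pairs contributing 0;
- nodal efficiency $E_{nodal}(i) = \mathrm{mean}_{j \neq i}\, 1/d_{ij}$;
- local efficiency $E_{loc}$ = mean over nodes of the global efficiency of
  the subgraph induced by each node's neighbours (weights retained, no
  renormalization; nodes with fewer than two neighbours contribute 0);
- characteristic path length $L_p = 1/E_{glob}$ by default (the harmonic
  convention, finite and monotone on partially disconnected sparse
  graphs); an arithmetic-mean-of-finite-distances alternative is a
  configuration switch, reported in the run metadata, because toolbox
  conventions differ and published values rarely state which was used.

Under these conventions all efficiencies lie in $[0, 1]$, a complete
unit-weight graph attains $E_{glob} = E_{loc} = L_p = 1$, and adding an
edge can never decrease $E_{glob}$ or any $E_{nodal}$ — properties the
test suite checks against an independent Floyd-Warshall-based brute-force
implementation.

## The inference layer

The group analysis mirrors standard neuroimaging practice:

- **Normality screening** uses the Kolmogorov-Smirnov statistic with
  estimated mean/sd. Because estimating parameters makes the classical
  null anticonservative, the reference p-value comes from a seeded
  Monte-Carlo null of the Lilliefors statistic (default 10,000
  replicates); the naive K-S p is reported alongside for auditability.
- **ANCOVA**: a linear model of each metric on the group factor plus head
  motion, age, sex and education; the omnibus test is the partial F for
  the group block; adjusted means are evaluated at the covariate means;
  pairwise contrasts are unadjusted model-based t tests (the LSD
  convention extended to the covariate-adjusted model). The control group
  is the dummy-coding reference; sex enters as a single 0/1 dummy. With no
  covariates the ANCOVA reduces exactly to one-way ANOVA.
- **Summary-statistic ANOVA** (`anova_oneway_summary()`) recomputes the
  omnibus F from per-group (n, mean, sd) alone, enabling exact re-analysis
  of published demographic tables; the package ships one such table
  (`reference_cohort_summaries()`) as a worked example.
- **Partial correlation** between metric and cognitive score residualizes
  both on the covariates; $t = r\sqrt{df/(1-r^2)}$ with $df = n - 2 - c$.
- **FDR**: Benjamini-Hochberg across all metric-by-score pairs within one
  group's correlation analysis. Published analyses often leave the family
  unstated; both raw p and adjusted q are therefore always reported.

## The synthetic cohort generator

Real multimodal MRI cohorts cannot ship with a package, so every stage is
validated against a generator that emulates the statistical structure the
analysis assumes, with ground truth recorded.

**Structural networks.** Edge weights are log-normal
(`sdlog = 0.45`, between-module location `meanlog = -4`, within-module
location shift `+1`), giving the right-skewed, block-structured weight
distribution typical of connection-probability matrices.

**Coupled functional networks.** All SC edge weights are rank-normalized
*globally* to normal scores $z$ (one transform over all edges, so the
modular SC elevation carries into FC). Each edge belongs to a scope —
its module for within-module edges, a between-module scope otherwise —
and a latent edge value is drawn per scope as
$\lambda = a\,z + \sqrt{1-a^2}\,\varepsilon$,
$\varepsilon \sim N(0, \texttt{noise\_sd}^2)$, with scope-specific
association $a$. The FC weight is $|\tanh(0.25(\lambda + 2))|$: a
Fisher-z-scale squashing into $[0, 1)$ matching the absolute-FC
convention, with the location shift keeping the latent mostly positive so
the absolute value rarely folds. No biophysical time-series model is
implied — the analysis only assumes a monotone edge-wise association, and
this is the simplest construction that makes coupling a controllable,
recoverable parameter. (Time series with a prescribed correlation target
are available separately via `generate_time_series()`, which samples a
multivariate normal after projecting the target onto the nearest valid
correlation matrix with Higham's alternating-projection algorithm.)

**Calibration of targets.** The estimated coupling is a monotone but
attenuated function of the latent loading $a$: attenuation comes from the
rank-to-raw shape mismatch, the tanh squash, and the range restriction of
correlating only the strongest FC edges. Published coupling values live on
the estimated scale, so group targets are mapped through the inverse of a
fixed calibration curve (`latent_loading()`): the generator's mean
estimated whole-brain coupling AUC tabulated by simulation at its design
point (90 regions, five modules, default threshold series), with the
0.40-0.60 latent band — where published whole-brain couplings land —
refined by a pooled local-linear fit. Because the whole-brain estimate
mixes within-module edges (≈35% of retained edges, carrying the module
loadings) with between-module edges, each default group also carries an
explicit `between` target, solved at design time so the *marginal*
whole-brain estimate lands on the published group values. With these
defaults the simulated regime reproduces group mean whole-brain coupling
AUCs of ≈0.268/0.278/0.284 (CSVD-s/CSVD-m/HC) with between-subject sd
≈0.03, the published Table-level regime.

**Cohort structure.** Default group sizes are 54/106/79. A subject-level
coupling deviation (sd 0.015 on the estimated scale, shared across scopes)
creates true between-subject coupling variation; cognitive scores (MoCA,
AVLT, SCWT, SDMT, TMT; the latter two inhibition/set-shifting scores
higher-is-worse) are linear in the subject's true whole-brain coupling
plus small age and education effects and Gaussian noise, with slopes
chosen so observed (estimation-attenuated) partial correlations fall in
the 0.2-0.4 band reported for patient cohorts. Covariates: age
$N(62, 8^2)$ years, education $N(12, 3.3^2)$ years, sex Bernoulli(0.55),
head motion $N(0.12, 0.04^2)$ mm truncated at 0.01. An optional
`efficiency_shift` per group applies the monotone transform
$f^{1-\text{shift}}$ to FC weights, moving weighted efficiencies without
changing edge ranks (hence without touching coupling ordering). All
randomness flows through a single stream seeded from the configuration,
so identical configurations are byte-identical on disk.

**What the generator does *not* emulate.** No hemodynamics, no spatial
autocorrelation or distance-dependent connectivity, no lesion topography,
no site or motion artifacts, and FC noise that is exchangeable across
edges. Passing tests therefore demonstrate that the *pipeline* recovers
the structure it assumes — not that real CSVD data satisfy those
assumptions.

## Numerical choices and degenerate inputs

- Symmetry tolerance on input matrices is 1e-9; matrices are exactly
  symmetrized after passing it. Diagonals must be exactly zero. `NA` is a
  hard error in matrices but allowed in cognitive scores (excluded
  pairwise).
- Region order is canonicalized to the partition's order on load, so
  label misalignment between FC, SC and partition files cannot occur
  silently.
- Rounding of the retained edge count is half-away-from-zero, matching
  common connectome toolboxes; `round()`'s half-even rule would disagree
  at, e.g., $k = 0.5 + m$.
- The nearest-correlation projection clips eigenvalues at 1e-8, iterates
  with Dykstra's correction to tolerance 1e-10 (max 200 iterations), and
  finishes with one strict clip-and-rescale so the output is exactly
  unit-diagonal and numerically PSD.
- The Lilliefors Monte-Carlo p-value uses the add-one estimator
  $(\#\{D_0 \geq D\}+1)/(B+1)$, which cannot return 0.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to exercise every code path while staying lightweight: oracle
equivalence on 200+ random networks of up to 10 nodes; parameter recovery
over a 9-point loading grid with 10-20 replicates at the full 90-region
scale; statistical calibration on 2000 simulated nulls of 60 subjects; and
the end-to-end default cohort (239 subjects, 90 regions, 27 thresholds)
repeated 8-9 times. The scaled-down Lilliefors calibration in the unit
tests uses n = 100 samples with 300-replicate nulls.

## Known limitations

- The shipped five-module AAL-90 partition is a documented approximation
  of the standard resting-state division; studies with their own
  assignment should supply it via `read_partition()` (all downstream code
  is partition-agnostic).
- The calibration curve of `latent_loading()` is tabulated at the
  generator's design point; for very different region counts, partitions
  or threshold schemes the mapping remains monotone but its absolute scale
  drifts, so targets should then be interpreted qualitatively.
- Coupling is edge-wise Pearson on a shared edge set; communication-model
  SC transforms (shortest-path, diffusion), node-level coupling, and
  dynamic (sliding-window) coupling are out of scope.
- The ANCOVA assumes homogeneous covariate slopes across groups and the
  partial correlations assume linearity; both are standard but untested
  assumptions of the emulated analysis.
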