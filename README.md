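# scfcoupling

Structural-functional connectivity (SC-FC) coupling analysis for brain
connectomes, with a validated synthetic-cohort test bed.

## What this is for

In network neuroscience, the white-matter structural connectome (SC,
probabilistic-tractography connection probabilities between atlas regions)
constrains the resting-state functional connectome (FC, inter-regional BOLD
correlations). How tightly an individual's FC tracks their SC — *SC-FC
coupling* — is studied as a marker of network damage in cerebral small
vessel disease (CSVD) and other conditions: coupling is expected to fall
with lesion burden and to correlate with cognitive performance.

`scfcoupling` implements that analysis chain end to end for users who have
region-by-region connectivity matrices (or regional time series) and a
subject table:

- **Network construction** — Pearson FC from time series (absolute or
  signed convention), symmetrization of directed tractography output.
- **Proportional thresholding** — retain the `round(s·n(n−1)/2)` strongest
  edges for a sparsity series (default 8%–60% by 2%, 27 levels), with a
  deterministic tie rule giving nested edge sets.
- **Coupling** — at each sparsity `s`, the Pearson correlation between the
  retained FC edge weights and the same edges' SC weights,

  `r(s) = cor({f_ij}, {w_ij}), (i,j) ∈ E(s)`,

  whole-brain and within each of five functional modules
  (auditory/motor, vision, attention, default-mode, limbic/subcortical on
  the 90-region AAL atlas; user-replaceable partition).
- **Weighted topology** — global/local/nodal efficiency and characteristic
  path length of the sparse FC graphs (lengths `1/weight` after
  max-normalization).
- **AUC summaries** — every per-threshold curve is reduced to its
  trapezoidal integral divided by the threshold range, so summaries share
  the metric's scale.
- **Inference** — ANCOVA controlling head motion, age, sex and education
  with LSD post hoc contrasts; chi-square and summary-statistic ANOVA for
  demographic tables (including re-analysis from published n/mean/sd
  alone); partial correlations with cognition; Benjamini-Hochberg FDR;
  Lilliefors-corrected normality screening.
- **Synthetic cohorts** — a generator producing coupled SC/FC connectomes
  with controllable, recoverable coupling, group structure, covariates and
  cognition, used to validate every stage with known ground truth.

## Worked example

Simulate one healthy-control-like subject and profile it:

```r
library(scfcoupling)
set.seed(42)
part <- default_partition()                       # AAL-90, five modules
sc   <- generate_base_sc(90, part)                # modular tractography-like SC
fc   <- generate_fc_from_sc(                      # FC coupled to SC
          sc, latent_loading(default_coupling_targets()[["HC"]]),
          partition = part)

coupling_profile(fc, sc, part, threshold_scheme(), subject = "sub-001")
#> <coupling_profile> subject sub-001, 27 thresholds (0.08-0.60), 6 scope(s)
#>   AUC (threshold-averaged coupling):
#>     whole_brain          0.2643
#>     auditory_motor       0.1758
#>     vision               -0.0832
#>     attention            0.1606
#>     dmn                  0.4191
#>     limbic_subcortical   0.2082
```

The whole-brain AUC (0.26) is the subject's threshold-averaged SC-FC
coupling — directly comparable to published group values around
0.27–0.28 — and the modular values show the typical spread (default-mode
highest; a small module like vision is noisy at strict thresholds).
Topology of the same functional network:

```r
topology_profile(fc, threshold_scheme(values = seq(0.1, 0.6, 0.1)),
                 subject = "sub-001")
#> <topology_profile> subject sub-001, 6 thresholds (0.10-0.60), 90 regions, Lp convention: harmonic
#>   AUC: Lp = 1.9975, Eglob = 0.5041, Eloc = 0.4536
```

Re-analysis of a published demographic row from its printed summaries
(54/106/79 subjects; symbol digit modalities test):

```r
s <- anova_oneway_summary(n = c(54, 106, 79),
                          mean = c(26.18, 32.18, 40.42),
                          sd = c(11.85, 12.43, 14.33))
#> SDMT: F(2, 236) = 20.40, p = 6.73e-09
```

A full cohort analysis — simulate 239 subjects in three groups, run the
whole chain, and write report tables (demographics, group comparison,
correlations, curves) — is one call:

```r
report <- run_all(run_config(simulate = sim_config(seed = 1),
                             out_dir = "results/run1", seed = 1))
```

or from the shell via the bundled wrapper
(`inst/scripts/scfc-pipeline.R simulate|run-all`).

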