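---
title: "Consensus-ICA connectivity analysis for placebo-controlled pharmacological fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-ICA connectivity analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconn)
```

# What this package computes

`metaconn` implements the analysis chain of a within-subject, placebo-controlled
resting-state pharmacological fMRI study. Each subject contributes one placebo
and one drug scan. The chain has five stages:

1. **Confound removal** — motion/global-signal outlier flagging, nuisance
   regression (polynomial drift, motion parameters and derivatives,
   white-matter/CSF signals, spike regressors for flagged volumes), a
   zero-phase 0.008–0.09 Hz bandpass, and 6 mm FWHM masked Gaussian smoothing.
2. **Consensus network identification** — group ICA is repeated 10 times on
   the *placebo* scans with randomized scan-concatenation order; components
   are matched across runs by absolute spatial correlation (threshold 0.7);
   sets of mutually matching components, one per run, are averaged into
   consensus resting-state networks (RSNs). A second pass at reduced support
   (4 of 10 runs) rescues networks that only a minority of runs recover.
3. **Within-network contrasts** — dual regression projects the consensus maps
   onto every session; subject-wise drug−placebo difference maps enter a
   one-sample t test per voxel, enhanced with TFCE, with familywise error
   controlled by sign-flip permutation (5000 permutations) and a Bonferroni
   gate across networks × directions.
4. **Between-network contrasts** — stage-1 time courses give a K×K Fisher-z
   correlation matrix per session; paired edge t tests gated at p < 0.01 form
   a suprathreshold graph whose connected components are tested by the
   network-based statistic (NBS, component mass, p < 0.05 familywise).
5. **Behavior** — drug ratings are summarized as peak change scores (PCS:
   maximum post-dose deviation from the same-session pre-dose baseline),
   tested with a two-factor fully-within-subject repeated-measures ANOVA, and
   correlated (Pearson, Bonferroni-corrected) with per-subject connectivity
   change at every significant finding.

No raw data from the motivating study are available, so the package ships a
synthetic-study generator with planted ground truth; every stage is validated
by recovery, calibration, and oracle-equivalence tests rather than by
reproducing printed statistics.

# The generative model

A study is a set of K compact spatial weight maps $X \in \mathbb{R}^{V\times K}$
(anisotropic Gaussian blobs, truncated at 5% of peak, pairwise spatial
correlation < 0.3, zero outside an ellipsoidal mask), per-session network time
courses $S \in \mathbb{R}^{T\times K}$, and white voxel noise:

$$Y = X S^\top + E,\qquad E_{vt} \sim \mathcal N(0, \sigma^2),$$

which is exactly the converse of dual regression. The rows of $S$ are Gaussian
with a prescribed correlation matrix: `edge_corr_placebo` in placebo sessions,
`edge_corr_placebo + edge_delta_drug` under drug, plus one symmetric
subject-level perturbation (SD `subject_sd`) shared across a subject's two
sessions — the within-subject structure the paired tests exploit. Invalid sums
are projected to the nearest correlation matrix (`Matrix::nearPD`) and the
projection is recorded.

Defaults mirror the emulated acquisition: 22 subjects × 2 sessions, TR = 3 s,
124 volumes, a 16×16×12 grid with an ellipsoidal mask, noise SD 1.

Three generator choices deserve comment, because the spec left them open and
the validation suite forced a position:

* **Network time courses are band-limited (0.01–0.08 Hz), not white.**
  Resting-state signal is low-frequency by definition; with white courses the
  analysis bandpass would discard half the *signal* and cleaning could never
  improve edge recovery. Filtering the white draws before mixing preserves the
  planted correlation exactly (filtering and mixing commute), so closed-form
  checks remain valid; only the effective temporal degrees of freedom shrink.
* **Motion spikes are structured.** A flagged volume receives a global offset
  (which trips the global-signal detector), an iid heterogeneous pattern, and
  a component aliased onto the planted maps — per-voxel scale 4× the noise SD.
  A purely global offset would be absorbed by the stage-1 intercept and would
  corrupt nothing, leaving the scrubbing machinery without true positives.
  Each spike also moves the recorded head position by 0.8 mm for one volume,
  so the framewise-displacement detector has true positives too.
* **Tissue surrogates are designated signal-free regions.** The generator
  marks two in-mask regions untouched by any planted map as the white-matter
  and CSF stand-ins, as anatomy would; surrogates chosen blindly (e.g. mask
  deciles) overlap planted networks, and regressing them out removes real
  signal.

Drug-responsive ratings are a smooth rise-and-fall response peaking between
the second and third post-dose timepoints (schedule −10, 15, 30, 75, 115,
200 min), with amplitude `drug_effect_size` × a per-subject sensitivity factor
(mean 1, SD 0.25, floored at 0.2), normalized so the noiseless peak change
score equals amplitude × sensitivity exactly.

What the generator does **not** emulate: hemodynamic response convolution,
physiological (cardiac/respiratory) noise, scanner drift beyond the quadratic
the denoiser removes, and actual head-motion image transformations (spikes are
signal-level surrogates). A green recovery test therefore establishes that the
pipeline's statistics behave as designed on data obeying its own linear
generative model — not that the pipeline is robust to every artifact of real
scanners.

# Confound removal: order and numerical choices

The stage order is fixed: outlier detection → nuisance regression (with spike
regressors) → bandpass → smoothing.

* **Framewise displacement** is the Power-style composite: sum of absolute
  backward differences of the three translations plus the three rotations
  converted to arc length at a 50 mm head radius. No universal "composite
  motion" formula exists; this one matches the 0.5 mm threshold scale and is
  the field standard. Volume *t* is flagged when FD(t) > 0.5 mm or the
  z-scored global-signal change exceeds 3 SD ("conservative" settings).
  Subjects are excluded when a session's mean FD exceeds 0.5 mm or more than
  50% of its volumes do (strict inequalities).
* **The bandpass is an ideal zero-phase frequency mask**, not a Butterworth:
  pass/stop behavior is then exact and testable bin by bin. A high cutoff
  above Nyquist (1/(2·TR) = 0.167 Hz at TR 3 s) is clamped to 0.99×Nyquist
  with a warning — printed acquisition parameters sometimes quote such
  cutoffs (0.9 where 0.09 is meant), and the clamp surfaces rather than hides
  the problem.
* **Continuous nuisance regressors are band-limited with the same passband
  before the regression.** Otherwise filtering reintroduces components of the
  regressors into the residuals (the censoring-vs-filtering problem). With
  this choice, regression and filtering commute, and the cleaning chain is
  exactly idempotent on sessions without flagged volumes. Spike indicators
  are inherently broadband, so strict idempotence cannot extend to scrubbed
  sessions; the scrubbing guarantee — residuals exactly zero at flagged
  volumes — holds immediately after the regression stage. Spatial smoothing
  is excluded from any idempotence claim: two Gaussian passes compose to a
  wider kernel by definition.
* **Smoothing is a normalized masked convolution** (numerator and denominator
  smoothed separably, ratio taken inside the mask): voxels outside the mask
  are neither read nor written, and a constant field inside the mask is
  preserved exactly.

# Consensus ICA

Each run reduces every session to 1.5×M temporal principal components,
concatenates them in a seeded random order, reduces to M group components, and
runs fixed-point spatial ICA (logcosh contrast, symmetric decorrelation,
bounded restarts — implemented in the package; no ICA dependency exists in
this environment). Maps are z-scored in-mask and sign-oriented to nonnegative
skewness. The model order M is re-estimated per run by Minka's Laplace
approximation to the PCA model evidence, evaluated on the eigenvalue spectrum
of the concatenated reduced data (columns = voxels as samples); the estimate
is exercised on planted-rank problems in the tests.

Matching across runs uses |Pearson r| over the mask (ICA signs are arbitrary)
with the 0.7 threshold. Because no edge ever joins two components of the same
run, any clique of the match graph automatically has at most one component
per run; consensus extraction therefore enumerates maximal cliques
(`igraph::max_cliques`), accepts them greedily by descending mean internal
|r| with single-use components, sign-aligns members to the best-connected
member, averages, and re-z-scores. The relaxed pass repeats this on leftover
components at `min_support = 4`, and returned networks carry their true
support count. Greedy-by-coherence resolution of overlapping candidate sets
is a package choice — deterministic and maximizing within-set coherence; the
source procedure did not specify one.

Visual artifact identification cannot be automated faithfully, so a heuristic
stands in: a network is flagged when >50% of its top-decile weight voxels lie
on the mask boundary shell, or when its members' mixing time courses carry
most of their spectral power above 0.1 Hz; a manual override list always wins.

# Inference

**Within-network.** The paired design is tested as a one-sample sign-flip on
subject difference maps — the exact exchangeability for a within-subject
drug/placebo contrast. TFCE uses E = 0.5, H = 2, dh = max(stat)/100,
26-connectivity (the method's standard defaults; the source gives none); the
negative tail is enhanced by applying the transform to the negated map. The
implementation sweeps thresholds from high to low with an incremental
union-find that accumulates cluster-wide increments lazily at cluster roots
(C++), and is tested to 1e-10 against a brute-force oracle that rebuilds
clusters independently at every threshold. Familywise p values are
$p(v) = (1 + \#\{\text{perm max} \ge \text{obs}(v)\})/(1 + n_{perm})$, with
the observed statistic serving as the identity permutation; all $2^N$ sign
patterns are enumerated when $2^N \le n_{perm}$. The Bonferroni gate divides
α = 0.05 by (networks × 2 directions) — with 23 networks that is 0.05/46 ≈
0.001, the source's gate.

**Between-network.** Edge t tests on Fisher-z differences are gated at
uncorrected p < 0.01; connected components of the suprathreshold graph are
scored by mass (sum of |t|; extent available). Sign flips are applied to
whole difference matrices, never per edge. The null distribution is the
permutation maximum of component mass over *both* contrast directions: with
separate per-direction nulls at α = 0.05 each, the familywise error of the
two-direction analysis is ~0.10, which violates the calibration the package
promises; the joint maximum controls the whole analysis at α without
splitting it (measured familywise error 0.055 over 200 null studies).
Directions are still reported separately, decreases first, |t| descending —
the conventional reporting layout.

**Behavior.** MAP = (SBP + 2·DBP)/3 (the clinical standard; the source's
formula figure is blank in the available text). The RM-ANOVA is a direct
sum-of-squares decomposition with each effect tested against its own
subject-interaction error term and uncorrected df (a Greenhouse–Geisser
epsilon is computed and can be applied, but the emulated analysis reported
uncorrected df); it is tested to 1e-10 against `stats::aov` with an `Error()`
stratum. Brain–behavior correlations multiply raw p values by the number of
connectivity measures tested.

# Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `fd_thresh` | 0.5 | mm | conservative scrubbing threshold |
| `gs_thresh` | 3 | SD | global-signal outlier threshold |
| `drift_order` | 2 | — | linear + quadratic drift |
| `low_hz`, `high_hz` | 0.008, 0.09 | Hz | resting-state passband (0.9 read as a misprint for 0.09; clamp rule applies) |
| `fwhm_mm` | 6 | mm | smoothing kernel |
| `n_runs` | 10 | — | ICA repetitions |
| `match_threshold` | 0.7 | \|r\| | cross-run component match |
| `relaxed_support` | 4 | runs | minority-network rescue pass |
| `n_perm` | 5000 | — | permutations per GLM |
| TFCE `E`, `H`, `dh` | 0.5, 2, max/100 | — | standard TFCE defaults |
| `edge_p` / `component_alpha` | 0.01 / 0.05 | — | NBS gates |
| `familywise_alpha` | 0.05 | — | Bonferroni budget across networks × directions |
| `edge_delta_drug` | ±0.2 | correlation units | free choice; the source reports only t statistics, no effect size |

# Known limitations

* The ICA runs differ only by concatenation order and initialization; on
  identical input data, strongly reproducible components (including structured
  noise at liberal model orders) can reach full support. At estimated model
  orders and realistic SNR this is the intended behavior of the consensus
  procedure, but it means "support 10" certifies stability, not neural origin
  — exactly why the artifact-flagging stage exists.
* Permutation p values are discrete: with 500 permutations the smallest
  attainable p is 1/501, so gates tighter than that are unreachable at test
  scale; the shipped defaults use 5000.
* The NIfTI reader/writer covers the single-file NIfTI-1 subset this package
  emits (float32/float64/int16/uint8, scl scaling on read); it is not a
  general neuroimaging I/O layer.
* `rm_anova` requires complete balanced tables and names the offending cells
  otherwise; the emulated study's differing per-measure Ns are handled by
  analyzing complete cases per measure.

# A worked miniature

```{r example, eval = FALSE}
library(metaconn)
cfg <- study_config(n_subjects = 10, n_networks = 5, n_perm = 500,
                    grid_shape = c(12L, 12L, 10L), noise_sd = 0.4,
                    spike_prob = 0.02, n_runs = 10, seed = 1)
bundle <- run_full(cfg, verbose = TRUE)
print(bundle)
bundle$between$pairs          # significant network pairs, Table-1 layout
bundle$behavior$anova         # drug x time repeated-measures ANOVA
```

The same analysis is driven from the shell by the wrapper installed at
`exec/metaconn` (`simulate`, `run-all`, … subcommands) and by
`scripts/acceptance.R`, which runs this miniature end-to-end under a given
seed.
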