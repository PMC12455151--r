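---
title: "Methods and design notes for uncflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for uncflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uncflow)
```

`uncflow` implements the computational chain used to analyse
uncertainty-manipulating spatial-cueing (Posner-type) EEG experiments:
behavioural signal detection, time-frequency power, electrode-cluster
permutation statistics, beamformer source reconstruction, and directed
(effective) connectivity between reconstructed sources. Every stage can be
exercised on synthetic data whose ground truth is fully known, so each
statistical claim the package makes is testable without any recordings.

This vignette explains the models and their assumptions, the tunable
parameters, what the synthetic generator does and does not emulate, and the
design decisions taken where the design was genuinely open.

## Behavioural model

Trials are a 3 (uncertainty condition) x 2 (cue validity) within-subject
design, one 256-trial block per condition with exactly 25% valid trials
(cue and target collocated). The two response letters are treated as a
signal-detection problem: correct responses to the signal letter are hits,
incorrect responses to the noise letter are false alarms, and sensitivity
is

$$d' = \Phi^{-1}(\text{hit rate}) - \Phi^{-1}(\text{false-alarm rate}).$$

Empirical rates of exactly 0 or 1 are replaced by $1/(2N)$ and $1 - 1/(2N)$
before the probit transform. We chose this correction (over log-linear
smoothing) because it is the most widely used convention and keeps single
cells with perfect performance finite without touching the other cells.
Note that under the correctness-based hit/false-alarm bookkeeping, swapping
which letter counts as signal maps hits onto correct rejections and misses
onto false alarms, so $d'$ is *invariant* to the assignment — which is the
operational content of "the assignment is arbitrary".

Participants with overall accuracy at or below 55% are excluded
(strictly greater than 55% is retained). RT analyses drop incorrect trials
and RTs outside [100, 2000] ms; the bounds are strict ("faster than 100 ms,
slower than 2000 ms"), so RTs exactly at the bounds survive.

`rm_anova()` is a textbook within-subject sums-of-squares decomposition:
each effect is tested against its own effect-by-subject interaction and
effect sizes are partial eta squared,
$SS_\text{eff} / (SS_\text{eff} + SS_\text{err})$. No sphericity correction
is applied, deliberately, so the degrees of freedom mirror the raw cell
structure of the design. `paired_contrasts()` provides the planned cell
comparisons; the package always emits both the omnibus tests and the
contrasts and leaves the inferential policy (e.g. gating contrasts on the
interaction) to the analyst.

The trial generator draws correctness as Bernoulli variables from per-cell
hit/false-alarm rates and RTs from a lognormal distribution. Lognormal was
chosen because RTs are positive and right-skewed; the default location/scale
parameters put the cell means near the magnitudes typical for this paradigm
(roughly 370-490 ms, with valid faster than invalid).

## Time-frequency decomposition

`morlet_power()` convolves each trial and channel with complex Morlet
wavelets of a fixed number of cycles ($n_c = 5$ by default). At frequency
$f$ the Gaussian envelope has

$$\sigma_t = \frac{n_c}{2\pi f}, \qquad \sigma_f = \frac{f}{n_c},$$

so the conventional quoted pairing "3 Hz spectral bandwidth, 53 ms temporal
resolution" is realised at $f = 15$ Hz. Wavelets are normalised to unit
energy, which makes power carry squared input units and makes white-noise
power flat across frequencies — the property the test suite checks.

Samples closer than $3\sigma_t$ to an epoch edge are flagged invalid and
excluded from baselines and window averages; epochs are long (default
-2 s to +2 s around the cue at 256 Hz) precisely so the 0-1000 ms analysis
window never touches the contaminated zone. Baseline correction subtracts
the mean power in [-200, 0] ms per trial, channel and frequency (absolute
subtraction; a relative/dB mode was considered and rejected to keep the
power scale interpretable against the generator's known burst amplitudes).
The default frequency grid is 1 Hz steps over 4-12 Hz, covering theta
(4-7 Hz) and alpha (8-12 Hz).

## Cluster-based permutation statistics

`cluster_test()` runs a paired t test at every channel, keeps channels
significant at the 5% sample level, groups them into connected components
of a sensor neighbourhood graph (split by sign), and scores each cluster by
the sum of its t values. The phrase "at least two pairs of neighbouring
electrodes" is ambiguous between "two channels that are neighbours" and
"two neighbouring pairs"; we implement the stricter literal reading — a
cluster must contain at least two graph *edges* — and expose `min_edges`
so the looser reading (`min_edges = 1`) is one argument away.

The Monte-Carlo null exchanges the two conditions within subject
(sign-flipping each subject's difference vector) and records the maximum
absolute cluster mass per draw; using the maximum makes the test
family-wise valid across clusters. A trial-level exchange
(`method = "trial_shuffle"`) is also provided for per-trial input, since
descriptions of this procedure in the literature vary between the two; the
subject-level flip is the default because the inferential unit in the
intended design is the subject. Cluster p values use the
$(1 + \#\{\text{null} \ge \text{obs}\})/(1 + n_\text{perm})$ convention so
that p is never exactly zero. Bonferroni correction across contrasts is a
plain multiplication capped at 1.

## Beamforming

Both beamformers are unit-gain minimum-variance spatial filters,

$$w_s = \frac{C^{-1} l_s}{l_s^{\mathsf T} C^{-1} l_s},$$

with $C$ the sensor cross-spectral density (DICS, complex, estimated from
Hann-tapered FFT cross-products over 0-600 ms and the target band) or the
time-domain covariance (LCMV). Ridge regularisation defaults to 5% of the
mean sensor power — the paper-trail for this analysis style rarely reports
the regularisation constant, so a conventional value was fixed once and is
exposed as `lambda`. Filters can be built from condition-concatenated data
and applied per condition ("common filters"), which avoids filter-induced
condition differences. Source masks keep the top 5% of sources by power
(ceiling count, ties included). ROI time courses default to the
peak-power source's filter output; a first-principal-component alternative
sits behind `method = "pc1"`.

The synthetic forward model is deliberately minimal: sensors on a unit
sphere, sources on an interior shell, gains falling off with squared
distance. It preserves the geometry that beamforming needs (distinct,
full-rank leadfield columns) and nothing else — no volume conduction, no
tissue compartments, no anatomical labels. Green beamforming tests
therefore establish correctness of the estimator, not realism of source
localisation on a human head.

## Effective connectivity (nonlinear MVAR network)

Source signals are band-limited with a zero-phase Hamming-windowed sinc
FIR filter (applied forward and backward; the default tap count follows
the Hamming transition-width rule with a 2 Hz transition band). A linear
VAR order scan (`select_model_order()`) reports both the Akaike and
Schwarz criteria; the operation returns the AIC minimiser, but users
should know AIC's well-documented ~25% overselection probability — the
test suite holds SBC to the stricter recovery bound for exactly this
reason.

The nonlinear MVAR model expresses the current sample of all $M$ sources
as a function of the $M \times p$ past samples,
$x_n = f(x_p) + \sigma_n$, and fits $f$ with a one-hidden-layer tanh
network (10 hidden units by default), trained by incremental
back-propagation with momentum, an adaptive learning rate (multiplied by
1.05 after an epoch that reduces training MSE, by 0.7 otherwise — the
classic incremental heuristic), uniform initialisation in [-0.5, 0.5],
permuted cross-validation with an 80/10/10 split and patience-based early
stopping on validation MSE. Signals are standardized per region before
training, which makes the connectivity estimates invariant to channel
rescaling. Trial boundaries are never crossed when building the lagged
regression problem.

The fitted map is split as $f = f(0) + f_\text{Lin} + f_\text{NonLin}$,
where $f_\text{Lin}$ is the first-order Taylor term at the origin with
Jacobian $J = W_\text{out}\,\mathrm{diag}(g'(b))\,W_\text{in}$. Linear
connectivity $lC_{i \to j}$ is the mean over lags of $|J|$ entries mapping
region $i$'s past to region $j$; nonlinear connectivity $NC_{i \to j}$ is
the data-averaged sensitivity of $f_\text{NonLin}$ — the mean over
training samples and lags of the absolute deviation of the local Jacobian
from $J$. The original method's extraction formulas are not printed in the
sources available to us, so these Taylor/average-sensitivity definitions
are this package's own and are kept behind the single
`decompose_connectivity()` interface so alternatives can be swapped in.
They are verified against finite-difference derivatives in the tests.

Significance uses time-shifted surrogates: each region's concatenated
series is circularly shifted by an independent offset of at least 10% of
its length, which preserves each series' own dynamics while destroying
cross-regional temporal precedence; the full estimator is re-run on each
surrogate with identical hyperparameters (re-training, not re-scoring —
frozen weights cannot produce a null for training-derived quantities), and
the per-connection threshold is the 90th percentile of the null. Group
comparisons then use a paired t test for linear and a Wilcoxon signed-rank
test for nonlinear connectivity, with subjects excluded per connection
when the connection fails the mask — which is why group degrees of freedom
can differ by connection.

### What the 90% threshold can and cannot deliver

A correctly calibrated 90th-percentile threshold flags each truly absent
connection about 10% of the time — the calibration the test suite
verifies. It follows arithmetically that *exact* recovery of a 3-node
graph, which requires all 10 absent connection tests (5 linear + 5
nonlinear off-diagonals) to stay below threshold simultaneously, cannot
exceed roughly $0.9^{10} \approx 0.35$ of runs for a calibrated estimator.
The package therefore reports both numbers in its acceptance suite: edge
*sensitivity* (the true linear and nonlinear edges exceed their thresholds
in the right matrices), which is high, and strict exact recovery, which is
bounded by the calibration and is left as a red, documented expectation
rather than loosened. Users who need family-wise edge selection should
raise the per-connection quantile or apply a multiplicity correction to
the surrogate p values.

## Synthetic data: scope and honesty

The generator emulates: the blocked 3 x 2 trial structure with exact valid
proportions; condition-dependent hit/false-alarm rates and lognormal RTs;
sensor epochs with theta/alpha bursts confined to 0-1000 ms post-cue on a
1/f-like noise floor, with condition effects on a known channel subset;
and source-level signals from stationary (non)linear MVAR systems
projected through the spherical leadfield with Gaussian innovations
(burn-in 200 samples per trial) and Gaussian sensor noise. The nonlinear
term library is restricted to `square` and `tanh_product` interactions —
rich enough to give the connectivity estimator a genuinely nonlinear
signal, small enough that analytic oracles exist.

It does not emulate: ocular or muscular artifacts, electrode drift, line
noise, volume conduction, inter-subject anatomical variability, or any
preprocessing chain. A green test on synthetic data establishes that the
*estimators* are correct, not that preprocessing-sensitive conclusions
about real EEG would replicate.

## Reproducibility and numerics

Every stochastic function takes a seed; the pipeline fans a master seed
out to stages via a documented affine map (`master * 97 + stage`, folded
into 32-bit range), so stages can be re-run independently and a fixed
config reproduces all outputs bit-identically. The C++ training core uses
its own `mt19937` generator seeded from the fold seed, so network training
is reproducible regardless of R's RNG state. Run configurations are JSON
(chosen over TOML/YAML because a JSON parser is a hard dependency anyway
and needs no extra parser); unknown keys are rejected by name and every
applied default is listed in a warning.

Degenerate inputs are handled explicitly: zero-variance channels get
t = 0 with a log entry, all-zero difference vectors give Wilcoxon p = 1
with a note, rank-deficient covariances demand a positive ridge, unstable
MVAR systems are rejected with the companion spectral radius in the
message, and non-finite training losses abort with the MSE history.

## Known limitations

- The beamforming stage has no realistic head model; localisation claims
  are structural (grid indices), never anatomical.
- The connectivity decomposition formulas are this package's documented
  choice; other published variants would give numerically different (if
  qualitatively similar) lC/NC scales.
- AIC-based order selection overselects by design; prefer the reported
  SBC order for parsimony.
- Surrogate re-training makes significance testing expensive: cost scales
  linearly in `n_surrogates` times the training cost; the defaults
  (100 surrogates, 10 folds) are intended for real analyses, while the
  test suite runs reduced desk-scale configurations (documented in each
  test) to stay within CI budgets.
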