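---
title: "Whole-brain Stuart-Landau modelling and strength-dependent perturbation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-brain Stuart-Landau modelling and strength-dependent perturbation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`hopfwb` simulates whole-brain resting-state BOLD dynamics as a network of
coupled Stuart-Landau oscillators, the normal form of a supercritical Hopf
bifurcation. Each brain region (node) carries a complex state
$z_j = x_j + i y_j$ obeying

$$\dot z_j = (a_j + i\omega_j)\,z_j - (1 + i\beta)\,z_j |z_j|^2
  + G \sum_k C_{jk}(z_k - z_j) + \nu\,\eta_j(t) + F_j(t),$$

where the real part $x_j$ plays the role of the regional BOLD signal.

* **Bifurcation parameter $a_j$** selects the local regime. Strongly
  negative values give noise around a stable fixed point; values just below
  zero give the *fluctuating* (subcritical) regime in which noise excites
  transient oscillations; positive values give self-sustained oscillations
  (supercritical) with amplitude $\sqrt a$. The canonical regime values are
  $-1.3$ (noise), $-0.02$ (fluctuating), $+0.02$ (supercritical
  fluctuations) and $+1.3$ (oscillatory); see `regime_spec()`.
* **Shear (nonisochronicity) $\beta$** couples amplitude to frequency: on a
  cycle of radius $r$ the phase velocity is $\omega - \beta r^2$. Shear
  prevents full synchronization of coupled oscillators and plays the role
  viscosity plays in fluid turbulence; raising it suppresses amplitude
  turbulence.
* **Global coupling $G$** scales all pairwise structural couplings; the
  coupling is diffusive, $C_{jk}(z_k - z_j)$.
* **Intrinsic frequencies $\omega_j$** (rad/s) are taken from the data:
  each node's spectral peak inside the resting-state band, 0.008-0.08 Hz,
  averaged across subjects (`estimate_node_frequencies()`).
* **Noise SD $\nu$** defaults to 0.01, the value used across the Hopf
  whole-brain modelling literature; it is configurable.
* **Forcing $F_j(t) = F_{0j}(\cos\omega^f_j t + i \sin\omega^f_j t)$**
  emulates external stimulation (TMS/tACS-like). $F_{0j}$ is zero for
  untargeted nodes; $\omega^f_j$ defaults to the node's average intrinsic
  frequency.

## Connectome construction

The coupling matrix follows the exponential distance rule (EDR) with
optional long-range (LR) additions:
$C_{jk} = e^{-\lambda r_{jk}} + \mathrm{LR}_{jk}$, with
$\lambda = 0.18\,\mathrm{mm}^{-1}$ (the decay fitted on human cortical
connectivity) and $r_{jk}$ the Euclidean distance between region centroids.
Long-range entries are taken from a structural connectome (normalized to a
maximum of 0.2, `normalize_sc()`). Which entries count as "long-range" is a
pluggable rule (`add_long_range()`): the default keeps the top-$K$ positive
residuals over a log-linear exponential fit of the SC's own
distance-weight relation, i.e. connections stronger than the exponential
rule predicts; a plain distance threshold is also provided. The rule is
configurable because the extraction used upstream of this model is not
fully specified by its sources.

Two kernels must not be confused: the *dynamical* coupling
(`edr_coupling()`) has a zero diagonal (a node is not diffusively coupled
to itself), while the *measurement* kernel for local synchronization
(`edr_kernel()`) keeps the self-weight $e^0 = 1$ so a node's own phase
participates in its local order parameter.

## Numerical integration

Time stepping uses the stochastic Heun scheme: a trapezoidal (RK2)
correction of the drift with additive Gaussian increments shared between
the predictor and corrector stage. The obvious alternative, an explicit
Euler-Maruyama step at $\Delta t \approx 0.1$ s, is unstable in exactly the
regimes this model needs: in the oscillatory regime with large shear the
amplitude-dependent rotation $\omega - \beta r^2$ is fast, and the Euler
step diverges at $\beta = 2.2$ for $\Delta t = \mathrm{TR}/7$ and even at
$\mathrm{TR}/36$ for $\beta = 6$ (and where it survives it biases $|z|$ by
3-6%). Heun is stable at the default $\Delta t = \mathrm{TR}/16 = 0.045$ s
for every working point used here ($\beta$ up to 6) with under 1% amplitude
bias, and reproduces the analytic single-oscillator results
($|z| \to \sqrt a$, rotation rate $\omega - \beta a$) to high accuracy.
Long sweep protocols use $\mathrm{TR}/8$, verified stable for their two
working points. A divergence guard ($|z| > 10\max(1, \sqrt{\max(a, 0)})$)
aborts a run with an error of class `"hopfwb_divergence"` reporting the
offending volume and node; grid search flags such cells and excludes them
from the optimum rather than dropping them silently.

Noise is injected independently in the real and imaginary equations by
default (`shared_noise = FALSE`); the shared variant is available because
the continuous-time formulation is ambiguous on this point. The forcing
clock starts at the beginning of the simulation, and sustained forcing is
active during the discarded transient (20 volumes by default) so the
retained window is stationary.

## Observables

BOLD series are band-passed (0.008-0.08 Hz, zero-phase 2nd-order
Butterworth) and converted to phases via the analytic signal; 10 volumes
per side are trimmed against filter edge effects. From the phases:

* **Local Kuramoto order parameter** $R_n(t)$: modulus of the
  EDR-kernel-weighted mean of $e^{i\varphi_p(t)}$ around node $n$
  (`local_kuramoto()`).
* **Amplitude turbulence** $D$: the standard deviation of $R_n(t)$ pooled
  over nodes and time (`amplitude_turbulence()`).
* **Global order parameter** $gR(t)$ and **metastability** $M$, its SD over
  time -- the coarse-parcellation stand-in for turbulence, used when the
  parcellation is too coarse to resolve spatial synchronization structure.
* **Functional connectivity**: Pearson correlations of the filtered
  signals, compared to a reference FC by `fc_metrics()`: `eFC` (RMS
  difference of the upper triangles -- the raw Euclidean norm divided by
  the square root of the number of elements, which keeps values comparable
  across parcellation sizes; the raw norm is also reported), `corrFC`
  (Pearson of upper triangles), and `ssimFC` (a single global structural
  similarity index with the conventional stabilizing constants
  $K_1 = 0.01$, $K_2 = 0.03$, computed after rescaling both matrices
  jointly to $[0,1]$; windowed SSIM is out of scope).

Fitting errors are absolute differences: $e_D = |D_{sim} - D_{emp}|$,
$e_M = |M_{sim} - M_{emp}|$. When several subjects are available, the
empirical reference is computed per subject and averaged.

## Grid fitting and regime comparison

`hopf_fit()` explores a $(G, \beta)$ grid exhaustively for a fixed regime,
running `n_sims` simulations per cell matched in length and TR to the
reference data, and selects the cell minimizing $e_D$ (fine mode) or $e_M$
(coarse mode) -- never the FC error, which is reported alongside. Ties
break towards lower $G$, then lower $\beta$. All cells share one
per-simulation seed stream (common random numbers): enlarging a grid never
changes existing cells, and the argmin compares cells under identical noise
realizations, which matters because the error surfaces are shallow. With a
multi-subject reference, `omega_sampler` lets each fitting simulation draw
its own node frequencies from the generative law, keeping the simulated
observable distribution matched to the reference. The published exploration
ranges are available as presets (`grid_preset()`); the fine supercritical
preset uses a 0.01 coupling step, the only step consistent with its printed
range.

Identifiability at desk scale deserves honesty. In the subcritical regime
the shear parameter is quasi-degenerate: $D$, $M$ and FC change by about
$10^{-4}$ over $\beta \in [0, 1.6]$ (the shear term is $O(r^2)$ and
subcritical amplitudes are noise-level), so $\beta$ is recovered only
through a micro-gradient that common random numbers make consistent but
that a different reference realization can flip -- especially with the
true $\beta^* = 0$ at the domain edge. The coupling $G$ is identifiable
through the turbulence level, but a 10-subject reference pins the matching
point only to about $\pm 0.25$ in $G$. The packaged recovery experiment
therefore fits in fine ($e_D$) mode -- $D$ has roughly ten times less
sampling noise than $M$ here -- on a grid whose 0.4 step matches that
measured precision, and isolates the fitted parameters by simulating with
the generative node-mean frequencies and per-simulation frequency draws.

`compare_regimes()` quantifies how well fitted working points (and their
shear-inflated surrogates, `surrogate_model()`) reproduce the reference
observables: trial-level means are compared pairwise with two-sided
Wilcoxon rank-sum tests. Regimes share the per-(trial, sim) seed stream,
so identical working points give identical samples (and tied samples are
reported with $p = 1$ rather than an error).

A note on the shear surrogates: in these synthetic coarse-scale conditions
the turbulence-suppressing effect of raising $\beta$ is only measurable in
the oscillatory regime (where amplitudes are of order 1 and the
$\beta r^2$ term bites); at the subcritical working point amplitudes are
noise-level and the surrogate shifts $D$ by far less than the trial-level
noise. The surrogate analyses here therefore demonstrate the suppression on
the oscillatory working point with $\beta = 6$.

## Strength-dependent perturbation protocols

All protocols force with the additive periodic term above and read out
order-parameter changes against unperturbed reference runs *sharing the
same seed* (noise and initial conditions), a paired design that makes every
measure exactly zero at $F_0 = 0$:

* **Susceptibility** $\chi(F_0)$: mean over time, trials and (for the local
  observable) space of the perturbed-minus-unperturbed order parameter.
* **Information capability**: across-trial population SD of the per-trial
  mean differences (sample SD available), measuring how variably the
  stimulation is encoded; the absolute IC is referenced to zero forcing,
  which under the paired design equals the raw value.
* **Global protocol** (`run_global_protocol()`): all nodes forced,
  amplitudes 0 to 0.001 in steps of $10^{-4}$, repeated `reps` times
  (published counts: 50 trials x 50 sims x 20 repetitions; desk-scale
  defaults are far smaller). Each trial can draw its own node frequencies
  (`omega_sampler`), emulating subject-to-subject variability; the forcing
  stays at the node-average frequencies. With per-trial frequency draws the
  across-trial SD captures how differently detuned system instances encode
  the same stimulus.
* **Local protocol** (`run_local_protocol()`): homotopic node pairs forced
  one at a time (amplitudes up to 0.02; the step is 0.001 following the
  finer of the two published descriptions, with the coarser 0.005 step a
  preset choice), producing per-pair response surfaces and a perturbative
  node hierarchy ranked at a reference amplitude.
* **PCI** (`run_pci_protocol()`): non-sustained forcing, 600 volumes on
  then 200 off; the post-perturbation window is z-scored node-wise against
  the unperturbed ensemble's statistics (so "activation" means deviation
  from background), binarized at $z > 2$, flattened node-major, and scored
  by entropy-normalized Lempel-Ziv complexity
  $\bar c_L = c_L \log_2 L / (L\,H(L))$, which is calibrated to score about
  1 on i.i.d. fair-coin sequences and defined as 0 for constant sequences.
  The index is the background-corrected difference
  $\mathrm{PCI} = \bar c_L - \bar c_L^{back}$, with the background computed
  from the same unperturbed ensemble and the same window length.

Two behaviours of these measures in this package's synthetic conditions are
worth knowing. First, the regimes separate sharply in susceptibility: the
subcritical response rises monotonically with amplitude while the
oscillatory regime -- whose limit cycle cannot be entrained by weak forcing
detuned beyond its Arnold tongue -- is statistically unresponsive. Second,
the *absolute information capability* of the oscillatory regime has a
finite-sampling floor under the paired design: infinitesimal forcing fully
decorrelates a chaotic trajectory from its unperturbed partner over a long
run, so the across-trial SD cannot fall below the time-averaging
variability of $gR$, about $\sigma(T)/\sqrt{n_{sims}}$. The subcritical
regime's IC is governed by the same scaling (its long correlation time,
roughly 70 volumes versus 5 for the oscillatory regime, makes its
variability larger), so the IC *contrast* between regimes is bounded near
$\sqrt{\tau_{osc}/\tau_{sub}}$ regardless of how many trials or repetitions
are run. The susceptibility contrast, being mean-based, has no such floor.
A related saturation effect: in these conditions the subcritical IC rises
steeply at small amplitudes and then declines mildly once the system is
strongly entrained (by $F_0 \approx 6\times10^{-4}$ the susceptibility
already reaches $\sim$0.3), because a near-deterministic entrained response
varies less across trials; the IC-versus-amplitude curve is therefore
rise-then-plateau rather than strictly increasing.

The supplementary question of how the subcritical response depends on the
distance to the bifurcation is answered empirically: susceptibility is
computed over $a \in \{-0.02, -0.1, -0.3\}$ and the monotone ordering is
asserted, with the direction reported from the run rather than assumed,
because the source descriptions of this effect are contradictory.

## Network-level analyses

`rsn_modulation()` applies sustained forcing at a fixed amplitude
($F_0 = 0.01$) to homotopic pairs and reports the change in mean
within-network FC (mean over unordered within-network node pairs, excluding
self-pairs) for each of the seven canonical resting-state networks, with
rank-sum tests on the per-simulation samples. `network_specificity()`
normalizes the per-network difference profile by its maximum absolute
value and flags the top 15%. `strength_maps()` and
`hierarchy_correlations()` relate perturbative node hierarchies (e.g. the
node-level PCI from `pci_hierarchy()`) to structural and functional node
strength and to regional heterogeneity maps (T1w:T2w-like, transcriptomic
PC1-like), with Pearson correlation by default (Spearman available).

In the modular network-specificity experiment the within-network boost
(0.02) and coupling ($G = 0.6$) keep the system below synchronization
saturation; at stronger coupling FC is at ceiling and differences are
uninformative. In these conditions the stimulated network's FC gain is
reliably the largest, while off-network changes are noise-level with mixed
signs (a stronger, uniformly positive enhancement needs the larger
simulation counts of the full-scale protocol).

## The synthetic study

`synthetic_spec()` defines a fully synthetic study with known ground truth
so every stage is testable without downloads: N = 68 regions sampled on a
70 mm hemispheric shell and mirrored across the midline into exact
homotopic pairs; seven spatial k-means network labels shared within pairs;
EDR coupling at $\lambda = 0.18\,\mathrm{mm}^{-1}$ plus 40 random
long-range additions among top-distance-quartile pairs with weights in
$[0.1, 0.2]$; ground-truth regime $a = -0.02$ at $(G^*, \beta^*) = (2.2, 0)$
-- the coarse-scale fluctuating working point of the fitted model -- node
frequencies drawn per subject from a normal distribution with mean 0.05 Hz
and SD 0.005 Hz truncated to the analysis band; $\nu = 0.01$; TR = 0.72 s;
10 subjects of 400 volumes (desk scale; the published-scale run length is
1200 volumes, which the sweep protocols use).

What the generator emulates: hemispheric geometry with exact homotopy,
EDR-dominated coupling with sparse long-range shortcuts, band-limited
oscillatory BOLD with subject-varying node frequencies, and smooth
heterogeneity maps with controllable correlation to structural node
strength (a Gaussian-process draw over the node geometry with exponential
covariance, length scale 30 mm). What it does not emulate: hemodynamic
convolution and measurement noise spectra, head-motion artefacts,
non-exponential weight distributions of real tractography, subcortical
structures, and empirical inter-subject variability beyond the frequency
draws. Passing tests on this generator therefore validate the machinery
and the model's qualitative regime structure, not empirical claims about
real brains.

Problem sizes used in the tests and the acceptance script are the
generator defaults above with protocol counts of order 10 trials x 10
simulations (sweeps) and 10-20 trials elsewhere; the published-scale
counts (100 simulations per grid cell, 50x50 to 50x100 trial structures,
20 repetitions) are available as arguments and presets throughout.

## Degenerate inputs and numerical conventions

* Parcellations must have finite coordinates and a left/right label per
  node; homotopic pairing requires matched names and reports the offending
  regions otherwise. Odd node counts are an error.
* All coupling matrices are validated symmetric, nonnegative,
  zero-diagonal; all-zero structural matrices are rejected as degenerate.
* The band-pass rejects bands outside $(0, 1/(2\,\mathrm{TR}))$ and series
  too short for the filter order or the edge trim.
* A flat in-band spectrum (judged against the white-noise exceedance null,
  threshold $1 + (\log K + 3)/\sqrt S$ for $K$ bins pooled over $S$
  subjects) sends a node to the band-midpoint fallback with a warning.
* The local order parameter requires strictly positive row sums; row
  normalization happens in the weights, never in the phases.
* LZ76 input must be strictly binary; constant sequences score 0 by the
  $H = 0$ guard. Flattening order is node-major (node 1's full time
  course, then node 2's, ...), fixed and documented.
* Wilcoxon tests on fully tied samples report $p = 1$ instead of failing.
* All randomness flows from user-supplied integer seeds through
  `derive_seed()` (a Lehmer-style mixing step); protocols derive
  per-(cell/trial/sim) seeds so results are independent of execution order
  and stable under grid or protocol enlargement.

## Known limitations

* The shear-suppression contrast and the uniform RSN enhancement require
  full-scale simulation counts to reach significance in the subcritical
  regime; at desk scale they are demonstrated on the oscillatory working
  point and as network specificity, respectively.
* The absolute-IC regime contrast is floor-limited under the paired
  design, as analysed above.
* Amplitude turbulence on a 68-node parcellation lacks the spatial
  resolution it has at 1000 nodes; the coarse pipeline fits metastability
  instead, following the source methodology.
* The simulator outputs the oscillator's real part as "BOLD"; no
  hemodynamic forward model is applied (out of scope).
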