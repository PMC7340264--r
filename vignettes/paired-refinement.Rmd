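---
title: "Choosing a high-resolution cutoff by paired refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Choosing a high-resolution cutoff by paired refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xtalcut)
```

## The problem

Macromolecular diffraction intensities weaken with resolution until they
disappear into noise, and the data are conventionally truncated at a
cutoff chosen from data-quality indicators such as the shell
signal-to-noise ratio or the half-set correlation CC1/2. Those indicators
describe the *data* alone; they cannot say whether a weak shell still
improves the *model*. Paired refinement answers the model question
directly: refine the structure against data extended by one shell, then
compare the new and old models **against the same lower-resolution
data** — the only comparison in which their R values are on a common
footing. Shells that reduce the cross-validation residual Rfree carry
information; shells that raise it do not. `xtalcut` automates this
ladder, reports the full panel of monitoring statistics, and leaves the
final decision to the user: there is deliberately no decision-making
routine in the package.

## Statistics monitored

For a model with calculated amplitudes $|F_c|$ and observed amplitudes
$|F_o|$, the package reports, per shell and overall:

* $R = \sum\bigl||F_o| - k|F_c|\bigr| / \sum|F_o|$ on the work and free
  sets, with the scale $k = \sum|F_o||F_c| / \sum|F_c|^2$ fitted on the
  work set only and applied to both. A single overall scale is used —
  per-shell scaling would absorb exactly the signal the ladder monitors.
* $R_\mathrm{gap} = R_\mathrm{free} - R_\mathrm{work}$, the overfitting
  gap, computed for every step's model at the *starting* resolution so
  the curve is comparable across cutoffs.
* $\Delta R_\mathrm{work}, \Delta R_\mathrm{free}$ for each cutoff pair
  $X \to Y$, both models evaluated at $X$ with their own work-set scales.
* CCwork/CCfree: Pearson correlations between observed and calculated
  *intensities* (squared scaled amplitudes) per set.
* Merging statistics of the unmerged observations: multiplicity,
  completeness against the Friedel-unique sphere, mean $I/\sigma$,
  Rmerge, Rmeas (multiplicity-corrected), Rpim (precision of the merged
  mean), CC1/2 by seeded random half-sets, its one-sided Student
  significance at the 1:1000 level, and
  $CC^* = \sqrt{2\,CC_{1/2}/(1 + CC_{1/2})}$, the model-independent
  estimate of the correlation attainable against the true signal. A
  CCwork above CC* in a shell marks overfitting; an Rwork above 0.42 in a
  shell (the R value of a perfect model against random acentric data) is
  flagged in the report, again as an annotation rather than a filter.

## The ladder and complete cross-validation

`runLadder()` takes a model previously refined at the starting resolution
A and a vector of descending cutoffs. Each step refines at the next
cutoff — by default starting from the previous step's model, which
matches the stepwise narrative of the protocol; `restart = "fresh"`
restarts each cutoff from the input model as a sensitivity check — and
records the paired comparison at the previous cutoff, the agreement at A,
and the per-shell CC panel.

Because a model refined against one choice of free set remembers it,
`runCompleteCV()` repeats the whole ladder once per free-flag set
q = 0..k−1, erasing that memory beforehand by perturbing the coordinates
and resetting the atomic displacement parameters (ADPs), with a per-set
seed derived deterministically from the master seed
(`child = (master * 48271 + 1000003 * q) mod (2^31 - 1)`). Per step it
reports the mean, sample SD and SEM = SD/sqrt(k) of the monitored
differences and the counts of rises and falls of delta-Rfree across sets.

Two conventions were genuinely open and are fixed as follows: the ladder
is cumulative by default (each refinement continues from the previous
step's model), and the Rgap curve at A uses each step model's own
work-set scale at A rather than a re-refined scale.

## The toy refinement backend

Production refinement programs are external to this package; the backend
contract (`refineModel()`) only requires that free reflections never
enter the minimised target, that the result carry structure factors for
*all* reflections to the cutoff, and that output be deterministic. The
built-in toy engine implements the contract with an amplitude
least-squares target over a global scale (closed form each cycle), a
global ADP shift, and optionally all coordinates, minimised by
Levenberg–Marquardt (adaptive damping, default initial 1e-6; step
rejected unless the working residual decreases, so the residual trace is
non-increasing by construction; convergence declared below a relative
improvement of 1e-9). A singular normal matrix falls back to a
scale-and-ADP-only cycle and is noted in the result.

Scattering uses point atoms: $F_c(h) = \sum_j o_j Z_j
e^{-B_j/(4d_h^2)} e^{2\pi i\, h\cdot x_j}$, a constant electron count in
place of tabulated form factors. This is deliberately non-physical; it
keeps the calculation analytic and exactly linear in the atoms while
preserving every statistical property the ladder monitors. The target is
least squares rather than maximum likelihood for the same reason: a
closed-form scale, simple Jacobians, and enough realism to reproduce
overfitting and noise-shell phenomenology on synthetic data. There are no
geometry restraints, no bulk solvent, no anisotropic ADPs. An adapter for
external programs is provided
(`externalRefine()`, a validated command template with `{model_in}`,
`{hkl_in}`, `{d_cutoff}`, `{model_out}`, `{fc_out}` placeholders) and is
exercised in tests only through a mock.

## Synthetic data and the planted information limit

`generateData()` simulates at the intensity level (image simulation is
out of scope): true intensities $|F_c|^2$ from a ground-truth model on
the full Friedel-unique sphere in P1, `multiplicity` observations per
unique, and a planted information limit `dInfo`. Each observation is
$I = w I_\mathrm{true} + (1-w)J + \varepsilon$ with $w(d)$ equal to 1
down to `dInfo`, falling to 0 over a cosine ramp of width `transition`;
$J$ is exponential noise scaled to the shell mean intensity (so mean
$I/\sigma$ declines realistically with resolution) and $\varepsilon$ is
Gaussian with $\sigma = a|{\rm signal}| + b\langle I\rangle_{\rm shell}$.
Free flags are uniform over k = 20 sets by default (5% per set),
mirroring standard 20-fold cross-validation practice. Space-group
symmetry beyond Friedel pairing is deliberately absent — real data must
be pre-merged to the asymmetric unit — and completeness is therefore
defined against the Friedel-unique sphere.

Defaults: a 30 x 35 x 40 Angstrom P1 cell, 40 carbon-like atoms with B
uniform in 10–30 square Angstrom, data to 1.2 Angstrom at multiplicity 4,
a = 0.05, b = 0.10, dInfo = 1.5 Angstrom with a 0.05 Angstrom
transition. The degradation recipe for starting models
(`degradeModel()`) is a coordinate perturbation along isotropically
random directions with exponential magnitudes — the stated mean shift
fixes only the mean, and the exponential is the maximum-entropy choice
for a positive magnitude with fixed mean; its RMSD is then
$\sqrt 2 \times$ the mean shift — followed by an ADP reset to the mean
(or a stated value, e.g. 15 square Angstrom).

## The planted-limit recovery experiment

The headline property test generates data to 1.2 Angstrom with
dInfo = 1.5 Angstrom and asks whether the first ladder step with
delta-Rfree > 0 falls within one 0.05 Angstrom shell of the planted
limit in at least 8 of 10 master seeds. The experiment runs at a
desk-scale configuration chosen once for a realistic
parameter-to-observation ratio (~1:10, as in protein refinement): a
15 x 16 x 17 Angstrom cell with 60 atoms (~181 positional/ADP parameters
against ~1800 work reflections at the 1.65 Angstrom start), strong noise
(a = 0.2, b = 1.0) so the refined model is noise-limited rather than
data-exhausted, a sharp information cutoff (transition = 0), four
free-flag sets (a 25% test set, which keeps the free-set sampling noise
of each delta-Rfree well below the information signal), a 0.1 Angstrom
starting perturbation that stays inside the unrestrained engine's
convergence radius, and refinements run to convergence (cycle budgets
150/80). The degraded model keeps the true ADPs: the toy engine refines
only a global ADP shift, so a per-atom B error could never be repaired
and would permanently misfit exactly the high-resolution shells under
test. With a weakly perturbed, fully-converged model the paired
differences reflect the information content of each shell rather than
optimizer path effects. The larger default cell at a realistic parameter
ratio would need ~1000 atoms and is not a desk-scale experiment, which
is why the recovery test pins this smaller configuration explicitly.

## What passing tests do and do not show

The generator emulates resolution-dependent signal decay, counting-like
noise, multiplicity, and free-set structure. It does **not** emulate
geometry restraints, bulk solvent, anisotropy, radiation damage,
twinning, tNCS, or space-group symmetry — so a passing recovery test
shows the *protocol logic* is sound (matched-resolution comparison,
free-set hygiene, aggregation), not that any particular real data set
should be cut at a particular place. On real data the refinement engine,
restraints and solvent model dominate; the package's external-backend
contract exists for exactly that reason.

## Numerical conventions and degenerate inputs

* Resolution shells are half-open `[d_upper, d_lower)` in d; a reflection
  exactly at an interior edge belongs to the higher-resolution shell; the
  final edge is inclusive, matching `selectResolution()`'s `d >= cutoff`
  rule (boundary inclusivity is not specified by the protocol; inclusive
  was chosen and is tested).
* Uniques observed once are excluded from Rmerge/Rmeas/Rpim and CC1/2
  (the multiplicity corrections are undefined at n = 1) but count toward
  multiplicity and completeness.
* Negative merged intensities are retained in means and CC1/2 — clipping
  would bias weak shells — and amplitudes are `sqrt(max(I, 0))` when
  intensity data must be used as amplitudes (no French–Wilson treatment).
* CC values need at least three pairs and nonzero variance in both
  halves; undefined statistics propagate as NA, never as 0.
* Statistical tables are written at full precision with fixed formatting,
  so a rerun at the same seed is byte-identical.

## Known limitations

Point-atom scattering and the unrestrained least-squares target make
absolute R values optimistic relative to real refinements; the 0.42
random-data flag retains its interpretive role but the package does not
re-derive that constant (it depends on intensity-truncation conventions
for noise data that are out of scope, and the uncorrelated-amplitude
regime reproduced here sits near 0.55–0.59). MTZ and other binary
formats, space-group handling beyond Friedel reduction, anomalous
statistics, TLS and anisotropic ADPs are out of scope; text formats and
external converters stand in for them.
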