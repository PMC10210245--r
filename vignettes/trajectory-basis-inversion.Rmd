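---
title: "Inverting time-resolved scattering data in a trajectory basis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inverting time-resolved scattering data in a trajectory basis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The inverse problem

A pump-probe scattering experiment (ultrafast X-ray scattering, UXS, or
ultrafast electron diffraction, UED) measures a percent-difference signal
$\%\Delta I_{\mathrm{exp}}(q, t') = 100\,(I_{\mathrm{on}}/I_{\mathrm{off}} - 1)$
on a grid of momentum transfer $q$ and pump-probe delay $t'$. Recovering a
time-dependent molecular model from this signal is ill-posed: the data are
noisy, the temporal resolution is limited, and a rotationally averaged
gas-phase pattern retains only interatomic distances.

`tbfit` regularizes the inversion with dynamics. A set of $N_{\mathrm{TBF}}$
semiclassical trajectories from nonadiabatic molecular-dynamics
simulations (surface hopping, Ehrenfest, spawning methods — generated
upstream, supplied as multi-frame XYZ) serves as a basis of physically
admissible histories. The model is the basis with adjustable,
time-independent, nonnegative weights $w_n$, $\sum_n w_n = 1$: the fit
redistributes probability among simulated histories rather than inventing
structures, so continuity and the correct initial conditions are built in.

## Forward model

Within the independent atom model (IAM), the rotationally averaged elastic
intensity of a rigid geometry is the Debye sum

$$ I_{\mathrm{el}}(q) = \sum_{A}\sum_{B} f_A(q)\, f_B(q)\,
   \frac{\sin(q R_{AB})}{q R_{AB}}, $$

with the $A=B$ terms entering through the $\mathrm{sinc}\to 1$ limit (this
convention is what makes $I_{\mathrm{el}}(0^+) = (\sum_A Z_A)^2$ for
X-rays). The geometry-independent inelastic background is the incoherent
sum $\sum_A S_A(q)$. A trajectory contributes one such intensity per
frame; the weighted ensemble intensity is linear in $\mathbf{w}$.

Elastic X-ray form factors use the standard four-Gaussian Cromer-Mann
parameterization with embedded published coefficients for H, C, N, O and
S (accuracy at $q=0$: within 0.5% of $Z$). Electron form factors follow
the Mott-Bethe conversion $(Z_A - f_A(q))/q^2$; the $q \to 0$ singularity
is excluded by a hard cutoff (default $10^{-3}\,\mathrm{\AA}^{-1}$) rather
than regularized, because experimental s-grids never include zero and
silent regularization would hide configuration errors. Inelastic factors
are shipped as sampled tables with monotone cubic interpolation; the
embedded table is generated from
$S_A(q) = Z_A\,(1 - (f_A(q)/Z_A)^2)$, exact for one-electron atoms and
satisfying $S_A(0)=0$, $S_A \to Z_A$. Since the inelastic term is
geometry-independent it cancels in the numerator of the difference signal
and only weakly scales the denominator, so percent-difference fits are
insensitive to its absolute accuracy; any other tabulation can be
substituted per species. Probe prefactors (Thomson/Rutherford cross
sections, polarization, $s^{-4}$) are multiplicative in $q$ alone and
cancel exactly in the percent-difference form, so they are not applied.

## Apparatus mapping

The measured signal differs from the raw theory by instrument effects,
applied in this fixed order on the fine model time grid:

1. **Percent difference with excitation fraction.**
   $\%\Delta I_{\mathrm{mod}} = 100\,\gamma_{\mathrm{eff}}(q)\,
   (I_{\mathrm{mod}}/I_{\mathrm{off}} - 1)$, where $I_{\mathrm{off}}$
   comes from a reference geometry or an averaged ground-state ensemble.
   Only the excited fraction $\gamma$ of molecules deviates from the
   reference, so $\gamma$ scales the difference signal. For long
   interaction regions a sampled profile $\gamma(q)$ with a uniform scale
   factor $x$ replaces the scalar; only $x$ is optimized.
2. **Instrument response.** Each $q$ row is convolved with a unit-area
   Gaussian parameterized directly by its FWHM $\tau_c$ (the pump-probe
   cross-correlation plus jitter). The model is a $\delta$-pulse-excited
   difference signal, identically zero before excitation, so the leading
   edge is padded with zeros; the trailing edge holds the last value
   (difference signals are near-stationary at late delays). Convolution
   precedes binning — binning first would alias the response.
3. **Time zero and binning.** The experimental axis is
   $t' = t + t_0$ with $t_0$ a fitted global; the convolved model is
   box-averaged inside each experimental bin, the bin centered on the
   experimental time stamp (the only symmetric convention). A bin
   narrower than the model step falls back to linear interpolation at the
   bin center.

Whether the original analyses binned before or after convolving is not
something the data formats record; the order here is fixed and documented.

## Objective, optimization, two-step procedure

The fit minimizes the confidence-weighted squared misfit

$$ F(\mathbf{w}, \mathbf{c}) = \sum_{i j} p_{ij}
   \left[ \%\Delta I_{\mathrm{mod}}(q_i, t_j; \mathbf{w}, \mathbf{c})
        - \%\Delta I_{\mathrm{exp}}(q_i, t_j) \right]^2 $$

where $\mathbf{c} = (t_0, \tau_c, \gamma\ \mathrm{or}\ x)$ are global
parameters and $p_{ij} \in [0,1]$ is a confidence matrix. When per-point
standard deviations are available the surrogate $p \propto 1/\sigma$
(max-normalized, invalid points zeroed) is provided; any externally
computed matrix is accepted, and a threshold $p^{\min}_{\mathrm{conf}}$
zeroes low-confidence points outright. Because masking only removes
nonnegative terms, $F$ is monotone non-increasing in the threshold.

Weights are optimized from a pool of $N_{\mathrm{init}}$ Monte-Carlo
initial vectors (i.i.d. uniform, normalized) by bounded
Levenberg-Marquardt least squares on the residual vector
$\sqrt{p_{ij}}\,(\%\Delta I_{\mathrm{mod}} - \%\Delta I_{\mathrm{exp}})$,
with box constraints $w_i \in [0,1]$ and renormalization to the simplex
inside every model evaluation. This makes the objective scale-invariant
along rays, enforces $\sum w = 1$ exactly, and—because the mapped model
is linear in the normalized weights—reduces every residual and Jacobian
evaluation to products with a precomputed per-trajectory design matrix.
Converged candidates are ranked by $F$ with deterministic tie-breaks
(lower relative absolute error, then lower weight variance, then first
found). Global parameters are scanned on a grid (`scan_globals()`), the
best cell taken as the candidate global optimum.

For noisy data the two-step variant first integrates the signal over the
highest-confidence $q$ window and fits only $\gamma$ (closed form) for
each $(t_0, \tau_c)$ cell under an equal-weight model — defensible near
$t \approx t_0$ where the wavepacket has not yet dispersed. Because that
equal-weight approximation biases the step-one ranking (most strongly in
$t_0$), step two refits the weights with $\gamma$ freed for the best cell
of *each distinct* $t_0$, then for the remaining $\tau_c$ values at the
winning $t_0$, and keeps the lowest final $F$. A large relative drift of
$\gamma$ from its step-one value (default threshold 25%) flags
inconsistent globals.

Fit quality is reported as the relative absolute error (RAE: summed
absolute misfit of the optimized model over that of the uniform-weight
model; below 1 means the optimization helped), RMSE, the variance of the
weight vector, and the Euclidean distance $D_b$ to a reference solution
(conventionally plotted squared).

## The synthetic generator

Real trajectory ensembles and beam-time data cannot ship with a package,
so `tbfit` generates both. The toy system is a CS$_2$-like linear
triatomic whose two bond lengths follow analytic time courses:

- **bound** members: damped oscillations (period 50–120 fs, amplitude
  0.06–0.25 Å, damping 250–800 fs), each bond with its own phase so
  members mix symmetric and antisymmetric stretch character;
- **dissociative** members: one bond additionally ramps at a constant
  asymptotic speed (0.006–0.025 Å/fs) after an onset delay (30–400 fs);
- **all** members acquire a hot excited-state mean-bond elongation
  (0.08–0.18 Å, switched on over 30 fs). Photoexcited molecules are
  structurally displaced from the ground state; without this, a weakly
  displaced bound member would scatter like the reference and its weight
  would trade freely against $\gamma$ — the same artifact real fits show
  when the reference resembles part of the basis.

Per-member parameters are drawn stratified (Latin-hypercube style) from
these ranges, emulating generous, well-spread sampling of the dynamical
space; all members start at the shared equilibrium geometry. The two
qualitative motifs of the real signals appear: an oscillating
enhancement/depletion band at intermediate $q$ and a growing low-$q$ rise
upon dissociation.

The pseudo-experiment applies the full apparatus mapping at known
$(\mathbf{w}^*, t_0, \tau_c, \gamma)$ and adds heteroscedastic Gaussian
noise (Poisson photon statistics are out of scope). The reference fixture
used by the acceptance tests has 40 trajectories (10 bound, 30
dissociative), 8 active with a sparse weight pattern whose two bound
members total 28%, noise at 10% of the peak signal,
$t_0 = -60$ fs, $\tau_c = 40$ fs, $\gamma = 0.05$, $q \in [1, 8]$ Å$^{-1}$
in 0.025 Å$^{-1}$ steps and delays $-200$ to $1400$ fs in 10 fs steps.
These sizes are chosen to represent a well-posed modern measurement:
the IRF (40 fs, XFEL/MeV-UED grade) is shorter than the vibrational
periods it must resolve, the $q$ grid matches the fine azimuthal binning
detectors deliver, the lower $q$ bound reflects the beam stop, and the
delay window extends past every dissociation onset. Identifiability is a
property of the experiment design: widening the IRF beyond the
vibrational periods, coarsening the grids, or making basis members
near-duplicates degrades recovery long before the optimizer fails, which
users should expect with real data too. Passing tests on this fixture
demonstrate correct inversion machinery under honest noise; they do not
demonstrate that any particular real data set is as informative.

## Numerical choices and degenerate inputs

- Trajectories are aligned to the model grid by per-coordinate linear
  interpolation (propagator steps are fs-scale; the induced error is far
  below signal noise). Members ending early are held at their last frame
  by default (dissociative asymptotes), with a strict mode available.
- Duplicate or near-duplicate trajectories are permitted: the data cannot
  distinguish them, any weight split between them is reported as found,
  and the degeneracy shows up as near-zero curvature, not an error.
- The integrated step-one signal uses the trapezoidal rule on the
  experimental grid, with window endpoints off the grid included by
  linear interpolation.
- Solver tolerances default to $10^{-8}$ (function and step); all
  stochastic stages derive from one recorded integer seed.
- An all-zero confidence matrix is refused as a degenerate objective; a
  reference intensity that is not strictly positive is an error.

## Limitations

The IAM ignores electronic-state-specific and inelastic-coherent
scattering, so channels that differ mainly electronically (e.g. singlet
vs triplet products at early separation) are distinguished only through
their nuclear paths. Weights are time-independent; slow population
transfer not present in the basis cannot be represented. The $\gamma(q)$
profile is fixed up to a uniform scale. Multi-experiment joint fits are
accepted only through a fixed per-experiment regularization factor; no
automatic balancing is implemented.
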