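# tbfit

Forward-optimization inversion of time-resolved scattering data in a
trajectory basis.

## What it does

Ultrafast X-ray scattering (UXS) and electron diffraction (UED)
experiments record a pump-probe percent-difference signal
`%ΔI(q, t) = 100 (I_on/I_off − 1)` from photoexcited molecules.
Recovering the underlying structural dynamics from such data is an
ill-posed inverse problem. `tbfit` solves it by *forward optimization in
a trajectory basis*: a set of semiclassical trajectories from
nonadiabatic molecular-dynamics simulations is taken as a basis of
physically admissible histories, and nonnegative, time-independent
weights `w` (summing to 1) are fitted so that the predicted signal
matches the experiment. The dynamics supply the continuity constraints
that plain structure fitting lacks; the result identifies which
simulated motifs (e.g. ring-open vs ring-closed paths, singlet vs
triplet dissociation, bound vibration) the data actually support, and
with what fractions.

The forward model is rotationally averaged independent-atom-model
scattering (the Debye formula, X-ray or electron form factors), composed
with an apparatus mapping: excitation fraction `γ` (scalar or `γ(q)`
profile with a fitted uniform scale), Gaussian instrument-response
convolution of FWHM `τ_c`, time-zero shift `t0`, and temporal binning.
The objective is a confidence-weighted least-squares target

    F(w, c) = Σ_ij p_ij [ %ΔI_mod(q_i, t_j; w, c) − %ΔI_exp(q_i, t_j) ]²

minimized over Monte-Carlo-initialized, box-constrained
Levenberg-Marquardt runs, with grid scans over the globals `c` (one-step
mode) or a two-step procedure for noisy data (fit `t0`, `τ_c`, `γ` on
the q-integrated signal first, then refit weights with `γ` freed,
checking self-consistency). Fit quality is reported as the relative
absolute error (RAE < 1 means the optimized model beats the
uniform-weight theory), RMSE, weight variance, and distance to a
reference solution.

A synthetic-data module generates toy trajectory ensembles (a CS₂-like
linear triatomic with bound and dissociative members) and
pseudo-experiments with known ground truth, so the full pipeline is
testable end to end without any external data.

## Worked example

Generate the reference synthetic fixture (40 trajectories, 8 active,
10% peak-signal Gaussian noise) and invert it with the two-step
procedure:

```r
library(tbfit)

fx <- reference_fixture(seed = 42)         # ensemble + pseudo-experiment
pe <- fx$experiment
stack <- ensemble_signal_stack(fx$ensemble, pe$signal$q)

s1 <- step1_fit_globals(pe$signal, fx$ensemble,
                        global_params(t0 = 0, tau_c = 40, gamma = 0.05),
                        pe$reference, q_window = c(3, 6),
                        t0_grid = seq(-100, 0, by = 20),
                        tau_c_grid = c(20, 40, 60),
                        bin_width = 10, stack = stack)
s2 <- step2_fit_weights(pe$signal, pe$conf, fx$ensemble, pe$reference,
                        s1, optimization_config(n_init = 8, seed = 1),
                        n_candidates = 6, bin_width = 10, stack = stack)
print(s2$best)
score <- score_recovery(s2$best$best_weights, pe$truth, s2$best$best_params)
str(score[c("linf", "class_fraction_error", "t0_error", "gamma_rel_error")])
```

```
<tbf_fit: F = 411.902, 8/8 inits converged, best init 3>
<fit_report: F = 411.902, RAE = 0.9007, RMSE = 0.09542, Var_w = 0.005615>
  dominant trajectories (n = 8):
    toy012       dissociative    43.85%
    toy003       bound           18.48%
    toy007       bound            9.14%
    toy018       dissociative     8.50%
    toy023       dissociative     6.56%
    toy033       dissociative     3.91%
    toy029       dissociative     3.56%
    toy011       dissociative     1.48%
List of 4
 $ linf                : num 0.019
 $ class_fraction_error: Named num [1:2] 0.471 0.471
  ..- attr(*, "names")= chr [1:2] "bound" "dissociative"
 $ t0_error            : num 0
 $ gamma_rel_error     : num 0.00368
```

Eight trajectories dominate the recovered model; the ground truth behind
this fixture put 45.6% on `toy012` and 28.5% total on two bound members,
and the fit reproduces every individual weight to within 0.019 (`linf`),
the bound/dissociative split to 0.5 percentage points, the time zero
exactly on its 20 fs scan grid, and the excitation fraction to 0.4%.
`RAE = 0.90 < 1` quantifies the improvement over the unoptimized
equal-weight model at this noise level (10% of the peak signal).

Bookkeeping on the bundled example weight tables from published fits of
two photochemical systems:

```r
cs2 <- example_weight_table("cs2")
class_totals(cs2)                              # bound 28% of the total
branching_ratio(cs2, "singlet", "triplet")     # singlet : triplet = 1 : 3.37
chd <- example_weight_table("chd")
class_totals(chd, c(open = "open", closed = "closed"))  # 47.9 / 52.1
```

## Command line

A thin driver over the same functions ships in `inst/scripts/tbfit.R`:

```sh
Rscript inst/scripts/tbfit.R simulate --config run.yaml
Rscript inst/scripts/tbfit.R invert   --config run.yaml --seed 1
Rscript inst/scripts/tbfit.R metrics  --model m.tsv --theory th.tsv --exp e.tsv
```

The YAML config names the ensemble manifest, experiment/sigma matrices,
probe kind, mode (`one_step`/`two_step`), scan grids, confidence
threshold and seeds; every run writes a manifest (config hash, seed,
package version) sufficient to reproduce it.

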