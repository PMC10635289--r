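# crbsvd

Temporal subspace bases for quantitative MRI that preserve the Cramér–Rao
bound (CRB) of the biophysical parameters — not just the signal energy.

## The problem

Subspace (low-rank) reconstruction of transient-state qMRI data compresses
each voxel's temporal fingerprint `s ∈ C^{N_T}` to coefficients
`c = U's + ε` in an orthonormal basis `U ∈ C^{N_T×N_c}`. Parameters
`θ = (M0, R1, R2)` are then estimated from `c`, so the relevant precision
limit is the CRB *of the coefficients*. The classical basis — the first
`N_c` left singular vectors of a simulated dictionary `S` — maximizes
preserved signal energy `‖UU'S‖_F²` and can severely degrade that CRB at
small `N_c`.

This package implements CRB-aware basis design. With
`j_{i,⊥} = (I − P_{J_i}) j_i` the orthogonalized derivative of the signal
(the component of `∂s/∂θ_i` orthogonal to all other parameters'
derivatives), three bounds are available per parameter:

* uncompressed `B_u = σ²/‖j_{i,⊥}‖²`,
* exact compressed `B_ec` (same formula on `U'J`),
* approximate compressed `B_ac = σ²/‖U'j_{i,⊥}‖²`,

with `B_u ≤ B_ac ≤ B_ec` always. The **CRB-SVD basis** is the SVD of the
concatenation

```
D = [ (1−λ)·S , λ·J_⊥ ],   λ ∈ [0, 1]
```

where `J_⊥` stacks the unit-normalized orthogonalized derivatives of the
parameters of interest for every dictionary fingerprint. `λ = 0` recovers
the traditional SVD; moderate `λ` (0.3–0.5) buys large reductions in the
exact compressed CRB loss `ΔB_ec = Σ(1 − B_u/B_ec)` for a small signal
fidelity cost. The ratio `R = mean(B_ac/B_ec) ≤ 1` certifies near-optimality
of the result.

Included building blocks: an analytic inversion-recovery/decay toy model, a
deterministic isochromat-ensemble FISP fingerprinting simulator with
finite-difference Jacobians, dictionary simulation/augmentation/splitting,
dictionary-matching and Levenberg–Marquardt NLLS estimators, a Monte-Carlo
bias/variance harness, and a minimal Cartesian subspace reconstruction demo
(unitary DFT, conjugate-gradient normal equations, voxel-wise matching).

## Worked example

Sweep basis quality over the CRB weighting `λ` and subspace size `N_c` for
a small FISP dictionary (200-pulse train, T1 500–1400 ms, T2 20–120 ms),
with a 67/33 train/test split:

```r
library(crbsvd)

model <- fisp_model(fisp_spec(flip_train = default_flip_train(200),
                              n_isochromats = 32))
grid  <- parameter_grid(t1 = c(500, 100, 1400), t2 = c(20, 20, 120))
sweep_report(model, grid, lambdas = c(0, 0.3, 0.6), n_cs = c(3, 5), seed = 1)
#> # A tibble: 6 × 8
#>   lambda   n_c signal_energy_loss delta_b_ac delta_b_ec mean_loss_ac ...
#> 1    0       3          0.00102        3.45       3.58       0.0862
#> 2    0       5          0.0000206      0.236      0.236      0.00589
#> 3    0.3     3          0.00194        3.08       3.18       0.0769
#> 4    0.3     5          0.0000307      0.210      0.211      0.00525
#> 5    0.6     3          0.00907        2.88       2.99       0.0721
#> 6    0.6     5          0.000138       0.206      0.206      0.00515
```

Reading the table: at `N_c = 3`, moving from `λ = 0` to `λ = 0.6` lowers the
held-out exact CRB loss `delta_b_ec` from 3.58 to 2.99 (the average per
fingerprint-parameter pair, `mean_loss_ec`, from 0.089 to 0.075) while the
signal energy loss grows only from 0.10% to 0.91%. `autoplot()` on the
returned tibble draws the λ-sweep panels.

Building one basis directly:

```r
dict  <- simulate_dictionary(model, grid)
parts <- split_train_test(dict, 0.67, seed = 1)
jacs  <- lapply(seq_len(n_fingerprints(parts$train)), function(i)
  model_jacobian(model, parameter_vector(r1 = parts$train$theta$r1[i],
                                         r2 = parts$train$theta$r2[i])))
basis <- crb_svd(parts$train, build_ortho_set(jacs), lambda = 0.3, n_c = 3)
basis
#> <subspace_basis>  200 time points x 3 components, lambda = 0.3
glance(basis)
#> # A tibble: 1 × 4
#>     n_t   n_c lambda captured_energy
#> 1   200     3    0.3           0.985
```

`monte_carlo()` then quantifies estimator bias/std under a basis against
the `√B_u` and `√B_ec` references, and `cg_subspace_recon()` + `fit_maps()`
run the imaging demo.

## Command line

A thin pipeline wrapper is installed with the package:

```sh
crbsub=$(Rscript -e 'cat(system.file("cli", "crbsub", package = "crbsvd"))')
Rscript "$crbsub" simulate-dict --config cfg.yaml --out dict.rds
Rscript "$crbsub" basis --config cfg.yaml --dict dict.rds --lambda 0.5 --nc 5 --out basis.rds
Rscript "$crbsub" sweep --config cfg.yaml --out sweep.csv
```

See `vignette("crb-svd-methods")` for the model, the noise convention, all
tunable parameters and the package's design decisions.
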