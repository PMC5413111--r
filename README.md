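# popinfo

How much of the stimulus information encoded by a noisy neural population
survives transmission through a noisy, possibly spiking, downstream circuit?
`popinfo` implements the framework for answering that question with **linear
Fisher information**: for a population with tuning curves `f(s)` and noise
covariance `Σ_ξ(s)`, relayed as `y = g(Wx + ζ) + η`,

    I_x(s) = f'(s)ᵀ Σ_ξ⁻¹ f'(s)
    I_y(s) = f'(s)ᵀ [Σ_ξ + (W_effᵀ Σ_eff,η⁻¹ W_eff)⁻¹]⁻¹ f'(s)

the package asks how the *structure* of `Σ_ξ` — at fixed `I_x` — controls the
surviving output information `I_y`. It is aimed at computational
neuroscientists studying noise correlations and population coding.

Core results it operationalizes:

* **Differential correlations** `Σ_ξ ∝ f'f'ᵀ` minimize encoded information
  among trace-constrained covariances, yet maximize robustness to downstream
  noise regardless of the downstream circuit.
* For linear gains, the *entire family*
  `Σ_ξ = (α I_η / I_x) Σ_y + ((1-α)/I_x) f'f'ᵀ` is maximally robust: every
  member transmits exactly `I_y = I_x / (1 + I_x/I_η)`.
* Redundancy is neither necessary nor sufficient for robustness: equally
  informative redundant codes can differ sharply in robustness, and
  synergistic codes can be maximally robust.

The package provides heterogeneous Von Mises tuning populations, the
structured covariance constructors (Poisson-like base, tilted rank-one
perturbations with information matching, the optimal family), analytic
information formulas, a dichotomized-Gaussian spiking layer with Monte Carlo
information estimation, and seeded experiment pipelines returning tidy
tibbles with ggplot helpers.

## Worked example

Two codes with identical tuning curves and identical input information, but
noise concentrated along the signal direction (`aligned`) versus tilted 1/8
radian away (`tilted`), pushed through an identity-weight linear channel with
iid output noise of variance `sigma2`:

```r
res <- run_noise_sweep(n = 50, n_stimuli = 20, sigma2_grid = c(0, 0.1, 1, 10),
                       match_correlations = FALSE, seed = 2)
res
#> # A tibble: 8 × 8
#>   population sigma2   I_y   I_x I_shuffled  fano avg_corr eps_u_mean
#>   <chr>       <dbl> <dbl> <dbl>      <dbl> <dbl>    <dbl>      <dbl>
#> 1 aligned       0    420.  420.       711.  1.02 0.000296    0.001
#> 2 aligned       0.1  416.  420.       711.  1.02 0.000296    0.001
#> 3 aligned       1    392.  420.       711.  1.02 0.000296    0.001
#> 4 aligned      10    278.  420.       711.  1.02 0.000296    0.001
#> 5 tilted        0    420.  420.       701.  1.02 0.000637    0.00127
#> 6 tilted        0.1  404.  420.       701.  1.02 0.000637    0.00127
#> 7 tilted        1    369.  420.       701.  1.02 0.000637    0.00127
#> 8 tilted       10    262.  420.       701.  1.02 0.000637    0.00127
plot_noise_sweep(res)
```

Reading the numbers: both codes start from the same input information
(`I_x ≈ 420 rad⁻²`, transmitted losslessly at `sigma2 = 0`), both are
redundant (`I_shuffled > I_x`: removing correlations would *increase*
information), and both have Poisson-like variability (Fano factors ≈ 1).
Yet at output noise `sigma2 = 1` the aligned code still carries 392 rad⁻²
while the tilted one has dropped to 369 — information content alone does not
determine robustness.

The optimal-family invariance, checked numerically:

```r
verify_optimal_family(n = 25, sigma_y = "random", seed = 3)
#> # A tibble: 5 × 5
#>   alpha admissible    I_x   I_y I_y_bound
#>   <dbl> <lgl>       <dbl> <dbl>     <dbl>
#> 1  0    TRUE       17454. 8727.     8727.
#> 2  0.25 TRUE       17454. 8727.     8727.
#> 3  0.5  TRUE       17454. 8727.     8727.
#> 4  0.75 TRUE       17454. 8727.     8727.
#> 5  1    TRUE       17454. 8727.     8727.
```

Every admissible `alpha` — from pure differential correlations (`alpha = 0`)
to the matched covariance (`alpha = 1`) — transmits exactly the bound
`I_x / (1 + I_x/I_η)`.

Spiking transmission (`run_dg_sweep()`) estimates output information through
a dichotomized-Gaussian layer by Monte Carlo; with the noise aligned to the
signal direction (`theta_u = 0`), information increases monotonically with
the rank-one strength `eps_u`, while a small tilt (`theta_u = 0.1`) makes it
fall off. A thin command-line wrapper lives in `inst/cli/popinfo.R`:

```sh
Rscript inst/cli/popinfo.R run dg --seed 1 --profile test --out runs/dg
```

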