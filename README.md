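# sddsgd

Step-wise dual dynamic differentially private SGD (SDD-DPSGD) for
class-imbalanced classification, with Rényi-DP accounting and budget
calibration.

## The problem

Differentially private SGD (DP-SGD) clips every per-sample gradient to an
L2 norm bound *C* and adds Gaussian noise with standard deviation *σC* to
the clipped gradient sum. On severely imbalanced data — the motivating case
is dermoscopic lesion classification, where one benign class holds roughly
two thirds of the samples and several diagnostic classes are few-shot — a
*static* (σ, C) pair faces a dilemma: a large fixed C drowns the fragile
minority-class gradients in early-stage noise, while a small fixed C clips
them away. Either way, the privacy mechanism acts as a regularizer that
disproportionately penalizes underrepresented classes.

## The method

SDD-DPSGD divides the `T` training iterations into stages whose durations
grow geometrically while both schedule dials move geometrically:

- stage durations: `D_i = D_0 · λ^i`, with dynamics factor `λ = 1/γ > 1`;
- noise multiplier: `σ_i = σ_0 · β^{-i}` (grows when `β < 1`);
- clipping threshold: `C_i = C_0 · a^i` (decays when `a < 1`).

The first stage is deliberately long, low-noise and high-threshold, so
minority gradients pass through unclipped while the model learns
foundational features. The number of stages is not free: requiring the
first stage to cover at least a fraction `ρ` of the budget (the
*protection horizon*) gives

```
n = ⌊ log_λ( 1 + (λ − 1)/ρ ) ⌋,
```

e.g. `n = 3` at `λ = 1.1, ρ = 0.3`. Uniform privacy expenditure — each
stage contributing equally to the RDP cost proxy `D_i/σ_i²` — holds exactly
at `β = √γ`; `β` slightly below that (0.8 at `γ = 0.9`) is a conservative
margin. Because the effective injected noise variance is
`V_i = (σ_i C_i)² = V_0 (a/β)^{2i}`, choosing `a < β` makes the absolute
noise power *decay* even though the multiplier grows.

Privacy is tracked with a Rényi-DP accountant: each step of the Gaussian
mechanism costs `α/(2σ²)` at order `α` (an optional Poisson-subsampled
integer-order bound is provided), costs compose additively, and the total
converts to `(ε, δ)`-DP via `ε = min_α [ rdp(α) + log(1/δ)/(α − 1) ]`.
`calibrate_sigma0()` bisects on `σ_0` so a full run consumes a target
budget exactly.

## Worked example

```r
library(sddsgd)

# the headline schedule: lambda = 1.1, beta = 0.8, a = 0.6, rho = 0.3
cfg <- schedule_config(2000, lambda = 1.1, beta = 0.8, a = 0.6,
                       rho = 0.3, sigma0 = 1, c0 = 5)
tab <- stage_table(cfg)
print(tab)
#> Dual dynamic schedule: T = 2000 iterations, 3 stages (lambda = 1.1, beta = 0.8, a = 0.6)
#>   stage duration  sigma clip cumulative_start
#> 1     0      604 1.0000  5.0                0
#> 2     1      665 1.2500  3.0              604
#> 3     2      731 1.5625  1.8             1269
print(schedule_stats(tab))
#> Schedule statistics:
#>   sigma0            1
#>   weighted mean     1.28872
#>   weighted variance 0.0530692
#>   D0 fraction       0.302
```

The first stage holds 30.2% of the budget (≥ ρ = 0.3), the noise
multiplier grows by 1/β = 1.25 per stage, and the injected noise variance
shrinks by (a/β)² = 0.5625 per stage.

```r
# calibrate sigma0 so the run consumes epsilon = 3 at delta = 1e-3,
# then compare against static DPSGD at the same budget
cal <- calibrate_sigma0(3, delta = 1e-3, cfg, q = 128 / 2800)
cal$sigma0
#> [1] 49.63916

cmp <- run_comparison(
  ham10000_like_preset(n_samples = 3500, seed = 20260924),
  algorithms = c("sdd", "static"), eps_targets = 3, seeds = 1:5,
  schedule = cfg, delta = 1e-3, learning_rate = 0.1, batch_size = 128
)
cmp$aggregate[, c("algo", "accuracy", "mcc", "few_shot_accuracy")]
#>    algo accuracy    mcc few_shot_accuracy
#>     sdd   0.7509 0.5366            0.2927
#>  static   0.7364 0.5095            0.2656
```

At matched ε = 3 the dual schedule yields higher MCC and better few-shot
group accuracy than the static baseline on the synthetic imbalanced
benchmark — the ordering the method predicts.

A command-line front end with subcommands `schedule`, `account`,
`calibrate`, `simulate`, `train` and `compare` is installed at
`inst/cli/sddsgd` (run it with `Rscript`).

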