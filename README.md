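# syndfe

Forward simulation and site-frequency-spectrum (SFS) inference for
studying how purifying selection on **synonymous** mutations biases
demographic inference and, downstream, the inferred distribution of
fitness effects (DFE) of **nonsynonymous** mutations.

Standard DFE inference assumes synonymous variants are neutral: a
demographic model (here one-epoch, or two-epoch with size ratio ν and
time T in units of 2N<sub>a</sub> generations) is fitted to the
synonymous SFS by maximizing the Poisson random field composite
likelihood

LL = Σ<sub>i</sub> [ x<sub>i</sub> log m<sub>i</sub> − m<sub>i</sub> − log x<sub>i</sub>! ],

where the expected spectrum at equilibrium is

E[X<sub>i</sub>] = θ ∫ C(n,i) x<sup>i</sup>(1−x)<sup>n−i</sup>
(1−e<sup>−2γ(1−x)</sup>) / ((1−e<sup>−2γ</sup>) x(1−x)) dx,
  γ = 2N<sub>a</sub>s<sub>het</sub>, θ = 4N<sub>a</sub>μL,

and non-equilibrium expectations come from a finite-volume solution of
the forward Kolmogorov equation. Conditional on the fitted demography, a
gamma DFE over deleterious γ is fitted to the nonsynonymous SFS
(shape a, scale in 2N<sub>a</sub>s units; s<sub>dhet</sub> = γ/2N<sub>a</sub>).
The package pairs this inference stack with a diploid Wright–Fisher
forward simulator (exon/intron mosaic, NS:S opportunity 2.31:1, gamma
nonsynonymous DFE with shape 0.186 and 2Ns-scale 706.899, configurable
selection on synonymous mutations, recombination, multi-deme
demographies, rescaling) so that the inference can be run against data
whose truth is known. When synonymous mutations are in fact deleterious,
their SFS is skewed towards rare variants; the demographic stage explains
the skew as a false recent expansion, and the conditioned DFE estimates
deform — unless the DFE fit is conditioned on a demography estimated
from truly neutral variants (`neutral_swap()`), which restores recovery.

## Worked example

```r
library(syndfe)
library(dplyr)

# neutral-synonymous control vs pervasive weak selection (s = 1e-4),
# at the package's desk scale (Q = 10, 2 Mb coding, 5 replicates)
ctrl <- run_scenario(scenario("control"), seed = 101)
sel  <- run_scenario(
  scenario("constant_1e-4",
           syn_model = selection_model("constant", s = 1e-4)),
  seed = 202)

bind_rows(ctrl, sel) |>
  group_by(scenario) |>
  summarise(two_epoch = mean(model == "two_epoch"),
            delta_ll_median = median(delta_ll),
            nu_median = median(nu, na.rm = TRUE),
            shape_mean = mean(shape))
#> # A tibble: 2 × 5
#>   scenario      two_epoch delta_ll_median nu_median shape_mean
#>   <chr>             <dbl>           <dbl>     <dbl>      <dbl>
#> 1 constant_1e-4       1             36.8       2.83     0.0782
#> 2 control             0.2            1.88      1.22     0.215
```

The control chooses the constant-size model in most replicates (the odd
small inferred expansion is the classic footprint of linked selection),
with the DFE shape recovered near its generating value of 0.186. Under
pervasive weak selection on synonymous mutations every replicate is
called a ~3-fold population expansion with overwhelming likelihood
support (median ΔLL ≈ 37 against a threshold of 3) even though the
population size never changed, and the conditioned DFE shape collapses
to ~0.08. Re-fitting
those same nonsynonymous spectra conditioned on the control replicates'
demography brings the estimates back:

```r
rescued <- neutral_swap(sel, ctrl)
summarise(rescued, standard = mean(shape), rescued = mean(swap_shape))
#> # A tibble: 1 × 2
#>   standard rescued
#>      <dbl>   <dbl>
#> 1   0.0782   0.191
```

`report_results()` writes the result table, per-replicate spectra in
"fs" text format, and the standard figures (inferred-size trajectories,
shape/scale scatter, discretized-DFE bars, π/π₀ boxplots).

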