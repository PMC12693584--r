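---
title: "Selection on synonymous variants and SFS-based inference: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection on synonymous variants and SFS-based inference: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question

Standard inference of the distribution of fitness effects (DFE) of
nonsynonymous mutations from polymorphism data proceeds in two stages:
a demographic model is fitted to the site-frequency spectrum (SFS) of a
putatively neutral class — conventionally synonymous variants — and,
conditional on that demography, a gamma DFE is fitted to the
nonsynonymous SFS. The neutrality of synonymous sites is an assumption,
not a fact. `syndfe` provides a controlled laboratory for the question:
if synonymous mutations are themselves weakly deleterious, what happens
to the demographic estimates, and downstream, to the nonsynonymous DFE?

The package contains both halves of that laboratory:

* a forward Wright–Fisher simulator with linked selection that generates
  data under known selection on synonymous mutations, and
* a Poisson random field inference stack (expected spectra under one- and
  two-epoch demographies with genic selection, composite-likelihood
  fitting, gamma-DFE inference conditioned on a fitted demography).

Running the two against each other reproduces a clean mechanistic story:
purifying selection on synonymous variants skews their SFS towards rare
alleles; the demographic stage, which assumes neutrality, explains the
skew as a recent population expansion; the DFE stage, conditioned on this
false expansion, misattributes low-frequency nonsynonymous variation and
inflates the apparent proportions of neutral and strongly deleterious
mutations. Conditioning the DFE fit on a demography estimated from truly
neutral variants removes the bias.

# Simulation model

`simulate_population()` is a discrete-generation diploid Wright–Fisher
simulator. Each generation: parents are sampled with probability
proportional to fitness (multiplicative across sites: heterozygote
$1-s/2$, homozygote $1-s$; dominance is additive and only $h=0.5$ is
supported); each transmitted gamete is a recombinant mosaic of the
parent's two haplotypes with a Poisson number of crossovers ($r$ per bp);
new mutations arrive as a Poisson stream with rate $2N\mu L_\text{exonic}$
placed uniformly on exonic positions under an infinite-sites convention
(occupied positions are re-drawn). Fixed mutations are purged
periodically and logged as substitutions; the purge interval (default
500 generations) is memory hygiene only and affects no statistic.

The genome is an exon/intron mosaic from `generate_layout()`. Exon and
intron lengths are exponential with means 300 bp and 4,200 bp — chosen
so that the exonic fraction is 1.4 Mb in 21 Mb, i.e. one part coding to
fourteen parts spacer; empirical length tables can be supplied instead.
Intronic positions carry no tracked mutations (a neutral mutation in a
spacer would alter no analyzed statistic) but contribute recombinational
distance, so linkage between selected sites — hence background
selection — is represented.

Two mutation classes arise in exons at a 2.31:1 nonsynonymous:synonymous
opportunity ratio. Nonsynonymous effects are gamma-distributed with shape
0.186 and scale 706.899 on the $2Ns$ scale (mean homozygous $s \approx
0.013$ at $N = 10{,}000$). Synonymous effects follow the scenario:
neutral; constant $s \in \{10^{-5}, 10^{-4}, 10^{-3}\}$; "partial" (22%
selected at those values); or a gamma DFE (shape 0.14, $2Ns$-scale 55)
for the human-like design. Gamma draws are clamped at $s = 1$; a
homozygote for such a mutation simply has fitness zero.

`rescale(config, Q)` applies standard population-genetic rescaling
($N/Q$, $Q\mu$, $Qr$, $Qs$, generations$/Q$), which preserves all
population-scaled compounds and therefore per-site diversity and SFS
shape. Constant coefficients with $sQ \ge 1$ are refused.

A multi-deme mode (piecewise-constant sizes, split events, per-epoch
migration) supports an out-of-Africa-style history; the shipped
configuration `inst/extdata/ooa_gutenkunst_approx.yaml` encodes the
classic four-deme structure with rounded literature-style values and
growth discretized into stepwise epochs. Its parameter values are
deliberately labelled approximate; it is exercised at toy scale in the
test suite, and full 800 Mb runs are cluster-scale usage, not part of
the default checks.

# Expected spectra and the diffusion solver

The inference side needs $E[X_i]$, the expected number of sites at
derived count $i$ in a sample of $n$ haplotypes. At mutation–selection–
drift equilibrium the Poisson random field closed form is

$$E[X_i] = \theta \int_0^1 \binom{n}{i} x^i (1-x)^{n-i}
  \frac{1 - e^{-2\gamma(1-x)}}{(1-e^{-2\gamma})\,x(1-x)}\,dx,$$

with $\gamma = 2N_a s_\text{het}$ (negative when deleterious) and
$\theta = 4 N_a \mu L$; the neutral limit is $\theta/i$, and $\pi$ of the
expected spectrum equals $\theta$. `expected_sfs_equilibrium()`
integrates this bin by bin with adaptive quadrature, using an
asymptotic-safe form of the selection factor that is stable to
$|\gamma| \approx 2000$.

Non-equilibrium expectations (`expected_sfs_two_epoch()`) come from a
finite-volume discretization of the forward Kolmogorov equation for the
frequency density $\phi(x,\tau)$, written in flux form with effective
drift $\gamma x(1-x) - (1-2x)/2\nu$ and diffusion $x(1-x)/2\nu$ (time in
units of $2N_a$ generations). Numerical choices that matter:

* **Grid.** Cell centres on $(0,1)$ crowded towards both boundaries by a
  tanh warp (`sfs_grid()`, default 800 cells, crowding 8), because the
  density behaves like $1/x$ near the origin and the singleton bin draws
  much of its mass from that region. With the defaults the discrete
  stationary spectrum matches the closed form to better than $10^{-3}$
  per polymorphic bin at $n = 100$ for $\gamma \in \{0,-1,-10,-100\}$.
* **Fluxes.** Scharfetter–Gummel exponential fitting, which remains
  positive and accurate at large cell Péclet numbers (strong selection)
  and whose discrete stationary state is solved exactly by one
  tridiagonal solve — the transient integration therefore starts from the
  *discrete* ancestral equilibrium and is exactly stationary when
  $\nu = 1$.
* **Boundaries.** One-way absorbing fluxes at both ends (loss and
  fixation leave the polymorphic density); mutational influx enters the
  first interior cell at a rate calibrated once per grid so that the
  discrete neutral equilibrium obeys $\pi = \theta$ exactly.
* **Time stepping.** Implicit Euler with a geometrically growing step
  ($5\times10^{-4}$ growing by 8% per step, capped at
  $\max(2\times10^{-3}, T/100)$) and early exit at stationarity. Against
  a near-exact fine-step reference the transient error is below 0.2% per
  bin — smaller than the Monte-Carlo error of the coalescent cross-check
  in the test suite.

An independent neutral two-epoch coalescent simulator
(`coalescent_sfs()`) ships purely as a cross-validation oracle: it shares
no code with the diffusion solver.

# Fitting

`poisson_loglik()` treats polymorphic bins as independent Poisson counts;
monomorphic bins are always masked. $\theta$ is profiled analytically
(the maximizing multiplier is $\sum x_i / \sum m_i$), removing one
dimension from every optimization.

`fit_demography()` fits the one-epoch model in closed form and the
two-epoch model ($\nu$, $T$) by box-constrained quasi-Newton optimization
in log-parameter space from 25 random log-uniform starts (the default).
Bounds are $\nu \in [10^{-4}, 3000]$ and $T \in [10^{-4}, 500]$ — wide
enough to allow biologically absurd expansions, which is intentional:
estimates pinned at a bound (`at_bounds`) are themselves a diagnostic of
model misspecification, and the $\nu$ upper bound corresponds to
$\theta_s \sim 1.5$, an ancestral size of a few individuals. The open
lower ends replace the degenerate $\nu = 0$, $T = 0$. A fit is recorded
as converged when the two best starts agree to $10^{-4}$ relative
log-likelihood — an automated stand-in for by-eye inspection of fit
quality. A `method = "grid"` mode scans a cached lattice of two-epoch
spectra and polishes from the best cell with a single local
optimization. The scenario pipeline and the likelihood-ratio
calibration use this mode: the scan visits the whole bounded surface —
at least as thorough as any practical number of random restarts — at a
small fraction of the cost.

`select_model_lrt()` prefers the two-epoch model when
$\Delta LL > 3$, i.e. $2\Delta LL$ exceeding the 95th percentile of
$\chi^2_2$ (5.99) to the precision quoted. One caveat worth knowing: the
constant-size null is not an interior point of the two-epoch space but a
ridge ($\nu = 1$ at any $T$, and small-$T$ limits), so the asymptotic
$\chi^2_2$ approximation is not exact. `lrt_calibration()` measures the
realized false-positive rate on Poisson-noise neutral spectra: at the
package's study condition ($n = 100$, $\theta_s \approx 540$) it sits at
the nominal ~5%, while at ten-fold larger $\theta$ the rule becomes
conservative (~2%). Either way the rule never over-calls expansions,
which is the direction that matters for the study's conclusions.

`fit_dfe()` maximizes the same composite likelihood over the gamma DFE
(shape, scale in $2N_a s$ units), mixing cached expected spectra over a
log-spaced grid of 81 values of $|\gamma|$ spanning $[10^{-4}, 2000]$
plus the neutral endpoint (`build_gamma_cache()`). Gamma mass below the
smallest grid point is assigned the neutral spectrum; mass above the
largest is assigned the top spectrum, whose polymorphic contribution is
negligible — which is also why the strongly deleterious tail is weakly
identified by polymorphism data. Halving the grid density changes the
mixture by under 0.2% per bin. $\theta_{ns}$ is not re-fitted: it is
fixed at $2.31\,\hat\theta_s$, the mutational-opportunity multiple of the
synonymous estimate, matching the convention of the standard tooling.
Conversions use $\hat N_a = \hat\theta_s / (4\mu L_s)$ and
$s_\text{dhet} = \gamma / 2N_a$. `discretize_dfe()` reports bin masses
on $[0,10^{-5}), [10^{-5},10^{-4}), [10^{-4},10^{-3}),
[10^{-3},10^{-2}), [10^{-2},\infty)$ by exact gamma-CDF differences; a
10,000-draw Monte-Carlo mode exists for parity with draw-based
reporting, but the CDF is the default because it is exact.

# The desk-scale study and what it can show

`scenario()` / `run_scenario()` wire the two halves together. The
package-default scale is a deliberate desk-scale rendering of the
full design, fixed a priori from a power calculation on closed-form
spectra rather than tuned on outcomes:

* rescaling $Q = 10$: 1,000 diploids, 10,000-generation burn-in
  (ten times the rescaled population size), 100 further generations;
* 2 chunks of 1 Mb coding sequence per replicate (2 Mb coding,
  $\theta_s \approx 360$), 5 replicates per condition, sample of 100
  haplotypes.

At this size the weakest pervasive selection condition
($s = 10^{-4}$, $\gamma \approx -1$) carries an expected two-epoch
log-likelihood advantage near 50 — more than an order of magnitude above
the decision threshold of 3 — so the qualitative contrasts (control
mostly one-epoch; pervasive selection always "expanding"; bound-hitting
under $s = 10^{-3}$; rescue by the neutral swap) are decisively powered.
What desk scale does *not* deliver is the full-scale precision of the
DFE point estimates: with 20-fold less sequence than a 30 Mb replicate,
single-replicate estimates wander along the well-known shape–scale
likelihood ridge, and only averages across replicates are meaningful.
The tests therefore assert directions and confidence-interval overlap
for DFE parameters, and exact behaviour only for the decisively powered
demographic contrasts.

Simulated data differ from real data in ways that bound what passing
tests show: a single pair of mutation classes with known ancestral
states and error-free genotypes; no mutation-rate or recombination-rate
heterogeneity, gene conversion, hotspots, or beneficial mutations; and
an exactly gamma nonsynonymous DFE, so the inference model is correctly
specified up to linkage and the synonymous-selection violation under
study.

```{r}
library(syndfe)
library(dplyr)

ctrl <- run_scenario(scenario("control"), seed = 101)
sel  <- run_scenario(
  scenario("constant_1e-4",
           syn_model = selection_model("constant", s = 1e-4)),
  seed = 202)

bind_rows(ctrl, sel) |>
  group_by(scenario) |>
  summarise(two_epoch = mean(model == "two_epoch"),
            nu_median = median(nu, na.rm = TRUE),
            shape_mean = mean(shape))

rescued <- neutral_swap(sel, ctrl)
report_results(bind_rows(ctrl, sel), "results")
```

# Known limitations

* The simulator copies full haplotypes every generation; it is engineered
  for the desk-scale study (minutes per condition), not for tree-sequence
  scale genomics.
* Only marginal (single-deme) spectra are produced and consumed; joint
  multi-population inference is out of scope.
* Only deleterious gamma DFEs are modelled — no beneficial mass, no
  alternative DFE families — matching the inference convention under
  study.
* The human-like demographic configuration is an approximate stand-in
  and should be replaced via `read_sim_config()` when exact parameter
  values matter.
* Folded spectra are carried by the container but the study-facing
  analyses are unfolded-only.
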