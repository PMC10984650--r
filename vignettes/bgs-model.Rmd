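---
title: "Quantitative-genetic background selection: model, maps and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative-genetic background selection: model, maps and inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgsmap)
```

## The model

Purifying selection against recurrent deleterious mutations in conserved
genomic segments perturbs linked neutral variation. `bgsmap` models this
through the quantitative-genetic view of linked selection: heritable fitness
variance $V_A$ inflates the stochastic variance of allele-frequency change,
so a neutral allele experiences a *fitness-effective* population size
$N_f < N$. Because perturbations from a linked fitness background are
autocorrelated across generations until the background recombines off or is
removed by selection, the cumulative effect of $V_A$ is inflated by
$$Q = 1 + \sum_{t \ge 1} \left[(1-r)(1-\kappa)\right]^t
    = \frac{1}{\kappa + r(1-\kappa)},$$
where $r$ is the recombination fraction to the fitness-variance block and
$\kappa$ the per-generation decay rate of the associated variance
(`q_flank()`).

For a conserved segment of $L$ bp with per-bp deleterious mutation rate
$\mu$ (diploid segment rate $U = 2\mu L$), heterozygous cost $s$ (homozygous
$2s$, multiplicative across sites) and internal map length $M$ Morgans, the
package jointly solves (`solve_equilibrium()`):

* the fitness-effective-size equation $N_f = N\exp(-V_A Q^2/2)$,
* the substitution-rate equation $R = 4 N_f U_h s / (e^{4 N_f s} - 1)$
  with $U_h = \mu L$, and
* the fitness-variance equation $V_A = (U - 2R)s$,

with the within-segment inflation factor
$Q^2 = 2/[(1-Z)(2 - (2-M)Z)]$ and retention factor $Z = 1 - s - M$
(`q2_segment()`). The solution $(\tilde N_f, \tilde R, \tilde V_A)$ is an
equilibrium of the mutation–selection–drift process. Substitutions drain
fitness variance: when selection is strong ($2Ns \gg 1$) no deleterious
allele fixes, $\tilde V_A = Us$, and the model collapses exactly onto the
classic background-selection model; when selection is weak, $\tilde R$
approaches the neutral rate $\mu L$ and $\tilde V_A \to 0$ smoothly, which
is what lets the model fit weakly constrained annotation classes that break
classic-BGS-based inference.

### Rate conventions

Printed forms of the substitution-rate and variance equations differ in
whether the segment mutation rate is counted per haploid ($\mu L$) or per
diploid ($2 \mu L$) genome. We resolve the system so that the three
equations are mutually consistent: $R$ entering $V_A=(U-2R)s$ is on the
haploid scale (neutral limit $\mu L$, the standard neutral substitution
rate), making $V_A$ non-negative and continuous for every $s \ge 0$. All
reported substitution rates are *fractions of the neutral rate*
($\tilde R/\mu L$), which is invariant to the ploidy convention.

### Drift dissipation in the within-segment solver

The closed-form retention factor $Z = 1-s-M$ ignores that genetic drift
also dissolves the association between an allele and its fitness
background, at rate $\approx 1/(2N)$ per generation. Without that term the
within-segment $Q^2$ grows like $1/s^2$ as $s \to 0$ and the predicted
reduction does not vanish at neutrality. The solver therefore uses
$Z = 1 - s - M - 1/(2N)$, which caps $Q$ near $2N$ (an association cannot
outlive the coalescent timescale). The term is negligible whenever
$2Ns \gg 1$, so it leaves the classic strong-selection limit untouched; at
desk scale it is what makes the predicted $B$ match the package's own
Wright–Fisher simulations in the $2Ns \le 1$ domain (see below).

## Reduction maps

`compute_bprime()` tabulates, for every evaluation position $x$ (fixed
10 kb step by default, left edges) and every cell of a log10-spaced grid
of selection coefficients ($10^{-8} \le s \le 10^{-2}$ by default,
$10^{-1}$ on the strong grid) and mutation rates
($10^{-11} \le m \le 10^{-7}$),
$$\log B(x; m_i, s_j, k) = -\tfrac12 \sum_{g \in k}
   \tilde V_{A,g}(m_i, s_j)\, Q^2\!\big(s_j, r_{x,g}\big),$$
with one tensor layer per feature class $k$ so that a DFE can later mix
classes. `compute_classic_b()` produces the same layout with the
mutation–selection-balance variance $U s$ (the classic model; independent
of $N$). Design choices that matter:

* **Flanking decay rate.** The flank $Q$ uses $\kappa = s_j$, which makes
  classic BGS an exact special case whenever $\tilde R = 0$. A consequence
  is that at *exactly* $r = 0$ the flank kernel lacks the drift floor, so
  quasi-neutral grid cells would predict spurious reductions for a position
  exactly at a segment midpoint; real evaluation positions sit at $r > 0$
  where the effect is negligible ($\propto (s/r)^2$). A `kappa_flank`
  switch provides the drift-extended kernel for sensitivity analyses and
  for generating data from the physically wider kernel.
* **Recombination fractions** are Haldane-transformed map distances from
  the position to the segment midpoint ($r = \tfrac12(1 - e^{-2d})$,
  capped at $1/2$); segments longer than $10^{-3}$ Morgans are split first
  so the single-$r$ approximation stays accurate.
* **Unlinked segments** (other chromosomes) contribute at $r = 1/2$
  exactly — the genome-wide fitness-variance effect is retained, never
  dropped; a configurable floor only removes contributions below
  $10^{-10}$ in $|\log B|$.
* Maps are stored and combined in log space, so disjoint segment sets
  combine additively (multiplicativity of $B$) by construction.

`local_rescale()` re-solves every segment's equilibrium with $N$ replaced
by $\hat B(x_g) N$ (the fitted reduction at the segment, averaged over a
configurable window, 1 kb by default) — an approximation to
selective (Hill–Robertson) interference. It is exactly a no-op when
$\hat B \equiv 1$ and leaves strong-selection cells unchanged, because
$\tilde R$ underflows to zero at either population size.

## Composite-likelihood inference

Diversity data enter as windowed pairwise-difference counts: per window
$b$, $Y_b$ differing comparisons out of $n_b$ (built from per-site allele
counts by `windowed_diversity()`; megabase windows by default). The model
is $Y_b \sim \text{Binomial}(n_b, \pi_0 \bar B(b; \mu, \mathbf W))$
treated as independent across windows (a composite likelihood), with free
parameters: baseline diversity $\pi_0$, a single global deleterious rate
$\mu$ (bounded above by $8\times 10^{-8}$), and a DFE matrix $\mathbf W$
whose columns (one per feature class) are probability simplexes over the
selection grid.

Because the precomputed tensors are, per layer, smooth in the mutation
rate, $\log B(x; \mu, \mathbf W)$ is evaluated at arbitrary
$w = \mu\mathbf W$ by interpolating each $(s_j, k)$ layer between the two
bracketing mutation-rate grid columns and summing (`logB_mix()`). The
default rule interpolates $\log(-\log B)$ linearly in $\log_{10} m$: since
$\log B$ is exactly proportional to $m$ in the strong-selection regime,
this rule is exact there, whereas interpolating $\log B$ itself carries an
$O(\Delta^2)$ convexity error on a log-spaced grid (the linear rule remains
available via `interp = "linear"`). Both rules return grid nodes
bit-for-bit.

`fit_mle()` maximises the composite likelihood with BOBYQA (a bounded
derivative-free quadratic-model method), parameterising DFE columns by
softmax logits and $\mu$ by $\log_{10}\mu$. Two details stabilise the
optimisation considerably: $\pi_0$ is profiled out analytically at every
objective evaluation (Newton on the one-dimensional binomial score), which
removes the scale coupling between $\pi_0$ and the map amplitude; and the
seeded random (Dirichlet) multi-starts are augmented with one
deterministic point-mass start per selection class, which places at least
one start in each basin of the strongly multimodal DFE surface. The spread
of the best optima across starts is reported as a stability diagnostic.

Model assessment follows standard practice for this model class:
in-sample $R^2$ on window diversity, leave-one-chromosome-out
$R^2_{\mathrm{LOCO}}$ (`loco_r2()`), block-jackknife standard errors over
10 Mbp blocks with the $(g-1)/g$ scaling (`block_jackknife()`), and a
coalescent-noise ceiling $R^2_{\mathrm{coal}}$ (`r2_coal()`) that
approximates the largest explainable variance given irreducible
genealogical noise. The ceiling uses the classic pairwise-diversity
sampling variance $a_1\theta + b_1\theta^2$ for a linked block with the
window-specific scaled size $\bar B(b) N$, attenuated by an approximate
number of independent genealogical blocks per window
($1 + 4N_b M_w$, with $M_w$ the window map length); windows are treated
as equally weighted throughout (an `n_b`-weighted variant is a
configuration flag away, but megabase windows are near-equal in content).

Substitution rates are predicted per feature class by re-solving the
equilibria at a fixed pedigree-scale mutation rate
($\mu = 1.5\times10^{-8}$ by default, since linked-selection estimates of
$\mu$ carry bias) and mixing $\tilde R/R_{\text{neutral}}$ over the fitted
DFE (`predict_substitution()`); `implied_divergence()` converts the
fraction to per-bp divergence over a 6–12 Mya range at a 28-year
generation time.

## The ground-truth engines

### Wright–Fisher forward simulator

`wf_forward()` simulates a diploid Wright–Fisher population with
multiplicative purifying selection in a single region: Poisson mutation
at uniform continuous positions (infinite sites), fitness
$(1-s)^{\#\text{het}} (1-2s)^{\#\text{hom}}$ truncated at zero, fitness-
proportional parent sampling, Poisson crossovers, and an interleaved
neutral-site tracer from which $B_{\text{obs}} =
\hat\pi / (4N\mu_{\text{neutral}})$ is measured. Fixations are counted
after a 10 N-generation burn-in, over a further 10 N generations of
sampling with censuses every 25 generations; the additive genic variance
is accumulated as $\sum_l 2p_l(1-p_l)s^2$. Every mutation reconciles to
segregating, lost, or fixed. The inner loop draws from a xoshiro256+
stream seeded from R's RNG, so results are reproducible under
`set.seed()` while keeping 100-replicate parameter sweeps on a single
core practical.

Desk-scale defaults are $N = 500$, $L = 50$ kb, $r_{\text{bp}} = 10^{-8}$
(the canonical human genome-wide average), neutral tracer rate
$5\times10^{-8}$, and 100 replicates per parameter cell — chosen so a full
validation grid over $\mu \in \{10^{-8}, 10^{-7}\}$ and
$2Ns \in \{0.2, 2, 20\}$ runs in minutes on one core, while the
coalescent-noise CI on mean $B_{\text{obs}}$ is a few percent: wide enough
to be honest, tight enough to separate the classic and quantitative-genetic
predictions in the weak-selection domain. `validate_theory()` tabulates
observed versus predicted $B$, substitution-rate fraction, and $V_A$ per
cell with CI-inclusion flags.

What these simulations do *not* emulate: dominance ($h \ne 1/2$),
epistasis, back mutation at substituted sites, non-equilibrium demography,
and multi-segment genomes (interference between segments therefore enters
only through the single region's own dynamics). Passing the validation
grid shows the single-segment equilibrium theory is accurate at these
scales; it does not certify genome-wide behaviour under strong
interference, which the genome-scale phenomenon of locally reduced
efficacy (`local_rescale()`) only approximates.

### Synthetic genomes

`synth_genome()` lays out non-overlapping conserved segments (800 per
20 Mb chromosome, 0.5–2 kb long, ~5% of sequence — a density comparable to
conserved annotation in mammalian genomes) on a piecewise-constant
recombination map (log-normal rates around 1 cM/Mb, 2 Mb pieces), computes
the true reduction map under a configured $(\pi_0, \mu, \mathbf W, N)$,
and draws $Y_b \sim \text{Binomial}(n_b, \pi_0\bar B(b))$ with $n_b$ from
25 sampled diploids. Defaults follow the validation design: five
chromosomes, $\pi_0 = 10^{-3}$, $\mu = 1.5\times10^{-8}$, $N = 1000$, a
point-mass DFE. The layout seed is separate from the sampling seed so
noise can be re-drawn on a fixed genome. An optional Gamma multiplier on
the window probability (mean 1, shape $\nu$) mimics genealogical
variance; the binomial default isolates estimator behaviour from
coalescent noise, which makes recovery tests sharp but also makes the
data *exactly* a draw from the fitted model family — a caveat that
matters when studying misspecified fits (see the next paragraph).

Because the generator's standard truth maps use the same flank kernel
($\kappa = s$) as the classic model, a classic-BGS fit to weak-selection
truth can mimic the generating map's spatial shape exactly and fail only
through its amplitude — recovering the selection coefficient while
deflating $\hat\mu$ by the substitution factor $1 - \tilde R/(\mu L)$.
Data from the *true* process (forward simulations) instead have the wider,
drift-floored kernel, which is what additionally drives the classic fit
toward spuriously strong selection. The generator exposes this via
`truth_kernel = "physical"`, which builds the truth map with the
drift-extended kernel; the misspecification experiments use it.

## Numerical choices

* All $e^x - 1$ terms use `expm1`; exponents are computed and stored in
  log space; the substitution rate has explicit underflow branches (never
  NaN).
* The equilibrium solver is a damped fixed-point iteration on $N_f$ with a
  guaranteed bracketed-bisection fallback (after substitution the map is
  monotone, so the root is unique); tolerance $10^{-8}$ relative on
  $N_f/N$, 500 iterations before fallback.
* Degenerate inputs: $s = 0$ segments return the neutral solution
  directly; $Z \ge 1$ or a non-positive $Q^2$ denominator raise errors
  naming the offending $(U, s, M)$; empty segment sets give $B \equiv 1$.
* Ties and edges: evaluation positions are left edges; windows are
  0-based half-open tiles; a window with no accessible positions is
  flagged rather than silently dropped.
* BOBYQA runs with `rhobeg = 0.5` on the transformed scale and
  `rhoend = 10^{-8}`; the best optimum is polished with a small trust
  region. Fits are deterministic given `seed`.

## Problem sizes used in the test-suite experiments

The packaged validation experiments are sized for a single core: the
simulator grid uses $N = 500$, $L = 50$ kb, 100 replicates per cell; the
recovery experiment uses the five-chromosome synthetic genome above with
megabase windows (100 windows). These are the package's desk-scale
renditions of the corresponding chromosome-scale experiments; the same
functions scale to larger designs by changing the configuration objects.

## Known limitations

* The equilibrium theory is least accurate in the nearly neutral domain
  ($2Ns \approx 1$) under high mutational input, where linkage
  disequilibria build up and the model over-predicts the reduction even
  with the drift term; local rescaling absorbs part, not all, of this
  error. The package reports the discrepancy rather than hiding it: see
  `validate_theory()`'s CI-inclusion flags.
* A single global $\mu$ is shared by all feature classes; per-class rates
  are intentionally excluded (they are unidentifiable against track
  composition through the compound $\mu L$).
* The DFE is a discrete simplex on the selection grid; continuous
  parametric families are out of scope.
* $R^2_{\mathrm{coal}}$ uses an approximate independent-blocks variance
  model; it is a ballpark ceiling, not an estimator with guarantees.
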