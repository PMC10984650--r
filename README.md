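# bgsmap

Quantitative-genetic background selection: equilibrium theory, genome-wide
diversity-reduction maps (B′), and composite-likelihood inference of the
distribution of fitness effects (DFE) and deleterious mutation rate from
windowed nucleotide diversity.

## The problem

Purifying selection against recurrent deleterious mutations in conserved
genomic segments reduces linked neutral diversity ("background selection").
Classic BGS theory assumes mutations are deleterious enough that they never
fix; it therefore mispredicts diversity — and badly biases parameter
estimates — wherever selection is weak (2*Ns* ≲ 1). `bgsmap` implements the
quantitative-genetic alternative: heritable fitness variance *V*<sub>A</sub>
inflates the variance of stochastic allele-frequency change, giving a
*fitness-effective* population size

&nbsp;&nbsp;&nbsp;&nbsp;*N*<sub>f</sub> = *N* exp(−*V*<sub>A</sub>*Q*²/2),&nbsp;&nbsp;
*Q* = 1/(κ + *r*(1−κ)),

coupled with the deleterious substitution rate
*R* = 4*N*<sub>f</sub>*U*s/(e^(4*N*<sub>f</sub>s) − 1) and the equilibrium
variance *V*<sub>A</sub> = (*U* − 2*R*)*s*, solved jointly per conserved
segment. Classic BGS is the exact special case *R* = 0. The per-position
reduction *B*(x) = *N*<sub>f</sub>/*N* is tabulated over grids of selection
coefficients and mutation rates (the **B′ maps**), and a binomial composite
likelihood over genomic windows, π̄(b) = π₀·B̄(b; μ, **W**), is maximised
with BOBYQA over (π₀, μ, softmax-parameterised DFE columns **W**) — one DFE
per annotation class. The package also predicts per-class deleterious
substitution rates (as fractions of the neutral rate) and the divergence
they imply, and ships its own ground-truth engines: a Wright–Fisher forward
simulator of multiplicative purifying selection and a synthetic-genome
generator, used by the test suite to validate theory and inference end to
end. See the methods vignette (`vignettes/bgs-model.Rmd`) for the model,
conventions and design choices.

## Worked example

Generate a synthetic genome with a known truth, build the B′ maps, and
recover the parameters:

```r
library(bgsmap)

cf  <- synth_config(n_chroms = 3, chrom_length = 1e7, n_segments = 400)
sim <- synth_genome(cf, seed = 5)          # truth: pi0 = 1e-3, mu = 1.5e-8,
                                           # DFE point mass at s = 1e-2
bm  <- compute_bprime(sim$segments, sim$recmap, population_context(cf$N),
                      grid_axes(), chrom_lengths = sim$chrom_lengths)
fit <- fit_mle(likelihood_data(bm, sim$windows), n_starts = 12, seed = 7)

c(pi0 = fit$mle$pi0, mu = fit$mle$mu, sbar = unname(fit$sbar), r2 = fit$r2)
#>          pi0           mu         sbar           r2
#> 1.000022e-03 1.499172e-08 9.996991e-03 9.985905e-01
```

The fit recovers the baseline diversity π₀ (here to 0.0002%), the
deleterious mutation rate μ (1.50 × 10⁻⁸ against a truth of 1.5 × 10⁻⁸),
and places the DFE mass on the true selection coefficient (mean selection
coefficient 0.0100), explaining ≈ 99.9% of window-level diversity variance
in this noise-free-truth design. Substitution rates for the fitted DFE at a
fixed pedigree-scale mutation rate:

```r
predict_substitution(fit$mle$W, s_values = grid_axes()$s_values,
                     segments = sim$segments,
                     pop = population_context(cf$N),
                     mu_fixed = 1.5e-8, classes = "conserved")
#>    conserved
#> 0.0002547261
```

— about 0.03% of the neutral rate: mutations with s = 10⁻² cannot fix at this population
size, so the predicted divergence in such segments is far below the
neutral expectation.

To validate the theory itself against forward simulation:

```r
cells <- data.frame(N = 500, L = 5e4, mu = 1e-7, s = c(2e-4, 2e-2))
validate_theory(cells, replicates = 20, seed = 1)[, c(
  "two_Ns", "B_obs", "B_pred", "B_classic", "R_frac_obs", "R_frac_pred")]
```

which tabulates the observed diversity reduction, substitution rate and
fitness variance against the equilibrium predictions (and against classic
BGS, which fails in the 2*Ns* = 0.2 row).

## Command line

A thin front-end over the same functions lives at `inst/cli/bgsmap.R`
(stages `synth`, `bmap`, `fit`, `predict-sub`, `simulate`; YAML config;
`--preset paper-default` or `paper-strong-grid`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/bgsmap.R", package="bgsmap"))')" \
    synth --out out/ --seed 3
```
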