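# hellbayes

Robust **and** efficient parameter estimation by combining the minimum
Hellinger distance functional with Bayesian nonparametric density
estimation.

## The problem

Likelihood inference for a parametric family `f_θ` is efficient when the
model is right and badly non-robust when a few observations are gross
errors.  Minimum Hellinger distance estimation keeps both properties: define

```
T(g) = argmin_θ h(f_θ, g),     h²(f, g) = ∫ (√f − √g)² = 2 − 2∫√(fg),
```

the map sending any density `g` to the parameter of its Hellinger-closest
family member.  Evaluated at a consistent density estimate, `T` ignores
outliers (a distant contamination spike barely changes the affinity
`∫√(f_θ g)`) yet attains the Cramér–Rao bound `I(θ₀)⁻¹` at the model.

`hellbayes` builds the density estimate with Bayesian nonparametrics and
provides:

* **MHB** — `mhb()`: apply `T` to the *expected posterior density*
  `g*ₙ = ∫ g π(dg | Xₙ)`.  A robust, asymptotically efficient point
  estimator.
* **BMH** — `bmh()`: push posterior density draws `g ~ π(g | Xₙ)` through
  `T`, yielding a posterior `π(θ | Xₙ) = π(T(g) | Xₙ)`.  A
  Bernstein–von-Mises property holds: the posterior is asymptotically
  normal with variance `I(θ₀)⁻¹/n`, so its standard deviations double as
  honest standard errors — while remaining robust to gross errors.

Two density priors are included: a conjugate **random histogram prior**
(Dirichlet weights on `k` equal bins, optionally a prior on `k`) and a
**Dirichlet-process mixture of normals** (1-D and 2-D) with conjugate
normal–inverse-Wishart base and collapsed Gibbs sampling.  Supporting
machinery: Fisher information and efficient influence functions with the
identity `‖T̃‖²_L = I(θ)⁻¹`, Bernstein–von-Mises diagnostics
(`bvm_diagnostic()`), and a gross-error contamination model with
robustness curves (`robustness_curve()`).

## Worked example

66 measurements, 64 from `N(27.75, 5.08²)` plus two gross negative
outliers at −44 and −2 (a synthetic stand-in for the classical light-speed
data):

```r
library(hellbayes)

x   <- gen_newcomb_like(seed = 4)
fam <- family_normal1d()

post  <- fit_histogram_posterior(x, k_prior_dirac(100),
                                 alpha = function(k) rep(1 / k, k))
gstar <- expected_posterior_density(post)
grid  <- make_grid(gstar$support, breakpoints = gstar$breakpoints)

mhb(x, fam, gstar, grid)
#> <tresult> family normal1d
#>   theta_hat: mu = 28.734, sigma = 4.6514
#>   hellinger = 0.350533 (affinity 0.938563), 2 local optimum/a from 3 starts

draws <- sample_posterior_density(post, 300, seed = 5)
tp <- bmh(x, fam, draws, grid)
tp
#> <theta_posterior> family normal1d, 300 converged draws (0 failed)
#>               mu   sigma
#> eap     28.79600 4.41950
#> post_sd  0.53686 0.24827

round(fam$mle(x), 2)           # contaminated MLE: pulled down, inflated
#> [1] 27.31 10.71
round(fam$mle(x[x > 0]), 2)    # after removing outliers by hand
#> [1] 28.88  4.80
```

The two outliers move the MLE by 1.5 units and double its scale estimate;
MHB and the BMH posterior mean sit on top of the outlier-free answer with
no manual cleaning.  `bvm_diagnostic(tp, fam, n = length(x))` compares the
posterior sds with `sqrt(diag(I(θ̂)⁻¹)/n)`; at this small `n` the σ
coordinate runs about 35% under the asymptotic scale and the diagnostic
says so (`sd_ratio` 0.99 / 0.65, verdict `fail`) — the asymptotic regime
has not fully set in at `n = 66`.

The headline 2-D benchmark — 100 points, 90 from a bivariate normal and
two 5-point contamination clusters, DP-mixture posterior pushed through
`T` for the bivariate normal family — is packaged as `bivariate_demo(seed)`.

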