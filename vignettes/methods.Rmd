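---
title: "Summary statistics imputation: model, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary statistics imputation: model, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zimpute)
```

## The model

A GWAS regresses a standardized continuous phenotype on each standardized
genotype separately; the per-variant statistic is $a_k = g_k' y / N$ and
$z_k = a_k\sqrt{N}$. Across a region the vector of Z-statistics is
approximately multivariate normal with correlation matrix equal to the
genotype (LD) correlation matrix. The statistic of an untyped variant $u$
is therefore estimated by the conditional mean given the typed tags $M$:

$$\hat z_u = c' C^{-1} z_M,$$

with $C = \mathrm{Cor}(g_M)$ and $c = \mathrm{Cor}(g_u, g_M)$ estimated
from an external reference panel of $n$ individuals. Key assumptions: (i)
the trait is independent of $g_u$ conditional on the tags (the imputation
is performed under the null for the target, so truly causal untyped
variants are attenuated rather than inflated); (ii) the panel's LD matches
the GWAS population's LD; (iii) effects are small, so the normal
approximation holds. Assumption (ii) is the binding one in practice — LD
estimated from a few thousand individuals has sampling noise of roughly
$1/\sqrt{n}$ per entry, which is why shrinkage is not optional.

## Shrinkage

$C_\lambda = (1-\lambda)C + \lambda I$ and $c_\lambda = (1-\lambda)c$.
$\lambda \in [0,1]$ interpolates between the raw panel estimate and
independence; any $\lambda > 0$ makes $C_\lambda$ positive definite when
$C$ is a valid correlation matrix. The default is the widely used fixed
$\lambda = 0.1$; the panel-size rule $\lambda = 2/\sqrt n$ and explicit
values are selectable (`choose_lambda()`). Linear systems are solved by
Cholesky factorization, never explicit inversion; if factorization fails
(only possible at $\lambda \approx 0$ with duplicated tags) the code falls
back to a pseudo-inverse with a warning rather than stopping, because
degenerate duplicate columns are data conditions, not programming errors.

## Imputation quality

$r^2_{\mathrm{pred}} = c_\lambda' C_\lambda^{-1} c_\lambda$ is the
variance of the target genotype explained by the tags — the expected
squared correlation between imputed and true statistic. Two numerical
choices: the raw quadratic form can exceed 1 by sampling noise at small
$\lambda$, so the reported value is clamped to $[0,1]$ (the raw value is
kept as an attribute); and because $q \gg n$ inflates explained variance,
an adjusted version discounts by panel size,
$r^2_{\mathrm{adj}} = 1 - (1-r^2_{\mathrm{pred}})\frac{n-1}{n-q_{\mathrm{eff}}-1}$,
clamped below at 0 and above at 1, returning 0 with a warning when
$n \le q_{\mathrm{eff}}+1$.

$q_{\mathrm{eff}}$, the effective number of tags, is computed spectrally:
the smallest number of leading eigenvalues of $C_\lambda$ whose sum reaches
99.5% of the trace. The threshold is a tuning constant (configurable via
`qeff_threshold`); 99.5% was chosen because it leaves $q_{\mathrm{eff}} = q$
exactly for independent tags while collapsing perfect-LD pairs, and the
adjusted quality is insensitive to it in the regime $n \gg q$ where the
package operates. This spectral definition was an open design point — the
literature offers several "effective number of tests" estimators — and was
picked for being monotone, cheap and exact in both limiting cases.

## Variable sample size

Meta-analysis tags rarely share one sample. If tag $k$ was measured in
$N_k \le N_{\max}$ individuals, correlations between observed statistics
attenuate by $\delta_{kl} = N_{k \cap l}/\sqrt{N_k N_l}$, where
$N_{k\cap l}$ is the sample overlap. Since overlap counts are rarely
published, two bracketing estimators are provided:

* **dependent** (default): $N_{k\cap l} = \min(N_k, N_l)$, i.e.
  $\delta = \min(\sqrt{N_k/N_l}, \sqrt{N_l/N_k})$ — maximal overlap, the
  conservative choice (it minimises the imputed statistic), and empirically
  the realistic one: cohorts contribute a variant either for all their
  members or not at all, which pushes overlap toward the maximum;
* **independent**: $N_{k\cap l} = N_k N_l / N_{\max}$, i.e.
  $\delta = \sqrt{N_k N_l}/N_{\max}$ — missingness at random;
* **known**: user-supplied overlap counts.

The adjusted system is $D_{kl} = (C_\lambda)_{kl}\,\delta_{kl}$ (unit
diagonal restored) and $d_k = (c_\lambda)_k \sqrt{N_k/N_{\max}}$;
imputation is $\hat z_u = d' D^{-1} z^\circ_M$ and the standardized effect
$\hat a_u = \hat z_u / (\sqrt{N_{\max}}\, d' D^{-1} d)$, where
$d' D^{-1} d$ is the corresponding imputation quality. Design decision:
shrinkage is applied *first* and $\delta$ scaling second, with $d$ built
from the shrunk $c_\lambda$. This makes the equal-$N$ case collapse
bitwise onto the base estimator (a property the tests assert), which any
other ordering would break. The quality divisor in the effect conversion
has a floor of $10^{-4}$; below it the effect estimate would be noise
amplified by orders of magnitude, so it is suppressed (the Z-statistic is
still reported). Imputed Z-statistics are deliberately *not* divided by
$r^2$: for null variants this would re-inflate what the conditional mean
correctly shrank, trading type-I error control for an unbiasedness that
only holds if the target is causal.

## Windowing

Genome scans proceed in 1 Mb core windows with 250 kb flanks: all targets
in a core share the tag set (core + flanks) and one matrix factorization.
The grid is anchored at the smallest tag position per chromosome rounded
down to a multiple of the core width — deterministic and independent of the
target set. Positions are 1-based; window intervals are half-open. Windows
without tags yield quality-0 records rather than errors. Leave-one-out
validation (`mask_and_impute()`) instead uses a ±750 kb tag radius around
the focal variant. Targets are filtered to panel MAF ≥ 0.1% by default
(below that, LD from a few-thousand-strong panel is mostly noise); results
carry a `quality_ok` flag at $r^2_{\mathrm{adj}} \ge 0.3$ rather than being
dropped.

## Conditional analysis and locus scan

A variant's statistic conditional on a set $S$ of known signals is the
standardized residual
$z_{\mathrm{cond}} = (z_u - c' C^{-1} z_S)/\sqrt{1 - c' C^{-1} c}$ with
shrunk $c, C$. This Z-space residual form (rather than an effect-size
joint model) is used because the whole pipeline operates on standardized
statistics, where the two formulations agree. When the residual variance
falls below $10^{-3}$ — the target is essentially a proxy of a conditioner —
the result is flagged non-estimable instead of returning an inflated
statistic. The locus scan takes, per core window, all imputed variants with
$r^2_{\mathrm{adj}} \ge 0.3$ and $P \le 10^{-8}$, conditions each on every
reported variant within 1 Mb of the set's span, and declares a candidate
locus if any survives; the smallest conditional $P$ defines the top variant
(ties broken by position, then id). Adjacent-window loci are merged by
conditioning the weaker top on the stronger. The $10^{-8}$ threshold is a
plain configuration value.

## The simulator

The generator emulates the statistical structure the estimators care
about, not human genome sequence: (i) LD-block genotypes — two independent
latent-Gaussian haplotype layers per individual, thresholded at the MAF
quantile, with the latent correlation *calibrated* (by solving a
bivariate-normal rectangle-probability equation) so the realized dosage
correlation hits the requested LD; without calibration, thresholding would
attenuate a 0.9 target to roughly 0.8; (ii) a phenotype
$y = \sqrt{h^2} g_{\mathrm{std}} + e$ with a single causal variant
(default $h^2 = 0.02$; the power experiments use $10^{-4}$, a typical
single-SNV GWAS effect); (iii) per-variant sample sizes resampled from a
wide (13–110219, log-uniform) or narrow (50000–187167, uniform) empirical
range, rescaled so the upper bound maps to the simulated GWAS size
(default 12500); (iv) missingness masks interpolating between nested
observation sets ($\theta_{\mathrm{miss}} = 1$, maximal overlap) and
independent uniform draws ($\theta_{\mathrm{miss}} = 0$) by drawing a
Binomial$(N_k, \theta)$ share of each set from a shared nesting order —
exact at both endpoints and monotone between them, which is all the
endpoint-only definition of $\theta_{\mathrm{miss}}$ pins down.

What the simulator does *not* reproduce: recombination-map LD decay,
allele-frequency spectra, polygenicity (one causal variant only),
population structure, and haplotype-level (non-linear) tagging. Passing
tests therefore demonstrate correctness of the estimators under their own
model assumptions and the direction of the missingness-correction effects —
not genome-scale error magnitudes, which depend on real LD and real
missingness patterns.

## Validation design and problem sizes

The test suite checks every estimator against an independent route:
imputation against a generic QR solve on the same matrices, the GWAS
Z-statistic against the regression $t$, overlap masks against their
hypergeometric/nested expectations, FPR against uniform-null binomial
bands. The missingness-correction experiment runs 10 regions × 50
replicates at a GWAS size of 2500 with $\theta_{\mathrm{miss}} \in
\{0, 0.5, 1\}$ under both sample-size distributions — sizes chosen so the
full grid completes in a couple of minutes while leaving the qualitative
orderings (conventional worst everywhere; dependent best under nested
missingness, independent best under random missingness) resolvable. Because
the three estimators share every simulated draw, the dependent-versus-
independent contrast is assessed as a paired per-region difference; the
unpaired cell medians differ by well under the Monte-Carlo noise at this
scale. The locus-scan experiment plants one reported and one independent
novel signal ~1.5 Mb apart (different core windows) with effects large
enough that the imputed novel signal clears $10^{-8}$ when tagging works.

## Known limitations

Rare variants (panel MAF below $\approx 1/(2n)$) cannot be tagged linearly;
quality estimates from small panels are themselves noisy and the adjusted
metric is deliberately conservative. The ridge-regression out-of-sample
quality estimator is a documented extension point, not implemented.
Chromosome X, cross-ancestry panels and genotype imputation itself are out
of scope.
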