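# uta

Single-cell analysis of miRNA-mediated repression from dual-fluorescence
reporter experiments.

## The problem

How strongly a microRNA silences its targets is not readable from its
expression level alone: some abundant miRNAs are nearly inert, some
moderately expressed ones repress potently. Dual-fluorescence reporter
assays resolve repression at the single-cell level — one fluorescent
protein (the *reference*, YFP-like) reports transcription/translation
activity, a second (the *reporter*, CFP-like) carries a perfectly
complementary miRNA target site in its 3'UTR. Because transient
transfection spreads expression over ~3 decades, one flow-cytometry run
samples the full dose–response of repression.

This package is for experimentalists and modellers analysing such data (or
validating analysis choices on realistic synthetic data). It implements:

* the **molecular titration model** of miRNA repression. Free target mRNA
  *r* at steady state, given unrepressed level *r₀*, effective miRNA
  abundance *θ* and effective dissociation parameter *λ*
  (*1/λ* = binding capability), is the non-negative root of
  *r² + r(λ + θ − r₀) − λr₀ = 0*:

  *r = ½[(r₀ − θ − λ) + √((r₀ − θ − λ)² + 4λr₀)]*

  For *λ = 0* (a perfectly binding miRNA) this is exactly threshold-linear:
  *r = max(r₀ − θ, 0)* — complete silencing up to *r₀ = θ*, linear
  transmission beyond. *θ* sets the threshold position, *1/λ* its
  sharpness.
* a **synthetic cytometry generator** (lognormal transfection, measurement
  noise, autofluorescence) with helpers for target-site copy number and
  siRNA competition experiments;
* **transfer functions**: binned log reference intensity vs mean log
  reporter intensity from gated events (0.05-wide log₁₀ bins);
* **weighted nonlinear least-squares estimation** of (θ, λ) plus a gain
  nuisance, returning a classed model object with the usual
  `print`/`summary`/`coef`/`predict`/`plot`/`residuals`/`simulate`
  methods;
* **functional classification** of fitted curves into the ordinal groups
  low / mid / high;
* **expression-profile utilities**: median-of-ratios size factors,
  RPM/RPKM, log₂ quartile ranking, cytoplasm/nuclear ratios, and
  Kruskal–Wallis + Dunn group comparisons;
* a reproducible **pipeline** (`run_pipeline()`) chaining
  simulate → gate → transfer → fit → classify with a manifest.

## Worked example

Simulate one reporter experiment (50,000 cells, θ = 150, λ = 15 intensity
units, default noise), reduce it to a transfer function, fit the model and
classify the miRNA:

```r
library(uta)

cfg    <- simulation_config(seed = 42, n_events = 50000, theta = 150, lam = 15)
events <- simulate_events(cfg, sample_id = "miR-example")
gated  <- gate_ref_positive(events, gate = 100)
tf     <- transfer_function(gated, af_mean = 50)
fit    <- fit_transfer_function(tf, seed = 42)
fit
#> Titration-model fit (weighted nonlinear least squares)
#>   theta = 1.451  lambda = 0.1517  gain = 0.9327  (relative units)
#>   weighted RSS 0.000382 over 35 bins; converged
```

Estimates are in relative reference-intensity units (intensity / gate);
multiplying by the gate recovers the simulation's units:

```r
coef(fit) * c(100, 100, 1)
#>       theta      lambda        gain
#> 145.1443269  15.1673089   0.9326933
```

θ̂ = 145 and λ̂ = 15.2 against true values 150 and 15 — about 3% and 1%
off. The fitted curve classifies as a mid-functional miRNA (its
repression threshold sits in the lower half of the observed intensity
range):

```r
classify_function(fit)
#> Functional category: mid (min r/r0 = 0.127, crossing at p = 0.44 over log10 range [-0.33, 1.38])
```

Comparing expression between functional groups uses the rank-based test:

```r
kruskal_dunn(c(1,2,3, 4,5,6, 7,8,9), rep(c("low","mid","high"), each = 3))
#> Kruskal-Wallis: H = 7.2, df = 2, p = 0.02732
#> Dunn pairwise comparisons (bonferroni adjustment):
#>  group_a group_b         z           p      p_adj
#>     high     low  2.683282 0.007290358 0.02187107
#>     high     mid  1.341641 0.179712495 0.53913748
#>      low     mid -1.341641 0.179712495 0.53913748
```

Only the extreme (low vs high) pair separates — the typical pattern when
expression only partially reflects function.

See `vignette("titration-model-methods")` for the model, the estimation
procedure, parameter-recovery results and design rationale.

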