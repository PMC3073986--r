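# inforate

Estimation of the **information transfer rate** (bits/s) between two
simultaneously sampled continuous signals, assuming only stationarity and
ergodicity — no linearity, no Gaussian statistics, no controlled inputs.
Intended for input–output analyses of nonlinear systems (e.g. sensory
neuron recordings) and for pairs of interrelated observables (e.g. surface
temperatures at two weather stations), where the classical coherence-based
Gaussian channel capacity is biased or invalid.

## The method

Under a finite-memory (Markov, order *L*) approximation of the joint
process, the mutual information between aligned blocks of *d* consecutive
samples grows linearly in *d*:

    I(X_{1..d}; Y_{1+T..d+T}) ≈ R·d + c,   d ≥ L

so the rate *R* (bits/sample; divide by the sampling interval for bits/s)
is the slope of MI versus the embedding dimension *d*. The pipeline:

1. standardize both signals and break ties with seeded jitter;
2. detect the latency *T* at the peak of the **cross mutual information
   function** (CMIF) and take *L* from the peak's half-width;
3. delay-embed both signals, project the blocks onto the top *N* principal
   components of the shifted output (N chosen so the above-noise-floor
   eigenvalue mass reaches 98%);
4. estimate MI per *d* with the Kraskov k-nearest-neighbour estimator
   (variant 1, max-norm, k = 3 by default, in C++);
5. fit an ordinary least-squares line over the automatically detected
   linear region within `[max(L, N), T]`.

A filtered-Gaussian validation channel with a closed-form capacity oracle
(`analytic_capacity()`), a Welch-coherence capacity estimator, and
preprocessing utilities for gappy/oversampled records (PCHIP gap filling,
Kaiser-window anti-aliased decimation, sliding windows) are included.

## Worked example

Simulate a Gaussian channel calibrated to a known capacity of 220 bits/s
and estimate its rate blind:

```r
library(inforate)
spec <- channel_spec(noise_variance = calibrate_noise_variance(220),
                     n = 40000, seed = 1)
sim <- simulate_gaussian_channel(spec)
fit <- information_rate(sim$x, sim$y, seed = 1)
fit
#> Information transfer rate estimate
#>   rate      : 204.8 bits/s  (0.2048 bits/sample)
#>   fit       : d = 4..20, R^2 = 0.9996, slope SE = 0.00101 bits/sample
#>   params    : n = 39960, dt = 0.001 s, k = 3, T = 20, L = 4, N = 4
analytic_capacity(spec)
#> [1] 220
```

The pipeline recovered the 20-sample group delay of the 41-tap channel
filter automatically and estimated 205 bits/s against the 220 bits/s
oracle — the ~7% shortfall is the characteristic small-sample bias of the
kNN MI estimator at this operating point (see the methods vignette).
`plot(fit)` draws the MI(d) curve with the fitted line; `summary(fit)`,
`coef(fit)`, `predict(fit)` and `residuals(fit)` expose the fit;
`as_report(fit)` gives a JSON-ready audit record.

A command-line interface wrapping the same functions (commands `rate`,
`capacity`, `simulate`, `validate`, `preprocess`) is installed at
`inst/cli/inforate.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/inforate.R", package="inforate"))')" \
    rate --input-x x.csv --input-y y.csv --dt 0.001 --out report.json
```

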