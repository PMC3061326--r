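# dipoleTrack

Dynamical estimation of current dipoles from MEG evoked responses by
random-finite-set (RFS) particle filtering.

Traditional dipole fitting assumes a fixed number of sources at fixed
locations for the whole epoch. `dipoleTrack` drops both assumptions: the
set of active dipoles is treated as a dynamical random variable, and at
every time sample the filter estimates the posterior probability that
0, 1, 2, … dipoles are active, together with their locations on a
discretized source space and their moments. A clustering pass then binds
the per-sample estimates into stable neural sources with mean locations
and continuous amplitude waveforms. The package is aimed at MEG/EEG
methodologists and at anyone who needs automatic, reproducible dipole
modeling of evoked fields.

## The model in brief

The state at sample *t* is a finite set of dipoles
X_t = {(r_1, q_1), …, (r_k, q_k)}, k ≤ k_max, with locations r on a
volumetric grid and moments q (nA·m). Data follow the linear forward model
y_t = Σ_j G(r_j) q_j + ε with Gaussian sensor noise. An RFS particle
filter propagates the posterior over X_t: per sample it (1) weights each
candidate set by exp(−‖r‖² / (2 n_ch (δσ)²)) where r is the ridge
least-squares residual of that set, σ the prestimulus noise level and δ
the *discrepancy* parameter (δ < 1 demands a tighter fit → more sources;
δ > 1 a looser fit → fewer, stabler sources); (2) forms the model-order
posterior P(k | y_1:t) and conditional dipole estimates; (3) resamples
systematically; (4) evolves every set by a birth/death/jump random walk
on the grid. Everything is seeded and bit-reproducible.

The spherical-conductor forward model (closed-form dipole field, planar
gradiometer and magnetometer channels), a calibrated six-source synthetic
benchmark, plain-text readers/writers, an STC exporter and a command-line
pipeline are included.

## Worked example

Simulate the six-source benchmark (204 planar gradiometers, 0.5 cm grid,
white noise of 3 fT/cm), run the filter at 2,000 particles and cluster
the estimates:

```r
library(dipoleTrack)

cond  <- SphereConductor()                      # 9 cm sphere at (0, 0, 4) cm
helm  <- fibonacciHelmet(conductor = cond)      # 102 x (2 GRAD + 1 MAG)
grid  <- neighborMatrix(buildSourceGrid(cond, spacing = 0.5,
             shellFraction = 0.85), radius = 1)
grads <- selectChannels(helm, channelKinds(helm) == "GRAD")
lf    <- assembleLeadField(grid, grads)

sim   <- simulateBenchmark(benchmarkSources(), helm, sigma = 3, seed = 7)
noise <- estimateNoiseFromPrestim(sim$measurements, discrepancy = 1)
noise
#> NoiseModel ( white ): sigma = 3.119004 , discrepancy = 1

fit <- runFilter(sim$measurements, lf, grid, noise,
                 FilterConfig(nParticles = 2000, seed = 7))
fit
#> FilterResult over 401 samples ( -100 .. 300 ms )
#>   model order range: 0 .. 5 ; estimated dipoles: 386

cs <- clusterDipoles(fit, maxClusters = 4)
round(clusterMeans(cs), 2)
#>          x     y    z
#> [1,] -1.43 -1.23 3.63
#> [2,]  3.03  2.70 7.49
#> [3,] -1.88  3.32 9.10
#> [4,] -1.30 -4.95 6.97
round(clusterLocationErrors(cs, sim$truth), 2)
#> [1] 2.53 2.02 0.64 0.61
round(mean(dipoleLocalizationErrors(fit, sim$truth)), 2)
#> [1] 1.45
snrDb(sim$truth$signal, sim$truth$noise)
#> [1] 11.06488
```

Reading the output: the noise level estimated from the −100..0 ms
prestimulus window is ≈3.1 fT/cm (truth: 3). Over the 401 samples the
filter produced 386 dipole estimates whose mean distance to the nearest
true source is 1.45 cm. Forced into 4 location clusters, two cluster means
land within 0.7 cm of true sources (the strong ones near the vertex);
the other two collect the deeper/weaker activity and stray low-amplitude
estimates, ending 2–2.5 cm off. The simulated epoch's Frobenius
signal-to-noise ratio is ≈11 dB.

The same pipeline runs from the shell:

```sh
Rscript inst/scripts/dipoletrack.R --simulate benchmark \
    --particles 10000 --discrepancy 1 --seed 7 --out results/
```

writing `dipoles.tsv`, `order_posterior.tsv`, `clusters.tsv`,
`cluster_waveforms.tsv`, `estimates.stc` and a run log; or from files via
`--source-space`, `--lead-field` and `--measurements` (ASCII formats
documented in `?readSourceSpace`, `?readLeadField`, `?readMeasurements`).

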