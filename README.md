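# cyclerates

Cell-cycle-resolved RNA kinetic rates from metabolic-labeling single-cell
RNA-seq.

## The problem

Pulse-labeling cultured cells with 4-thiouridine (4sU) marks RNA made during
the pulse: after alkylation, incorporated 4sU reads as C instead of T, so
newly synthesized molecules carry diagnostic T→C conversions. In droplet
scRNA-seq every captured transcript is additionally tagged with a UMI and
can be split into unspliced (precursor, `p`) and spliced (mature, `m`) form.
One experiment therefore yields four species per gene per cell — labeled and
unlabeled precursor and mature RNA (`pl`, `pu`, `ml`, `mu`) — which is
enough information to resolve *time-dependent* transcription, splicing and
degradation rates along a biological trajectory such as the cell cycle.

`cyclerates` implements the full desk side of that experiment for
unsynchronized cycling cells whose positions on the cycle (phase
Φ ∈ [0, 2π), period T hours, angular velocity ω = 2π/T) are known:

1. **Molecule calling** — UMI-level read merging with SNP-position masking,
   then a two-stage Bayesian classifier: per mismatch locus a binomial
   mixture separates true conversions from sequencing errors
   (`conversion_posterior`), and per molecule a Poisson/binomial mixture
   gives the posterior probability `pnew` of being newly synthesized
   (`new_molecule_posterior`), summed into the four count matrices.
2. **Kinetic model** — along cell-cycle characteristics Φ(t) = Φ₀ + ωt the
   four species obey

       pu' = −β pu          pl' = α − β pl
       mu' = β pu − γ mu    ml' = β pl − γ ml

   with phase-dependent rates α(Φ) (transcription), β(Φ) (splicing, 1/h),
   γ(Φ) (degradation, 1/h). Short labeling pulses make the solutions
   invertible in closed form: the full model recovers all three rates from
   the precursor and mature profiles, and a precursor-free simplified model
   (splicing ≫ degradation) recovers

       γ̂(Φ) = −(1/t)·log[ mu(Φ,t) / m(Φ−ωt) ]
       α̂(Φ) = γ̂(Φ)·m(Φ−ωt)·ml(Φ,t) / (m(Φ−ωt) − mu(Φ,t))

   from the mature species alone.
3. **Downstream analysis** — cyclic penalized-spline smoothing (mgcv,
   `bs = "cc"`, k = 20, gamma = 1.4), peak calling (peaking iff
   max/min ≥ 1.5), cycling / well-predicted (dev ≤ 0.2) / robust-cycling
   gene classification, kinetic-mode assignment from constant-rate
   deviations, mean half-lives t₁/₂ = ln2/γ̄, bootstrap confidence bands and
   a downsampling analysis of profile validity under dropout.
4. **Synthetic data** — ground-truth generators (three regulation regimes
   that produce the *same* expression profile from different kinetics,
   sampled cells, read-level tables) so the whole pipeline is testable
   without any sequencing data.

## Worked example

Simulate one cycling gene whose transcription rate is dynamic (Case I
construction: target mature profile m(Φ) = 20 + 8 sin Φ, β = 12/h,
γ = 0.5/h, cell-cycle period 19.33 h), sample 2,000 cells after a 1 h pulse,
and characterize it:

```r
library(cyclerates)

grid     <- phase_grid(n = 300, period = 19.33)
rates    <- rates_case1(sine_target(20, 8), beta = 12, gamma = 0.5, grid = grid)
totals   <- simulate_total_profiles(rates)
profiles <- simulate_labeled_profiles(rates, totals, t = 1)
counts   <- sample_cells(list(CCNE2 = profiles), n_cells = 2000, depth = 3,
                         capture_sigma = 0.25, seed = 42)

cells <- tibble::tibble(phase = counts$cells$phase,
                        mu = as.numeric(counts$mu["CCNE2", ]) / 3,
                        ml = as.numeric(counts$ml["CCNE2", ]) / 3)
fit <- fit_gene_kinetics(cells, t = 1, grid = grid)
fit
#> <gene_kinetics> cycling: TRUE; well-predicted: TRUE (dev = 0.0467); mode: dynamic transcription; t1/2 = 1.52 h
tidy(fit)
#>   is_cycling well_predicted robust_cycling    dev dev_c_alpha dev_c_gamma
#> 1       TRUE           TRUE           TRUE 0.0467       0.331      0.0369
#>                    mode half_life_hours n_peaks_expression n_peaks_alpha n_peaks_gamma fc_global
#> 1 dynamic transcription            1.52                  1             1             0       2.2
```

The gene is called cycling (one expression peak, fold change 2.2), its
predictions reconstruct the observed profiles to within 4.7% (well below
the 0.2 well-predicted cutoff), and holding transcription constant degrades
predictions (dev_c = 0.33) while holding degradation constant does not
(dev_c = 0.037) — the classifier correctly reports *dynamic transcription*.
The estimated mean degradation rate 0.457/h gives a half-life of 1.52 h
against the generating truth ln 2 / 0.5 = 1.39 h; `autoplot(fit)` overlays
the observed and predicted profiles.

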