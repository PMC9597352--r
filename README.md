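# vesiquant

Quantitative analysis of vesicle motility and organelle imaging assays in R.

Intracellular cargo — endosomes carrying the cation-independent
mannose-6-phosphate receptor (CI-M6PR), lysosomes, mitochondria — moves by
alternating motor-driven runs and diffusive pauses. Studies of
endosome-to-TGN trafficking quantify this behaviour from live-cell
single-particle tracks, and complement it with a standard battery of
image quantifications: colocalization coefficients, organelle morphometry
after maximum-entropy thresholding, radial intensity profiles, corrected
total cell fluorescence (CTCF), degradation time courses and ratiometric
lysosomal pH. `vesiquant` implements that battery as tested, reusable R
functions, together with a synthetic-data generator with full ground truth
so every stage can be validated without microscopy data.

## The core analysis

For a 2D trajectory sampled every `dt` seconds, the time-averaged mean
squared displacement at lag Δt is

    MSD(Δt) = ⟨ |r(t + Δt) − r(t)|² ⟩   (average over all ordered pairs)

and its scaling is summarized by the anomalous diffusion exponent α from the
ordinary least-squares fit

    log MSD(Δt) = α · log Δt + C.

Directed (motor-driven) transport gives α → 2, free diffusion α = 1,
confinement α < 1. Tracks of at least 25 frames are analyzed and classified

* **processive** if α > 1.45,
* **diffusive** if 1 ≤ α ≤ 1.45,
* **non-processive** if α < 1.

Each track is further segmented into **active** and **passive** phases with a
rolling-window local-exponent vote refined by maximum-likelihood
changepoints, and each active phase contributes one **run length** — the net
displacement accumulated during the run — to a population histogram with
1-µm bins.

The imaging assays follow the field's standard definitions: Kapur's
maximum-entropy histogram threshold; connected-component particle
morphometry (areas in µm²); Pearson's r and thresholded Manders M1/M2;
ring-integrated radial profiles about the nucleus or measured from the
nuclear rim; `CTCF = integrated density − cell area × mean background`;
residual fractions `I(t)/I(0)` for pulse-chase degradation; and a linear
340/380 nm excitation-ratio calibration over pH 4–6 inverted to report
lysosomal pH.

## Worked example

Simulate a mixed population (directed, diffusive and state-switching
vesicles), then run the full motility pipeline:

```r
library(vesiquant)

mix <- list(
  list(model = motion_model("ballistic", speed = 1,
                            localization_noise_sd = 0.01), weight = 1),
  list(model = motion_model("brownian", diffusion_coeff = 0.1,
                            localization_noise_sd = 0.01), weight = 1),
  list(model = motion_model("switching", speed = 1, diffusion_coeff = 0.02,
                            p_active_to_passive = 1/40,
                            p_passive_to_active = 1/40,
                            localization_noise_sd = 0.01), weight = 1))
pop <- simulate_population(mix, n_tracks = 120, n_frames = 100, dt = 1,
                           seed = 42)
summarize_population(pop$tracks)
#> <motility_summary: 120/120 tracks retained (>= 25 frames)>
#>   processive 67.5%  diffusive 14.2%  non-processive 18.3%
#>   111 run-length records, median 59.98 um
```

Ballistic and switching tracks (two thirds of the mixture) are recovered as
processive; the Brownian third splits across the diffusive and
non-processive classes because its per-track exponent estimate straddles
α = 1 — see the methods vignette. Colocalization on a synthetic two-channel
field with a known 50% colocalized fraction:

```r
syn <- synth_two_channel_puncta(150, coloc_fraction = 0.5,
                                image_shape = c(512L, 512L), seed = 1)
coloc_pipeline(syn$channel_a, syn$channel_b)
#> <coloc_result: r = -0.500, M1 = 0.500, M2 = 0.500 (thr 10.8/10.8, 6352 px, union_mask)>
```

M1/M2 recover the generated fraction; r is negative here because, within
the union of the two supra-threshold masks, the non-colocalized puncta of
one channel coincide with background in the other.

A thin command-line wrapper over the same functions is installed as
`exec/vesiquant` (stages: `simulate`, `motility`, `morphometry`, `coloc`,
`radial`, `ctcf`, `ph`, `degradation`); every run writes a JSON report with
the resolved parameters, seed and input checksums.

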