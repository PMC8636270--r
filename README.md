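# posidoniaSIP

Quantitative toolkit for studies of nitrogen-fixing symbioses in seagrass
meadows — for biogeochemists and microbial ecologists who need the full
measurement chain from in-situ fluxes to single-cell isotope imaging in one
tested, scriptable place.

Seagrasses such as *Posidonia oceanica* sustain high primary production in
nitrogen-poor coastal seas, supported by diazotrophic bacteria living in
their root tissue. Quantifying that symbiosis couples four very different
measurements, each implemented here as a module:

* **Eddy covariance** (`ec_process()` and friends): net benthic O₂ fluxes
  from high-frequency velocity/optode series,
  F = mean(w′·C′), with despiking, double-rotation tilt correction,
  low-pass decomposition, scalar-lag optimization, cumulative-flux jump
  screening, 60-min bursts and day/night daily summaries
  (CO₂-equivalent = −1 × O₂, 1:1 molar).
* **¹⁵N₂ tracer rates** (`compute_rates()`, `n2_fixation_rate()`):
  rate = (at%_sample − at%_NA)/(at%_N₂ − at%_NA) × N_content / t,
  with detection limits at 3× the natural-abundance s.d., censoring,
  fixing/non-fixing plant classification, leaf-allocation fractions and an
  areal N-supported carbon production budget.
* **Amplicon QC** (`apply_qc()`, `symbiont_organellar_ratio()`): the
  ≥10% organellar-read screen for root 16S libraries and the
  symbiont:organellar read ratio as an absolute-abundance proxy.
* **Correlative FISH/nanoSIMS imaging** (`binarize_tissue()`,
  `detect_cells()`, `stitch()`, `accumulate_planes()`,
  `masked_mean_enrichment()`, `transfer_mass_balance()`): segmentation at
  1%-of-max thresholds, exclusion masking, ±5 px cross-correlation
  registration, at% = 100·r/(1+r) ratio images with a count-statistics
  validity floor, relative incorporation per day, and the area-weighted
  host-transfer mass balance.
* **Transcription** (`tpm()`, `housekeeping_normalize()`):
  TPM_i = (c_i/l_i)/Σ_j(c_j/l_j) × 10⁶ and per-sample scaling to the mean
  of eight housekeeping genes.

Every input class has a synthetic generator with known ground truth
(`gen_ec_timeseries()`, `gen_tissue_isotopes()`,
`gen_correlative_images()`, `gen_amplicon_table()`, `gen_count_table()`),
and `run_pipeline()` orchestrates all stages from one YAML configuration
with a checksummed, bit-reproducible manifest. A thin CLI wrapper is
installed under `inst/cli/posidonia-sip`.

## Worked example

Simulate a 24-h benthic deployment with a true flux of 2 mmol O₂ m⁻² h⁻¹,
a 2.5-s sensor lag, 5° instrument tilt and 20 velocity spikes at
signal-to-noise 5, then process it:

```r
library(posidoniaSIP)

rec <- gen_ec_timeseries(ec_truth(true_flux = 2, lag_s = 2.5, tilt_deg = 5,
                                  spike_count = 20, seed = 1),
                         duration_s = 86400, snr = 5)
res <- ec_process(rec)
res$lag_s
#> [1] 2.5
res$daily
#> <daily_flux> net O2 47.97 (CO2 -47.97) mmol m-2 d-1, sd 0.01
#>   day 2.00 (n=12), night 2.00 (n=12) mmol m-2 h-1
```

The chain recovers the injected lag exactly and the daily flux
(2 × 24 = 48) to 0.07%. Tracer rates from a simulated whole-plant
incubation (pool 5.4 at% ¹⁵N, 0.3‰ natural-abundance spread):

```r
tab <- gen_tissue_isotopes(rate_truth(rates = c(root = 0.5, rhizome = 0.05,
                                                leaf = 0.05), seed = 1))
r <- compute_rates(tab, pool_enrichment(5.4))
aggregate(rate ~ tissue, r, mean)
#>    tissue       rate
#> 1    leaf 0.00000000
#> 2 rhizome 0.05767718
#> 3    root 0.50190294
classify_plant(r$rate[r$tissue == "root"])
#> [1] "fixing"
```

Root and rhizome rates are recovered within the natural-abundance noise;
the small leaf transfer rate falls below its detection limit here and is
censored to zero — exactly how near-LOD transfer measurements behave.
Single-cell enrichment at the midpoint of the labelling ceiling over a
two-day incubation corresponds to a relative incorporation of:

```r
relative_incorporation((0.367194 + 5.4) / 2, 0.367194, 5.4, t = 2)
#> [1] 25
```

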