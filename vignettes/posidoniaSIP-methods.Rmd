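---
title: "Methods and design choices in posidoniaSIP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in posidoniaSIP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(posidoniaSIP)
```

posidoniaSIP implements the measurement chain used to quantify a
nitrogen-fixing root symbiosis in seagrass meadows: benthic eddy-covariance
oxygen fluxes, bulk ¹⁵N₂ tracer rates, an amplicon library QC screen,
correlative FISH/nanoSIMS single-cell isotope quantification, and TPM
transcript normalization. Every stage has a synthetic-data generator with
known ground truth, so the whole chain is testable without field data. This
vignette explains the models, the tunable parameters, and the design
decisions taken where the underlying procedures left genuine freedom.

## Eddy-covariance flux processing

The aquatic eddy-covariance (EC) method estimates the areal O₂ exchange flux
as the covariance of vertical velocity fluctuations $w'$ and scalar
fluctuations $C'$: $F = \overline{w'C'}$, in mmol m⁻² s⁻¹ for velocities in
m s⁻¹ and concentrations in mmol m⁻³. The processing chain in
`ec_process()` follows standard benthic practice:

1. **Downsampling** (`downsample()`): velocity (16 Hz) is block-averaged
   onto the scalar timestamps (1–4 Hz).
2. **Despiking** (`despike()`): samples deviating more than `k_mad` (default
   6) MADs from a running median (window 9 samples) are replaced by the
   running median. The despiking rule itself is a choice — a running
   median/MAD filter was picked because it is deterministic and admits an
   exact oracle (an injected outlier of known position must be flagged);
   phase-space despiking would add complexity without changing the flux at
   the spike densities considered here.
3. **Tilt correction** (`rotate_tilt()`): double rotation — yaw to zero
   mean transverse velocity, pitch to zero mean vertical velocity. Double
   rotation was chosen over planar fit because it is deterministic per
   deployment and exactly inverts the rigid instrument tilt applied by the
   generator.
4. **Decomposition** (`decompose()`): a centred moving average (window
   `cutoff_s`, default 300 s, shrinking at the edges) defines the steady
   component; the fluctuation is the residual, so the decomposition is
   exactly conservative by construction.
5. **Lag optimization** (`optimize_lag()`): the scalar is shifted against
   $w'$ until the (signed) cross-correlation is maximal, within
   ±`max_lag_s` (default 10 s); ties break toward zero lag. Positive lag
   means the scalar is delayed relative to $w$.
6. **Screening and averaging**: instantaneous fluxes are integrated
   cumulatively (trapezoid); an increment exceeding `jump_k` (default 50)
   MADs of all increments truncates the series at the first such jump.
   Fluxes are averaged into 60-min bursts (mmol m⁻² h⁻¹) and summarized
   into a daily net flux (mean of hourly fluxes × 24). Bursts are
   classified day/night by mean PAR against 1% of the maximum burst PAR,
   and the reported uncertainty is the quadrature sum of the day and night
   standard deviations — a documented convention, not a statement about
   independence. CO₂-equivalent fluxes are the O₂ fluxes times −1
   (1 mol O₂ : 1 mol CO₂). No gap-filling is performed before the daily
   integration.

### The turbulence surrogate

`gen_ec_timeseries()` does **not** mimic a turbulence spectrum. The
vertical velocity fluctuation is a sum of sinusoids
(periods 20, 30, 50, 60 s) plus white noise, and the scalar fluctuation is
a scaled, lagged copy plus independent noise, with the scale chosen so that
$\mathrm{cov}(w', C')$ equals the requested flux exactly. Two properties
motivated this choice: the covariance has a closed form (exact oracles),
and the default periods divide the 300-s low-pass window exactly, so the
moving-average decomposition nulls them without leakage. Consequences for
interpretation: passing tests demonstrate that the processing chain is
unbiased and recovers lag, tilt and spikes under *this* surrogate; they say
nothing about cospectral attenuation, wave bias or storage terms in real
deployments, which are out of scope. Default conditions: mean current
5 cm s⁻¹, O₂ 250 mmol m⁻³ with a tide-scale trend, signal-to-noise ratio 5,
spikes of 50 MADs at recorded indices (well above the 10-MAD detectability
floor even after 4:1 block averaging).

## ¹⁵N₂ tracer rates

Bulk rates use the standard tracer mass balance
$$\mathrm{rate} = \frac{\mathrm{at\%}_{sample} - \mathrm{at\%}_{NA}}
{\mathrm{at\%}_{N_2} - \mathrm{at\%}_{NA}} \cdot \frac{N_{content}}{t}$$
in µmol N g$_{DW}$⁻¹ d⁻¹ (`n2_fixation_rate()`). Leaves sit outside the
tracer compartment, so their enrichment measures within-plant transfer of
freshly fixed N; `transfer_rate()` is deliberately the identical
calculation. Conversions between δ¹⁵N and atom percent use
$R_{AIR} = 0.0036765$ and are exact bijections.

Detection limits are three times the standard deviation of the
natural-abundance δ¹⁵N within a tissue type (`detection_limit()`),
propagated through the rate equation (`rate_lod()`). Negative rates and
rates below the LOD are censored to zero. When a tissue has fewer than two
control rows, `compute_rates()` falls back to the pooled controls of the
nearest condition with a warning; with a single control row overall the LOD
degrades to zero (flagged). Plants are classified as fixing when the
*mean* censored root rate strictly exceeds the average detection limit
(default 0.01 µmol g⁻¹ d⁻¹); the mean rather than the maximum across root
pieces is used, configurable via the `stat` argument. The budget
(`production_budget()`) multiplies per-tissue rates by biomass per shoot,
shoot density and molar C:N; mass-ratio C:N inputs are converted with
12/14. Dry-to-wet weight conversion coefficients are not defaulted — they
are site-specific empirical values and must be supplied by the user.

The generator (`gen_tissue_isotopes()`) inverts the rate equation exactly,
so with zero natural-abundance spread the recovery is exact to floating
point. Default study conditions (chosen once, as realistic for seagrass
tissue): 8 pieces per tissue, 24-h incubation, natural-abundance spread
0.3‰ between pieces, N contents 700/500/1500 µmol g⁻¹ for
root/rhizome/leaf (≈1%, 0.7%, 2% N of dry weight), 10% log-normal
variation in piece N content and dry weight. The June-2014-style design —
one measured batch of enriched water, ~40% of the incubation water
replaced — is supported by `pool_enrichment()`'s dilution mode.

## Amplicon QC ratios

`apply_qc()` retains samples with at least 10% organellar reads of the
total ("minimum of 10%" is read as inclusive: a sample at exactly the
boundary is retained). `symbiont_organellar_ratio()` divides symbiont reads
by organellar reads as a proxy for absolute-abundance changes; it is
computed before organellar reads would be discarded. Category labels come
from an input mapping — taxonomy inference, OTU clustering and diversity
statistics are deliberately out of scope.

## Correlative FISH/nanoSIMS quantification

Fluorescence processing: root tissue is binarized from the green
(autofluorescence) channel at 1% of its maximum intensity
(`binarize_tissue()`); hybridized cells from the combined red+blue channel
with the same default rule (`detect_cells()`; the combined-channel
threshold is not fixed by the original procedure, so it defaults to the
tissue rule and is configurable). Strongly autofluorescent layers
(rhizoplane, epidermis, hypodermis, innermost stele) are removed from the
cell mask via `apply_exclusion()`. Areas integrate white pixels at
0.01 µm² per pixel — "1 px represents 0.1 µm" is read as the pixel *edge*
length; the pixel size is a parameter should the area reading be wanted.

Ion-count processing: planes are drift-corrected by integer
cross-correlation against the first plane and accumulated
(`accumulate_planes()`); the per-plane drift algorithm of the original
tooling is not described publicly, and plane-to-first cross-correlation is
the adopted stand-in. Tiles are stitched from nominal stage positions with
cross-correlation refinement within ±5 px; a pair whose best correlation
stays below `min_cor` (default 0.5) keeps its nominal offset and is flagged
for manual correction (`stitch()`). Per pixel,
$r = {}^{12}C^{15}N^- / {}^{12}C^{14}N^-$ and
$\mathrm{at\%} = 100\, r/(1+r)$; pixels with accumulated ¹²C¹⁴N⁻ below 100
counts (configurable) are invalid rather than erroneous, because regions
without plant material have too few counts for a meaningful ratio.

**Averaging order.** Class means are computed in ratio space and converted
to at% once (`masked_mean_enrichment()`), matching the order in which the
binary matrices are multiplied with the ratio matrices and then averaged.
At natural abundance the alternative (converting per pixel, then averaging)
is numerically indistinguishable; at high enrichment the two differ, and
the order is therefore fixed and tested. Cell pixels are excluded from the
tissue class so host-tissue enrichment is not inflated by symbiont pixels.

The host-transfer mass balance
(`transfer_mass_balance()`) weights each class's excess at% by its
occupied area, assuming area is representative of biomass contribution.
Because FISH dilutes the isotopic signal, quantified cell at% values are
minimum estimates; no correction factor is applied.

The generator (`gen_correlative_images()`) draws, per pixel and plane, a
Poisson total N-bearing count and a binomial ¹⁵N share — the counting
statistics of electron-multiplier detection — with 2000 accumulated counts
per pixel on plant material and a 10-count embedding-medium background
(safely below the validity floor). The fluorescence PSF is a Gaussian of
σ = 1 px. Two geometric consequences are worth recording:

* At the 1% threshold, a blurred step edge extends
  $\Phi^{-1}(0.99)\,\sigma \approx 2.33$ px beyond the true boundary. For
  the default tissue disk (radius 240 px in a 512×512 frame) that is a
  $2 \times 2.33 / 240 \approx 1.9\%$ area overshoot — the geometry was
  sized by this closed-form argument so that segmentation-area checks at
  the 2% level are meaningful.
* The same growth applies to cells (radius 3 px), so fluorescence-derived
  cell masks include a skirt of tissue pixels. Segmentation quality is
  therefore assessed on areas and connected-component counts, while
  isotope recovery is assessed on the ground-truth masks; cell centres are
  placed with enough separation that blurred cells never merge.

`blur_overlay()` (Gaussian kernels of 3–20 px over the inverted tissue
image) is presentation only and is never used in quantification.

## Transcription

`tpm()` implements
$\mathrm{TPM}_i = \frac{c_i/l_i}{\sum_j c_j/l_j} \times 10^6$ with lengths
in kilobases (bp inputs are converted on request, with a message), so each
sample sums to exactly 10⁶. `housekeeping_normalize()` divides by the mean
TPM of *rpoA, rpoB, ftsZ, rho, recN, gyrB, recA, gyrA* per sample —
normalization is per sample, not pooled. Missing housekeeping features are
reported by name.

## Pipeline, configuration and reproducibility

`run_pipeline()` executes simulate → eddyflux → rates → screen → imaging →
tpm from a single nested configuration (YAML or list; unknown keys are
rejected with a typed error). Every stage reads its inputs from files —
delimited tables and 16-bit multi-page TIFFs (counts stored as
value/65535) — so the run also exercises the package's I/O round trips.
The manifest records the package version, seed, resolved configuration and
MD5 checksums of all outputs; reruns with the same seed and configuration
are bit-identical. `validate_inputs()` checks delimited inputs against
column schemas and reports violations instead of raising. A thin
command-line wrapper is installed at `inst/cli/posidonia-sip`.

## Problem sizes and numerical tolerances

The bundled checks use problem sizes chosen to make the statistical bounds
sharp while staying desk-scale: 24 h of 4-Hz scalar data for the EC
end-to-end recovery (5% band, lag exact to one sample), 100 simulated
plants for rate recovery (bias below the s.e.m. of the estimates,
evaluated across plants, where the spread is dominated by the true rate
range), and one 512×512, 40-plane image set (class means
within three Poisson standard errors of the mean-of-ratios estimator).
Degenerate inputs fail loudly where a result would be undefined (all-zero
TPM samples, zero-variance lag inputs, zero mean velocity for rotation,
zero total excess in allocation or mass balance) and softly where a value
can be flagged instead (invalid ratio pixels, zero-read samples,
unresolved stitching pairs).

## Known limitations

No turbulence cospectra, storage or wave corrections; no gap-filling of
burst series. Rates assume a constant pool enrichment over the incubation
(start/end averaging is the only temporal treatment). Registration is
integer-pixel only — subpixel drift and rotation are not modelled, matching
the generator. FISH-induced isotope dilution is acknowledged but not
corrected; quantified cell enrichments are minimum estimates. The amplicon
module screens libraries; it does not analyse communities.
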