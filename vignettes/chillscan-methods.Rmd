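---
title: "Methods: tray-image rosette phenotyping and chilling-tolerance genetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tray-image rosette phenotyping and chilling-tolerance genetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

chillscan implements a complete desk-scale version of a high-throughput
chilling-tolerance screen in *Arabidopsis thaliana*: plug trays of seedlings
are photographed from above, each 12 x 12 half-tray frame is reduced to
per-cell rosette areas, growth statistics and broad-sense heritability are
computed across accessions, genotypes are scanned SNP by SNP for association
with the (log) growth trait, and candidate genes are validated against
knockout-mutant phenotypes. This vignette records the models, the tunable
parameters, and the design decisions, in that order of importance.

## The imaging model

A tray photograph is modelled as a projective view of a planar grid. The
six-step workflow is:

1. **Crop.** The largest tray-coloured region (HSV colour filter, then a
   morphological closing that bridges the cell ridges) defines the crop. If
   no region covers at least 20% of the frame the stage *fails loudly* and a
   manual crop rectangle from the configuration is honoured instead; the
   pipeline never silently passes the full frame through.
2. **Filter.** Within the filled tray region, pixels that are neither
   tray-surface nor plant are candidate ridge pixels; these are the linear
   features the grid detector consumes.
3. **Hough transform.** Votes in a (rho, theta) accumulator with 1 px rho
   resolution and 0.25 degree theta resolution, orientation classes within
   +/-20 degrees of horizontal and vertical. The top rows+1 and cols+1 peaks
   per class are taken after non-maximum suppression with a radius of half
   the expected line spacing (ties break towards smaller rho). Each peak is
   then refined by a total-least-squares fit to the mask pixels within a
   2 px band of the line, excluding pixels near a crossing line of the other
   orientation — junction pixels would otherwise bias the fit by a few
   hundredths of a pixel, which matters because the downstream exactness
   property needs sub-pixel line positions.
4. **Grid and homography.** Corners are the pairwise intersections of the
   refined lines. The homography to the orthographic tray plane is fitted
   from the four outer corners only (an exact 8 x 8 solve); interior corners
   only report an RMS diagnostic residual. Same-class lines that intersect
   inside the image, or coincide, are a degenerate grid and raise an error.
5. **Rectify and segment.** The *original unfiltered* image is resampled by
   inverse mapping with bilinear interpolation into a rows x cell_px by
   cols x cell_px frame and cut into cells by simple cropping. Sample
   coordinates within 1e-6 px of an integer are snapped, so an identity
   homography reproduces the input bit for bit.
6. **Measure.** The plant colour filter is applied to each rectified cell
   (the filter runs *after* rectification, matching the workflow's "rectify
   the unfiltered image" order); 8-connected components smaller than
   `min_blob_px` (default 10 px) are discarded, and the areas of **all**
   retained components are summed — a cell may hold a group of ~10-15
   seedlings, so taking only the largest object would be wrong. Mean colour
   over retained pixels and an optional mm^2 calibration complete the
   per-cell record.

### Colour filters

Filtering is done in HSV by default because hue separates leaf green from
tray plastic far more robustly than RGB boxes. The defaults are matched to
the synthetic renderer's palette: tray surface hue 15-60 degrees at value
>= 0.5; plant hue 77-160 degrees. The plant filter's lower hue bound is
deliberately placed at the hue of a 50/50 leaf/tray colour blend: after
bilinear resampling a boundary pixel then counts as plant exactly when the
leaf covers the majority of it, which makes measured areas first-order
unbiased under rectification. Real cameras will need retuned bounds; every
bound is an explicit `color_filter()` argument.

## The synthetic renderer as ground truth

`render_tray()` draws the tray in an *unwarped* frame — background border,
tray apron, 2 px ridges centred on every cell boundary, and rosettes
modelled as unions of 3-9 overlapping disks (leaf lobes) kept 4 px clear of
cell boundaries — measures the manifest there (the exact per-cell count of
pixels passing the plant filter), and only then applies the optional
projective warp, parameterised by four corner displacements capped at 10%
of the image size, with nearest-neighbour resampling so the warped frame
contains only palette colours. Rosette shape is a modelling choice (the
physical system publishes no shape model); what the tests rely on is only
that the manifest counts the generator's own pixels.

The renderer's default `noise_sd` is 0: the fixtures pin down *geometry*,
not sensor noise, and additive Gaussian noise is available as a parameter
and exercised separately. All randomness flows from a single integer seed
through isolated RNG scopes (`withr::with_seed`); nothing touches the
global random state.

What the synthetic trays do **not** emulate: leaf overlap between adjacent
cells, shadows and illumination gradients, specular highlights, lens
distortion, or colour variation within one rosette. A pipeline that is
exact here can still need filter retuning on real photographs; the
ground-truth agreement results bound the geometric error of the method, not
the photographic one.

Two accuracy regimes follow. Without warp the whole chain is integer-exact:
detected lines sit exactly on the half-integer cell boundaries, the
homography degenerates to an integer translation, bilinear weights collapse
to 1, and per-cell areas equal the manifest exactly. With warp the
agreement is bounded by resampling: the Pearson correlation over a full
144-cell tray exceeds 0.999 and the mean per-cell relative error stays
under 2%, but individual ~50 px rosettes carry irreducible quantisation
noise of several percent — a blob with ~30 boundary pixels cannot be
re-counted to 2% after two resampling steps, and no measurement method
could do so from the warped frame alone.

## Growth statistics and heritability

Growth rate is `(final - initial) * 100 / initial`; the ecotype growth rate
under cold stress is `day30 * 100 / day0`; proportionate tolerance divides
each ecotype's rate by the panel total (so it always sums to 100%). Areas
entering parametric tests are natural-log transformed (`log_transform()`,
with an optional offset for zero areas; the log base is a convention choice
as only ratios of variances matter downstream).

Broad-sense heritability uses the one-way random-effects ANOVA
decomposition: sigma2_e = MS_within, sigma2_g = (MS_between - MS_within) /
n0 clamped at zero, h2 = sigma2_g / (sigma2_g + sigma2_e) in [0, 1]. For
unbalanced panels n0 is the standard unequal-replication coefficient
`(N - sum(n_i^2)/N) / (k - 1)`. The estimator is invariant under shifting
and scaling of the trait. Whether the source study computed h2 on raw or
log areas is not recorded; the default here is raw areas with a `log_area`
switch. At the study's conditions — 417 accessions x 3 replicates,
sigma2_g = 21, sigma2_e = 4, i.e. a true h2 of 21/25 = 0.84 — a single
simulated panel estimates h2 with a standard deviation of about 0.012, and
the mean over 200 panels lands within 0.01 of truth.

Mutant comparisons use a two-sided two-sample t-test with Bonferroni
adjustment: significant iff p < alpha / m. Welch's form is the default (the
safer choice when a mutant's variance differs from Col-0's); the pooled
classic form is available via `pooled = TRUE`. The Bonferroni divisor m
defaults to the number of comparisons actually made in a run and is always
overridable, since the published analysis does not state its m.

## Association scans

SNPs pass the minor-allele-frequency filter when MAF > 0.05 — strictly
greater, computed on non-missing dosages; monomorphic SNPs always drop.
Missing dosages are mean-imputed per SNP (the convention of the web service
the original study used).

The **LR scan** is per-SNP ordinary least squares of the trait on dosage
with an intercept and a two-sided t-test on the slope, implemented in
vectorised closed form and verified against `lm()` to 1e-10.

The **mixed-model scan** follows the EMMAX construction: variance
components of y = mu + u + e, with u ~ N(0, sigma2_g K) for the
centred-and-scaled genomic relationship matrix K = Z Z' / m (columns of Z
standardised by sqrt(2 p (1 - p))), are estimated *once* under the null by
REML — one eigendecomposition of the projected kinship, then Brent
optimisation of log delta over [-10, 10] at tolerance 1e-8, where delta =
sigma2_e / sigma2_g — and every SNP is then tested by generalised least
squares with the fixed covariance, rotated through the eigenbasis of K so
each test costs O(n). With K = I the model collapses to OLS and reproduces
the LR scan to 1e-4 in -log10 p; with two simulated subpopulations and a
group phenotype shift the LR scan inflates (lambda_GC well above 1) while
the mixed model stays near 1 and still ranks a planted causal SNP at the
top. K must be symmetric PSD within tolerance (eigenvalues >= -1e-6
relative); violations are errors, as is a non-finite REML objective.

Scan calibration is summarised by the genomic inflation factor lambda_GC =
median(qchisq(1 - p, 1)) / qchisq(0.5, 1), with QQ coordinates from
`qq_table()` and `autoplot()`.

**Candidate calling** declares a gene a candidate when any SNP with
-log10 p >= 4.5 (inclusive, as the cutoff is printed) lies in the gene body
or its strand-aware 2-kb promoter window: `[start-2000, start-1]` on "+",
`[end+1, end+2000]` on "-". Coordinates are 1-based inclusive throughout;
BED input is converted on read. The fixed cutoff (not FDR) is the published
decision rule; Bonferroni-adjusted significance can be derived from the
returned p-values if wanted.

## Mutant validation and concordance

The validation rule over a gene's insertion mutants: two or more
significant mutants validate the gene; exactly one significant among two or
more tested makes a strong candidate; none makes it rejected; a single
tested mutant is always insufficient. Concordance compares the direction of
a gene's cold-stress expression change (cold/normal transcript ratio)
against the **mean** growth ratio of its knockouts: suppressed gene +
outgrowing mutants = concordant negative regulator; induced gene +
collapsing mutants = concordant positive regulator; exact ties on either
axis are indeterminate, never silently concordant. The mean (not, say, the
minimum) is used deliberately: one gene in the packaged table carries a
promoter-insertion mutant whose ratio moves opposite to its sibling —
averaging reproduces the published per-gene call, and a promoter insertion
that *raises* expression is not evidence against the gene.

The package ships the curated validation tables (16 validated genes with 34
mutant rows; 9 strong candidates) as plain TSV. On them, the concordance
tally is 9 negative + 4 positive = 13 of 16, and the previously-reported
fraction (ACD6, ADS2) is 12.5%.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make the statistics sharp while keeping a laptop-class run:
one 12 x 12 tray at 80 px cells for ground-truth agreement; 417 x 3 panels
for heritability; 10^6 null association tests (200 accessions, 20 chunks of
50,000 SNPs) for tail calibration at -log10 p >= 4.5 within three binomial
standard deviations; 250 x 2,000 structured simulations for the
inflation-ordering property. Degenerate inputs error rather than warn:
empty Hough masks, non-convex warps, non-PSD kinship, zero-variance
phenotypes, non-positive areas under log.

## Known limitations

* The renderer's palette is idealised; real trays need filter retuning and
  the colour defaults should be treated as documentation, not truth.
* Heritability is a one-way ANOVA estimate; randomised-block or
  repeated-measures designs are out of scope.
* The mixed model fits variance components once under the null (the EMMAX
  approximation); per-SNP REML would differ slightly for large effects.
* Candidate calling consolidates one scan; combining multiple experiments
  (union versus recurrence across runs) is left to the caller, and both
  per-run and pooled reports can be produced by running the scan per
  experiment.
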