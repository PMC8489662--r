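---
title: "Methods: from structured-panel GWAS to LD-calibrated QTL hotspots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from structured-panel GWAS to LD-calibrated QTL hotspots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlhotspots)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which parameters matter and
why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical decisions a maintainer would
want written down.

## 1. The scientific setting

The package targets structured cereal association panels — the concrete
template is a Mediterranean bread-wheat collection of ~354 accessions in
six genetic subpopulations, genotyped at ~10,000 mapped SNP markers over
21 chromosomes, phenotyped for three seasons in a non-replicated augmented
design with two replicated checks at a 1:4 check-to-test ratio, and imaged
by a four-band UAV multispectral camera (green 550 ± 40, red 660 ± 40,
red-edge 735 ± 10, NIR 790 ± 40 nm) at anthesis and post-anthesis. The
deliverable of the analysis is a table of QTL hotspots: genome regions
where marker–trait associations for several traits recur across years,
with genetic and physical confidence intervals tight enough to anchor a
candidate-gene search.

## 2. The synthetic-data generator

No public machine-readable release of such a panel's genotypes and plot
phenotypes exists, so the package generates its own inputs with known
ground truth. The generator is first-class, tested code: every recovery
claim the package makes is a claim about these simulated conditions.

**Genotypes.** Subpopulation allele frequencies follow a Balding–Nichols
model: for ancestral frequency $p \sim U(0.1, 0.9)$ and differentiation
$F$, subpopulation frequencies are
$\text{Beta}\!\left(p\tfrac{1-F'}{F'},\,(1-p)\tfrac{1-F'}{F'}\right)$.
Within each subpopulation a pool of $K$ founder haplotypes (default 16)
is drawn with a latent Gaussian AR(1) copula along the genetic map —
adjacent-marker latent correlation $\exp(-d/\lambda_{\mathrm{LD}})$ with
$\lambda_{\mathrm{LD}}$ the chromosome's LD-decay distance — which
respects the marginal frequencies exactly while giving within-founder
allele correlation that decays exponentially with cM distance. Accession
haplotypes are founder mosaics with crossovers at 1 per 100 cM. The
finite founder pool itself contributes roughly $1/K$ of drift variance
between subpopulations, so the Beta dispersion uses the shrunk
$F' = (F - 1/K)/(1 - 1/K)$; with that correction a Weir–Cockerham
estimate on a 1,000-accession panel recovers the nominal $F$ within
±0.05. Requested $F \le 1/K$ cannot be realized without enlarging the
founder pool (`founders_per_subpop`). Missing calls are
missing-completely-at-random with the per-marker count capped at
`missing_rate`; markers whose observed minor-allele frequency falls below
`maf_floor` are redrawn, so the panel respects the floor by
construction. Markers are inserted at every planted-QTL position, which
keeps the invariant that planted QTLs coincide with markers.

**Physical map.** bp(cM) is monotone piecewise-linear per chromosome:
the ±5 %-of-map window around the centromere carries 40 % of the
chromosome's physical length, emulating the suppressed pericentromeric
recombination of wheat. This matters downstream: hotspots whose genetic
CI reaches into that window explode in Mb and are (correctly) removed by
the 35 Mb exclusion rule.

**Phenotypes.** Plot values follow
$y = \mu + E_y + \textstyle\sum_q \beta_q x_q + u + (gE)_{iy} + r + c + \varepsilon$
with the core variance normalized to
$\sigma^2_G + \sigma^2_E + \sigma^2_{GE} = 1$, $\sigma^2_G$ equal to the
trait's target $H^2$, the remainder split between year main effect and
genotype-by-year by `e_share` (default ½), and plot residual
`sigma2_res` (default 0.25) on top. Planted-QTL allele effects are sized
so each explains its stated fraction of the plot-level phenotypic
variance $1 + \sigma^2_{res}$; the polygenic remainder is built from all
markers, orthogonalized against the planted QTLs. Realized draws of the
year, genotype-by-year, genetic and polygenic components are rescaled to
hit their target variances *exactly* (exact-variance conditioning). This
is a deliberate simulation design: with only three year levels, an
unconditioned draw of $E_y$ has enormous sampling variance and would
dominate every recovery experiment with noise that says nothing about
the estimator. The cost is that the generator's "random effects" are
conditioned samples, which slightly understates across-replicate
variance; the recovery tests average over replicates anyway. The field
layout replicates two designated check accessions at the 1:4 ratio on a
serpentine row × column grid with independent row and column effects
(default variance 0.02 each).

**Reflectance.** Each accession gets a latent canopy variable with
heritability `h2_canopy` (default 0.5, planted `"canopy"` QTLs enter its
genetic part); band reflectances are a deterministic linear
soil-to-vegetation mixture in the four bands, so NDVI is strictly
increasing in canopy and VIs inherit canopy's heritability. The
post-anthesis stage shifts the canopy distribution downward
(senescence). Not emulated: pixel-level imagery, radiometric or
geometric correction, within-plot spatial heterogeneity, band noise.
Passing tests therefore show that the *pipeline* recovers what was
planted under these idealized optics, not that any particular camera or
mosaicking workflow is unbiased.

## 3. Quantitative genetics

`fit_mixed_model()` fits, by REML via `lme4`,
`value ~ check_group + (1|accession) + (1|year) + (1|accession:year) +
(1|year:row) + (1|year:column)` — checks fixed (one level per check
cultivar, tests as reference), everything else random, the standard
augmented-design analysis pooled across years. We use `lme4` rather than
a hand-written EM-REML because it is the field-standard, heavily
validated REML implementation available to every R user; variance
components are non-negative by construction and singular fits are
tolerated (a component estimated at zero is a legitimate answer, e.g.
for a trait generated with $\sigma^2_{GE}=0$). A per-year mode can be
had by filtering the table to one year, but the pooled fit is the
default because the heritability formula below consumes across-year
components.

`heritability()` implements the Knapp broad-sense form
$H^2 = \sigma^2_G / (\sigma^2_G + \sigma^2_E + \sigma^2_{GE})$ with the
three components used exactly as estimated. The more common alternative
divides $\sigma^2_{GE}$ (and $\sigma^2_e$) by the number of years before
summing; we implement the printed three-component form and note the
alternative here rather than silently substituting it. Because the
generator targets the same three-component ratio, recovery experiments
(targets 0.3/0.6/0.9, 150 accessions × 3 years) come back within ±0.03
on average.

`variance_partition()` is a fixed-effects two-way ANOVA
(`value ~ year * subpop`) with sequential Type-I sums of squares in the
order year, subpopulation, interaction, reported as percentages of the
three-term sum. Type-I in that fixed order is the choice; on the
balanced synthetic layouts the three SS types coincide, and the order
matches the way seasonal and structural variation are conventionally
reported for such panels.

## 4. The association scan

`mlm_scan()` is the PCA + K mixed linear model: fixed intercept, six
genotype principal components (centered dosages, unscaled — the PCs of
the same matrix that builds the kinship), optional trait cofactors
(anthesis date by default in the pipeline, dropped automatically when
the response is the cofactor itself), and a random polygenic effect with
covariance proportional to the VanRaden kinship
$K = WW^\top / (2\sum_j p_j(1-p_j))$, $W$ the 2p-centered dosages.
Missing dosages are mean-imputed per marker inside the scan only — QC
and testing concerns stay separate.

Variance components are estimated once on the null model by profiling
the restricted likelihood over $\delta = \sigma^2_e/\sigma^2_g$ on a
log-grid (33 points in $[e^{-8}, e^{8}]$) followed by golden-section
refinement, using one eigendecomposition of $K$ — the EMMA restricted
likelihood. Those components are then reused for every marker (P3D).
This approximates "optimum compression" by its uncompressed limit:
compression is a speed device whose results converge to the uncompressed
mixed model, and at simulator scale (hundreds of accessions) the exact
per-marker REML would buy nothing but runtime. After whitening by the
null covariance, each marker's test is the partitioned-regression t test
on $n - p - 1$ degrees of freedom; PVE is reported as the marker's
partial $r^2$ given PCs and cofactors ($t^2/(t^2 + \mathrm{df})$),
since no other definition is canonical. Scan records are emitted for
*every* testable marker — thresholding is downstream — and zero-variance
markers are listed in a `skipped` attribute with reasons.

Calibration on structured null panels (300 accessions, 6 subpopulations,
$F_{ST}$ 0.2, 500 markers, polygenic trait with no QTL): genomic
inflation $\lambda$ averages ≈ 1.0 for the mixed model while plain
single-marker OLS on the same data inflates severalfold — the reason the
PCA + K model exists. A planted QTL explaining 10 % of phenotypic
variance (as the sole genetic signal, the textbook power design) is the
scan-wide maximum in ≥ 95 % of seeds at that panel size.

`gwas_thresholds()` returns the suggestive threshold (−log₁₀ p = 3 by
convention) and the corrected threshold $-\log_{10}(\alpha/M_{\mathrm{eff}})$
on the effective number of independent markers implied by LD decay
(3,696 by default, giving 4.8688). A genuinely data-dependent
Benjamini–Hochberg cutoff is also provided (`bh_threshold()`); the
fixed-count construction and the step-up procedure answer different
questions, so both are exposed and the pipeline configuration pins which
one gates reporting (default: suggestive, the threshold conventionally
used to feed hotspot detection).

## 5. The QTL overview index and hotspot rules

Each MTA on chromosome $c$ is smeared by a Gaussian centered at its cM
position with standard deviation $S_c = \mathrm{CI}_c/3.92$, where
$\mathrm{CI}_c$ is the chromosome's LD-decay distance playing the role
of a 95 % confidence interval (3.92 = two 1.96 half-widths). The
overview index on the 1-cM bin centered at $x$ is the *probability mass*
of all MTAs in that bin divided by the number of experiments:

$$u(x) = \frac{1}{nbE} \sum_q \left[ \Phi\!\left(\frac{x + \tfrac12 - \mu_q}{s_q}\right) - \Phi\!\left(\frac{x - \tfrac12 - \mu_q}{s_q}\right) \right].$$

Using bin mass rather than midpoint density is deliberate: it makes mass
conservation exact ($\sum u \cdot \Delta x = nbQTL/nbE$ up to edge
truncation, bounded by $2\,nbQTL\,\Phi(-d_{\mathrm{edge}}/s)$) and the
map-wide mean of $u$ equals the closed form $U = nbQTL/(nbE \cdot L)$ on
interior fixtures to 10⁻⁹. $nbE$ defaults to the number of distinct
(trait, environment) scans contributing MTAs — the only defensible
reading of "number of experiments" for a GWAS, where each trait–year
combination is one experiment.

**Peaks** are strict local maxima of $u$ above a threshold expressed as
a multiple of the map-wide mean; plateaus resolve deterministically to
their midpoint bin; a flat profile has no peaks. Two tiers are reported:
the mean threshold (multiplier 1) and a high threshold whose default
multiplier is 5 — chosen because the reference analysis style prints a
high threshold five times its mean threshold — and both multipliers are
configuration, never hard-coded values.

**Merging**: peaks on one chromosome whose CI windows
($\pm \mathrm{CI}_c/2$ around the peak) overlap merge into a hotspot
spanning the union. No merge rule is canonical in the literature for
reducing peaks to hotspots; window overlap is the single choice
consistent with the CI semantics, and the window multiplier is exposed.
Member MTAs are all associations inside the genetic bounds; trait and
environment sets are unions over members; a peak window containing no
MTA is an internal contradiction and raises an error rather than
emitting an empty hotspot. Flanking markers are the nearest mapped
markers at or outside the bounds, and the physical interval is
$|right_{bp} - left_{bp}|/10^6$ rounded **half-up** to one decimal —
half-up, not banker's rounding, to match how such tables are printed,
and with the absolute value because flanking markers can be physically
inverted relative to the genetic order (one published hotspot row
exercises exactly that case). Hotspot ids follow `QTL<chromosome>.<n>`
along each chromosome.

**Exclusion rules** (`filter_hotspots()`): a hotspot is dropped when the
centromere lies within its genetic bounds, its physical CI exceeds
35 Mb, its members come from fewer than 2 year-environments (the pooled
"mean" environment never counts toward this), or fewer than 2 traits.
Every exclusion is logged with its reasons.

## 6. Vegetation indices and LAI

The six index formulas are pinned in one internal registry (NDVI, RDVI,
MSAVI, MTVI2, GNDVI in their canonical published forms; TCARI/OSAVI as
the ratio of the transformed chlorophyll absorption index to the
optimized soil-adjusted index with the 0.16 soil constant) so the
algebra exists in exactly one place and tests compare it against
independent step-by-step arithmetic to 10⁻¹². Degenerate inputs — zero
denominators (e.g. red = 0 in the RE/R term), negative radicands —
produce a flagged record with `NA`, never a silent `NaN`. LAI is
estimated from MTVI2 by a single ordinary-least-squares line per
calibration set, mirroring the practice of calibrating on ~64
ceptometer-measured plots and predicting the full collection; whether
the original calibration methodology was linear is not documented in the
analysis style we follow, so the registry records the linear choice
explicitly rather than guessing a nonlinear form.

## 7. Pipeline, determinism and problem sizes

`run_pipeline()` orchestrates simulate (or load) → QC → VI → per
trait-environment scans → suggestive-threshold MTAs → overview index →
peaks → merge → exclusion rules, with every stage's parameters surfaced
in one YAML configuration carrying the conventional defaults (0.25
missingness, 0.05 MAF, 6 PCs, −log₁₀ p 3, α 0.05, 3,696 effective
markers, 35 Mb, ≥ 2 years, ≥ 2 traits, ×5 high threshold). All
randomness derives from the configuration seed; stage outputs are pure
functions of inputs, parameters and seed, and reruns are bit-identical
(the manifest records MD5 hashes). External inputs (VCF/CSV genotypes,
phenotype CSV, map, LD-decay and centromere tables) are validated before
any stage runs. There is no shell entry point: this is an R package and
`run_pipeline()` plus the exported stage functions are its interface.

The validation experiments use deliberately modest problem sizes — panels
of 150–300 accessions, 160–500 markers, 12–50 replicate seeds per claim —
chosen so the whole suite re-runs in minutes while keeping Monte-Carlo
error comfortably inside the asserted tolerances; the claims are about
estimator behavior at those sizes, which match the real panels the
package targets in accession count if not in marker density.

## 8. Known limitations

- The generator's LD is a single-scale exponential decay per chromosome;
  real panels mix ancient and breeding-program LD at multiple scales.
- Exact-variance conditioning makes variance-component recovery
  experiments sharper than fully random draws would be (Section 2).
- P3D reuses null variance components for every marker; for markers with
  very large effects the test is slightly conservative relative to exact
  per-marker REML.
- The Knapp heritability is implemented in its three-component form; on
  designs with many years it will differ from the year-scaled
  convention.
- The hotspot merge rule (CI-window overlap) is one defensible choice,
  not a community standard; alternative multipliers are configuration.
- Gene annotation consumes a GO-decorated GFF3 convention
  (`Ontology_term` + parallel `go_namespace`); real wheat annotations
  ship GO in side files that must be joined into that form first.
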