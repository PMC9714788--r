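---
title: "Methods: spatial metabolomics of bone MSI with osteomsi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial metabolomics of bone MSI with osteomsi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
behavior of the pipeline, and what the synthetic phantom does and does
not establish about real data.

## The data and its preprocessing

An MSI dataset is a mass spectrum per pixel of a 2-D grid (50 µm
notional spacing), acquired in negative-ion mode over m/z 75–1100.
Internally coordinates are 0-based, row-major; imzML files use the
standard's 1-based convention and both continuous (shared m/z axis) and
processed (per-pixel axes) modes are supported, with 32- or 64-bit
float arrays.

**Normalization.** Every spectrum is divided by its root-mean-square
intensity, so each pixel contributes on a comparable scale regardless
of total ion yield. RMS normalization is stable only when the spectrum's
energy is dominated by signals that do not differ between the groups
being compared; the phantom is constructed accordingly (below), and on
real data a handful of massively changed dominant ions would bias all
normalized fold changes — a known property of any global normalization.

**Peak picking** operates on the mean spectrum over *tissue* pixels
(the union of non-background mask labels). Off-tissue pixels are
excluded because they dilute thin compartments — the osteoid seam is
only a few pixels wide, and its peaks would otherwise fall below
threshold — and because matrix-dominated background spectra contribute
no tissue information. A peak is a strict local maximum whose
baseline-subtracted apex exceeds `snr` (default 3) times the local
noise. Noise is the sliding-window median absolute deviation scaled by
1.4826 (Gaussian-consistent), window 1 Da; the baseline is the local
median over the same window. The baseline subtraction in the S/N is the
package's interpretation of an apex-to-noise ratio: on a flat positive
offset a raw ratio would be ill-defined (0/0 on a flat spectrum) or
inflated everywhere, while the subtracted form reduces to the intuitive
ratio on zero-baseline spectra. The peak center is the apex m/z; no
centroid fitting is attempted.

**Ion images.** The data cube entry for (pixel, peak) is the sum of the
pixel's intensities within the center's ±4 ppm window (half-open at the
upper edge; overlapping windows resolve to the nearest center; max
aggregation is available as an option). The ±4 ppm window matches the
annotation tolerance. The pipeline additionally subtracts, per pixel and
peak, the local median of the spectrum in a 0.3 Da window around the
center (floored at zero). 0.3 Da spans many FTICR-scale peak widths
(σ ≈ 8 ppm) while staying below the typical peak spacing, so the
estimate tracks the additive chemical baseline plus, at most, a term
proportional to the peak's own flank — a subtraction of the form
`c + γ·apex`, which removes the additive offset without disturbing
between-group intensity ratios. The `build_datacube()` default remains
the raw windowed sum; the subtraction is the pipeline's configured
choice (`baseline_window`).

## pLSA segmentation

The aspect model factorizes the non-negative cube, treated as
pseudo-counts, as

$$P(d, w) = \sum_z P(z)\, P(d \mid z)\, P(w \mid z)$$

over pixels $d$, peaks $w$ and latent components $z$ (tissue
compartments plus one background component). EM maximizes the
log-likelihood $\sum_{d,w} V_{dw} \log P(d,w)$; every probability
vector stays normalized to within 1e-9 and the log-likelihood trace is
non-decreasing (both asserted in tests). Initialization is a seeded
uniform Dirichlet draw; the fit is deterministic given the seed.

Numerical behavior worth knowing:

- The op-level convergence default (relative log-likelihood change
  below 1e-6) is too loose for cubes with thousands of pixels, where
  the log-likelihood magnitude is ~1e7 and weakly separated components
  are still resolving when the relative change crosses 1e-6. The
  pipeline therefore runs EM to 1e-8 with up to 1000 iterations.
- EM is a local optimizer. The pipeline fits `plsa_restarts = 5` seeded
  runs and keeps the best final log-likelihood; in our experiments the
  occasional inferior optimum (pixels of two compartments merged) is
  clearly separated in likelihood from the good one.
- On an exactly rank-1 table with two components, EM settles on the
  over-parameterized model's flat ridge at a reconstruction error
  around 1e-6 of the data scale rather than machine precision; tests
  assert reconstruction at that level.

The background component is identified as the one whose pixel
probability mass is most concentrated on off-tissue (mask background)
pixels; ties resolve to the lowest index. Peaks are associated to the
argmax of $P(z \mid w) \propto P(z) P(w \mid z)$ over non-background
components; pixels to the argmax of $P(z \mid d)$. Because component
order is arbitrary, evaluation against ground truth uses the best
injective label-to-component assignment (exhaustive over the handful of
compartments). A group-level pLSA on per-section ROI mean intensities
(two components) plays the role of a score plot separating the groups.

PCA is the column-mean-centered SVD with a deterministic sign
convention (each loading's largest-magnitude entry positive).

## Annotation

Theoretical m/z values are built from IUPAC monoisotopic atomic masses;
ion m/z includes the electron mass (0.00054858 Da), which is needed to
reproduce the 9-aminoacridine matrix ion at m/z 193.0771 to four
decimals. The five negative adducts are M-H, M-H2O (interpreted as the
deprotonated water loss [M−H2O−H]⁻, since a negative-mode ion needs a
net charge), M+K-2H, M+Na-2H and M+Cl. Every candidate within the
tolerance is kept and ranked by |ppm error|; downstream statistics
operate per peak, so annotation multiplicity is reporting metadata
only, with a deterministic best-candidate rule (smallest |ppm|, then
record id) where a single name is needed. Exogenous records (drugs,
pesticides, the MALDI matrix) are excluded from biological reporting.

Glycan fragments are annotated compositionally: residue counts (Hex,
HexA, HexNAc, HexN, dHex, NeuAc, NeuGc, Pen as dehydrated residues, one
water added back for a free reducing end) and modification counts
(sulfate, phosphate, acetyl), enumerated within finite bounds (capped
mixed-radix enumeration; exceeding the cap warns and truncates),
ionized as [M−H]⁻ only, and labelled `Hex1P2`-style with residues in
the fixed order above. Structure-level topology is out of scope.

The bundled metabolite table is a synthetic, desk-scale stand-in for
KEGG/HMDB records: 167 curated endogenous metabolites (covering
glycolysis, the pentose phosphate pathway, TCA, purine/pyrimidine
nucleotides, UDP sugars and both Kennedy-pathway branches, amino acids,
sulfur metabolism, cofactors, fatty acids and representative
phospholipids — including every metabolite central to pyrophosphate
production) plus 11 flagged exogenous decoys. Stored masses are frozen
from the formulas and re-derivable to 1e-6 Da.

## ROI statistics

The statistical unit follows the pixel-wise convention: group
comparisons pool ROI pixels within each group and test with the
two-sided Mann-Whitney U (exact p by enumeration when the pooled n ≤ 12
without ties, otherwise normal approximation with tie and continuity
correction). A per-section-mean test is reported alongside as the
pseudoreplication-safe alternative. Log2 fold changes are always
computed from per-section ROI means (robust to section-size imbalance),
reference group first. Volcano classification calls a peak up when
log2FC ≥ 1 and p < 0.05, down when ≤ −1, otherwise ns.

Two properties of pixel-wise testing deserve emphasis:

- With thousands of pixels, any systematic per-section offset (for
  instance section-level chemical noise) is treated as replicated
  evidence, so pixel-wise p-values reach zero easily; the fold-change
  cutoff is the effective guard, and the per-section test is the
  honest replication-level check.
- On a pooled multi-compartment ROI the rank test is *conservative*:
  the compartment composition of each section is essentially fixed, so
  the between-compartment contribution to the rank variance — which the
  U variance formula assumes free — is frozen. Type-I error control is
  preserved (in the conservative direction). The null-calibration
  experiment is therefore run on the homogeneous mineralized
  compartment, where exchangeability holds and the empirical fraction
  of raw p < 0.05 sits at the nominal level.

Kruskal-Wallis (tie-corrected H, chi-square p on k−1 df) with Dunn's
post hoc z-tests on pooled midranks, Benjamini-Hochberg adjusted across
pairs, serves comparisons of more than two compartments. Pathway
over-representation uses the hypergeometric upper tail with the
enrichment ratio observed/expected; the background is the set of
annotated endogenous metabolites detected in the experiment.

## Spatial correlation networks

Ion-image pairs of annotated metabolites sharing at least one pathway
are candidate edges; Spearman's rank correlation (midrank ties, t
approximation for p) is computed over the cortical ROI pixels of a
representative section. Nodes lacking any correlation at p ≤ 0.05
(unadjusted, as a deliberate convention) are dropped; kept edges carry
rho, p and |rho| — the weight a Compound-Spring-Embedder-style layout
would use — plus the shared pathway ids; nodes carry the metabolite
name, log2FC and a label flag at |log2FC| ≥ 1. With thousands of
pixels nearly every correlation is "significant"; an optional |rho|
floor is exposed (default 0). Layout itself is out of scope; the
GraphML (numeric attributes as decimal strings with 10 significant
digits) loads in igraph, Cytoscape and kin.

## The synthetic phantom

The generator emulates what the analysis assumes about a bone section,
with defaults defining the reference scenario: a 64 × 64 grid with a
mineralized cortical ring (outer radius 28 px, width 6), an osteoid
seam (width 3), a marrow core, and background outside; per-section
seeded jitter of center and radii; two groups × 5 sections; ~300 peaks
drawn from the reference table at exact adduct m/z (≥ 0.5 Da apart,
≤ 1 ppm calibration jitter); 20 up- and 15 down-regulated peaks at
|log2FC| = 3 planted on cortical-home peaks; multiplicative log-normal
pixel noise with CV 0.2 (positive, right-skewed, as MSI intensities
are); Gaussian peak shapes with σ = 8 ppm; and an additive baseline.

Design choices that make the phantom's physics coherent with the
pipeline rather than adversarial to it:

- **Heterogeneous base intensities.** Home-compartment bases cycle over
  3–500 a.u., two orders of magnitude, with planted-effect peaks pinned
  at the mid-range 20. Real spectra carry a stable tier of dominant
  ions; with that backbone the planted effects are a small fraction of
  spectral energy and RMS normalization is stable.
- **Quantitative compartment specificity.** A peak shows 30% of its
  home base in the other tissue compartments (≈3.3× enrichment) and
  0.5% on background. Metabolites are rarely compartment-exclusive,
  and this keeps every planted feature quantifiable in the cortical
  ROI, anchoring null fold changes near zero.
- **Matrix ions.** Background pixels carry the 9-aminoacridine ion at
  m/z 193.0771 and 12 matrix-cluster ions at off-database m/z, strong
  enough that off-tissue spectra have energy comparable to tissue — as
  MALDI backgrounds do. These drive the background pLSA component.
- **Baseline.** A per-section chemical-noise pattern (half-normal,
  σ = 0.3) shared by the section's pixels plus per-pixel white noise
  (σ = 0.1). Separately acquired sections have independent chemical
  noise; per-section draws average out of 5-section ROI means, and the
  shared-within-section part keeps mean spectra realistically rough.

Identical spec and seed give byte-identical imzML output.

What passing on the phantom does **not** show about real data: there
are no isotope envelopes, no detector saturation, no spatial
autocorrelation of noise, no section-level biological random effects
(so pixel-wise and section-level tests agree more than they would in
vivo), no mass-calibration drift beyond 1 ppm, and compartment
geometry is far cleaner than histology. Recovery rates on the phantom
are upper bounds, not forecasts.

## Problem sizes and determinism

The reference scenario (64 × 64 × 10 sections, ~300 peaks) runs the
full pipeline in a few minutes on one CPU; the test suite exercises a
32 × 32, 2 × 2-section, 60-peak phantom for the fast checks and the
reference scenario once for the end-to-end recovery checks. All
randomness — phantom geometry, noise, jitter, EM initialization — is
seeded, and rerunning any stage with the same configuration reproduces
outputs checksum-identically; every exported table carries the
configuration hash in its comment line.
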