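---
title: "Methods: signed-KS phenotypic profiling of compound panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signed-KS phenotypic profiling of compound panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`phenoks` quantifies how compounds perturb per-cell image-feature
distributions in an EGF-stimulated receptor-trafficking screen and groups
compounds by the similarity of their phenotype profiles. This vignette is
the package's own account of the method: the statistical model and its
assumptions, the segmentation scheme, the synthetic-data generator, the
parameter defaults, and the numerical decisions taken where the design
was genuinely open.

## 1. The profiling model

For each descriptor $d$ (one statistic of one channel over one cellular
region), compound $c$, time point $t$ and replicate experiment $r$, the
per-cell values of the treated cells are compared with the same
replicate's control (DMSO) cells by a signed two-sample
Kolmogorov–Smirnov statistic. With $D^+ = \sup_x(F_{ctl} - F_{trt})$ and
$D^- = \sup_x(F_{trt} - F_{ctl})$, both evaluated exactly at every pooled
sample point,

$$\mathrm{signed}\ D = \begin{cases} +\max(D^+, D^-) & D^+ \ge D^- \\
-\max(D^+, D^-) & \text{otherwise,} \end{cases}$$

so a positive sign means the treated distribution is shifted toward
larger values. The exact tie $D^+ = D^-$ takes the positive sign; for
continuous data this is a measure-zero case, and the implementation
computes the ECDF differences from integer counts so that exact ties stay
exact in floating point.

The KS statistic of a genuinely inactive compound still fluctuates with
sample size, so each signed $D$ is standardized by the SD of the same
statistic under the null, estimated by bootstrap resampling of the
control sample (`n_boot = 1000`):

$$Z_{d,c,t} = \mathrm{signed}\ D_{d,c,t} \; / \; \mathrm{Std}_{d,t}.$$

**Bootstrap comparator.** The default draws *two independent resamples*
of the control (each of the control's size, with replacement) per
iteration and takes the signed KS between them. A treated-vs-control
comparison at sizes $n \approx m$ has null fluctuation
$\propto \sqrt{1/n + 1/m}$; resampling a control of the same size against
its own ECDF (the `"resample"` option) captures only the one-sample term
$\propto \sqrt{1/n}$ and under-estimates the null SD by a factor
$\approx\sqrt2$, which would leave null Z-scores with SD $\approx 1.4$
rather than 1. The pair comparator reproduces the two-sample scaling, and
the package's calibration suite verifies that control-vs-control Z-scores
at $n = 600$ have mean in $[-0.2, 0.2]$ and SD in $[0.7, 1.3]$.

Under resampling, the null distribution of the statistic depends on the
control sample only through the multiplicity pattern of its sorted values
(for continuous, tie-free data it is fully distribution-free). Bootstrap
results are therefore memoized on that pattern: all continuous
descriptors at a given sample size share one computation. This is an
exact property, not an approximation; `cache = FALSE` disables it.

The null SD is computed per (descriptor, time, replicate) from that
replicate's own control cells, keeping each independent experiment's
Z-scores self-contained and the resample size equal to the comparison
size. Constant control samples give $\mathrm{Std} = 0$ and are flagged
degenerate; the affected descriptor is excluded downstream (never turned
into $\pm\infty$).

**Reliability filter.** A descriptor–time pair is retained only when the
Pearson correlation of its Z vector across compounds between the two
replicate experiments exceeds 0.4 (strictly). Columns with zero variance
or missing Z in either replicate have undefined $r$ and are dropped. The
filter is computed across the treated compounds only; the control's
held-out row (below) is not allowed to inflate the correlation.

**The Z matrix.** Rows are the compounds plus the control; columns the
retained (descriptor, time) pairs; replicate Z-scores are combined by
their mean (concatenation is available as an option). The control row
comes from a held-out random half-vs-half split of the control cells, so
it sits near 0 — note it is over-dispersed by $\approx\sqrt2$ relative to
compound rows because the split halves are half-sized; on the scale of
compound effects (|Z| of 5–40) this is negligible.

**Dimension reduction and clustering.** PCA centers the columns but does
not rescale them: Z-scores are already standardized by construction, and
rescaling would promote pure-noise columns to the same footing as strong
effects (correlation-mode PCA is available via `scale.`). The retained
components are the smallest set reaching 95% cumulative variance.
Compounds are clustered on the retained PC scores (unweighted) with
Euclidean distance and Ward's minimum-variance criterion
(`hclust(method = "ward.D2")`, merge height $=\sqrt{2\,\Delta SSE}$). The
tree is flattened below the largest gap between successive merge heights —
a reproducible stand-in for the by-eye dendrogram cut a screen analyst
would make; `fixed_k` overrides it. If every merge sits at height 0 (all
profiles identical) the rule returns one cluster.

`descriptor_correlation_clusters()` provides the complementary view:
Pearson correlations between descriptor–time columns across compounds,
clustered at distance $1 - r$, with group counts reported at the largest
gap (major groups) and at the largest gap below it (minor groups).

## 2. Segmentation and feature extraction

The region scheme follows the standard high-content convention:

* **nucleus** — Otsu threshold of the Gaussian-smoothed ($\sigma = 1$ px)
  DNA channel, hole filling, connected components, area filter,
  border-touching nuclei removed. Otsu was chosen because it is standard
  and parameter-free; a constant image yields zero nuclei (not an error).
* **cell** — seeded propagation from the nuclei across the receptor
  (GFP-EGFR-like) channel: each foreground pixel joins the seed with
  minimal accumulated step cost
  $(1-\lambda)\,|\Delta I| + \lambda\,\|\Delta p\|$ over 8-connected
  steps. Small $\lambda$ makes boundaries follow intensity ridges; large
  $\lambda$ approaches a nearest-seed partition. Default
  $\lambda = 0.05$. The foreground is Otsu on the receptor channel with
  hole filling; border-touching cells are kept (they carry PM signal).
  Cost ties between seeds are resolved by a fixed neighbour scan order,
  so results are deterministic; the implementation is a label-correcting
  relaxation whose converged costs equal the Dijkstra shortest-path
  costs, and tests assert exactly that on small images.
* **cytoplasm** $=$ cell $\setminus$ nucleus, exactly (a pixel-set
  identity asserted in tests).
* **perinuclear** — nucleus dilated by a Euclidean disc of radius
  `expand_px` (default 7 px), minus the nucleus, clipped to the cell.
* **PM** — cell minus its erosion by a disc of radius `shrink_px`
  (default 5 px); when the erosion empties (radius beyond the inradius)
  the PM ring is the whole cell. The expand-7/shrink-5 defaults follow
  the more detailed of two conflicting published conventions
  (7-px nucleus expansion, 5-px cell shrinkage); both radii are plain
  arguments, and "pixels" are interpreted as the structuring-element
  radius. Distances are computed within the image only — pixels beyond
  the border are neither foreground nor background — which matches the
  Euclidean distance transform used for the morphology and the
  brute-force enumeration oracle used to test it.

**Endosome detection** applies a grayscale white top-hat (image minus its
opening with a Euclidean disc, radius default 5 px; authored in the
package as a min/max filter because the available image library's
morphology is binary-only), thresholds the enhanced image, labels
connected components and assigns each object to the cell and region
containing its centroid (priority PM > perinuclear > cytoplasm >
nucleus where rings overlap; an object straddling rings counts once). The
default threshold is mean $+ 3\,$SD of the top-hat *background*, defined
as the positive response below its 90th percentile — flat regions respond
exactly 0 and carry no information about the response floor — with two
robustness guards: a floor of $10^{-6}\max(\text{tophat})$ against
numerical residue on noise-free images, and a minimum object area of 4 px
against sub-resolution fragments. On structured images with a bright
membrane band the adaptive rule is deliberately conservative; the
absolute `min_intensity` override is then the calibrated choice (for the
package's own rendered fields, half the spot amplitude).

**Descriptors.** Integrated intensity is the exact pixel sum over the
region, mean is sum/area (zero-area regions give missing values), counts
come from the endosome objects, colocalization counts objects of channel
A whose pixel overlap with the union of channel-B objects reaches
`min_overlap_frac` of the A-object's area, and the perinuclear/PM ratio
divides the two per-cell pixel sums (cells with an empty PM sum are
flagged and excluded from ratio statistics). The per-batch
perinuclear-vs-PM regression slope is ordinary least squares *with*
intercept — the published analysis says only "regression coefficient",
and an intercept-free fit would force the line through the origin for no
physical reason. The default catalogue (26 descriptors: region × channel
means, whole-cell integrated intensities, endosome counts, one
colocalization count, one ratio) is a documented, configurable stand-in:
the original screen's full descriptor list is not public, so the
catalogue size is a free parameter, not a claim.

## 3. What the synthetic generator emulates

`generate_panel()` draws one batch per (compound, time, replicate) —
default 14 compounds + DMSO, times 0/5/30/60/180 min, 2 replicates, 600
cells per condition (within the 500–1000 cells a screen typically pools
per well). Everything is a pure function of the config and `rng_seed`,
with per-batch substreams so results do not depend on execution order.

* **Control kinetics.** Intensities are log-normal (positive,
  right-skewed, CV 0.35 — multiplicative cell-to-cell variation), counts
  Poisson. After stimulation the receptor channel's perinuclear/PM ratio
  rises to a maximum at 30 min and then decays while total receptor
  declines (degradation); pERK peaks at 5 min, pAkt at 5–30 min; the
  transferrin-like marker stays largely at the PM. The schedules are
  piecewise-linear interpolations between anchor time points, not a
  mechanistic ODE — the shape, not the biochemistry, is what downstream
  statistics see.
* **Compound effects.** A mechanism archetype assigns each descriptor a
  location shift (in control-SD units) and a scale factor; treated values
  are $m + (x - m)\,s_{\text{eff}} + \delta_{\text{eff}}\,\sigma$,
  clamped at 0 (counts shift the Poisson rate by
  $\delta\sqrt\lambda$ analogously). Effects switch on after stimulation
  (0 at 0 min, 70% at 5 min, full from 30 min) and are scaled by a
  deterministic per-compound potency (0.9/1.0/1.1 cycling), giving
  within-group spread. The four default archetypes — null, Akt-axis
  block, receptor block, trafficking block — touch distinct descriptor
  blocks at 0.3–1.8 SD so the groups are roughly equidistant in Z space;
  the effect sizes are free generator parameters, not claims about real
  compounds.
* **Image mode** renders fields of deformed-ellipse cells with
  concentric nuclei, perinuclear/PM-weighted receptor signal,
  PM-retained transferrin, Gaussian endosome spots ($\sigma = 2$ px,
  optionally colocalized across channels), diffraction-like structural
  blur, flat background and optional Gaussian read noise. Ground truth
  (masks, spot coordinates and counts) exactly matches the rendered
  content. Image-mode compound effects map onto a reduced set of
  rendering knobs and are coarser than feature-table mode.

**What it does not emulate:** illumination gradients and their
correction, mitotic/apoptotic outliers, cell-cycle structure, texture or
shape phenotypes, spatial correlation between neighbouring cells, channel
bleed-through, or the original screen's exact descriptor list. Passing
the recovery suite therefore shows the pipeline is correct and calibrated
under its stated noise model — not that it would survive every artifact
of real microscope data.

## 4. Numerical choices and problem sizes

* Exact KS ties are handled through pooled ECDFs evaluated at ends of
  tied runs; integer-count arithmetic keeps $D^+ = D^-$ ties exact.
* PCA "non-zero" components are eigenvalues above
  $10^{-9}\,\lambda_{max}$; full reconstruction is verified to
  $\|residual\|/\|Z\| < 10^{-8}$.
* Degenerate inputs: constant images segment to zero nuclei; no seeds
  propagate to an empty labeling; zero detected endosomes is a valid
  result; degenerate null SDs and undefined reliability correlations drop
  the descriptor with a logged report instead of erroring the run.
* The test suite verifies the oracles at deliberately small sizes where
  brute force is exact: 1000 random KS pairs at $n \le 20$, exhaustive
  Ward merging at $n \le 7$, Dijkstra propagation on $18\times18$ grids,
  pixel-enumeration morphology on $\le 40\times40$ masks. The end-to-end
  recovery suite runs the full default panel (600 cells/condition,
  `n_boot` 1000) over 20 seeds and requires four main clusters and
  adjusted Rand index $\ge 0.8$ against the generator's groups in at
  least 90% of them; null calibration uses 200 control-vs-control trials
  at $n = 600$. These sizes were chosen so each property is tested at
  full fidelity while the whole suite stays comfortably interactive.

## 5. Known limitations

* The propagation cost functional is a reconstruction of the qualitative
  behaviour of seeded-propagation segmentation (boundaries follow
  intensity ridges, distance fallback), not a bit-exact port of any
  particular implementation.
* The reliability filter assumes exactly two replicates, as in the
  original design; more replicates currently require pairwise use.
* The adaptive endosome threshold is tuned for spot-on-smooth-background
  images; strongly textured channels need the absolute override.
* The largest-gap cut can undersplit when true groups are at very
  different mutual distances; `fixed_k` is the escape hatch, and the
  merge-height profile in `plot(fit)` is the diagnostic.
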