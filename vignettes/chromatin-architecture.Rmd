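---
title: "Chromosome architecture analysis with hicarch: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome architecture analysis with hicarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicarch)
```

# Scope

`hicarch` implements a single-chromosome Hi-C architecture workflow:
contact-matrix normalization, per-bin directionality and insulation
tracks, per-domain diamond and corner scores, consensus TAD calling
with diamond-score/size/density filters, loop filtering and
loop-domain annotation, k-means classification of TAD borders by
directionality-index (DI) asymmetry, rescaled aggregate-TAD maps,
A/B compartment score projection, and spike-in scale factors.  A
seeded generator plants all of these structures so that every analysis
step is validated against known truth.  This vignette records the
models, the tunable parameters, and the design decisions taken where
the methodology left choices open.

# The data model

A chromosome is tiled into fixed-width, 0-based half-open bins
(`bin_table`).  Contacts are stored as upper-triangle triplets
`(i, j, value)` (`contact_matrix`); the implied matrix is symmetric
and all operations are cis (per chromosome).  Missing bins — those
masked during normalization — propagate as *entry deletion*, never as
zeros, so unmappable and unobserved remain distinguishable.

# Normalization

Three per-bin weightings are provided (`compute_normalization`):

* **VC** (vanilla coverage): `w_i = c / rowsum_i`, with `c` chosen so
  the weighted total equals the raw total;
* **VC_SQRT**: `w_i = c / sqrt(rowsum_i)`;
* **balanced**: iterative proportional fitting until the relative
  standard deviation of non-missing weighted row sums drops below
  `1e-6` (cap 500 iterations).  This matches the equal-row-sum
  contract of Knight–Ruiz balancing while being simpler and
  well-conditioned at the scale this package targets.

Bins whose marginal falls below 2% of the median non-zero marginal
are masked before any weighting; the methodology we follow does not
state its sparse-bin rule, so this mirrors common practice.

# Domain metrics

**Directionality index.**  For each bin, `A` and `B` are the total
contacts with the 40 upstream and 40 downstream bins (400 kb at 10-kb
bins) and `DI = sign(B - A) ((A-E)^2/E + (B-E)^2/E)`, `E = (A+B)/2`.
The printed form has an indeterminate sign factor when `A = B`; we
define `DI = 0` there (a directionless bin).

**Insulation.**  The raw score of a bin is the mean contact in the
40×40 square that crosses it; the reported value is the log2 ratio to
the per-chromosome mean of the raw scores.  The reference normalization
(per chromosome vs genome) is not stated upstream; per-chromosome keeps
the track scale-invariant, which the tests assert directly.

**Diamond score.**  `DS = middle / (upstream + middle)`, where
`middle` sums the full intra-domain square and `upstream` the
rectangle against an equal-length upstream flank.  The published
equation's denominator uses only the upstream and middle areas even
though a downstream area is defined; we implement the equation as
printed and expose `variant = "symmetric"`
(`middle / (up + down + middle)`) for the alternative.  Flanks
truncated by a chromosome edge are rescaled by full/available area;
below 25% availability the downstream flank is used, and failing that
the domain is unscorable.  A featureless matrix scores 0.5; a 3-fold
enriched domain scores 0.75.

**Corner score.**  From the arrowhead transform
`T[i, i+d] = (M[i,i-d] - M[i,i+d]) / (M[i,i-d] + M[i,i+d])`, the
score contrasts the triangle of pixels just beyond each border whose
mirror pixel is intra-domain (positive at a true corner) against the
equal-height triangle just inside (near zero), averaging the two
borders; triangle height is capped at 20 bins.  The external
implementation this score emulates is not reproduced bit-for-bit —
only its ranking behavior is asserted (planted domains score above a
structureless null, rank test at α = 0.01).

# Consensus calling and filtering

The internal caller takes insulation minima with topographic
prominence ≥ 0.2 log2 units as borders.  The default prominence is
calibrated on the default fixture: compartment-scale insulation
wobble (~0.25 log2 units peak-to-trough at plaid amplitude 0.3)
must not split large domains, while true boundaries (prominence
≳ 0.5) must all pass.

Candidate sets from multiple callers are merged by pooling boundary
bins, chaining greedily left-to-right (a border joins a group when
within 4 bins, inclusive, of the group's last member — the grouping
topology is not specified upstream; greedy chaining is deterministic
after sorting), and replacing each group with its lowest-insulation
member (leftmost on ties).  Filters then remove domains with diamond
score < 0.6 or size < 100 kb, and domains whose mean intra-domain
*observed/expected* falls below the 5% quantile of the candidate pool.
Using O/E rather than raw counts for the density floor is deliberate:
mean raw counts fall with domain size under distance decay, so a raw
floor preferentially deletes the largest true domains; O/E density is
size-unbiased and still sends masked regions to ~0.  The pipeline
applies the density floor *before* the diamond filter, while the weak
calls that should anchor the quantile are still in the pool.

Two domain sets are compared by reciprocal overlap (`-f X -r`
semantics): a pair matches when the intersection covers at least the
stated fraction of both members.

# Loops and loop domains

Candidate loops (external caller output in BEDPE) are filtered by
anchor separation (≤ 2 Mb, midpoint distance) and by the
VC-normalized contact values in the pixel box spanned by ±5 kb around
both anchors: boxes whose minimum normalized value is below 1 mark
calls in sparse areas.  We read the "±5 kb surrounding
vanilla-coverage values" as matrix values rather than the raw
normalization vector because border-proximal bins *always* have
below-average marginals in an insulated genome — the vector reading
would veto every corner loop by construction, while the matrix reading
implements the stated purpose of the filter (suppressing false
positives of the upstream peak caller).  `stat = "mean"` is exposed
for fine resolutions where Poisson zeros populate larger boxes.

A domain is a **loop domain** when some loop places its first anchor
within `tol` of the 5′ border and its second within `tol` of the 3′
border, `tol = min(50 kb, 0.2 L)`.

# Border clustering and DI bias

Each domain yields a 20-column vector: DI at ±5 bins around the 5′
border, then ±5 around the 3′ border.  (Upstream text gives the bin
size of this window inconsistently as 10 kb and 5 kb; we use the
DI/TAD-calling resolution, 10 kb.)  Lloyd k-means with `k = 3` on the
raw vectors (no standardization) is restarted 100 times — a dozen
points in 20 dimensions trap a 10-restart run about once in ten — and
clusters are relabeled canonically by centroid asymmetry measured on
the border-proximal *inside* bins (columns 6–10 vs 11–15), where
one-sided extrusion shows; outside bins mostly carry neighbor signal.
Cluster 1 is 5′-dominant, cluster 3 is 3′-dominant.

`DI bias = log2(|mean DI of 3 bins right of the 5′ border| /
|mean DI of 3 bins left of the 3′ border|)`, windows strictly inside
the domain; `inset` moves both windows fractionally into the interior
for the interior-bias variant.  Cluster-2 members are ranked by signed
DI bias (ties by start coordinate) and split into five contiguous
groups whose sizes differ by at most one.

# Aggregation

Each domain window (domain plus 50% flanks) is resampled to a 90×90
grid by area-weighted averaging — the resampling conserves the window
mean to 1e-9, which a brute-force integration oracle asserts — then
averaged over domains and divided by the grand mean.  The upstream
description delegates grid and flank values to an external method
without parameters; 90/0.5 are the fixed exposed defaults.  For
knockdown-style comparisons, condition matrices are aggregated on the
*control* domain set and divided element-wise by the control map;
zero denominators yield missing values, never infinities.

# Compartments

The compartment chain is: reference vector → orientation → projection
→ normalization → A/B labels → switch tracking.

* The **reference vector** is the leading eigenvector of the Pearson
  correlation matrix of O/E columns — a stand-in generator for an
  external compartment-propensity tool, swappable for a file-based
  track.  A vector is flagged *degenerate* when the leading eigenvalue
  sits within 20% of the second (on the correlation-matrix eigenvalue
  bulk there is no two-state mode to report).  `min_separation`
  optionally neutralizes near-diagonal pixels before correlating.
* **Orientation**: the vector is negated if it anticorrelates with an
  active-mark coverage track, so positive = A (active).  Direction
  only; no magnitude reweighting.
* **Projection**: `score_i = sum_j OE[i, j] ref_j` transfers the
  reference orientation onto any stage's O/E matrix (each stage uses
  its own expected profile).
* **Normalization**: subtract the mean over defined bins, divide by
  the maximum absolute value.  Division by the max (rather than
  min–max rescaling) preserves zero as the A/B boundary; the upstream
  phrasing admits both readings.  The operation is idempotent.
* **Switching**: consecutive stage pairs classify each bin as
  stable-A/stable-B/A→B/B→A, excluding bins unlabeled in either.

# The synthetic worlds

The generator draws `Poisson(λ_ij)` over the upper triangle with
`λ_ij = depth (1+d)^-α · tad · loop · compartment · asymmetry ·
boundary`, mirrored to a symmetric matrix; a seed makes every world
bit-reproducible.

**Default (TAD) fixture** (`default_fixture_spec`): 1,000 bins of
10 kb, `α = 1`, depth 30 at 1-bin separation; 12 domains of 40–120
bins (fold 2–3) separated by 4-bin unorganized spacers; 4 corner
loops (fold 8 on a 3×3 pixel block); a 50-bin alternating compartment
profile at amplitude 0.3; and a 3/6/3 split of 5′-biased / symmetric /
3′-biased domains.  Choices that deserve justification:

* *Spacers and boundary regions.*  Real TADs are separated by
  boundary regions, not mathematical points, and the insulation
  statistic at a 40-bin block cannot localize a boundary inside a
  featureless spacer more finely than the spacer itself.  Planted
  border positions are therefore the spacer midpoints, and planted
  **territories** (what a caller can delimit) extend to those
  midpoints; with 4-bin spacers any minimum inside the spacer is
  within the ±2-bin recovery tolerance.  Spacers also keep a domain's
  border-window DI features from being dominated by its neighbor's
  class — with zero-width shared borders the three asymmetry classes
  are not identifiable from ±5-bin windows even in principle.
* *Boundary elements.*  Contacts crossing a planted boundary are
  depleted ×0.7 per crossing, saturating at two crossings.  This is
  the extrusion-blocking insulation of real boundaries; it pins the
  insulation minimum at the boundary (without it, balancing-induced
  weight dips at stripe onset bins displace minima into domains), and
  the saturation leaves long-range, compartment-driven contacts with
  their relative structure intact.
* *Asymmetry as stripes.*  A 5′-biased domain multiplies the contacts
  of bins near its 5′ border by a factor declining linearly to 1 at
  the 3′ border (magnitude 4, onset 1 bin inside the border so the
  boundary bin itself stays depleted) — the intra-domain signature of
  one-sided loop extrusion, which produces one-sided DI, one-sided
  border signal, and stripe-like aggregates.  Magnitude 4 makes class
  membership, not the sampled per-domain strength, the dominant
  direction in DI feature space; at 3 the strength draw occasionally
  masquerades as a class.
* *Weak compartments.*  Amplitude 0.3 (same/cross contact fold ~1.2)
  reflects embryonic chromatin with emerging compartments and — more
  practically — is as strong as the plaid can be before
  compartment-scale insulation wobble starts splitting large domains
  during border calling.

**Compartment fixture** (`compartment_fixture_spec`,
`compartment_stage_series`): 1,000 bins of 25 kb, depth 100, no TADs,
50-bin (1.25-Mb) blocks at amplitude 0.6 (same/cross fold ~1.8, the
plaid contrast of differentiated tissue).  Compartment recovery,
projection self-consistency and switch tracking are validated here.
This split mirrors the methodology itself, which calls TADs at 10 kb
and compartments at 25 kb: at 10-kb/depth-30 sparsity the long-range
plaid is statistically invisible (per-pixel signal-to-noise ~10⁻³),
and raising the amplitude until it is visible corrupts border calling.
**A green compartment test therefore establishes recovery in a
compartment-scale world, not at TAD-calling sparsity.**

**Signal tracks** are Poisson with Gaussian border peaks (sd 1 bin);
with `asymmetric = TRUE` the designated border's enrichment is
multiplied by the domain's asymmetry magnitude.  **Spike-in counts**
split a total binomially so the expected target/spike ratio equals the
planted one.

What the generator does *not* emulate: mappability and GC coverage
bias, nested domain hierarchies, negative-binomial overdispersion
(Poisson is sufficient for recovery testing and has one fewer
parameter), trans contacts, and polymer physics.  Green tests
establish that the pipeline recovers what was planted under Poisson
sampling — not performance on real libraries.

# Numerical choices and degenerate inputs

* Balancing tolerance 1e-6 (relative SD of row sums), cap 500
  iterations; non-convergence returns with the statistic set and a
  warning.
* All-zero matrices normalize to all-missing with a warning; empty
  domain sets flow through merging/filtering; an impossible filter
  threshold yields an empty report rather than an error.
* Ties: lowest-insulation border groups take the leftmost bin;
  DI-bias ranking ties break by start coordinate; `DI = 0` when
  `A = B`.
* The switch-recovery tolerance is 0.05 absolute: per-stage A/B
  misclassification (~1%) dominates the binomial standard error of
  the planted fraction (~0.01).

# Known limitations

* The consensus machinery assumes one chromosome per matrix; multi-
  chromosome runs loop externally.
* The internal insulation caller is plumbing, not a reimplementation
  of any published caller; real analyses should feed external calls
  through the same merge/filter chain (BED in, BED out).
* The "adjusted DI" domain variant mentioned upstream is undefined
  there and not implemented; `di_bias(inset=)` covers the interior
  variant with the same formula.
* Aggregate maps are emitted as TSV grids; no image rendering.
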