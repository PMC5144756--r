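---
title: "Building and applying data-driven fiber-cluster atlases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and applying data-driven fiber-cluster atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Whole-brain tractography reconstructs hundreds of thousands of streamlines
("fibers") per subject from diffusion MRI. Identifying named white-matter
tracts — the corticospinal tract that carries motor signals, the C-shaped
arcuate fasciculus that links language areas — in an individual patient is
traditionally manual: an expert draws regions of interest and prunes
spurious streamlines. `tractatlas` automates this with a *fiber-cluster
atlas*: a data-driven parcellation of the white matter learned from a group
of subjects, which can then be applied to a new subject — including one
whose anatomy is distorted by a tumor — to recover the same clusters and,
through an anatomical hierarchy, the named tracts they compose.

The pipeline has four stages, each exposed as ordinary R functions:

1. **Groupwise registration** (`register_groupwise`, optionally
   `register_groupwise_bspline`) aligns all training subjects into one
   unbiased common frame.
2. **Spectral clustering** (`build_atlas`) embeds the pooled fibers with a
   Nyström approximation, clusters them with k-means, and iteratively
   rejects outlier fibers.
3. **Application** (`assign_subject`) registers a new subject to the atlas,
   embeds its fibers out-of-sample, assigns each to the nearest cluster and
   flags outliers against the stored cluster statistics.
4. **Evaluation** (`signed_distance_volume`, `tract_min_signed_distance`,
   `consistency_summary`, `tract_volume`) quantifies tract-to-activation
   colocalization and cluster consistency.

## Fiber similarity

Every comparison between two fibers starts from equal-arclength resampling
to `n_points` (default 15) points. The default distance is the *mean
corresponding-point distance*, minimised over forward and reversed point
order so it is orientation invariant; a symmetrised *mean closest-point*
distance is available as an alternative. Distances are mapped to
affinities with a Gaussian kernel,

$$a(f_i, f_j) = \exp\!\big(-d(f_i, f_j)^2 / \sigma^2\big),$$

so that $a = 1$ for identical fibers. With `bilateral = TRUE` the distance
is the minimum over the direct comparison and the comparison with the
mirror image across the midsagittal plane $x = 0$ (equivalently, the
maximum of the two affinities). Mirror-symmetric structures therefore
become mutual neighbours and clusters form *bilaterally* — one cluster per
anatomical structure, covering both hemispheres — which is what lets a
left-hemisphere tract be recognised even when its right twin is distorted.

The resampling count trades fidelity against the $O(n^2)$ point
comparisons inside the distance; fibers at the 40–120 mm scale are smooth,
so 15 points recover lengths to well under 1% and the pairwise distance
kernel (implemented in C++) dominates the run time.

## Entropy-based registration

Registration maximises the kernel-density overlap between a moving fiber
set and a pool: the cost of a transform is

$$-\sum_{i \in \text{moving}} \log\Big(\tfrac{1}{|P_i|}\sum_{j \in P_i}
\exp(-d(f_i, f_j)^2/\sigma^2) + \varepsilon\Big),$$

where $P_i$ excludes fibers from the moving fiber's own subject in the
groupwise setting, and $\varepsilon = 10^{-12}$ guards the logarithm when
every affinity underflows. The schedule of kernel widths runs from 20 mm
down to 2 mm (default 20, 10, 5, 2): wide kernels give a smooth, almost
convex landscape for coarse alignment; narrow kernels sharpen the optimum.

The optimizer is a derivative-free per-parameter line search over
parameter groups (translation, then rotation, then log-scale, then shear),
with steps that halve every sweep and only cost-decreasing moves accepted —
so the objective is non-increasing along the accepted trajectory by
construction. Rotation, scale and shear act about the moving set's
centroid, which decouples them from translation. The objective is cheap
but not differentiable in any useful closed form, which is why a
pattern-search scheme is used rather than a gradient method.

Groupwise registration sweeps the subjects in turn, registering each
against the pooled others, and after every sweep composes all transforms
with the inverse of their elementwise average. Two consequences matter:

* the group-average transform is the identity *exactly* at the end
  (unbiasedness — no subject defines the frame and the group cannot
  drift); and
* only relative alignment is identifiable. A groupwise method can recover
  the per-subject transforms only up to one global transform of the whole
  group. The synthetic cohort generator therefore centres its per-subject
  affine jitters so that the mean *inverse* jitter is the identity; under
  that convention the consensus frame of a perfect registration coincides
  with the template frame, and inverse-recovery error can be read directly
  as mean point displacement (about 0.4 mm on the default toy cohorts).

The optional b-spline stage refines each subject with a cubic free-form
displacement field over the group bounding box, coarse-to-fine control
grids ending at 8×8×8 by default. Control-point displacements are capped
at 0.4× the control spacing, a standard folding guard. The pattern-search
step is scaled to the current kernel width rather than the (much coarser)
control spacing, since the residual misalignment after the affine stage is
a few millimetres.

## Nyström spectral embedding and clustering

Clustering all pooled fibers directly would need the full $N \times N$
affinity matrix. Instead, `nystrom_m` sample fibers (2500 at the default
operating point) are drawn; their affinity matrix $A$ is scaled
normalized-cuts style, $D^{-1/2} A D^{-1/2}$, with degrees estimated as the
mean affinity of each sample to the full pooled set (a Nyström estimate of
the full-graph row sums, exact up to an irrelevant constant factor). The
top `n_eigenvectors` eigenpairs define the embedding basis. Any fiber —
training or new — is embedded by its affinity row to the sample fibers,
degree-normalized, projected on the eigenvectors and scaled by the
reciprocal eigenvalues. Embedding vectors are then normalized to unit
length before k-means, the standard final step of normalized spectral
clustering: it makes cluster membership depend on embedding *direction*
rather than on how central a fiber is, and empirically it is what keeps
well-separated synthetic bundles from splitting. With `nystrom_m` equal to
the pool size the construction reproduces dense normalized spectral
clustering exactly (the test suite checks agreement to machine precision).

k-means uses a seeded k-means++-style initialisation with 10 restarts,
keeping the best within-cluster sum of squares; labels are canonicalized
by descending cluster size so runs are comparable. Everything downstream
of a seed is deterministic, and rebuilt atlases are bitwise identical.

Outlier rejection then alternates with clustering: each fiber's
probability is its mean affinity to the other fibers of its cluster,
excluding its own subject (leave-one-out across subjects), so a spurious
fiber present in only one subject scores low even if it has look-alikes
within its own subject. Fibers below the cluster mean minus
`outlier_threshold_sd` (default 2) standard deviations are dropped, the
surviving sample fibers are re-used as the Nyström basis, and the
survivors are re-embedded and re-clustered. Two rounds are the default.
Per-cluster probability means and standard deviations from the final
round are stored in the atlas; at application time a patient fiber is
flagged as an outlier when its mean affinity to the atlas's kept sample
fibers of its assigned cluster falls below the same threshold. Exclusion
by subject is impossible at application (there is one subject), which is
why the stored cluster statistics take that role.

### Default operating point

| parameter | default | meaning |
|---|---|---|
| `k` | 800 | clusters in the parcellation |
| `nystrom_m` | 2500 | Nyström sample fibers |
| `fibers_per_subject` (clustering) | 10,000 | per-subject sample, i.e. 12.5 fibers per cluster per subject |
| `min_fiber_length` (clustering) | 60 mm | drops short-range connections |
| `fibers_per_subject` (registration) | 20,000 | per-subject registration sample |
| `min_fiber_length` (registration) | 40 mm | registration length threshold |
| `sigma_schedule` | 20, 10, 5, 2 mm | multiscale registration kernels |
| `bspline_grid` | 8×8×8 | final free-form control grid |
| `sigma_cluster` | 30 mm | clustering kernel width |
| `n_eigenvectors` | 20 | embedding dimensionality |
| `outlier_rounds` / `outlier_threshold_sd` | 2 / 2 | rejection schedule |

The clustering kernel width and embedding dimensionality are exposed
because no single value suits every dataset: 30 mm matches bundle-scale
separation for 40–120 mm fibers, and 20 eigenvectors is a practical
dimensionality for an 800-cluster parcellation. On the six-bundle toy
cohorts used in the tests, `k = 6` with 8 eigenvectors is the analogous
configuration. Where only the endpoints of the kernel schedule are fixed
by the method (20 mm down to 2 mm), the intermediate ladder (10, 5) was
chosen once as a roughly geometric progression for coarse-to-fine
stability. The number of sweeps per kernel level
(`max_iterations_per_stage`) defaults to 3, and the registration fiber
subsample is drawn once per run (not per iteration) so that runs are
reproducible functions of their seed.

## Atlas application and tract extraction

`assign_subject` runs: affine registration of the subject to the atlas
sample fibers (the application path is affine-only by default; the
b-spline stage exists for atlas construction), embedding of all fibers at
least as long as the atlas minimum, nearest-centroid assignment in
embedding space, probability/outlier evaluation against the stored
cluster statistics, and hemisphere labelling. A fiber is `"left"` when at
least 80% of its points lie at $x < 0$ in the atlas frame, `"right"`
symmetrically, otherwise `"commissural"`; the threshold is exposed since
any hard rule is a convention. A cluster is "present" in a subject when
at least `min_fibers` (default 1, the most permissive reading of
"detected") non-outlier fibers are assigned to it.

Hierarchies are plain JSON trees — named nodes with either children or
leaf lists of cluster indices; a cluster may serve several nodes.
`select_tract` unions the non-outlier fibers of a node's transitive leaf
set, optionally filtered by hemisphere, in either the subject's native
frame or the atlas frame (the subject→atlas affine is stored with the
assignment, so the two selections map onto each other exactly).

## Evaluation against activation masks

Colocalization with functional MRI is summarised by the *minimum signed
distance* from a tract to an activation mask: negative when the tract
penetrates the activation (magnitude = maximum depth), positive when it
does not (magnitude = closest gap). The mask's signed distance field is
computed with an exact separable Euclidean distance transform on voxel
centres, honouring anisotropic voxel sizes; fibers are resampled to ≤1 mm
steps and the field is interpolated trilinearly. Distances are thus taken
to the mask's voxel discretization rather than to a triangulated surface;
the two differ by at most about half a voxel, which is within the
reporting precision of the statistic. Boundary contact (distance exactly
0) counts as intersecting. Tract volumes are voxel counts (default 2 mm
grid) over points resampled at half the voxel size, in cc; the voxel size
is a parameter because the volume of a thin structure depends on it.

## The synthetic test surface

`make_bundle` / `make_subject` / `make_cohort` generate the entire test
surface; no imaging data ships with the package. A bundle is a parametric
centerline (straight, gentle arc, or half-turn C — caricatures of
association, projection and arcuate-like geometry) plus per-fiber smooth
offsets: Gaussian control offsets (scale = `dispersion`, default 2 mm)
spline-interpolated along arclength, so fibers are parallel-ish and
bundle-like rather than white noise. The default six bundles sit at
brain-like coordinates with ≥45 mm separation, mirrored across $x = 0$.
Subjects of a cohort share one template fiber draw — so inter-subject
geometry is known exactly — while planted outliers (smooth random
polylines spanning the bounding box, labelled −1) are drawn per subject,
mimicking spurious fibers that appear in only one subject. Per-subject
affine jitters default to ±10 mm translation, ±10° rotation and 0.9–1.1
scale, centred as described above. The tumor model deletes every fiber
entering a sphere and pushes surviving points radially outward with a
Gaussian falloff — a deliberately simple disruption-plus-mass-effect
caricature meant to test assignment robustness, not biophysics.

What passing these tests shows — and does not show: the synthetic cohorts
have exactly repeated anatomy, well-separated bundles, no crossing or
fanning fibers, no length-distribution skew, and affine-plus-smooth-warp
inter-subject variation only. Success on them validates the machinery
(registration recovery, embedding correctness, outlier logic, bookkeeping
across frames), not clinical-grade performance on real tractography.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on deliberately small
instances: 3–5 subjects, 6 bilateral bundles of 12–15 fibers each,
Nyström samples of 300–400, toy masks up to 40³ voxels. These sizes were
chosen so the full suite completes in about a minute while still
exercising every code path at meaningful signal-to-noise; all scores
(ARI = 1.0, 100% outlier rejection, sub-millimetre registration recovery)
are stable across seeds at these sizes. Other numerical conventions:
voxel indices are 0-based when mapped through affines; TrackVis "voxmm"
coordinates are divided by voxel size and sent through the header affine
(no half-voxel shift, so voxel (0,0,0) maps to the affine translation
column); k-means ties break on first occurrence; degenerate inputs
(zero-length fibers, empty masks, empty tractograms) raise errors rather
than propagate NaN; a fiber with no affinity to any basis sample embeds
at the origin and is flagged rather than dropped silently.

## Known limitations

* The b-spline stage optimises control points by pattern search; it is
  effective for smooth few-millimetre warps but slow for dense grids, and
  it provides no diffeomorphic guarantee beyond the displacement cap.
* Grid (b-spline) transforms cannot be inverted; mapping atlas-frame
  results back to subject space uses the affine only.
* The per-fiber distance ignores fiber-local features (curvature,
  diffusion indices); two geometrically coincident tracts are one cluster.
* Hemisphere labelling assumes the midsagittal plane is $x = 0$ in the
  atlas frame, which holds for the synthetic cohorts by construction and
  for real data only after adequate groupwise alignment.
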