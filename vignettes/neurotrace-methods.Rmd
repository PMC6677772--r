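---
title: "Methods: segment-wise image-quality profiling and collaborative reconstruction QC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segment-wise image-quality profiling and collaborative reconstruction QC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotrace)
```

# The problem

Tracing the complete three-dimensional morphology of a single neuron from a
whole-brain light-microscopy volume is hard precisely where the image is
bad: punctuated axons, weak signal over a high noise floor, and densely
intermingled fibers. `neurotrace` provides the headless computational core
of a reconstruction-QC workflow around that fact: it quantifies, per
neurite segment, how hard the underlying image is; it compares repeated
reconstructions of the same neuron; and it makes multi-annotator
collaborative annotation a deterministic, replayable process rather than a
pile of diverging files.

Everything operates on two standard objects: an SWC reconstruction (a
rooted tree of nodes `id type x y z radius parent`) and a 3-D grayscale
volume (TIFF stack, NRRD, or a raw+JSON pair), with coordinates in voxel
units unless the SWC header declares micrometers. The package never
converts units silently; it carries the flag.

# Segment decomposition

A reconstruction is decomposed into *segments*: maximal node paths bounded
by a pair of critical points — the soma (the root node, whatever its SWC
type code), branch points (two or more children), and terminal tips — with
only pass-through nodes in between. The decomposition partitions the
tree's edges exactly once, so segment lengths sum to the total cable
length; the test suite asserts this conservation to a relative 1e-9 over
hundreds of seeded random morphologies. Zero-length edges (coincident
consecutive nodes, which real tracings contain) are permitted and
contribute zero length. Forests parse fine, but operations that need a
single root refuse them with a typed error instead of guessing a root.

# The segment SNR statistic

For a segment embedded in its volume:

* **Foreground** `F` — the voxels whose centers lie inside the
  sphere-swept tube around the segment's polyline. A voxel center is
  inside when its distance to the polyline is at most the node radius
  linearly interpolated at the nearest polyline point. Distances are exact
  per linear piece with endpoint clamping; the nearest piece is chosen by
  minimum distance with ties broken by piece order, so the voxel set is
  deterministic.
* **Background** `B` — the segment's axis-aligned bounding box (every node
  position expanded by that node's radius, plus a configurable margin,
  default 0) minus the foreground.
* **Critical background** `B_crt` — the brightest 20% of `B`
  (`ceiling(0.2 |B|)` voxels, minimum 1; ties broken by ascending linear
  voxel index after descending intensity). Taking the brightest fifth
  rather than all of `B` makes the noise estimate conservative: it is the
  part of the background an annotator actually confuses with signal.

The segment SNR is

$$\mathrm{SNR} = \frac{\bar F}{\bar B_{\mathrm{crt}} + \varepsilon},$$

with ε a small stabiliser (default 1e-6; configurable). SNR is computed on
raw stored intensities — no normalisation — so it is invariant (up to
O(ε)) under global intensity rescaling.

Segments are classified into four ranges, right-closed at each boundary:
**very low** (−∞, 1.0], **low** (1.0, 1.2], **mid** (1.2, 1.4] and
**high** (1.4, ∞). The neuron-level summary is the segment SNR averaged
with length weights (a per-segment-count weighting is available as an
option but is not the default), together with:

* `vlsnr_portion` — the length fraction of the neuron in the very-low
  range;
* `basnr_portion` — the length fraction whose segment SNR falls below the
  neuron's own length-weighted SNR. "Average" here is deliberately the
  neuron's own weighted SNR; no external reference is defined.

Two boundary decisions deserve emphasis. First, when a whole neuron is
profiled, each segment's background excludes the voxelized foreground of
*every* segment, not only its own: near a branch point the sibling tube
runs through the bounding box, and counting the neuron's own bright signal
as "background" would inflate `B_crt` and bias SNR low. `profile_segment`
on its own still uses only the segment's own foreground (plus whatever is
passed in `exclude`). Second, segments clipped by the volume border are
profiled on their in-bounds part and flagged, rather than rejected; a
segment with no in-bounds foreground, or whose box is entirely foreground,
raises a typed degenerate-profile error and is reported (not silently
dropped) by `profile_neuron`.

## VR-usage analysis

When nodes carry a `gen_method` label (`VR` / `nonVR`, attributing each
edge to its child node), `vr_portion()` returns the length-weighted VR
fraction, and `correlate_portions()` fits the least-squares line of VR
portion on very-low-SNR portion across neurons and reports the Pearson
correlation — the question being whether immersive tracing effort
concentrates in the low-quality image regions.

# Reconstruction QC and comparison

* **Sharp turns** — at every node with a predecessor and a successor, the
  turning angle between the incoming and outgoing direction vectors
  (0° = straight, 180° = reversal), with an alert strictly above the
  threshold (90° and 135° are the conventional choices). A `window`
  parameter spans each direction vector over several edges to ignore
  node-level jitter. Angles are intrinsic, so alerts are invariant under
  rigid motions.
* **Sholl analysis** — crossings of concentric spheres centered at the
  soma; an edge crosses radius r when one endpoint is nearer than r and
  the other at r or beyond (half-open, so a node exactly on a sphere
  counts once).
* **Spatial apartness** — each tree's polylines are resampled at
  `sampling_step` (default 1 voxel) and each sample is measured to the
  nearest point on the other tree's polylines (exact point-to-piece
  distance, not node-to-node). The directed means are symmetrised, and a
  lateral (XY-plane) variant is always reported alongside the full 3-D
  value because tracing displacement is usually assessed in the imaging
  plane of the z-stack; whether "lateral" should exclude z is genuinely
  ambiguous, so both numbers are printed. Halving the sampling step moves
  the means by less than the step.
* **Length consistency** — across repeated reconstructions,
  `100 * (max − min) / mean` of total cable length.
* **Give-up rate** — failed attempts over all attempts for a tract.

# The pyramid store

Whole-brain volumes are consumed region-by-region, never whole. The
package's store writes `n_levels` resolutions of a volume into a
directory: level 0 is the source, bit-exact; level l+1 mean-pools 2×2×2
blocks of level l (partial boundary blocks averaged over their existing
voxels), rounding half-even for integer dtypes, so level dims follow
`ceil(d / 2^l)`. Mean pooling (not max) keeps downsampled intensities
representative for the mean-based SNR statistics. Chunks are raw
little-endian files `L{level}/{bz}_{by}_{bx}.bin` (x fastest, then y,
then z) beside a single `meta.json`; ROIs are half-open, 0-based, ordered
(z, y, x) everywhere in the package — stated at every interface because
the axis-swap bug is the classic failure of this code shape. Out-of-bounds
fetches are errors, never zero-padded: silent padding would corrupt the
background statistics computed on fetched blocks.

One subtlety: averaging partial boundary blocks over their existing voxels
reweights edge voxels at the next level, so the global mean is conserved
*exactly* only while every level's dims are even; the tests exercise the
exact invariant on power-of-two dims and the dims formula separately on
odd dims.

# Collaborative annotation

The collaboration engine is a pure state machine over a server-ordered
command stream — the transport is pluggable and the tests never open a
socket. Annotators connect (receiving a deterministic color from a fixed
32-entry palette by join order; reconnecting reuses the color), and every
edit is one of five command kinds (`add_segment`, `delete_segment`,
`add_marker`, `delete_marker`, `set_node_attr`) validated against the
current state, stamped with the next sequence number, applied, and
appended to a JSONL log whose first line is a versioned header carrying
the client registry. Client-local node ids are remapped to fresh global
ids server-side. Conflicting commands (deleting a node that is already
gone, labelling a missing node) are *rejected* without consuming a
sequence number: the underlying system describes queue ordering but no
reconciliation rule, so rejection is this package's choice — it keeps
replay total and deterministic, which is the property the tests pin down:
replaying a log reproduces the state byte-for-byte in the exported SWC,
regardless of client timing, and gapped or duplicated logs are refused.
Avatar position updates are ephemeral presence messages and never enter
the log. Wall-clock timestamps ride along in commands for audit but never
influence a transition.

# Synthetic data: what it emulates, and what it does not

`generate_morphology()` grows a single-root tree by a seeded random walk
(per-step angular jitter = tortuosity; a fixed number of bifurcation
events; reflection at the volume walls), and `render_volume()` turns a
tree into an fMOST-like phantom: constant background plus truncated
Gaussian noise, a tube signal composed by maximum where tubes cross
(crossing neurites brighten, they do not add without bound), per-edge
signal dropout emulating punctuated axons, bright Gaussian clutter blobs
with amplitudes between background and signal, and an optional 1-D
Gaussian blur along z for anisotropic depth resolution. Both generators
are pure functions of their spec and seed.

Default render conditions (background 100, tube amplitude 120, noise SD
15, dropout 0.1, 2 clutter blobs per 10³ voxels, z-blur SD 1, 64³ voxels,
uint16) sit deliberately in the "hard but traceable" regime: the designed
tube contrast of 2.2 lands in the high range, while noise, dropout and
clutter push individual segments down the scale.

The tube cross-section is a flat core at full amplitude by default, with a
`"gaussian"` radial-falloff mode available. The flat core is the
calibration mode: a neuron rendered noiseless at background b and
amplitude a profiles to a weighted SNR of exactly (b + a)/b (the tests
demand 1e-3), which a radial falloff would break by making the foreground
mean depend on tube radius. The phantoms do *not* model optics (no real
PSF), multi-channel acquisition, or spatially varying background, so a
passing suite says the statistics are computed correctly — not that any
particular real brain image will profile the same way.

The VR-correlation recovery study (50 simulated neurons whose designed
low-contrast segments are labelled VR, generating relation
vr = vlsnr) uses sparse, gently curved phantoms — tortuosity 6°/step,
segment length 18, radius 1, a 64³ field — because the study needs
spatially resolvable per-segment contrasts: in cramped, highly tortuous
trees, sibling tubes overlap right after a branch and max-composition
paints a designed-low segment bright, which is physically honest
(overlapping neurites genuinely mix signal) but confounds the designed
labels the study is trying to recover.

# Numerical choices and degenerate inputs

* SWC numeric fields are serialised with the shortest representation that
  round-trips doubles exactly, so write-then-read reproduces node tables
  bit-for-bit and exports are byte-stable across machines.
* ε defaults to 1e-6; the B_crt count is `ceiling(0.2 |B|)` with the
  deterministic tie rule above, because "the brightest 20%" leaves
  rounding and ties open and reproducibility demands a fixed answer.
* Turning-angle evaluation skips zero-length direction vectors (duplicate
  nodes) rather than emitting NaN alerts.
* Degenerate profiles, multi-root trees, out-of-bounds ROIs, palette
  exhaustion, out-of-order or gapped logs all raise *typed* conditions
  (`neurotrace_degenerate_error`, `neurotrace_structural_error`, ...), so
  callers and the CLI can map them to stable exit codes (0 success, 2
  usage, 3 input format).
* All randomized entry points require an explicit seed; the RNG kind is
  pinned so identical seeds give identical output across platforms.

Problem sizes throughout the test suite (volumes up to 64³, trees of a few
hundred nodes, 50–200 seeded replicates per property) were chosen as the
smallest sizes at which every statistic is exercised away from its
degenerate corners; the generators scale to larger fields if heavier
experiments are wanted.

# Known limitations

* The store is a desk-scale analogue of hierarchical whole-brain formats,
  not bit-compatible with any external tool's on-disk layout, and does no
  compression.
* Segment SNR depends on reconstruction correctness: a mistraced segment
  profiles the image under the wrong tube.
* The collaboration engine orders commands through a single sequencer;
  concurrent editing without a central server (CRDT-style) is out of
  scope, as is any authentication beyond a username.
* Multi-point soma contours are not modelled; the root node is the soma.
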