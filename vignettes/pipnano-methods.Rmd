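---
title: "Methods: nanodomain analysis of coarse-grained membranes and fluorescence data"
author: "PIPNano authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanodomain analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PIPNano)
```

# Scope and model of the data

PIPNano analyzes cation-induced PI(4,5)P₂ nanodomains at two levels:
coarse-grained (Martini-style) membrane configurations, and fluorescence
spectroscopy observables (steady-state anisotropy, TCSPC lifetimes,
thermal transitions). A configuration is a `MembraneFrame`: an
orthorhombic box (lengths in nm) plus beads grouped into lipids, with a
per-species topology that names the headgroup beads, the phosphodiester
bead (`PO4`, common to all species in scope), and the acyl chains as
ordered bead lists from the glycerol end. Coordinates are stored in nm
internally; PDB input (Å) is converted on load. Only orthorhombic boxes
are supported and triclinic input is rejected loudly — a silent shearing
error in periodic distances would corrupt every downstream cutoff-based
analysis, whereas a refusal is diagnosable.

All periodic geometry uses the minimum-image convention, which for an
orthorhombic box reduces to a per-axis wrap. In-plane (x, y) distances
are the default for lateral analyses because nanodomains are
leaflet-lateral objects.

## Leaflet assignment

Lipids are split into leaflets by the z position of one reference bead
per lipid (the phosphodiester bead by default, since every species in
scope carries one) relative to a **grid-local midplane**: the per-cell
mean reference-bead z over a coarse (4 nm) in-plane grid, with a
global-mean fallback for sparse cells. For flat membranes this reduces
to the global midplane; for undulating membranes it follows the
mid-surface, which keeps assignment correct up to amplitudes comparable
to the monolayer thickness. How strongly-undulating systems should be
assigned is genuinely open; the grid-local rule is this package's
choice, made explicit and tested against generated ground truth rather
than inherited from any published convention. Assignment is invariant to
rigid z-translation. If either side ends up empty, or the two groups'
mean separation from the midplane falls below 1 nm (roughly one thermal
width above the generator's bead jitter), the geometry is degenerate —
e.g. a monolayer — and an error is raised instead of a fabricated split.

# Cluster analysis

Two lipids of the selected species are adjacent iff **any pair of their
selected beads** lies within a cutoff under minimum image; clusters are
the connected components of that graph. Defaults: cutoff 0.6 nm with the
headgroup + phosphodiester bead set. The cutoff sits just beyond the
Martini first-neighbor shell (bond length 0.47 nm); because published
cluster-size analyses rarely state their contact criterion, both the
cutoff and the bead set are exposed parameters so sensitivity can be
tested. Cation beads never enter the adjacency definition — clustering
is defined purely lipid–lipid, with cation bridging implicit in the
geometry it produces.

Two cluster-size averages are computed and must be labeled in any
output: the number-weighted mean (Σs / k, monomers included; the
headline default) and the mass-weighted mean (Σs² / Σs). For sizes
{10, 10, 80} these give 33.33 and 66.0 — the distinction matters
whenever a few large clusters coexist with monomers, and published
average-size curves are often ambiguous about which is meant.
Correctness is pinned by two independent routes: planted-partition
recovery (the generator's ground truth must be recovered exactly
whenever gap > cutoff > intra-spacing) and equivalence with a
brute-force union-find over explicitly enumerated periodic images on
random frames.

# Order analysis

## S-value profiles

The S-value of a chain bond is the second Legendre polynomial of its
angle to the membrane normal, S = (3⟨cos²θ⟩ − 1)/2: +1 for bonds
parallel to the normal, −0.5 for in-plane bonds, 0 for an isotropic
sample (the magic angle cos²θ = 1/3). The bond-wise second-Legendre
convention against the global z axis (per-leaflet sign, which cos²
renders immaterial) is the standard coarse-grained "S-value"; local
normals from the curvature module are only needed for strongly
undulated systems, which the large flat systems of interest restrain.
Profiles index bonds from the glycerol end and carry standard errors
from the per-bond sample spread.

## Distance-resolved order

To quantify how PI(4,5)P₂ orders its POPC surroundings, each probe
(POPC) lipid is assigned the in-plane minimum-image distance from its
glycerol-proximal bead (GL1) to the **nearest PI(4,5)P₂ molecule** —
molecule-level, i.e. the minimum over that molecule's beads — within the
same leaflet. The S-value of the probe's first chain bonds is then
averaged per distance bin (default 0.2 nm bins to 3 nm, matching the
~1 nm range over which ordering effects concentrate and dissipate).
Empty bins are reported as missing (NA), never as zero order. Pooling
all bins must reproduce the unconditioned first-bond S — a conservation
check that guards against silent sample loss.

## Hexagonality

Gel (Lβ-like) phases pack extended acyl chains on a triangular lattice,
so each chain sees six neighbors at 60° spacing. Each chain is reduced
to its in-plane centroid; a chain is classified hexagonal iff it has at
least 6 neighbor centroids within 0.55 nm **and** its six nearest,
sorted by azimuth, show consecutive gaps of 60° ± 15°. The cutoff sits
between the gel lattice constant (0.48 nm) and the fluid chain spacing
(~0.8 nm); the tolerance accepts ±10 % thermal jitter of a true lattice.
Both are exposed parameters, and results record chain counts and all
thresholds, since published hexagonality counts rarely state whether
chains or lipids are counted or which thresholds were used (this
implementation counts chains). A deliberately excluded alternative is
the 2D hexatic ψ₆ order parameter: it measures bond-orientational
coherence, not lattice membership, and is not what a
"chains within hexagonal lattices" count reports. On a perfect 127-chain
hexagonal disc exactly the 91 interior chains (those with six in-lattice
neighbors) classify hexagonal, and the classification is invariant to
in-plane rotation of the whole lattice. A temperature-labeled series
adds a descriptive Spearman trend statistic.

# Surface analysis

Leaflet surfaces are gridded: cell height = mean reference-bead z
(periodic cell indexing, masked where empty). Mean curvature is
estimated by fitting the local quadratic Monge patch
z = ax² + by² + cxy + dx + ey + f to occupied cells within a 2.5 nm
radius and evaluating

H = (a(1 + e²) + b(1 + d²) − c·d·e) / (1 + d² + e²)^{3/2},

the full first-fundamental-form expression, which is exact for tilted
planes (H ≡ 0 whatever d, e). Grid-based local fits were chosen over
triangulated-surface curvature-tensor methods because they are
self-contained and analytically verifiable against closed forms: a
sinusoid of amplitude A and wavelength L has crest curvature
−A(2π/L)²/2 (−0.0316 nm⁻¹ for A = 1, L = 25), and a spherical bowl of
radius 10 nm has H = +0.1 nm⁻¹. **Sign convention:** H carries the sign
of the height Laplacian — a crest bulging toward +z has H < 0, a valley
H > 0 — and every output records it, because "negative curvature"
claims are meaningless without one. Rank-deficient fits, cells with
fewer than 6 neighbors, and values beyond the 1/(2·spacing) resolution
bound are masked, not guessed.

Thickness maps subtract the lower-leaflet height field from the upper
(masked where either is empty) and carry per-species mean reference-bead
heights, which expose gel-type height offsets (~1 nm for a planted gel
patch). A symmetric undulation displaces both leaflets equally and must
leave thickness constant — a decoupling check.

Inter-leaflet registration of a species is the Pearson correlation of
the two leaflets' binary occupancy grids (+1 registered, 0 independent,
−1 anti-registered). Pearson on occupancy was chosen over overlap-area
fractions because it is bounded, symmetric under leaflet exchange and
zero-centered under independence, giving "strongly unregistered" a
quantitative reading; since published supplementary registration metrics
are typically unavailable in detail, the grid spacing is exposed so its
sensitivity can be reported alongside the coefficient.

# Fluorescence analysis

Steady-state anisotropy is ⟨r⟩ = (I_VV − G·I_VH)/(I_VV + 2·G·I_VH) with
the instrument factor G = I_HV/I_HH. Physical values lie in [−0.5, 1];
out-of-range results are flagged, never clamped, because clamping hides
background-subtraction errors. Anisotropy and G are invariant to overall
intensity scaling.

TCSPC decays are modeled as i(t) = Σᵢ αᵢ·exp(−t/τᵢ) with delta
excitation: no instrument-response convolution is performed, and the
synthetic generator makes the same assumption, so generator and fitter
form a self-consistent pair (instrument IRFs are setup-specific).
Fitting integrates the model over each channel and minimizes
Poisson-weighted squared residuals (weights 1/max(c, 1); the floor
avoids division by zero in empty channels) with Levenberg–Marquardt.
Because multi-exponential fits are initialization-sensitive, the fit is
multistarted from log-spaced lifetime grids spanning the window and the
best reduced χ² kept; amplitudes are renormalized to Σαᵢ = 1 and
components sorted by lifetime for identifiability. Goodness of fit is
judged from the reduced χ², the weighted residuals and their
autocorrelation: a correctly specified fit at 10⁶ photons lands near
χ² ≈ 1 (within the customary ≤ 1.3 acceptance bound — adopted here for
the IRF-free setting, where it is if anything a looser condition), while
fitting one component to two-component data drives χ² well above 1.3
and leaves strongly structured residual autocorrelation. The
amplitude-weighted mean lifetime is τ̄ = Σᵢ αᵢτᵢ.

Melting temperatures are extracted from anisotropy-versus-temperature
scans by fitting the symmetric logistic
r(T) = r_low + (r_high − r_low)/(1 + exp((T − Tm)/w)); Tm is the
midpoint. A parametric family must be declared for a "midpoint" to be
reproducible, and the symmetric logistic is the minimal one; generator
and fitter share it. If the fitted amplitude is below 3× the residual
SD the profile has no clear inflection and is reported as
"no transition detected" (the behavior expected of probes whose
response drifts without a phase transition); a midpoint outside the
sampled range is flagged as extrapolated and unreliable.

# The synthetic-data generators

The generators plant structure; they do not simulate it. They emulate
the statistical features the analyses consume — compositions,
spacings, planted partitions, lattices, height offsets, undulations,
photon statistics — with recorded ground truth and bit-reproducible
seeds.

Defaults and their rationale:

* area per lipid 0.64 nm² (fluid POPC-like) and gel lattice spacing
  0.48 nm per chain — typical coarse-grained values for Martini-like
  systems, made explicit configuration defaults;
* chains are geometric bead strings with 0.47 nm bonds, not physical
  polymers — the analyses depend only on positions and bond vectors.
  `chainDisorder` interpolates bond directions between the leaflet
  normal (0: every bond parallel to z, S = 1 exactly) and isotropic
  (1: S ≈ 0), giving analytically known order limits;
* reference compositions follow the studied systems: symmetric patches
  with 10 % PI(4,5)P₂, and asymmetric patches carrying 10 mol%
  PI(4,5)P₂ in the lower leaflet only with leaflet areas balanced
  through per-species areas per lipid;
* planted clusters are hexagonally packed disks (nearest-neighbor
  spacing ≤ `intraSpacing`, inter-disk bead gap ≥ `minGap`), so any
  detection cutoff between the two recovers the partition exactly —
  the module's central contract;
* the gel patch is a contiguous triangular lattice of straight,
  fully extended chains raised by a planted height offset (default
  1 nm, the gel-versus-fluid height difference scale seen in
  coarse-grained bilayers), with a cleared moat so boundary
  classification is deterministic;
* undulations are sinusoidal with the analytic mean-curvature field
  recorded;
* TCSPC histograms draw Poisson counts from channel-integrated
  expected intensities (delta excitation, matching the fitter), and
  thermal profiles use the same logistic family as the fitter with
  planted Tm (default 45 °C, the gel-to-fluid midpoint scale of
  saturated PI(4,5)P₂ domains).

What the generators deliberately do **not** emulate bounds what passing
tests show about real data: there is no force-field energetics, no
emergent phase behavior, no cation beads, no lipid diffusion, no
instrument response, and the gel height offset is planted rather than
emergent. Recovery of planted structure validates the estimators —
their contracts, conventions and numerics — not any thermodynamic
prediction about membranes.

# Numerical choices and problem sizes

Degenerate inputs fail loudly: empty selections, one-leaflet
registration, monolayers, zero-length bonds, unparseable or triclinic
coordinate files, under-sampled thermal scans. Ties and near-ties in
the decay fit (collapsed lifetime components) are flagged rather than
silently reordered. Test and example problem sizes were chosen so the
full suite runs in minutes on one CPU while keeping each statistical
check comfortably powered: 300–1952-lipid bilayers, 50-frame oracle
sweeps, 10⁵ Monte-Carlo bonds, 10⁶-photon decays, 26-point thermal
scans. Monte-Carlo tolerances are stated in units of the exact sampling
SE (e.g. Var[(3cos²θ−1)/2] = 1/5 under isotropy).

# Known limitations

* Cluster detection is geometric; no kinetic modeling of aggregation.
* The supplementary conventions of published in-house analyses (exact
  S-value normalization, hexagonality thresholds, registration metric)
  are not always recoverable from the literature; this package pins
  explicit, tested conventions and exposes every threshold, but a
  quantitative comparison against a specific published curve may
  require re-matching those conventions.
* Curvature is estimated on gridded leaflet surfaces; extreme
  curvatures beyond the grid resolution bound are masked rather than
  reported.
* PDB input is single-frame; multi-frame trajectories use concatenated
  GRO (compressed binary trajectory formats are out of scope to keep
  I/O dependency-light).
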