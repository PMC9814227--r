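# PIPNano

Divalent cations such as Ca²⁺ cross-link the polyanionic headgroups of
PI(4,5)P₂ (phosphatidylinositol 4,5-bisphosphate) and condense the lipid
into nanodomains whose order, packing and curvature depend strongly on
acyl-chain saturation — fully saturated species can even form gel-like
(Lβ-type) domains. Characterizing such nanodomains requires a small zoo of
bespoke computations on coarse-grained membrane configurations and on
fluorescence-spectroscopy data. PIPNano packages those computations as a
tested, reusable pipeline for membrane biophysicists:

* **Membrane data model** — GRO/PDB coordinate input for Martini-style
  bead topologies, orthorhombic periodic boxes (nm), minimum-image
  geometry, and leaflet assignment robust to undulation.
* **Cluster analysis** — PI(4,5)P₂ cluster detection under periodic
  boundaries (connected components of a bead-contact graph) and
  number-/mass-weighted average cluster-size time series.
* **Order analysis** — acyl-chain S-value profiles
  S = (3⟨cos²θ⟩ − 1)/2 per bond against the membrane normal,
  POPC order versus distance to the nearest PI(4,5)P₂ molecule, and
  hexagonal acyl-chain lattice detection (the gel-phase hallmark).
* **Surface analysis** — gridded leaflet height fields, bilayer thickness
  maps, local mean curvature by quadratic Monge-patch fits
  H = (a(1+e²) + b(1+d²) − cde)/(1+d²+e²)^{3/2}, and an inter-leaflet
  registration coefficient (Pearson correlation of leaflet occupancy).
* **Fluorescence analysis** — steady-state anisotropy
  ⟨r⟩ = (I_VV − G·I_VH)/(I_VV + 2·G·I_VH) with G = I_HV/I_HH,
  multi-exponential TCSPC decay fitting i(t) = Σᵢ αᵢ·exp(−t/τᵢ) by
  Poisson-weighted Levenberg–Marquardt least squares with reduced-χ²
  and residual-autocorrelation diagnostics, amplitude-weighted mean
  lifetime τ̄ = Σᵢ αᵢτᵢ, and melting-temperature (Tm) extraction as the
  midpoint of a logistic anisotropy-versus-temperature fit.
* **Synthetic data** — generators for fluid/asymmetric bilayers, planted
  cluster partitions, hexagonal gel patches with a planted height offset,
  sinusoidal undulations with analytic curvature, TCSPC photon
  histograms and thermal scans — all with recorded ground truth and
  bit-reproducible seeds, so every analysis stage is testable without MD
  or instruments.

## Worked example

Plant four clusters of known membership in a 600-lipid bilayer with 15 %
PI(4,5)P₂, then detect them:

```r
library(PIPNano)
syn  <- buildFluidBilayer(nLipids = 600, pip2Fraction = 0.15, seed = 1)
pc   <- plantClusters(syn$frame, c(30, 25, 20, 15),
                      intraSpacing = 0.5, minGap = 2, seed = 2)
detectClusters(pc$frame, "PIP2", cutoff = 0.6)
#> ClusterPartition (PIP2): 90 lipids in 4 cluster(s); cutoff 0.60 nm
#>                          (headgroup beads, in-plane)
#>   sizes: largest 30, number-avg 22.50, mass-avg 23.89
```

The recovered partition equals the planted one exactly: 90 PI(4,5)P₂
lipids in clusters of 30, 25, 20 and 15; the number-weighted average
(22.5 lipids, monomers included) and the mass-weighted average (23.89)
are both reported because published cluster-size curves rarely state
which convention they use.

Fit a two-exponential TCSPC decay at realistic photon statistics:

```r
sim <- simulateDecay(c(0.6, 0.4), c(1, 10), nPhotons = 1e6, seed = 7)
fitDecay(sim$hist, 2)
#> DecayModel:
#>   component 1: alpha = 0.5998, tau = 0.9817 ns
#>   component 2: alpha = 0.4002, tau = 9.854 ns
#>   amplitude-weighted mean lifetime: 4.532 ns
#>   reduced chi-squared = 1.0602 (4096 channels, 4 parameters)
```

Both lifetimes are recovered within 2 %, the amplitudes within 0.001,
and the reduced χ² sits near 1 — below the 1.3 bound customarily used to
accept TCSPC fits. Extract a melting temperature from a thermal
anisotropy scan:

```r
tp <- simulateThermalProfile(Tm = 45, seed = 8)
fitThermalTransition(tp$profile)
#> TransitionFit: Tm = 44.95 C (width 3.04 C), r: 0.0505 -> 0.2495
```

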