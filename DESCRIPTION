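Package: PIPNano
Title: Analysis of Cation-Induced PI(4,5)P2 Nanodomains in Coarse-Grained Membranes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to characterize cation-induced PI(4,5)P2 nanodomains in
    coarse-grained lipid bilayer configurations and in fluorescence
    spectroscopy data. Provides a data model for Martini-style membrane
    snapshots with GRO/PDB input, periodic-boundary geometry and leaflet
    assignment; cluster detection under periodic boundaries with
    number- and mass-weighted average cluster sizes; acyl-chain S-value
    order-parameter profiles, distance-resolved order and hexagonal
    gel-lattice detection; gridded leaflet surfaces, bilayer thickness
    maps, local mean-curvature fields and an inter-leaflet registration
    coefficient; steady-state fluorescence anisotropy with G-factor
    correction, multi-exponential TCSPC decay fitting with chi-squared
    diagnostics, amplitude-weighted mean lifetimes, and
    melting-temperature extraction from thermal anisotropy profiles.
    A synthetic-data module generates bilayers with planted clusters,
    hexagonal gel patches, analytic undulations, asymmetric leaflet
    compositions, and synthetic photon data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    minpack.lm,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'PIPNano-package.R'
    'topology.R'
    'geometry.R'
    'cluster.R'
    'io.R'
    'synthetic-bilayer.R'
    'synthetic-fluor.R'
    'fluorescence.R'
    'leaflets.R'
    'methods-accessors.R'
    'order.R'
    'surface.R'
    'synthetic-structure.R'
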