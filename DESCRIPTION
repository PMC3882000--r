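Package: memgrid
Title: Grid-Based Mapping of Local Lipid Membrane Properties
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Maps local properties of lipid bilayers from molecular dynamics
    snapshots onto a two-dimensional grid. Lipids are assigned to leaflets,
    every grid cell is labelled with its nearest lipid (or embedded protein
    atom), and per-cell membrane thickness, area per lipid, deuterium order
    parameters (for saturated and double-bond carbons) and mean/Gaussian
    leaflet curvature are computed, with ideal Fourier band filtering of
    membrane undulations. Results are written as B-factor annotated PDB grids
    and plain-text matrices. A synthetic-membrane generator with analytically
    known geometry supports testing without simulation data.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    optparse,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
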