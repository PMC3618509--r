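Package: surfray
Title: Ray-Casting Construction, Triangulation, and Analysis of Closed
    Molecular Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds molecular surfaces of atomic systems under several
    definitions (solvent-excluded via weighted Delaunay / alpha shapes,
    van der Waals, solvent-accessible, skin surface via the mixed
    complex, and Gaussian isosurfaces) and imports closed triangle
    meshes.  Any of these closed surfaces is then inspected by
    grid-consistent axis-aligned volumetric ray casting protected by an
    even-intersection parity checksum with jittered re-casting.  On top
    of the cast grid the package estimates enclosed volume from ray
    intervals, detects interior cavities by floodfill and optionally
    fills them by volume threshold, triangulates the surface with an
    analytic-vertex marching-cubes variant whose vertices lie exactly on
    the surface, estimates total and per-grid-cube areas, and produces
    in/out grid colorings plus boundary-point surface projections for
    finite-difference PDE solvers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
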