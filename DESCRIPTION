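Package: topolearn
Title: Topological Model of Hippocampal Spatial Map Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates place-cell ensembles exploring planar arenas with
    obstacles, with optional theta-phase precession of spiking, and tracks how
    the time-filtered coactivity simplicial complex built from place-cell
    co-firing acquires the topology of the environment. Provides inhomogeneous
    Poisson spike-train generation over correlated-random-walk trajectories,
    coactivity-window binning, filtered simplicial complexes with f-vectors and
    connectivity indices, persistent homology over Z/2 with Betti curves and
    minimal learning times, spurious-loop statistics, learning-region parameter
    sweeps with GEV/gamma fits and Kolmogorov-Smirnov comparison matrices,
    coactivity-window scans (opening width, stabilization width, power-law
    exponent), and Mayer-Vietoris piecewise learning over arena partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    withr
Config/testthat/edition: 3
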