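Package: dynmem
Title: Dynamic Memory in Recurrent Networks with Fluctuating Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for memory storage in recurrent
    firing-rate networks whose synapses drift under activity-independent noise
    and homeostatic plasticity. Memories are embedded as low-rank perturbations
    of the connectivity matrix: symmetric (real outlier eigenvalue, fixed-point
    attractor) or anti-symmetric (imaginary eigenvalue pair, limit-cycle
    attractor). The package integrates the coupled neural/synaptic dynamics,
    provides three homeostatic rules (dissipation, rate control, decorrelation)
    and a rate-based STDP learning rule, tracks identity-matched eigenvalue
    trajectories of the evolving connectivity, and ships end-to-end protocols
    for memory erosion, learning, associative retrieval, capacity estimation,
    and the full memory life cycle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
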