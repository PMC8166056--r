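Package: shbdyn
Title: Short Hydrogen Bonds and Nonradiative Excited-State Decay
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Surrogate excited-state dynamics for hydrogen-bonded
    chromophores. Builds two-state model surfaces whose proton-transfer
    barrier and distortion-mode stiffness are controlled by the
    donor-acceptor hydrogen-bond length, propagates thermostatted classical
    trajectories that emit electronic frames, and accumulates
    fewest-switches-style nonradiative S1 to S0 decay probabilities (ANRP)
    over replica ensembles. Also provides proton-transfer free-energy
    profiles with well classification, carbonyl-stretch and
    ring-deplanarization descriptors, hydrogen-bond enumeration, Lorentzian
    stick broadening with second-derivative peak localization, and
    Franck-Condon factors for displaced harmonic oscillators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
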