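Package: sparkletr
Title: Quantal Analysis of Optical Calcium Sparklets and Vessel Reactivity
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantal analysis of optical single-channel calcium
    ("sparklet") recordings from native endothelium: Kalman stack filtering
    of fluorescence movies, F/F0 extraction from regions of interest,
    all-points amplitude histograms fit with equally spaced multi-Gaussian
    mixtures, trace idealization to quantal levels, dwell-time based NP_O
    estimation and sparklet sites per cell. Includes a seeded stochastic
    two-state channel-gating simulator with rendered traces and image
    stacks (known ground truth) for end-to-end verification, plus
    pressure-myography vessel reactivity metrics (percent constriction,
    percent dilation, myogenic tone) and Poiseuille wall shear stress.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
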