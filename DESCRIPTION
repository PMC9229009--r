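Package: qslb
Title: QCM-D Analysis of Supported Lipid Bilayer Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quartz crystal microbalance with dissipation
    monitoring (QCM-D) experiments that track supported lipid bilayer (SLB)
    formation from adsorbing vesicles. Classifies multi-harmonic frequency and
    dissipation traces into the canonical outcome signatures (supported vesicle
    layer, two-step bilayer formation via vesicle rupture, one-step bilayer
    formation, incomplete bilayer), extracts kinetic descriptors such as the
    initial adsorption slope and the frequency minimum, converts final
    frequency shifts to areal mass via the Sauerbrey relation with a trapped
    water-layer correction, and derives molecular packing geometry of the
    bilayer (lipid surface density, area per lipid, hydrophobic thickness) for
    arbitrary lipid mixtures. Also converts dynamic light scattering size
    distributions between intensity, volume and number bases and flags vesicle
    aggregation over time. A seeded synthetic-trace generator reproduces the
    canonical signature shapes so the whole pipeline runs without instrument
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
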