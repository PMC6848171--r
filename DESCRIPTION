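Package: maerlspi
Title: Dredging Pressure and Maerl Bed Structure from Sediment Profile Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the impact of dredge fishing on maerl (rhodolith) bed
    vitality and habitat complexity. Builds a high-resolution dredging-intensity
    raster from AIS vessel pings (speed-filtered dredging segments, swept-area
    rasterization on a 50 m cell lattice, multi-season cumulation), extracts
    vitality and complexity metrics from sediment-profile-imagery (SPI)
    cross-section images (red-channel live/dead classification, interface
    rugosity, penetration depth, interface-flattened vertical profiles at 5 mm
    resolution), measures thallus shape descriptors (perimeter, solidity index),
    and tests pressure effects with one-way PERMANOVA, PERMDISP and
    pressure-response regression families. Includes a synthetic-data generator
    emulating all input streams with exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    png,
    pracma,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff,
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
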