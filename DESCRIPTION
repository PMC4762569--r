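Package: sascifr
Title: Read, Write and Convert Small-Angle Scattering CIF (sasCIF) Files
Version: 0.5.1
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained toolkit for the extended sasCIF format used to
    archive small-angle X-ray and neutron scattering (SAXS/SANS) experiments.
    Provides an order-preserving CIF/STAR parser and writer, the sasCIF
    category vocabulary with MAIN/MODEL/FIT data-block assembly and
    validation, bidirectional converters between sasCIF and the legacy SAS
    file formats (three-column .dat scattering curves, indirect-transform
    .out files holding the pair-distance distribution p(r), .fit/.fir model
    fits, and PDB coordinate models), and a synthetic sphere-scattering
    entry generator so the whole toolchain can be exercised without
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    jsonlite,
    withr
Config/testthat/edition: 3
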