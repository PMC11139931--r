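Package: etobench
Title: Benchmarking Empirical Reference-Evapotranspiration Models Against Pan and Penman-Monteith Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes monthly reference evapotranspiration (ET0) for a site
    from climate normals with eighteen empirical models (eight
    temperature-based, ten radiation-based) and two reference baselines:
    pan-derived ET0 using an Allen-Pruitt pan coefficient and the FAO-56
    Penman-Monteith equation.  Includes the FAO-56 meteorological
    primitives (saturation vapour pressure, extraterrestrial and net
    radiation, psychrometric constant, Angstrom-Prescott solar radiation,
    Doorenbos-Pruitt daytime percentage), an eight-statistic model
    evaluation suite (FAC2, MB, MGE, NMB, NMGE, RMSE, Pearson r, refined
    index of agreement) with Taylor-diagram statistics and model ranking,
    packaged climate normals for a tropical highland station, and a seeded
    synthetic monthly-climate generator for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
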