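Package: pondgas
Title: Greenhouse-Gas Fluxes, Isotopic Source Attribution and Carbon Age for
    Permafrost Thaw Ponds
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the limnological greenhouse-gas budget of permafrost
    thaw ponds: dissolved CO2 and CH4 concentrations from headspace
    equilibration (Henry's law mass balance), wind-based diffusive fluxes
    (Cole-Caraco k600, Schmidt-number scaling, small-pond chamber
    correction), ebullition fluxes from submerged funnel traps,
    stable-isotope classification of the methanogenic pathway (CD diagram
    and apparent carbon fractionation), radiocarbon fraction-modern and
    two-endmember old-carbon apportionment, pond-type contrasts and
    landscape upscaling. Includes a seeded synthetic field-campaign
    generator with ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
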