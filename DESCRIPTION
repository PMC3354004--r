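Package: pelagitrack
Title: Travel-Speed Modality and Ocean Co-Location Analysis for Satellite-Tracked Marine Megafauna
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Argos satellite tracks of pelagic animals:
    speed filtering and 6-hourly regularization of raw fixes, travel-speed
    computation by first differencing, a from-scratch Hartigan dip test of
    unimodality with bootstrap calibration, identification of the modal
    transiting speed and classification of putative foraging (area-restricted
    search) locations, removal of surface ocean currents (geostrophic from sea
    surface height with an equatorial beta-plane treatment, plus a
    parameterized Ekman component) to recover swimming velocities, and
    co-location of tracks with chlorophyll-a composites and with thermocline
    and nutricline depths from a gridded climatology. A regime-switching
    correlated-random-walk simulator generates Argos-like tracks, dive
    summaries and ocean fields so the whole pipeline runs and is tested
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere
Config/testthat/edition: 3
RoxygenNote: 7.3.3
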