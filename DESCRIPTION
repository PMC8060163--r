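Package: cpfmove
Title: Movement Metrics for Central-Place Foragers from GPS Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing GPS tracks of central-place foragers:
    reading and writing GPX, CSV and GeoJSON track data; cleaning,
    projecting and resampling person-day trajectories; raster-based
    measures of daily land visited, cumulative land explored and
    geographic segregation by gender; minimum convex polygon home
    ranges; outbound, inbound and geographically weighted path
    sinuosity; proximity-based sociality sampling; and nonparametric
    summary statistics. Includes a correlated-random-walk simulator of
    camp-anchored foraging days so the full pipeline can be exercised
    and validated on synthetic data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, grDevices, graphics, xml2, jsonlite
Suggests: testthat (>= 3.0.0), geosphere, withr, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
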