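Package: haycal
Title: Near-Infrared Spectroscopy Calibration for Forage Nutritive Value
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Chemometric workflow for calibrating near-infrared reflectance
    spectra of hay against laboratory nutritive-value analyses (dry matter,
    crude protein, fiber fractions, in vitro digestibility). Implements the
    standard NIRS preprocessing toolbox (log 1/R absorbance, standard normal
    variate, detrend, gap-segment derivatives), NIPALS partial least squares
    regression with cross-validated factor selection, Mahalanobis (GH) and
    t-statistic outlier screening, calibration statistics (R2, SEC, SECV,
    RPD) with grid search over derivative treatments, and a synthetic
    hay-spectra generator that emulates ground versus unground sample
    preparation for end-to-end testing and simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
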