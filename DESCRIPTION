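Package: swim2dms
Title: Two-Dimensional Mass Spectrometry by Stored Waveform Ion Radius
    Modulation on Quadrupole Time-of-Flight Instruments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chromatography-free two-dimensional mass spectrometry
    (2DMS) on quadrupole time-of-flight instruments using stored waveform ion
    radius modulation (SWIM). Provides synthesis of the broadband SWIM
    excitation pulse sequence, the secular-frequency calculus of the linear
    quadrupole ion trap (Mathieu q, Dehmelt and Koizumi approximations, exact
    continued-fraction beta, encoding-frequency conversions and the
    autocorrelation-line mass calibration), a signal-level forward simulator
    of modulated precursor and fragment ion signals in the flux-constant,
    flux-periodic and mixed modes for UVPD, in-trap CID and beam CID, a Monte
    Carlo ion trajectory simulator with hard-sphere background-gas collisions
    and Gaussian-laser photodissociation, and the Fourier decoding pipeline
    that turns a cube of per-index product-ion spectra into a calibrated 2D
    mass spectrum with peak picking, harmonic flagging and spectral slicing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    mzR,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
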