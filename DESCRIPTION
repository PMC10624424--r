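Package: bnirseeg
Title: Coupled Broadband NIRS and EEG Analysis of Infant Neurovascular
    and Neurometabolic Coupling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline coupling broadband near-infrared
    spectroscopy (bNIRS) haemodynamic (HbO2, HHb) and metabolic (oxCCO)
    signals with EEG band-limited RMS power in infants. Implements
    wavelet-based motion correction of attenuation signals, multiwavelength
    least-squares chromophore resolution (UCLn / modified Beer-Lambert),
    intensity-count quality control, Butterworth filtering, EEG
    segmentation with two-stage baseline correction and artifact
    rejection, band RMS power, reconstruction of infant-specific
    haemodynamic and metabolic response functions by exhaustive
    double-gamma grid search, neural-regressor GLMs with
    Benjamini-Hochberg FDR-corrected group statistics, and a synthetic
    multimodal data generator with known ground-truth coupling for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
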