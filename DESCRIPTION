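Package: ecgqt
Title: Beat-to-Beat QT-Interval Measurement from Multi-Lead ECGs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic beat-to-beat QT-interval measurement from 12-lead
    electrocardiograms. Builds heart-axis-robust scalar channels (cross-lead
    RMS, cross-lead SD and the Kors vectorcardiogram magnitude), detects R
    peaks with a Pan-Tompkins detector, locates the QRS onset from the second
    derivative of the RMS channel, delineates the T-wave end per channel with
    the tangent method, and fuses the per-channel landmarks into a global
    per-beat T end by a median with 2-SD outlier rejection. Includes
    method-agreement statistics (Bland-Altman, Pearson with Fisher CI,
    two-way mixed absolute-agreement ICC), RR-stratified beat selection for
    validation, a synthetic 12-lead ECG generator with analytic ground-truth
    fiducials, and a small command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
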