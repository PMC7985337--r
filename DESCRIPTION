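Package: brachyqa
Title: Patient-Specific Dosimetric Verification for HDR Brachytherapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for patient-specific quality assurance of high-dose-rate
    (HDR) Ir-192 brachytherapy with a solid (ABS plastic) phantom. Implements
    the AAPM TG-43U1 line-source dose formalism with dwell-time superposition
    onto planar grids, a radial water-to-ABS conversion factor CF(r) so that
    doses computed in the water formalism can be compared with measurements
    made inside the plastic phantom, radiochromic-film net optical density
    calibration and scan-to-dose conversion with dose-range-dependent colour
    channel selection, and gamma-index (dose difference / distance-to-agreement)
    comparison of calculated against measured planar dose distributions,
    including an exhaustive-search oracle for validating the gamma search.
    A workflow layer generates the standard single-dwell, elliptical and
    concave test cases, synthesises measurements, and runs the end-to-end
    verification report.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
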