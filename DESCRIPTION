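Package: btlpn
Title: Closed-Loop Lumped-Parameter Hemodynamics of Shunt-Dependent
    Single-Ventricle Circulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for desk-scale analysis of shunt-dependent single-ventricle
    physiology with closed-loop lumped-parameter (0D) circulation models.
    Provides a netlist-based circuit model with three-element Windkessel
    outlets, diode heart valves and a time-varying-elastance ventricle; an
    implicit (backward Euler) circuit solver run to periodic steady state; a
    pipeline that constructs a patient-specific elastance curve from a valve
    flow waveform, a ventricular pressure trace and end-diastolic volume; a
    reduced-order resistive surrogate of the image-based arterial domain with
    Hagen-Poiseuille and Reynolds-number utilities; inference of effective
    Blalock-Taussig shunt occlusion from trans-shunt hemodynamics; a clinical
    comparison harness (percent-error scoring, shunt-design change tables);
    and a seeded virtual-patient generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
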