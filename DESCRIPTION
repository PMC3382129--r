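Package: sphenostim
Title: Quantification Pipeline for Cerebrovascular Stimulation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis stack for intravital imaging and electrophysiology of
    rodent photothrombotic stroke with sphenopalatine-ganglion stimulation:
    pial-vessel segmentation and diameter morphometry, fluorescent-angiography
    bolus-transit kinetics, laser-Doppler rCBF baseline normalization, ECoG
    band power and seizure-like-event burden, Evans-blue blood-brain-barrier
    quantification, cortical-volume loss from serial sections, and
    non-parametric group comparison. Ships seeded synthetic-data generators
    with programmed ground truth so every estimator has a parameter-recovery
    test, plus a deterministic end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    signal,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
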