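Package: astrosleep
Title: Astrocyte Calcium Events and Cortical Sleep Electrophysiology
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline linking cortical astrocyte calcium events to
    sleep electrophysiology in head-fixed rodents. Provides threshold-based
    sleep-state scoring from LFP/EMG/locomotion, detection and waveform
    classification of slow oscillations versus delta waves with a nested
    high-gamma polarity check, event-rate statistics and 20-feature PCA of
    astrocyte calcium event tables, event-triggered slow-wave-activity
    averaging, event-aligned Welch magnitude-squared coherence with
    random-alignment controls and Bonferroni correction, and
    chemogenetic-condition comparisons. A seeded synthetic multimodal session
    generator with known ground truth makes every stage testable without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    data.table,
    MASS,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
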