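Package: ecosyn
Title: Synthetic ECoG Cohorts and Quantification of Epileptiform Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and quantification of single-channel
    electrocorticography (ECoG) from the lithium-pilocarpine rat model of
    status epilepticus under a magnet/sham experimental timeline. Provides a
    synthetic ECoG generator with ground-truth event logs (anesthesia
    up/down-state background, epileptiform spikes, 80-200 Hz ripples),
    EDF and CSV input/output, signal conditioning (anti-aliased
    downsampling, zero-phase band-pass filtering, automatic epoching),
    detectors for epileptiform spikes (duration and amplitude-ratio
    criterion) and ripples (consecutive supra-threshold peak criterion),
    RMS amplitude and Welch band-power metrics, and a mixed
    repeated-measures ANOVA with Greenhouse-Geisser correction and Tukey
    multiple comparisons, composed into a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
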