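Package: steerlab
Title: Linking Descending-Neuron Activity to Steering in Walking Flies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline linking descending-neuron electrophysiology to
    locomotor steering in walking Drosophila. Provides treadmill kinematics
    preprocessing (offset correction, Gaussian and random-walk MAP smoothing,
    total speed, inactivity classification), intracellular spike detection and
    firing-rate estimation with recording quality control, frequency-domain
    (Wiener) linear-filter estimation between firing rate and behavior with
    Slepian-taper denoising and out-of-sample prediction, event-triggered
    analyses of movement transitions and two-neuron behavior maps, head-direction
    bump tracking and bump-jump trial classification from eight-sector
    fluorescence, six-leg gait and turning metrics from pose keypoints,
    label-randomization bootstrap and two-factor ANOVA machinery for
    perturbation experiments, and connectome pathway grouping and thresholding.
    Seeded synthetic-data generators emulate every input modality so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
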