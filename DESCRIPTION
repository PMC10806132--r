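Package: hybridgait
Title: Coordination Control of a Powered Ankle-Foot Orthosis and
    Functional Electrical Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for simulating and analysing a hybrid gait-rehabilitation
    system that couples a one degree-of-freedom powered ankle-foot orthosis
    (PAFO) with two-channel functional electrical stimulation (FES) of the
    tibialis anterior and soleus. Provides ball-screw linkage kinematics and
    impedance/admittance control of the orthosis, threshold-based gait-phase
    and speed estimation from foot-switch traces, speed-adaptive reference
    EMG envelope models, a one-dimensional convolutional network mapping
    two-channel EMG envelopes to ankle torque, a blanking/comb-filter/low-pass
    cascade that extracts volitional EMG from stimulation-contaminated
    recordings, assist-as-needed torque-sharing laws that split joint torque
    between orthosis, stimulation and volitional muscle activity, and a
    closed-loop synthetic gait simulator comparing control modes with and
    without consideration of volitional effort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
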