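Package: headmov
Title: Classification and Evaluation of Head Movements from Head-Mounted
    Display Rotation Traces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for detecting and characterising head movements in
    orientation streams recorded by virtual-reality head-mounted displays.
    Provides kinematic derivations from quaternion traces (angular speed,
    per-axis angular velocity, angular acceleration, head-angle magnitude),
    five movement classifiers (a baseline-adaptive elliptic velocity
    threshold, a Savitzky-Golay smoothed velocity threshold with
    acceleration-zero boundary search, a sliding-window percentage rule, an
    acceleration zero-crossing direction coder, and a decision tree), Cohen's
    kappa sample-by-sample agreement with leave-one-subject-out threshold
    fitting, midpoint event matching with onset/offset/duration/amplitude
    bias metrics, the amplitude versus peak-velocity main-sequence
    correlation, and a seeded simulator of head-rotation recordings with
    ground-truth events and synthetic raters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    rpart,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    e1071,
    tree
Config/testthat/edition: 3
RoxygenNote: 7.3.3
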