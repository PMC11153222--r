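Package: rtseizure
Title: Real-Time EEG Seizure Onset Detection with STFT Spectrograms and an
    Inception Convolutional Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A sliding-window pipeline for real-time detection of epileptic
    seizure onsets in multichannel scalp EEG. Recordings are band-pass
    filtered with a zero-phase Butterworth filter (1-60 Hz), segmented into
    1.35-s windows with 1-s overlap, and converted per window into a stacked
    band-limited short-time Fourier transform log-power image (120 x 344 for
    six channels over 20-60 Hz at 2 Hz resolution) that feeds a 29-level
    GoogLeNet-style inception convolutional network trained with SGD.
    Includes EDF input/output, CHB-MIT-style seizure annotations,
    leave-one-subject-out protocol helpers, event-based evaluation metrics
    (event sensitivity, window false-positive rate, detection delay,
    accuracy), a seeded synthetic EEG generator with annotated seizures for
    end-to-end testing without any data download, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    signal,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
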