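Package: imupipe
Title: Human Activity Recognition and Localization from Wearable Inertial and Audio Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for parallel human activity recognition and
    indoor/outdoor localization from smartphone and smartwatch sensor streams.
    Reads and aligns tri-axial accelerometer, gyroscope and magnetometer
    recordings (plus optional audio and GPS), denoises them with a zero-phase
    Butterworth filter, cuts Hamming-weighted five-second windows stacked in
    threes, and extracts two bespoke feature banks: chaotic time-series
    descriptors (maximum Lyapunov exponent, Higuchi fractal dimension,
    false-nearest-neighbour embedding dimension), Mel-frequency cepstral
    coefficients and higher moments for activity; step detection, dynamic
    step-interval estimation, tilt-compensated magnetometer/gyroscope heading
    fusion and audio cepstra for localization. Features are pruned by recursive
    feature elimination, augmented by a genetic-algorithm middle-third crossover,
    and classified by deep neural decision forests (a neural embedding feeding
    soft, differentiable decision trees). A seeded synthetic-data generator with
    activity-specific gait periodicity and location-specific audio spectra makes
    the whole pipeline testable without any dataset download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
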