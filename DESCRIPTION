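Package: shavok
Title: Structured Time-Delay Models with Frenet-Serret Curvature Diagnostics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Fits linear time-delay models of scalar time series by dynamic
    mode decomposition on the singular vectors of a Hankel matrix (the HAVOK
    family), including the structured variant (sHAVOK) that takes two
    independent SVDs of column-shifted Hankel matrices so that both coordinate
    bases are orthonormal. The sub- and super-diagonal entries of the resulting
    dynamics matrix estimate the Frenet-Serret curvatures of the delay
    trajectory; the package provides the analytic Gram-determinant curvature
    oracle, discrete orthogonal polynomial bases, sampling-adequacy checks,
    antisymmetry and tridiagonality diagnostics, forecasting with a scalar
    forcing term, and deterministic simulators (Lorenz, Roessler, double
    pendulum, sinusoid) for the systems commonly used to study these models.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
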