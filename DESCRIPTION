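Package: cetpflux
Title: Postprandial CETP-Mediated Triglyceride Redistribution Among
    Lipoprotein Fractions
Version: 0.1.0
Authors@R:
    person("Martin", "Keller", email = "mkeller.lipids@posteo.de",
           role = c("aut", "cre"))
Description: Tools for quantifying chylomicrons from two-chamber
    ultracentrifugation (Airfuge) measurements via an ApoA1-based
    spillover correction, computing lipoprotein particle counts, radii
    and total surface areas from fraction composition data, modeling
    cholesteryl ester transfer protein (CETP)-mediated triglyceride net
    fluxes among lipoprotein fractions as surface-driven carrier-mediated
    diffusion, calibrating the exchange rate constant against measured
    1-hour triglyceride redistribution, and paired fasting/postprandial
    cohort statistics (exact Wilcoxon signed-rank, Spearman correlation).
    Includes a synthetic-data generator with known ground truth so every
    pipeline stage is testable without patient data, and a command-line
    interface wiring the stages together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
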