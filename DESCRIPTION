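Package: spanlife
Title: Joint Sleep, Physical Activity and Nutrition Effects on Lifespan
    and Healthspan
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates lifespan (period life expectancy) and healthspan
    (disease-free life expectancy) gains associated with joint sleep,
    physical activity and diet-quality exposures.  Provides a synthetic
    cohort generator with configurable U-shaped sleep, J-shaped activity
    and linear diet effects on mortality and five chronic-disease
    incidence processes; exposure preparation (winsorisation, Tukey
    fences, tertiles, the 27-category joint exposure); multivariable Cox
    proportional-hazards models with restricted cubic spline
    dose-response curves; hazard-ratio-adjusted Chiang period life
    tables; a Sullivan-style disease-free life-table extension with
    parametric Monte Carlo uncertainty; additive-interaction indices
    (RERI, AP, S) with nonparametric bootstrap confidence intervals; and
    a composite 0-100 lifestyle score with minimum-dose inversion into
    native behaviour units.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    survival,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
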