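Package: prevharm
Title: Harmonize Child Thinness, Overweight and Obesity Prevalence Across
    BMI Growth References
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to convert child thinness, overweight and obesity
    prevalence rates between LMS-based body mass index references (such as
    IOTF, WHO and CDC). Cut-offs defined as z-scores on different references
    are placed on a common z-score scale by back-transforming each cut-off
    to BMI and re-scoring it on the other reference; the resulting cut-off
    distance drives a reversible probit conversion of prevalence rates.
    Includes look-up table generation over an age-sex grid, a probit
    regression validation framework with beta-binomial overdispersion for
    assessing the conversion on paired prevalence data, and a synthetic-data
    module generating LMS reference tables and grouped prevalence datasets
    under an exact z-score-shift population model or controlled violations
    of it.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
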