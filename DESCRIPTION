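Package: tetradr
Title: Crossover Patterning and Weinstein Tetrad Analysis for Multiply-Marked Drosophila Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing crossover patterning in multiply-marked
    Drosophila melanogaster crosses. Converts per-progeny marker phenotypes
    into crossover interval calls, tabulates recovered-chromatid crossover
    classes (NCO/SCO/DCO/TCO), builds interval genetic maps in centimorgans,
    and estimates the tetrad exchange-rank distribution (E0..Ek) by classical
    Weinstein inversion and by constrained multinomial maximum likelihood
    fitted with an expectation-maximisation algorithm. Includes Fisher exact
    genotype comparisons, percent-of-control centromere-effect readouts,
    viability-adjusted X and 4th chromosome nondisjunction rates, and a
    forward simulator of female meiosis (exchange-rank draws, interval
    placement, chromatid sampling without chromatid interference) for
    end-to-end validation and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
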