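Package: iupos
Title: Intrauterine Position Analysis of Fetal Growth in Multiparous Rodents
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for analysing fetal and placental weights from multiparous
    rodent necropsy records by intrauterine position. Maps ordered feti within
    each uterine horn to five anatomical categories (ovarian end, next-to-ovarian
    end, middle, next-to-cervical end, cervical end), applies per-horn and
    per-litter inclusion criteria with an auditable exclusion report, screens
    analysis cells with an iterative two-sided Grubbs test, normalizes fetal
    weight by maternal weight and feti per horn, computes placental efficiency,
    and runs the layered statistical comparisons (litter-mean Student's t-test;
    two-factor Type-III ANOVA with Sidak-adjusted pairwise contrasts; Cohen's d).
    Includes a seeded synthetic-litter generator and Monte-Carlo power
    experiments that contrast positional analysis with traditional
    litter-averaging.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), car, jsonlite, withr
Config/testthat/edition: 3
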