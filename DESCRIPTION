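Package: infodemic
Title: Infodemic Moniker Scoring and Search-Interest Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative infodemiology: a rubric-based infodemic
    scale (I-scale) that scores misinformation monikers on five categories
    and maps totals to severity classes; statistics over normalized relative
    search-volume (RSV) time series including average peak volume (APC) with
    Gaussian confidence intervals, breakout and spike detection, event
    alignment, ranking and severity-weighted aggregation; hashtag frequency
    share tables with display scaling; country-level correlation of search
    interest with disease incidence; and seeded synthetic-data generators
    for all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
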