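Package: riskytiming
Title: Bayesian Decision-Theoretic Analysis of Risky Timing Strategies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing timing strategies in coincident-timing tasks
    where the points earned on a trial depend on response time through a
    piecewise-linear gain function. Implements expected-gain maximisation
    under Gaussian motor noise (closed-form convolution of piecewise-linear
    gains with the normal density), bootstrap percentile confidence intervals
    for the optimal planned response time, distribution-shift estimation of
    the empirical optimum, risk-attitude classification (risk-seeking,
    risk-neutral, risk-averse), trial-by-trial lag-1 compensation analysis
    with M-scaled error bins, outlier filtering, split-half learning checks,
    and a synthetic-participant generator with parameter-recovery support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
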