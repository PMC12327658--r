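Package: bwsmaxdiff
Title: Best-Worst Scaling Designs and Maximum-Difference Choice Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for object-case best-worst scaling (MaxDiff) studies:
    construction and verification of balanced incomplete block designs for
    choice questionnaires, input/output and validation of long-format
    best/worst responses, maximum-likelihood estimation of item utilities
    under the maximum-difference (best-worst pair) conditional logit model
    with sum-to-zero identification, post-estimation summaries (marginal
    probabilities, pairwise utility-difference contrasts, greatest utility
    difference, best-minus-worst count scores), and a random-utility
    simulator for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr, optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
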