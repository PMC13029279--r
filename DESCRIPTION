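Package: pregvig
Title: Mechanistic Integration of Pregnancy Pharmacovigilance Reports
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for mechanistic interpretation of pregnancy-related
    individual case safety reports (ICSRs). Harmonises adverse drug
    reaction phenotype labels, computes drug-phenotype disproportionality
    (reporting odds ratios with Fisher exact tests and false discovery
    rate control), builds within-report co-medication networks with
    targeted-versus-random hub-removal robustness simulation, fits
    case-level seriousness regressions on polypharmacy burden, derives a
    drug-level mechanistic vulnerability index and regimen-level
    drug-drug interaction prioritisation scores, runs range-based Monte
    Carlo exposure-potency exceedance simulations under pregnancy
    pharmacokinetic bounds, and embeds drug-level feature matrices with
    leave-one-drug-out loading stability diagnostics. Includes a
    synthetic cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    igraph,
    ranger,
    jsonlite,
    sandwich,
    lmtest,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
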