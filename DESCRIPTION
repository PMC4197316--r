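Package: admitintent
Title: Classify Childhood-Cancer Hospital Admissions by Indication
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a stepwise, mutually exclusive algorithm that assigns
    each admission in KID-style administrative hospital-discharge data to one
    of four clinically meaningful indications -- chemotherapy delivery,
    cancer-directed procedure, infection treatment, or management of a
    non-infectious toxicity -- with remaining admissions labelled undefined.
    Diagnosis and procedure ICD-9-CM codes are first collapsed into Clinical
    Classifications Software (CCS) groups and then into diagnostic and
    procedure categories. The package also provides the validation arithmetic
    for such rule-based phenotyping (positive predictive value, sensitivity,
    Wald confidence intervals, confusion matrices), per-indication resource
    utilization summaries (inflation-adjusted cost from charges, length of
    stay, cost per day, stem-cell-transplant and intensive-care flags,
    one-way analysis of variance), and a synthetic discharge-record generator
    with known ground-truth labels so the whole pipeline is testable without
    access to restricted hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
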