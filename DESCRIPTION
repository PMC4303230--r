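Package: ctdx
Title: Circulating Tumor DNA Fragment-Size, Copy-Number and Clonality Analysis
Version: 0.1.0
Authors@R: person("ctdx", "developers", role = c("aut", "cre"),
    email = "ctdx@example.org")
Description: Tools for analysing circulating tumor DNA (ctDNA) in plasma of
    cancer patients: classification of cell-free DNA fragment-size histograms
    into mononucleosomal (monophasic) and di-/tri-nucleosomal (biphasic)
    profiles; shallow whole-genome sequencing copy-number profiling with
    least-squares segmentation, gain/loss calling and balanced/unbalanced
    profile decisions; a somatic variant prioritization cascade (germline
    subtraction, exonic restriction, driver-gene and shared-sample filters)
    with a full audit trail; allele-fraction quantification from targeted
    deep-sequencing read counts with whole-body mutant-fragment estimation;
    allele-fraction based clonal ordering of tumor lesions; cohort-level
    contingency statistics linking fragment-size class to copy-number
    detectability; and a seeded synthetic-cohort generator that emulates all
    of these inputs so every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    ape,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    data.table
Config/testthat/edition: 3
RoxygenNote: 7.3.3
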