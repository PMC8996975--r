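Package: crosspath
Title: Cross-Cohort Pathway Enrichment and Shared Gene Panel Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dual-cohort transcriptomic pipeline that discovers a gene panel
    shared between two disease cohorts (each profiled against healthy
    controls on expression microarrays). Implements two-track nonspecific
    probe filtering (linear-intensity floor intersected with a coefficient-of
    -variation window on the log2 track), probe-to-gene collapse by maximum
    mean expression, absolute-ranked gene set enrichment analysis with
    phenotype-permutation statistics (ES, NES, nominal p, FDR q, FWER,
    leading-edge tag/gene/signal), leading-edge frequency scoring,
    linear-scale fold-change classification, and cross-cohort intersection.
    Includes a synthetic-data generator with planted pathway enrichment for
    end-to-end testing, plus the downstream validation arithmetic:
    2^-DeltaDeltaCt relative quantification of qPCR data, Mann-Whitney group
    comparison, and Kaplan-Meier / log-rank survival analysis split by
    marker expression.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
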