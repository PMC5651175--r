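Package: esomics
Title: Integrative Multi-Omics Subtyping of Gastro-Oesophageal Tumour Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Re-usable implementations of the bespoke computational stages used
    to molecularly subtype oesophageal and gastro-oesophageal carcinoma cohorts:
    arm-level somatic copy-number alteration calling and chromosomal-instability
    (SCNA-high/low) classification from segmented copy-number profiles; merging
    and filtering of multi-caller somatic mutation call sets with coverage,
    allele-fraction, germline-site, panel-of-normals and 8-oxoguanine artifact
    rules; pathway-level differential-expression scoring by Fisher-combined
    Kruskal-Wallis p-values against a size-matched random-gene-set permutation
    null; per-sample epigenetic-silencing calls from paired promoter methylation
    and expression with exact Fisher subtype-association tests; per-platform
    hierarchical subtype clustering, nearest-centroid classification against
    external squamous subtype centroids, and cluster-of-cluster-assignments
    (COCA) / SuperCluster integration; and mutational-signature extraction from
    96-trinucleotide-context catalogs by automatic-relevance-determination
    Bayesian non-negative matrix factorization. A synthetic multi-platform
    cohort generator with recorded ground truth makes every stage testable at
    desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    cluster
Config/testthat/edition: 3
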