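Package: glycoSecretome
Title: Secretome and N-Glycosecretome Profiling by Label-Free Spectral Counting
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end label-free profiling of cell-line secretomes and their
    N-glycosecretomes across a metastatic-potential gradient. Implements
    target-decoy peptide q-values with a stepwise stringent quality-control
    filter, parsimony protein inference with gene-product collapsing,
    spectral-count quantification (SAF1/NSAF5), one-way ANOVA differential
    screening, k-means trend clustering over the metastatic ordering,
    N-glycosite validation from sequon context and the 18O deamidation mass
    shift, precursor-area glycosite quantification, secretion-pathway
    categorization from SignalP/SecretomeP/TMHMM predictor outputs, and the
    contingency-table statistics used for clinicopathological association.
    Includes a synthetic-data generator with planted ground truth so every
    stage is testable without raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
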