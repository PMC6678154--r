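Package: pgxpipe
Title: Proteogenomic Re-Annotation of Gene Models, lncRNAs and Transcript Isoforms
Version: 0.1.0
Authors@R: person("pgxpipe", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A tested, reusable pipeline for proteogenomic re-annotation.
    Translates annotated gene models, predicted long noncoding RNAs and
    alternative-splicing / alternative-polyadenylation transcript isoforms into
    candidate protein databases; validates candidates against peptide-spectrum
    match evidence under target-decoy false-discovery-rate control and a
    two-peptide rule; quantifies validated proteins by normalized spectral
    abundance factors (NSAF) and calls differential expression between two
    samples; classifies transcripts as nonsense-mediated decay (NMD) targets by
    the 50-nt last-junction rule; and compares domain composition across a
    gene's protein isoforms. Ships a synthetic-study generator so the whole
    analysis is exercisable end to end without external data.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
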