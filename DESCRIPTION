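Package: rfpsim
Title: Simulation and Cataloguing of Recurrent False Positive Variant Calls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained simulate/align/call/classify toolkit for studying
    recurrent false positive (RFP) single-nucleotide variant calls, the class of
    miscalls that arises when short sequencing reads are assigned at random
    between near-identical genomic paralogs. The package forges synthetic
    reference genomes with paralogous gene families at controlled divergence and
    full ground truth, simulates paired-end reads with substitution errors,
    aligns them with a deterministic seed-and-extend aligner whose tie-breaking
    reproduces the random-assignment mechanism, calls SNVs with two independent
    rules, and runs the iterative resample-realign-recall procedure that
    classifies variants as consistent, recurrent false positive, or sporadic
    from their call frequency across rounds. Companion tools cover
    population-frequency classification across cohorts, catalogue similarity,
    read-length sweeps, accumulation curves, alignability tracks, and
    blacklist filtering of variant call sets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
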