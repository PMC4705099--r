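Package: cpgswarm
Title: CpG Island Detection by Distance Clustering and Particle Swarm
    Optimization
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two-stage detector of CpG islands in DNA sequences. Stage one
    groups CpG dinucleotides into clusters by the physical distance between
    adjacent CpGs, using a percentile-derived distance threshold, and scores
    each cluster with a negative-binomial tail probability to keep only
    statistically compact clusters. Stage two extends each significant
    cluster by a fixed flank and runs a particle swarm optimizer inside the
    extended region to select the island (start, length) that maximizes a
    fitness combining GC content, observed/expected CpG ratio, and
    normalized length, subject to the Gardiner-Garden-Frommer island
    criteria (length >= 200 bp, GC >= 50%, O/E >= 0.6). Includes base-level
    evaluation metrics (accuracy, sensitivity, specificity, performance
    coefficient, correlation coefficient), FASTA/BED/TSV input and output,
    and a first-order Markov synthetic-genome simulator with planted
    islands for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
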