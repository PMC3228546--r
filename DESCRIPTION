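Package: ocw
Type: Package
Title: Over-Represented and Conserved Word Discovery in Promoter Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identification of candidate transcription-factor binding sites
    from sets of co-expressed gene promoters by word counting. Candidate
    oligo-nucleotides (words) are first screened for over-representation in
    the co-expressed promoters against a background promoter set with a
    one-sided Fisher's exact test, then scored for conservation in
    phylogenetically related promoters with a mutation-degree model: the
    allowed mutational divergence of each orthologous promoter is estimated
    from pairwise local alignment, and the corrected ratio of actual to
    expected occurrences of a word's mutational instances decides whether it
    is conserved. Includes a planted-motif benchmark generator with simulated
    orthologs, composition-matched neutral promoters and noise injection, and
    nucleotide-level evaluation (sensitivity, specificity, positive
    predictive value).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
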