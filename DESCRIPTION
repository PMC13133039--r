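Package: qsce
Title: Quorum-Sensing System Detection, Genomic-Context Clustering and
    Cophylogeny in Rhizobium Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surveying acyl-homoserine-lactone quorum-sensing
    systems (LuxI-like synthase / LuxR-like regulator pairs) across
    multipartite rhizobial genomes. Resolves hmmscan domain hits into
    non-overlapping Pfam domain architectures, detects canonical
    luxI/luxR gene pairs and their configuration within gene-rank
    windows, fingerprints gene neighbourhoods as binary
    architecture profiles and clusters them with Jaccard distances,
    UPGMA and a silhouette-optimal dendrogram cut, groups replicons by
    average-nucleotide-identity rules and assigns trait-based plasmid
    categories, and quantifies LuxI-LuxR codivergence with a
    Procrustean cophylogeny test (Cailliez-corrected principal
    coordinates, Procrustes superimposition, permutation p-values and
    quantile-banded link residuals). A synthetic-data generator emits
    all pipeline inputs with known ground truth for parameter-recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    cluster,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    mclust,
    rtracklayer,
    S4Vectors,
    IRanges,
    GenomicRanges,
    yaml,
    withr
Config/testthat/edition: 3
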