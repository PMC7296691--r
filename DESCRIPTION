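Package: mirnarank
Title: Disease miRNA Prioritization by Random Walk with Restart on
    miRNA-Target Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate disease-associated microRNAs by random walk
    with restart on a heterogeneous bipartite miRNA-target gene network,
    seeding the walk from known disease miRNAs together with their target
    genes. Includes the homogeneous shared-target-similarity baseline,
    leave-one-out cross-validation with AUC and restart/weight parameter
    sweeps, a planted-module synthetic network generator, PubMed
    co-occurrence evidence search with an injectable fetcher, annotated
    network export (SIF and GraphML), a command-line interface and an
    in-process service facade.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
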