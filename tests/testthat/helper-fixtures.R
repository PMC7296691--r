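# Toy 5-edge bipartite fixture used across the suite:
#   m1-{g1,g2}, m2-{g2,g3}, m3-{g4}; m3's component is disjoint from m1/m2's.
toy_edges <- function() {
  data.frame(mirna = c("m1", "m1", "m2", "m2", "m3"),
             gene = c("g1", "g2", "g2", "g3", "g4"),
             stringsAsFactors = FALSE)
}

write_edge_file <- function(edges, path = tempfile(fileext = ".tsv"),
                            delim = "\t", header = FALSE) {
  lines <- paste(edges$mirna, edges$gene, sep = delim)
  if (header) lines <- c(paste("miRNA", "gene", sep = delim), lines)
  writeLines(lines, path)
  path
}

make_network <- function(edges) {
  suppressMessages(load_target_network(write_edge_file(edges)))
}

toy_network <- function() make_network(toy_edges())

write_assoc_file <- function(records, path = tempfile(fileext = ".tsv"),
                             delim = "\t") {
  writeLines(do.call(paste, c(records, sep = delim)), path)
  path
}

make_assoc <- function(disease_id, disease_name, mirna_id) {
  suppressMessages(load_associations(write_assoc_file(
    list(disease_id, disease_name, mirna_id))))
}

# Random connected-enough bipartite network: Bernoulli edges plus one
# repair edge per empty row/column so every node has degree >= 1.
random_network <- function(n_m, n_g, p = 0.2, seed = 1) {
  withr::with_seed(seed, {
    m_ids <- sprintf("m%02d", seq_len(n_m))
    g_ids <- sprintf("g%02d", seq_len(n_g))
    draw <- matrix(runif(n_m * n_g) < p, nrow = n_m,
                   dimnames = list(m_ids, g_ids))
    for (i in which(rowSums(draw) == 0L)) draw[i, sample(n_g, 1L)] <- TRUE
    for (j in which(colSums(draw) == 0L)) draw[sample(n_m, 1L), j] <- TRUE
    idx <- which(draw, arr.ind = TRUE)
    make_network(data.frame(mirna = m_ids[idx[, 1L]],
                            gene = g_ids[idx[, 2L]],
                            stringsAsFactors = FALSE))
  })
}

random_simplex <- function(node_order, seed = 1) {
  withr::with_seed(seed, {
    x <- runif(length(node_order))
    setNames(x / sum(x), node_order)
  })
}

synthetic_files <- function(sim, dir = withr::local_tempdir(.local_envir =
                                                              parent.frame())) {
  net_path <- file.path(dir, "network.tsv")
  assoc_path <- file.path(dir, "associations.tsv")
  write_target_network(sim$network, net_path)
  write_associations(sim$associations, assoc_path)
  list(network = net_path, associations = assoc_path)
}
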