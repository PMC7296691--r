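#' Configuration for the planted-module bipartite network generator
#'
#' Defines a bipartite miRNA-target network in which a subset of miRNAs
#' and genes form a densely interconnected disease module (edge
#' probability `p_in`) against a sparse background (`p_bg`), emulating the
#' modular co-targeting structure that network propagation exploits. Known
#' disease miRNAs are drawn from the module.
#'
#' @param n_mirna Total miRNAs (default 60).
#' @param n_gene Total genes (default 200).
#' @param n_module_mirna Module miRNAs (default 12).
#' @param n_module_gene Module genes (default 40).
#' @param p_in Module miRNA to module gene edge probability (default 0.35).
#' @param p_bg Background edge probability (default 0.02).
#' @param n_known Known disease miRNAs sampled from the module (default 8).
#' @param rng_seed Integer seed; the generated data are fully reproducible
#'   from it.
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_mirna = 60L, n_gene = 200L,
                             n_module_mirna = 12L, n_module_gene = 40L,
                             p_in = 0.35, p_bg = 0.02, n_known = 8L,
                             rng_seed = 1L) {
  cfg <- list(n_mirna = as.integer(n_mirna), n_gene = as.integer(n_gene),
              n_module_mirna = as.integer(n_module_mirna),
              n_module_gene = as.integer(n_module_gene),
              p_in = p_in, p_bg = p_bg, n_known = as.integer(n_known),
              rng_seed = as.integer(rng_seed))
  if (cfg$n_mirna < 1L || cfg$n_gene < 1L) {
    stop("network must have at least one miRNA and one gene", call. = FALSE)
  }
  if (cfg$n_module_mirna > cfg$n_mirna || cfg$n_module_gene > cfg$n_gene) {
    stop("module cannot be larger than the network", call. = FALSE)
  }
  if (cfg$n_module_mirna < 1L || cfg$n_module_gene < 1L) {
    stop("module must contain at least one miRNA and one gene",
         call. = FALSE)
  }
  if (!(p_bg >= 0 && p_bg <= p_in && p_in <= 1)) {
    stop("need 0 <= p_bg <= p_in <= 1", call. = FALSE)
  }
  if (cfg$n_known > cfg$n_module_mirna || cfg$n_known < 1L) {
    stop("n_known must be between 1 and n_module_mirna", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

#' Generate a synthetic miRNA-target network with a planted disease module
#'
#' Edges between module miRNAs and module genes are drawn independently
#' with probability `p_in`; all other miRNA-gene pairs with `p_bg`
#' (Bernoulli edge model). Any degree-0 node is repaired with one
#' uniformly chosen edge, module-respecting for module nodes, so the edge
#' list defines every node. `n_known` module miRNAs are recorded as known
#' miRNAs of the synthetic disease `SYN1`.
#'
#' @param config A `generator_config`, or `NULL` for defaults.
#' @param ... Passed to [generator_config()] when `config` is `NULL`.
#' @return A list with `network` (`mirna_target_network`), `associations`
#'   (`association_table`) and `truth` (module membership:
#'   `module_mirnas`, `module_genes`, `known_mirnas`).
#' @examples
#' sim <- generate_synthetic(rng_seed = 7)
#' sim$network
#' @export
generate_synthetic <- function(config = NULL, ...) {
  cfg <- if (is.null(config)) generator_config(...) else config
  stopifnot(inherits(cfg, "generator_config"))
  withr::with_seed(cfg$rng_seed, {
    mirnas <- sprintf("mir%03d", seq_len(cfg$n_mirna))
    genes <- sprintf("gene%03d", seq_len(cfg$n_gene))
    module_m <- lex_sort(sample(mirnas, cfg$n_module_mirna))
    module_g <- lex_sort(sample(genes, cfg$n_module_gene))

    prob <- matrix(cfg$p_bg, nrow = cfg$n_mirna, ncol = cfg$n_gene,
                   dimnames = list(mirnas, genes))
    prob[module_m, module_g] <- cfg$p_in
    draw <- matrix(stats::runif(length(prob)) < prob, nrow = cfg$n_mirna,
                   dimnames = dimnames(prob))

    # degree-0 repair: one uniform edge, module-respecting for module nodes
    for (m in mirnas[rowSums(draw) == 0L]) {
      pool <- if (m %in% module_m) module_g else genes
      draw[m, sample(pool, 1L)] <- TRUE
    }
    for (g in genes[colSums(draw) == 0L]) {
      pool <- if (g %in% module_g) module_m else mirnas
      draw[sample(pool, 1L), g] <- TRUE
    }

    idx <- which(draw, arr.ind = TRUE)
    net <- new_target_network(mirnas[idx[, 1L]], genes[idx[, 2L]])
    known <- lex_sort(sample(module_m, cfg$n_known))
    assoc <- new_association_table(rep("SYN1", cfg$n_known),
                                   rep("synthetic module disease",
                                       cfg$n_known),
                                   known)
    list(network = net, associations = assoc,
         truth = list(module_mirnas = module_m, module_genes = module_g,
                      known_mirnas = known),
         config = cfg)
  })
}
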