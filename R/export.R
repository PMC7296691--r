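#' Build the annotated result graph around a disease
#'
#' Assembles an igraph object containing the disease node, the
#' top-ranked candidate miRNAs (carrying their `rank` and `score`), the
#' known disease miRNAs, the target genes of all included miRNAs, and —
#' when an evidence table is supplied — one node per supporting PubMed id.
#' Node classes are `disease`, `candidate_mirna`, `known_mirna`, `gene`,
#' `pubmed`; edge classes are `known_association`, `candidate_association`
#' (the classical solid/dashed distinction, as attributes), `targets` and
#' `evidence`.
#'
#' @param ranking A non-empty `mirna_ranking`.
#' @param net The `mirna_target_network` the ranking was computed on.
#' @param assoc An `association_table`.
#' @param disease_id Disease identifier present in `assoc`.
#' @param evidence Optional `evidence_table` for some of the candidates.
#' @param top Keep only the top `top` ranking rows (default: all).
#' @return An igraph graph with node attributes `name`, `node_class`,
#'   `rank`, `score` and edge attribute `edge_class`.
#' @export
build_result_graph <- function(ranking, net, assoc, disease_id,
                               evidence = NULL, top = NULL) {
  stopifnot(inherits(ranking, "mirna_ranking"), nrow(ranking) > 0L,
            inherits(net, "mirna_target_network"),
            inherits(assoc, "association_table"))
  if (!is.null(top)) ranking <- ranking[seq_len(min(top, nrow(ranking))), ]
  known <- intersect(known_mirnas_for(assoc, disease_id), net$mirna_ids)
  cand <- setdiff(ranking$mirna, known)
  ranking <- ranking[ranking$mirna %in% cand, , drop = FALSE]
  mirnas <- c(known, cand)
  genes <- lex_sort(unique(unlist(net$targets[mirnas], use.names = FALSE)))

  nodes <- data.frame(
    name = c(disease_id, cand, known, genes),
    node_class = c("disease", rep("candidate_mirna", length(cand)),
                   rep("known_mirna", length(known)),
                   rep("gene", length(genes))),
    rank = NA_real_, score = NA_real_, stringsAsFactors = FALSE
  )
  nodes$rank[match(ranking$mirna, nodes$name)] <- ranking$rank
  nodes$score[match(ranking$mirna, nodes$name)] <- ranking$score

  edges <- rbind(
    data.frame(from = rep(disease_id, length(known)), to = known,
               edge_class = "known_association", stringsAsFactors = FALSE),
    data.frame(from = rep(disease_id, length(cand)), to = cand,
               edge_class = "candidate_association",
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(mirnas, function(m) {
      tg <- net$targets[[m]]
      data.frame(from = rep(m, length(tg)), to = tg,
                 edge_class = "targets", stringsAsFactors = FALSE)
    }))
  )

  if (!is.null(evidence)) {
    stopifnot(inherits(evidence, "evidence_table"))
    ev <- evidence[evidence$mirna_id %in% mirnas & evidence$n_hits > 0L, ,
                   drop = FALSE]
    if (nrow(ev) > 0L) {
      ev_edges <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
        pmids <- paste0("pmid:", ev$pubmed_ids[[i]])
        data.frame(from = rep(ev$mirna_id[[i]], length(pmids)), to = pmids,
                   edge_class = "evidence", stringsAsFactors = FALSE)
      }))
      pm_nodes <- lex_sort(unique(ev_edges$to))
      nodes <- rbind(nodes, data.frame(name = pm_nodes,
                                       node_class = "pubmed",
                                       rank = NA_real_, score = NA_real_,
                                       stringsAsFactors = FALSE))
      edges <- rbind(edges, ev_edges)
    }
  }
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Export a ranking as an annotated network
#'
#' Writes the result graph of [build_result_graph()] either as GraphML
#' (`<out>.graphml`, attributes embedded) or as SIF plus a node-attribute
#' table (`<out>.sif` with one line per edge using the edge class as the
#' relation, and `<out>.nodes.tsv` with `id`, `node_class`, `rank`,
#' `score`).
#'
#' @inheritParams build_result_graph
#' @param format `"graphml"` or `"sif"`.
#' @param out Output path prefix (extensions are appended).
#' @return Invisibly, the character vector of files written.
#' @export
export_result_graph <- function(ranking, net, assoc, disease_id,
                                evidence = NULL, top = NULL,
                                format = c("graphml", "sif"), out) {
  format <- match.arg(format)
  g <- build_result_graph(ranking, net, assoc, disease_id,
                          evidence = evidence, top = top)
  if (format == "graphml") {
    path <- paste0(out, ".graphml")
    igraph::write_graph(g, path, format = "graphml")
    files <- path
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    sif <- paste0(out, ".sif")
    writeLines(sprintf("%s\t%s\t%s", el$from, el$edge_class, el$to), sif)
    nd <- igraph::as_data_frame(g, what = "vertices")
    attrs <- paste0(out, ".nodes.tsv")
    writeLines(c("id\tnode_class\trank\tscore",
                 sprintf("%s\t%s\t%s\t%s", nd$name, nd$node_class,
                         ifelse(is.na(nd$rank), "NA", format(nd$rank)),
                         ifelse(is.na(nd$score), "NA",
                                sprintf("%.17g", nd$score)))),
               attrs)
    files <- c(sif, attrs)
  }
  invisible(files)
}
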