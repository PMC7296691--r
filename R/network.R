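#' @importFrom stats setNames
NULL

# Canonical identifier form: matching is case-insensitive after trimming,
# so "hsa-miR-506" and "hsa-mir-506" are the same node.
canonical_id <- function(x) tolower(trimws(as.character(x)))

# C-locale lexicographic sort, independent of the session locale.
lex_sort <- function(x) sort(x, method = "radix")

detect_delimiter <- function(line) {
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

# Header heuristic: the first row is a header iff its first field carries
# no digit while the second row's does (ids such as "m1", "hsa-mir-506" or
# "114480" carry digits, column labels such as "miRNA" or "disease_id" do
# not). A file whose ids are all digit-free is read as all data.
looks_like_header <- function(rows) {
  length(rows) > 1L &&
    !grepl("[0-9]", rows[[1L]][[1L]]) &&
    grepl("[0-9]", rows[[2L]][[1L]])
}

read_delimited <- function(path, min_cols) {
  if (!file.exists(path)) stop("file does not exist: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty file: ", path, call. = FALSE)
  delim <- detect_delimiter(lines[[1L]])
  rows <- strsplit(lines, delim, fixed = TRUE)
  if (looks_like_header(rows)) rows <- rows[-1L]
  if (length(rows) == 0L) stop("no data rows in file: ", path, call. = FALSE)
  bad <- which(vapply(rows, length, integer(1)) < min_cols)
  if (length(bad) > 0L) {
    stop("row ", bad[[1L]], " of ", path, " has fewer than ", min_cols,
         " columns", call. = FALSE)
  }
  lapply(seq_len(min_cols), function(k) {
    vapply(rows, function(r) trimws(r[[k]]), character(1))
  })
}

new_target_network <- function(mirna, gene) {
  mirna <- canonical_id(mirna)
  gene <- canonical_id(gene)
  keep <- !duplicated(paste(mirna, gene, sep = "\r"))
  edges <- data.frame(mirna = mirna[keep], gene = gene[keep],
                      stringsAsFactors = FALSE)
  collision <- intersect(unique(edges$mirna), unique(edges$gene))
  if (length(collision) > 0L) {
    stop("identifier(s) used both as miRNA and as gene: ",
         paste(lex_sort(collision), collapse = ", "), call. = FALSE)
  }
  mirna_ids <- lex_sort(unique(edges$mirna))
  gene_ids <- lex_sort(unique(edges$gene))
  edges <- edges[order(edges$mirna, edges$gene, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  targets <- lapply(split(edges$gene, edges$mirna), function(g) lex_sort(unique(g)))
  structure(
    list(
      mirna_ids = mirna_ids,
      gene_ids = gene_ids,
      edges = edges,
      targets = targets[mirna_ids],
      node_order = c(mirna_ids, gene_ids)
    ),
    class = "mirna_target_network"
  )
}

#' Load a bipartite miRNA-target interaction network from an edge list
#'
#' Reads a two-column delimited file (miRNA id, target gene id). The
#' delimiter (tab or comma) is auto-detected from the first line and an
#' optional header row is skipped. Identifiers are matched
#' case-insensitively after trimming whitespace; duplicate edges are
#' dropped. Nodes exist only through edges, so every node has degree >= 1.
#'
#' @param path Path to the edge-list file.
#' @return A `mirna_target_network` with ordered `mirna_ids`, `gene_ids`,
#'   the deduplicated `edges` data frame, a per-miRNA `targets` list and the
#'   canonical `node_order` (all miRNAs first, then all genes, each class
#'   sorted lexicographically).
#' @examples
#' f <- tempfile()
#' writeLines(c("m1\tg1", "m1\tg2", "m2\tg2", "m2\tg3", "m3\tg4"), f)
#' net <- load_target_network(f)
#' length(net$mirna_ids)  # 3
#' @export
load_target_network <- function(path) {
  cols <- read_delimited(path, min_cols = 2L)
  net <- new_target_network(cols[[1L]], cols[[2L]])
  message(sprintf("loaded network: %d miRNAs, %d genes, %d interactions",
                  length(net$mirna_ids), length(net$gene_ids),
                  nrow(net$edges)))
  net
}

#' Write a miRNA-target network back to edge-list format
#'
#' @param net A `mirna_target_network`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return Invisibly, `path`.
#' @export
write_target_network <- function(net, path, delim = "\t") {
  stopifnot(inherits(net, "mirna_target_network"))
  writeLines(paste(net$edges$mirna, net$edges$gene, sep = delim), path)
  invisible(path)
}

#' @export
print.mirna_target_network <- function(x, ...) {
  cat(sprintf("miRNA-target network: %d miRNAs, %d genes, %d interactions\n",
              length(x$mirna_ids), length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

new_association_table <- function(disease_id, disease_name, mirna_id) {
  disease_id <- trimws(as.character(disease_id))
  disease_name <- trimws(as.character(disease_name))
  mirna_id <- canonical_id(mirna_id)
  records <- data.frame(disease_id = disease_id, disease_name = disease_name,
                        mirna_id = mirna_id, stringsAsFactors = FALSE)
  records <- records[!duplicated(records), , drop = FALSE]
  names_per_id <- lapply(split(records$disease_name, records$disease_id),
                         unique)
  conflicted <- names(names_per_id)[vapply(names_per_id, length,
                                           integer(1)) > 1L]
  if (length(conflicted) > 0L) {
    id <- conflicted[[1L]]
    stop("disease id ", id, " carries conflicting names: ",
         paste(dQuote(names_per_id[[id]], q = FALSE), collapse = ", "),
         call. = FALSE)
  }
  records <- records[order(records$disease_id, records$mirna_id,
                           method = "radix"), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(records = records), class = "association_table")
}

#' Load a known disease-miRNA association table
#'
#' Reads a three-column delimited file (disease id, disease name, miRNA id),
#' auto-detecting the delimiter and an optional header as in
#' [load_target_network()]. Exact duplicate records are dropped; a disease
#' id listed under two different names is an error. Disease ids are opaque
#' strings (typically OMIM-style numbers).
#'
#' @param path Path to the association file.
#' @return An `association_table` with a deduplicated `records` data frame.
#' @export
load_associations <- function(path) {
  cols <- read_delimited(path, min_cols = 3L)
  tab <- new_association_table(cols[[1L]], cols[[2L]], cols[[3L]])
  message(sprintf("loaded associations: %d diseases, %d records",
                  length(unique(tab$records$disease_id)), nrow(tab$records)))
  tab
}

#' Write an association table to delimited format
#'
#' @param assoc An `association_table`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return Invisibly, `path`.
#' @export
write_associations <- function(assoc, path, delim = "\t") {
  stopifnot(inherits(assoc, "association_table"))
  r <- assoc$records
  writeLines(paste(r$disease_id, r$disease_name, r$mirna_id, sep = delim),
             path)
  invisible(path)
}

#' @export
print.association_table <- function(x, ...) {
  cat(sprintf("disease-miRNA associations: %d diseases, %d records\n",
              length(unique(x$records$disease_id)), nrow(x$records)))
  invisible(x)
}

#' List diseases in an association table
#'
#' @param assoc An `association_table`.
#' @param query Optional case-insensitive substring matched against disease
#'   names; `NULL` or `""` returns all diseases.
#' @return A data frame of `disease_id`, `disease_name`, `n_known`
#'   (number of associated miRNAs), ordered by `disease_id`. An empty result
#'   is valid.
#' @export
list_diseases <- function(assoc, query = NULL) {
  stopifnot(inherits(assoc, "association_table"))
  r <- assoc$records
  per <- split(r, r$disease_id)
  out <- data.frame(
    disease_id = names(per),
    disease_name = vapply(per, function(d) d$disease_name[[1L]], character(1)),
    n_known = vapply(per, function(d) length(unique(d$mirna_id)), integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$disease_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(query) && nzchar(query)) {
    out <- out[grepl(tolower(query), tolower(out$disease_name),
                     fixed = TRUE), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

known_mirnas_for <- function(assoc, disease_id) {
  r <- assoc$records
  hit <- r$disease_id == trimws(disease_id)
  if (!any(hit)) {
    all_d <- list_diseases(assoc)
    close_ids <- unique(c(
      all_d$disease_id[agrepl(disease_id, all_d$disease_id, ignore.case = TRUE)],
      all_d$disease_id[agrepl(disease_id, all_d$disease_name,
                              ignore.case = TRUE, max.distance = 0.3)]
    ))
    hint <- if (length(close_ids) > 0L) {
      paste0("; close matches: ", paste(close_ids, collapse = ", "))
    } else ""
    stop("unknown disease id: ", disease_id, hint, call. = FALSE)
  }
  lex_sort(unique(r$mirna_id[hit]))
}

#' Derive the two-part seed set for a set of known disease miRNAs
#'
#' The seed set has two parts: `S_m`, the known disease miRNAs present in
#' the network, and `S_g`, the union of the target genes of the members of
#' `S_m`. Identifier matching is case-insensitive after trimming; known
#' miRNAs absent from the network are reported in `dropped`.
#'
#' @param net A `mirna_target_network`.
#' @param known_mirnas Character vector of known disease miRNA ids
#'   (non-empty).
#' @return A `seed_set` with fields `S_m`, `S_g` and `dropped`, all sorted.
#' @export
derive_seed_set <- function(net, known_mirnas) {
  stopifnot(inherits(net, "mirna_target_network"))
  if (length(known_mirnas) == 0L) {
    stop("known_mirnas must be non-empty", call. = FALSE)
  }
  known <- unique(canonical_id(known_mirnas))
  s_m <- lex_sort(intersect(known, net$mirna_ids))
  dropped <- lex_sort(setdiff(known, net$mirna_ids))
  if (length(s_m) == 0L) stop("no seed miRNA in network", call. = FALSE)
  s_g <- lex_sort(unique(unlist(net$targets[s_m], use.names = FALSE)))
  structure(list(S_m = s_m, S_g = s_g, dropped = dropped),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf("seed set: %d seed miRNAs, %d seed genes (%d input ids dropped)\n",
              length(x$S_m), length(x$S_g), length(x$dropped)))
  invisible(x)
}
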