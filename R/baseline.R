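#' Build a homogeneous miRNA similarity network from shared targets
#'
#' Two miRNAs are connected when they share at least one target gene. The
#' edge weight is either the raw count of shared targets
#' (`measure = "shared_count"`) or the Jaccard index of the two target sets
#' (`measure = "jaccard"`). Pairs with an empty intersection are omitted,
#' the weight matrix is symmetric and the diagonal is zero.
#'
#' @param net A `mirna_target_network`.
#' @param measure `"shared_count"` (default) or `"jaccard"`.
#' @return A `mirna_similarity_network`: list with `mirna_ids` and the
#'   sparse symmetric `weights` matrix.
#' @export
build_similarity_network <- function(net,
                                     measure = c("shared_count", "jaccard")) {
  stopifnot(inherits(net, "mirna_target_network"))
  measure <- match.arg(measure)
  mirnas <- net$mirna_ids
  mi <- match(net$edges$mirna, mirnas)
  gi <- match(net$edges$gene, net$gene_ids)
  inc <- Matrix::sparseMatrix(i = mi, j = gi, x = 1,
                              dims = c(length(mirnas),
                                       length(net$gene_ids)))
  shared <- Matrix::tcrossprod(inc)   # shared-target counts, incl. diagonal
  deg <- Matrix::diag(shared)
  diag(shared) <- 0
  shared <- as(Matrix::drop0(shared), "generalMatrix")
  if (measure == "jaccard") {
    trip <- Matrix::mat2triplet(shared)
    if (length(trip$i) > 0L) {
      uni <- deg[trip$i] + deg[trip$j] - trip$x
      shared <- Matrix::sparseMatrix(i = trip$i, j = trip$j,
                                     x = trip$x / uni,
                                     dims = dim(shared))
    }
  }
  dimnames(shared) <- list(mirnas, mirnas)
  structure(list(mirna_ids = mirnas, weights = shared),
            class = "mirna_similarity_network")
}

#' @export
print.mirna_similarity_network <- function(x, ...) {
  cat(sprintf("miRNA similarity network: %d miRNAs, %d weighted pairs\n",
              length(x$mirna_ids), length(x$weights@x) / 2L))
  invisible(x)
}

# Stationary scores of RWR with miRNA-only seeding on the similarity
# network. Isolated miRNAs (zero similarity to everything) cannot be
# normalized into a stochastic column: the walk runs on the non-isolated
# subgraph, isolated miRNAs score exactly 0 and isolated seeds carry no
# initial mass. Returns scores for ALL miRNAs (seeds included).
rwrmda_scores <- function(simnet, S_m, gamma = 0.5, tol = 1e-6,
                          max_iter = 1000L) {
  S_m <- unique(canonical_id(S_m))
  missing <- setdiff(S_m, simnet$mirna_ids)
  if (length(missing) == length(S_m)) {
    stop("no seed miRNA in the similarity network", call. = FALSE)
  }
  S_m <- setdiff(S_m, missing)
  colsum <- Matrix::colSums(simnet$weights)
  active <- simnet$mirna_ids[colsum > 0]
  seeds_active <- intersect(S_m, active)
  if (length(seeds_active) == 0L) {
    stop("all seed miRNAs are isolated in the similarity network",
         call. = FALSE)
  }
  keep <- match(active, simnet$mirna_ids)
  w <- simnet$weights[keep, keep, drop = FALSE]
  w <- w %*% Matrix::Diagonal(x = 1 / Matrix::colSums(w))
  dimnames(w) <- list(active, active)
  p0 <- initial_vector_mirna_only(seeds_active, active)
  run <- propagate(w, p0, gamma = gamma, tol = tol, max_iter = max_iter)
  scores <- setNames(numeric(length(simnet$mirna_ids)), simnet$mirna_ids)
  scores[active] <- run$p_inf
  attr(scores, "n_iter") <- run$n_iter
  scores
}

#' Rank miRNAs by RWR on the homogeneous similarity network (baseline)
#'
#' The comparison method: random walk with restart seeded only from the
#' known disease miRNAs, run on the shared-target miRNA similarity network
#' with its weighted adjacency column-normalized. miRNAs isolated in the
#' similarity network receive score 0 and rank last (ties by id).
#'
#' @param simnet A `mirna_similarity_network`.
#' @param S_m Character vector of seed miRNA ids.
#' @param gamma Restart probability in (0, 1].
#' @param tol L1 convergence threshold.
#' @param max_iter Iteration cap.
#' @return A `mirna_ranking` over all non-seed miRNAs of the similarity
#'   network.
#' @export
rank_rwrmda <- function(simnet, S_m, gamma = 0.5, tol = 1e-6,
                        max_iter = 1000L) {
  stopifnot(inherits(simnet, "mirna_similarity_network"))
  scores <- rwrmda_scores(simnet, S_m, gamma = gamma, tol = tol,
                          max_iter = max_iter)
  cand <- setdiff(simnet$mirna_ids, unique(canonical_id(S_m)))
  s <- as.numeric(scores[cand])
  ord <- order(-s, cand, method = "radix")
  out <- data.frame(rank = seq_along(cand), mirna = cand[ord],
                    score = s[ord], stringsAsFactors = FALSE)
  class(out) <- c("mirna_ranking", "data.frame")
  out
}

#' Write a miRNA similarity network as a three-column TSV
#'
#' One row per unordered pair with positive weight:
#' `mirna_a`, `mirna_b`, `weight`.
#'
#' @param simnet A `mirna_similarity_network`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_network <- function(simnet, path) {
  stopifnot(inherits(simnet, "mirna_similarity_network"))
  trip <- Matrix::mat2triplet(simnet$weights)
  keep <- trip$i < trip$j
  a <- simnet$mirna_ids[trip$i[keep]]
  b <- simnet$mirna_ids[trip$j[keep]]
  w <- trip$x[keep]
  ord <- order(a, b, method = "radix")
  writeLines(c("mirna_a\tmirna_b\tweight",
               sprintf("%s\t%s\t%.17g", a[ord], b[ord], w[ord])), path)
  invisible(path)
}
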