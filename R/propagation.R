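#' Build the column-stochastic transition matrix of a miRNA-target network
#'
#' The bipartite network is treated as an undirected, unweighted graph
#' (miRNA-target regulation is mutual), and the symmetric adjacency matrix
#' is normalized column-wise by node degree, so entry \eqn{(i, j)} is
#' \eqn{A_{ij} / \mathrm{deg}(v_j)}. Every column sums to 1 exactly: the
#' walker at node \eqn{v_j} moves to a uniformly chosen neighbour. Rows and
#' columns follow the network's canonical `node_order` (miRNAs first, then
#' genes, lexicographic within each class).
#'
#' @param net A `mirna_target_network`.
#' @return A `transition_matrix`: a list with the sparse `matrix`
#'   (`Matrix::dgCMatrix`), `node_order`, `n_mirna` and `n_gene`.
#' @export
build_transition_matrix <- function(net) {
  stopifnot(inherits(net, "mirna_target_network"))
  nodes <- net$node_order
  n_m <- length(net$mirna_ids)
  mi <- match(net$edges$mirna, nodes)
  gi <- match(net$edges$gene, nodes)
  adj <- Matrix::sparseMatrix(i = c(mi, gi), j = c(gi, mi), x = 1,
                              dims = c(length(nodes), length(nodes)),
                              dimnames = list(nodes, nodes))
  deg <- Matrix::colSums(adj)
  if (any(deg == 0)) {
    stop("zero-degree node(s): ",
         paste(nodes[deg == 0], collapse = ", "), call. = FALSE)
  }
  w <- adj %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(w) <- list(nodes, nodes)
  structure(
    list(matrix = w, node_order = nodes, n_mirna = n_m,
         n_gene = length(net$gene_ids)),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("transition matrix: %d nodes (%d miRNAs + %d genes), %d non-zeros\n",
              length(x$node_order), x$n_mirna, x$n_gene,
              length(x$matrix@x)))
  invisible(x)
}

check_probability_vector <- function(p, node_order) {
  if (length(p) != length(node_order)) {
    stop("probability vector length does not match node order", call. = FALSE)
  }
  if (any(p < 0)) stop("probability vector has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > 1e-10) {
    stop("probability vector does not sum to 1", call. = FALSE)
  }
  invisible(p)
}

#' Heterogeneous two-part initial probability vector
#'
#' Places mass \eqn{\alpha / |S_m|} on each seed miRNA and
#' \eqn{(1 - \alpha) / |S_g|} on each seed gene; all other entries are
#' zero. The weight `alpha` controls how much disease information starts on
#' the miRNAs themselves versus their target genes. `alpha = 1` is accepted
#' as the degenerate limit and reproduces the miRNA-only seeding of
#' [initial_vector_mirna_only()].
#'
#' @param seeds A `seed_set` (from [derive_seed_set()]).
#' @param alpha Seed weight in (0, 1].
#' @param node_order Character vector of node ids defining the layout.
#' @return Named numeric vector over `node_order`, summing to 1.
#' @export
initial_vector_heterogeneous <- function(seeds, alpha, node_order) {
  stopifnot(inherits(seeds, "seed_set"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1) {
    stop("alpha must be in (0, 1]", call. = FALSE)
  }
  if (length(seeds$S_m) == 0L) stop("empty seed miRNA set", call. = FALSE)
  if (length(seeds$S_g) == 0L && alpha < 1) {
    stop("seed miRNAs have no target genes in the network; ",
         "use miRNA-only seeding (initial_vector_mirna_only)", call. = FALSE)
  }
  p0 <- setNames(numeric(length(node_order)), node_order)
  p0[seeds$S_m] <- alpha / length(seeds$S_m)
  if (alpha < 1) p0[seeds$S_g] <- (1 - alpha) / length(seeds$S_g)
  check_probability_vector(p0, node_order)
}

#' miRNA-only initial probability vector
#'
#' Uniform mass \eqn{1 / |S_m|} on each known disease miRNA, zero
#' elsewhere — the classical seeding used by RWR on homogeneous miRNA
#' networks (the RWRMDA baseline).
#'
#' @param S_m Character vector of seed miRNA ids (non-empty), all present
#'   in `node_order`.
#' @param node_order Character vector of node ids defining the layout.
#' @return Named numeric vector over `node_order`, summing to 1.
#' @export
initial_vector_mirna_only <- function(S_m, node_order) {
  S_m <- unique(canonical_id(S_m))
  if (length(S_m) == 0L) stop("empty seed miRNA set", call. = FALSE)
  if (!all(S_m %in% node_order)) {
    stop("seed miRNA(s) not in node order: ",
         paste(setdiff(S_m, node_order), collapse = ", "), call. = FALSE)
  }
  p0 <- setNames(numeric(length(node_order)), node_order)
  p0[S_m] <- 1 / length(S_m)
  check_probability_vector(p0, node_order)
}

#' Random walk with restart to the stationary distribution
#'
#' Iterates \eqn{p_{t+1} = (1 - \gamma) W' p_t + \gamma p_0} until the L1
#' change \eqn{\|p_{t+1} - p_t\|_1} drops below `tol`. Because \eqn{W'} is
#' column-stochastic, total probability mass is conserved at every step and
#' the residual contracts by at least the factor \eqn{1 - \gamma} per
#' iteration, so convergence within
#' \eqn{\lceil \log(tol/2)/\log(1-\gamma) \rceil} steps is guaranteed.
#'
#' @param W A `transition_matrix`, or any column-stochastic matrix with
#'   dimnames.
#' @param p0 Initial probability vector aligned with the matrix columns.
#' @param gamma Restart probability in (0, 1].
#' @param tol L1 convergence threshold (default `1e-6`).
#' @param max_iter Iteration cap (default 1000).
#' @return A list with `p_inf` (the stationary probability vector),
#'   `n_iter` and `residuals` (the per-step L1 residual trace).
#' @export
propagate <- function(W, p0, gamma = 0.5, tol = 1e-6, max_iter = 1000L) {
  mat <- if (inherits(W, "transition_matrix")) W$matrix else W
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("gamma must be in (0, 1]", call. = FALSE)
  }
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  check_probability_vector(p0, colnames(mat))
  p <- as.numeric(p0)
  residuals <- numeric(0)
  for (it in seq_len(max_iter)) {
    p_next <- (1 - gamma) * as.numeric(mat %*% p) + gamma * as.numeric(p0)
    res <- sum(abs(p_next - p))
    residuals <- c(residuals, res)
    p <- p_next
    if (res < tol) {
      return(list(p_inf = setNames(p, colnames(mat)), n_iter = it,
                  residuals = residuals))
    }
  }
  stop(sprintf("no convergence after %d iterations (last L1 residual %.3g)",
               max_iter, residuals[length(residuals)]), call. = FALSE)
}

#' Closed-form stationary distribution (dense solve)
#'
#' Computes \eqn{\gamma (I - (1-\gamma) W')^{-1} p_0} by a dense linear
#' solve. Intended as an independent oracle for the iterative
#' [propagate()] on small networks (N up to about 2000).
#'
#' @inheritParams propagate
#' @return Named numeric stationary probability vector.
#' @export
stationary_direct <- function(W, p0, gamma) {
  mat <- if (inherits(W, "transition_matrix")) W$matrix else W
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 || gamma > 1) {
    stop("gamma must be in (0, 1] (gamma = 0 makes the system singular)",
         call. = FALSE)
  }
  check_probability_vector(p0, colnames(mat))
  n <- ncol(mat)
  a <- diag(n) - (1 - gamma) * as.matrix(mat)
  setNames(as.numeric(solve(a, gamma * as.numeric(p0))), colnames(mat))
}

#' Rank candidate miRNAs by stationary probability
#'
#' The candidate set is either the explicit `candidates` intersected with
#' the network's miRNAs, or (when `candidates` is `NULL`) all network
#' miRNAs excluding the seed miRNAs. Candidates are sorted by score
#' descending; ties are broken lexicographically by miRNA id. Genes never
#' appear in a ranking.
#'
#' @param p_inf Stationary probability vector aligned with the network's
#'   `node_order`.
#' @param net A `mirna_target_network`.
#' @param S_m Character vector of seed miRNA ids to exclude.
#' @param candidates Optional character vector of candidate miRNA ids.
#' @return A `mirna_ranking` data frame with columns `rank`, `mirna`,
#'   `score`.
#' @export
rank_candidates <- function(p_inf, net, S_m, candidates = NULL) {
  stopifnot(inherits(net, "mirna_target_network"))
  S_m <- unique(canonical_id(S_m))
  if (is.null(candidates)) {
    cand <- setdiff(net$mirna_ids, S_m)
  } else {
    cand_in <- unique(canonical_id(candidates))
    cand <- intersect(cand_in, net$mirna_ids)
    if (length(cand) == 0L) {
      stop("none of the supplied candidate miRNAs is in the network",
           call. = FALSE)
    }
    n_seed_overlap <- length(intersect(cand, S_m))
    if (n_seed_overlap > 0L) {
      warning(n_seed_overlap,
              " candidate(s) are seed miRNAs and were excluded",
              call. = FALSE)
      cand <- setdiff(cand, S_m)
    }
  }
  scores <- as.numeric(p_inf[cand])
  ord <- order(-scores, cand, method = "radix")
  out <- data.frame(rank = seq_along(cand), mirna = cand[ord],
                    score = scores[ord], stringsAsFactors = FALSE)
  class(out) <- c("mirna_ranking", "data.frame")
  out
}

#' @export
print.mirna_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("miRNA ranking: %d candidates\n", nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Write a ranking to TSV with a run-metadata comment header
#'
#' @param ranking A `mirna_ranking`.
#' @param path Output path.
#' @param metadata Optional named list written as `# key: value` comment
#'   lines before the table.
#' @return Invisibly, `path`.
#' @export
write_ranking <- function(ranking, path, metadata = list()) {
  stopifnot(inherits(ranking, "mirna_ranking"))
  header <- vapply(names(metadata), function(k) {
    sprintf("# %s: %s", k, paste(format(metadata[[k]]), collapse = ", "))
  }, character(1))
  body <- sprintf("%d\t%s\t%.17g", ranking$rank, ranking$mirna,
                  ranking$score)
  writeLines(c(header, "rank\tmirna\tscore", body), path)
  invisible(path)
}
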