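#' End-to-end ranking for a disease of interest
#'
#' The core ranking step of the four-step workflow: derive the two-part
#' seed set from the known miRNAs of `disease_id`, build the initial
#' vector, propagate to the stationary distribution and rank the
#' candidates. With `method = "rwrmda"` the homogeneous similarity-network
#' baseline is used instead.
#'
#' @param net A `mirna_target_network` (or a path to an edge-list file).
#' @param assoc An `association_table` (or a path to an association file).
#' @param disease_id Disease identifier present in `assoc`.
#' @param alpha Seed weight in (0, 1] (heterogeneous method).
#' @param gamma Restart probability in (0, 1].
#' @param tol,max_iter Convergence control.
#' @param candidates Optional candidate miRNA ids; default all non-seed
#'   network miRNAs.
#' @param top Optional cap on the number of returned rows.
#' @param method `"rwrmtn"` or `"rwrmda"`.
#' @return A `mirna_ranking` with a `run_info` attribute (seed counts,
#'   dropped ids, iterations, parameters).
#' @export
rank_mirnas <- function(net, assoc, disease_id, alpha = 0.5, gamma = 0.5,
                        tol = 1e-6, max_iter = 1000L, candidates = NULL,
                        top = NULL, method = c("rwrmtn", "rwrmda")) {
  method <- match.arg(method)
  if (is.character(net)) net <- load_target_network(net)
  if (is.character(assoc)) assoc <- load_associations(assoc)
  known <- known_mirnas_for(assoc, disease_id)
  seeds <- derive_seed_set(net, known)
  if (method == "rwrmtn") {
    W <- build_transition_matrix(net)
    p0 <- if (alpha >= 1) {
      initial_vector_mirna_only(seeds$S_m, W$node_order)
    } else {
      initial_vector_heterogeneous(seeds, alpha, W$node_order)
    }
    run <- propagate(W, p0, gamma = gamma, tol = tol, max_iter = max_iter)
    ranking <- rank_candidates(run$p_inf, net, seeds$S_m,
                               candidates = candidates)
    n_iter <- run$n_iter
  } else {
    simnet <- build_similarity_network(net)
    scores <- rwrmda_scores(simnet, seeds$S_m, gamma = gamma, tol = tol,
                            max_iter = max_iter)
    ranking <- rank_candidates(scores, net, seeds$S_m,
                               candidates = candidates)
    n_iter <- attr(scores, "n_iter")
  }
  if (!is.null(top)) {
    ranking <- ranking[seq_len(min(as.integer(top), nrow(ranking))), ,
                       drop = FALSE]
    class(ranking) <- c("mirna_ranking", "data.frame")
  }
  attr(ranking, "run_info") <- list(
    disease_id = disease_id, method = method, alpha = alpha, gamma = gamma,
    tol = tol, n_iter = n_iter, n_seed_mirnas = length(seeds$S_m),
    n_seed_genes = length(seeds$S_g), dropped = seeds$dropped
  )
  message(sprintf(
    "ranked %d candidates for %s (%s): %d seed miRNAs, %d seed genes, %d dropped, %d iterations",
    nrow(ranking), disease_id, method, length(seeds$S_m),
    length(seeds$S_g), length(seeds$dropped), n_iter))
  ranking
}

#' Stateful in-process service facade over a loaded dataset pair
#'
#' Mirrors the four REST-style operations of the automation interface on
#' one network/association pair: list diseases, filter diseases by name,
#' rank candidates for a disease (stored server-side), and retrieve the
#' top rows of the most recent ranking. All operations can return JSON.
#'
#' @param net A `mirna_target_network` or path.
#' @param assoc An `association_table` or path.
#' @return A `mirna_rank_service` list of functions:
#' \describe{
#'   \item{`disease_list(query = NULL, as_json = FALSE)`}{All diseases, or
#'     those whose name matches `query` case-insensitively.}
#'   \item{`rank(disease_id, alpha = 0.5, gamma = 0.5, candidates = NULL,
#'     ...)`}{Runs [rank_mirnas()] and stores the ranking; returns its
#'     number of rows.}
#'   \item{`get_rank(limit, as_json = FALSE)`}{Top `limit` rows of the
#'     stored ranking; an error with a 409 tag if no ranking exists yet.}
#' }
#' @export
mirna_rank_service <- function(net, assoc) {
  if (is.character(net)) net <- load_target_network(net)
  if (is.character(assoc)) assoc <- load_associations(assoc)
  state <- new.env(parent = emptyenv())
  state$ranking <- NULL

  maybe_json <- function(x, as_json) {
    if (as_json) jsonlite::toJSON(x, dataframe = "rows", auto_unbox = TRUE,
                                  digits = NA) else x
  }
  service <- list(
    disease_list = function(query = NULL, as_json = FALSE) {
      maybe_json(list_diseases(assoc, query), as_json)
    },
    rank = function(disease_id, alpha = 0.5, gamma = 0.5,
                    candidates = NULL, ...) {
      state$ranking <- rank_mirnas(net, assoc, disease_id, alpha = alpha,
                                   gamma = gamma, candidates = candidates,
                                   ...)
      invisible(nrow(state$ranking))
    },
    get_rank = function(limit, as_json = FALSE) {
      if (is.null(state$ranking)) {
        stop("no ranking available yet (409): POST a rank request first",
             call. = FALSE)
      }
      limit <- max(0L, as.integer(limit))
      out <- as.data.frame(state$ranking)[
        seq_len(min(limit, nrow(state$ranking))), , drop = FALSE]
      rownames(out) <- NULL
      maybe_json(out, as_json)
    }
  )
  structure(service, class = "mirna_rank_service")
}
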