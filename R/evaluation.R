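# Rank percentile of the held-out miRNA within a fold's candidate scores.
# Half credit for ties: (strictly below + 0.5 * tied others) / (n - 1).
# A strictly top-ranked held-out miRNA scores 1; a fold where every
# candidate ties scores exactly 0.5.
fold_percentile <- function(scores, held_out) {
  s <- scores[[held_out]]
  others <- scores[names(scores) != held_out]
  (sum(others < s) + 0.5 * sum(others == s)) / length(others)
}

# Competition rank of the held-out miRNA under the ranking tie rule
# (score descending, ties lexicographic by id).
fold_rank <- function(scores, held_out) {
  ids <- names(scores)
  ord <- order(-as.numeric(scores), ids, method = "radix")
  which(ids[ord] == held_out)
}

# Stationary scores of all network miRNAs for the heterogeneous method,
# given a prebuilt transition matrix. alpha = 1 degenerates to miRNA-only
# seeding.
rwrmtn_scores <- function(W, net, S_m, alpha = 0.5, gamma = 0.5,
                          tol = 1e-6, max_iter = 1000L) {
  seeds <- derive_seed_set(net, S_m)
  p0 <- if (alpha >= 1 || length(seeds$S_g) == 0L) {
    initial_vector_mirna_only(seeds$S_m, W$node_order)
  } else {
    initial_vector_heterogeneous(seeds, alpha, W$node_order)
  }
  run <- propagate(W, p0, gamma = gamma, tol = tol, max_iter = max_iter)
  scores <- run$p_inf[net$mirna_ids]
  attr(scores, "n_iter") <- run$n_iter
  scores
}

#' Leave-one-out cross-validation of miRNA ranking for one disease
#'
#' Each known disease miRNA present in the network is held out in turn:
#' the remaining known miRNAs seed the walk, all non-seed network miRNAs
#' (held-out included) form the candidate set, and the held-out miRNA's
#' rank percentile is recorded with half credit for ties. The AUC is the
#' mean fold percentile — equivalent to the standard pooled LOOCV ROC
#' construction (see [roc_points()]).
#'
#' The network topology does not change across folds, so the transition
#' matrix (heterogeneous method) or similarity network (baseline) is built
#' once and reused; results are bit-identical to per-fold rebuilding.
#'
#' @param net A `mirna_target_network`.
#' @param assoc An `association_table`.
#' @param disease_id Disease identifier present in `assoc`.
#' @param alpha Seed weight in (0, 1], heterogeneous method only.
#' @param gamma Restart probability in (0, 1].
#' @param tol,max_iter Convergence control for [propagate()].
#' @param method `"rwrmtn"` (heterogeneous miRNA-target network, default)
#'   or `"rwrmda"` (homogeneous similarity-network baseline).
#' @param measure Similarity measure for the baseline (see
#'   [build_similarity_network()]).
#' @return A `loocv_result`: list with `folds` (data frame of
#'   `held_out_mirna`, `rank`, `n_candidates`, `percentile`), `auc`,
#'   `params` and `method`.
#' @export
loocv <- function(net, assoc, disease_id, alpha = 0.5, gamma = 0.5,
                  tol = 1e-6, max_iter = 1000L,
                  method = c("rwrmtn", "rwrmda"),
                  measure = "shared_count") {
  stopifnot(inherits(net, "mirna_target_network"),
            inherits(assoc, "association_table"))
  method <- match.arg(method)
  known <- intersect(known_mirnas_for(assoc, disease_id), net$mirna_ids)
  if (length(known) < 2L) {
    stop("LOOCV needs at least 2 known miRNAs present in the network ",
         "(found ", length(known), ")", call. = FALSE)
  }
  W <- if (method == "rwrmtn") build_transition_matrix(net) else NULL
  simnet <- if (method == "rwrmda") {
    build_similarity_network(net, measure = measure)
  } else NULL

  folds <- lapply(known, function(m) {
    seeds <- setdiff(known, m)
    scores <- if (method == "rwrmtn") {
      rwrmtn_scores(W, net, seeds, alpha = alpha, gamma = gamma,
                    tol = tol, max_iter = max_iter)
    } else {
      rwrmda_scores(simnet, seeds, gamma = gamma, tol = tol,
                    max_iter = max_iter)
    }
    cand <- setdiff(net$mirna_ids, seeds)
    s <- setNames(as.numeric(scores[cand]), cand)
    data.frame(held_out_mirna = m,
               rank = fold_rank(s, m),
               n_candidates = length(cand),
               percentile = fold_percentile(s, m),
               stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, folds)
  rownames(folds) <- NULL
  structure(
    list(folds = folds, auc = mean(folds$percentile),
         params = list(alpha = alpha, gamma = gamma, tol = tol,
                       max_iter = max_iter, measure = measure),
         method = method, disease_id = disease_id),
    class = "loocv_result"
  )
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV (%s, disease %s): %d folds, AUC = %.4f\n",
              x$method, x$disease_id, nrow(x$folds), x$auc))
  invisible(x)
}

#' Pooled ROC points from LOOCV folds
#'
#' At each rank threshold k, the true-positive rate is the fraction of
#' folds whose held-out miRNA ranks within the top k; the false-positive
#' rate is the mean, over folds, of the remaining top-k slots divided by
#' the fold's number of negatives. The trapezoidal area over these points
#' equals the mean-percentile AUC up to ties (within `1/min(n_candidates)`).
#'
#' @param folds The `folds` data frame of a `loocv_result` (columns `rank`
#'   and `n_candidates`), or a `loocv_result`.
#' @return Data frame of `fpr`, `tpr` ordered by threshold, from (0, 0) to
#'   (1, 1), with the trapezoidal `area` as an attribute.
#' @export
roc_points <- function(folds) {
  if (inherits(folds, "loocv_result")) folds <- folds$folds
  stopifnot(nrow(folds) >= 1L, all(folds$rank >= 1L),
            all(folds$rank <= folds$n_candidates))
  ks <- 0:max(folds$n_candidates)
  tpr <- vapply(ks, function(k) mean(folds$rank <= k), numeric(1))
  fpr <- vapply(ks, function(k) {
    mean((pmin(k, folds$n_candidates) - (folds$rank <= k)) /
           (folds$n_candidates - 1L))
  }, numeric(1))
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "area") <- sum(diff(fpr) * (utils::head(tpr, -1) +
                                          utils::tail(tpr, -1)) / 2)
  out
}

#' LOOCV AUC over a grid of weight and restart parameters
#'
#' Runs [loocv()] for every combination of `alpha_values` and
#' `gamma_values`. Defaults reproduce the standard sweep: alpha in
#' \{0.1, 0.3, 0.5, 0.7, 0.9\} and gamma from 0.1 to 0.9 in steps of 0.1
#' (45 cells). Fully deterministic: each cell equals the standalone
#' [loocv()] call with the same parameters.
#'
#' @inheritParams loocv
#' @param alpha_values Numeric vector of seed weights.
#' @param gamma_values Numeric vector of restart probabilities.
#' @return A `sweep_grid`: list with the `auc` matrix (alpha rows x gamma
#'   columns, dimnames carry the values), `alpha_values`, `gamma_values`,
#'   `method`.
#' @export
parameter_sweep <- function(net, assoc, disease_id,
                            alpha_values = c(0.1, 0.3, 0.5, 0.7, 0.9),
                            gamma_values = seq(0.1, 0.9, by = 0.1),
                            method = "rwrmtn", tol = 1e-6,
                            max_iter = 1000L) {
  auc <- matrix(NA_real_, nrow = length(alpha_values),
                ncol = length(gamma_values),
                dimnames = list(alpha = format(alpha_values),
                                gamma = format(gamma_values)))
  for (i in seq_along(alpha_values)) {
    for (j in seq_along(gamma_values)) {
      auc[i, j] <- loocv(net, assoc, disease_id,
                         alpha = alpha_values[[i]],
                         gamma = gamma_values[[j]],
                         tol = tol, max_iter = max_iter,
                         method = method)$auc
    }
  }
  structure(list(auc = auc, alpha_values = alpha_values,
                 gamma_values = gamma_values, method = method,
                 disease_id = disease_id),
            class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  cat(sprintf("parameter sweep (%s, disease %s): %d alpha x %d gamma cells\n",
              x$method, x$disease_id, length(x$alpha_values),
              length(x$gamma_values)))
  print(round(x$auc, 4))
  invisible(x)
}

#' Write a LOOCV result as a TSV report
#'
#' Fold table plus a trailing summary comment line with the AUC.
#'
#' @param result A `loocv_result`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_loocv <- function(result, path) {
  stopifnot(inherits(result, "loocv_result"))
  f <- result$folds
  writeLines(c(
    sprintf("# method: %s", result$method),
    sprintf("# disease: %s", result$disease_id),
    sprintf("# alpha: %g  gamma: %g", result$params$alpha,
            result$params$gamma),
    "held_out_mirna\trank\tn_candidates\tpercentile",
    sprintf("%s\t%d\t%d\t%.17g", f$held_out_mirna, f$rank, f$n_candidates,
            f$percentile),
    sprintf("# AUC: %.17g", result$auc)
  ), path)
  invisible(path)
}

#' Write a sweep grid as TSV (alpha rows, gamma columns)
#'
#' @param grid A `sweep_grid`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sweep <- function(grid, path) {
  stopifnot(inherits(grid, "sweep_grid"))
  header <- paste(c("alpha\\gamma", format(grid$gamma_values)),
                  collapse = "\t")
  rows <- vapply(seq_along(grid$alpha_values), function(i) {
    paste(c(format(grid$alpha_values[[i]]),
            sprintf("%.17g", grid$auc[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}
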