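# Non-negative matrix factorization by Kullback-Leibler multiplicative
# updates (the classic Brunet scheme), with multi-restart consensus.

# One NMF run on V (components x samples). Returns W (m x k), H (k x n),
# the KL objective trace and final objective.
nmf_kl_single <- function(V, k, max_iter = 10000, tol = 1e-6,
                          trace_objective = FALSE) {
  m <- nrow(V); n <- ncol(V)
  eps <- 1e-9
  Vu <- V
  Vu[Vu == 0] <- eps  # pseudo-count inside updates only
  W <- matrix(stats::runif(m * k), m, k)
  H <- matrix(stats::runif(k * n), k, n)

  kl_div <- function(WH) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
  }

  WH <- W %*% H
  obj <- kl_div(WH)
  trace <- if (trace_objective) numeric(max_iter) else NULL
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, Vu / (WH + eps))) / (colSums(W) + eps)
    WH <- W %*% H
    W <- W * ((Vu / (WH + eps)) %*% t(H))
    W <- sweep(W, 2, rowSums(H) + eps, "/")
    WH <- W %*% H
    new_obj <- kl_div(WH)
    if (trace_objective) trace[it] <- new_obj
    if (it %% 10L == 0L || it == max_iter) {
      if (abs(obj - new_obj) <= tol * max(1, abs(obj))) {
        obj <- new_obj
        if (trace_objective) trace <- trace[seq_len(it)]
        break
      }
      obj <- new_obj
    }
  }
  list(W = W, H = H, objective = kl_div(W %*% H), trace = trace)
}

#' Multi-restart NMF of a catalog matrix
#'
#' Factorises the catalog (samples x components) as `V ~ W H` with `V` the
#' transposed catalog, using multiplicative updates under the
#' Kullback-Leibler divergence with random uniform initialisation. The run
#' with the lowest objective is returned together with the consensus matrix:
#' the average over runs of the sample connectivity matrix (1 when two
#' samples share the same dominant signature in `H`).
#'
#' @param catalog Non-negative matrix, samples x components, no all-zero
#'   rows.
#' @param k Factorization rank (number of signatures), `2 <= k <
#'   min(dim(catalog))`.
#' @param n_runs Number of random restarts.
#' @param seed Integer seed; run `r` uses seed `seed + r - 1`, so results
#'   are fully reproducible.
#' @param max_iter,tol Update iteration cap and relative objective tolerance.
#' @param trace_objective Keep the per-iteration objective of each run
#'   (diagnostic).
#' @return A list with `W` (components x k), `H` (k x samples), `objective`,
#'   `objectives` (per run), `consensus` (samples x samples), `best_run`,
#'   and `trace` (objective trace of the best run, if requested).
#' @export
run_nmf <- function(catalog, k, n_runs = 10, seed = 1L, max_iter = 10000,
                    tol = 1e-6, trace_objective = FALSE) {
  V <- t(as.matrix(catalog))
  if (any(V < 0)) stop("catalog must be non-negative", call. = FALSE)
  zero_rows <- rownames(catalog)[colSums(V) == 0]
  if (length(zero_rows)) {
    stop("catalog has all-zero sample row(s): ",
         paste(zero_rows, collapse = ", "), call. = FALSE)
  }
  if (k < 2 || k >= min(dim(V))) {
    stop("rank k must satisfy 2 <= k < min(#samples, #components)",
         call. = FALSE)
  }
  n <- ncol(V)
  consensus <- matrix(0, n, n)
  best <- NULL
  objectives <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    fit <- with_seed(seed + r - 1L,
                     nmf_kl_single(V, k, max_iter, tol, trace_objective))
    objectives[r] <- fit$objective
    assign_cluster <- apply(fit$H, 2, which.max)
    consensus <- consensus + outer(assign_cluster, assign_cluster, "==")
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      best$run <- r
    }
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(rownames(catalog), rownames(catalog))
  rownames(best$W) <- colnames(catalog)
  colnames(best$H) <- rownames(catalog)
  list(W = best$W, H = best$H, objective = best$objective,
       objectives = objectives, consensus = consensus, best_run = best$run,
       trace = best$trace)
}

#' Survey factorization ranks by consensus stability
#'
#' Runs multi-restart NMF at each candidate rank and computes the cophenetic
#' correlation coefficient: the correlation between the consensus
#' dissimilarity (1 - consensus) and the cophenetic distances of its
#' average-linkage hierarchical clustering. A perfectly reproducible
#' clustering gives 1. The suggested rank (largest `k` whose cophenetic
#' coefficient exceeds the next surveyed rank's by at least `margin`) is
#' advisory only; rank choice should also weigh interpretability.
#'
#' @inheritParams run_nmf
#' @param ranks Integer vector of candidate ranks.
#' @param margin Stability margin for the rank suggestion.
#' @return List with `summary` (a `data.frame`: rank, cophenetic, KL
#'   objective, relative reconstruction error), `consensus` (per rank),
#'   and `suggested`.
#' @export
survey_ranks <- function(catalog, ranks, n_runs = 10, seed = 1L,
                         max_iter = 10000, tol = 1e-6, margin = 0.005) {
  ranks <- sort(unique(as.integer(ranks)))
  res <- lapply(ranks, function(k) {
    fit <- run_nmf(catalog, k, n_runs = n_runs, seed = seed,
                   max_iter = max_iter, tol = tol)
    V <- t(as.matrix(catalog))
    recon <- fit$W %*% fit$H
    data_norm <- sqrt(sum(V^2))
    list(cophenetic = cophenetic_coefficient(fit$consensus),
         objective = fit$objective,
         recon_error = sqrt(sum((V - recon)^2)) / data_norm,
         consensus = fit$consensus)
  })
  summary <- data.frame(
    rank = ranks,
    cophenetic = vapply(res, `[[`, numeric(1), "cophenetic"),
    objective = vapply(res, `[[`, numeric(1), "objective"),
    recon_error = vapply(res, `[[`, numeric(1), "recon_error"))
  suggested <- ranks[1L]
  if (length(ranks) > 1L) {
    gain <- summary$cophenetic[-nrow(summary)] - summary$cophenetic[-1L]
    stable <- which(gain >= margin)
    suggested <- if (length(stable)) ranks[max(stable)]
                 else ranks[which.max(summary$cophenetic)]
  }
  list(summary = summary,
       consensus = stats::setNames(lapply(res, `[[`, "consensus"),
                                   paste0("k", ranks)),
       suggested = suggested)
}

# Cophenetic correlation between consensus dissimilarities and the
# cophenetic distances of their average-linkage dendrogram. A degenerate
# zero-variance dissimilarity (all runs identical) counts as perfectly
# stable.
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(1)
  stats::cor(as.vector(d), as.vector(cd))
}
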