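#' De novo signature extraction
#'
#' Runs multi-restart KL-NMF at the chosen rank, takes the best run, scales
#' each signature column of `W` to sum 1 (multiplying the scale factor into
#' the matching exposure row of `H`, so the reconstruction `W H` is
#' unchanged), and orders signatures deterministically. For copy number
#' catalogs the ordering is by ascending weighted-median segment-size bin of
#' the signature's SS block (signatures of short segments first); catalogs
#' without an SS feature (e.g. SBS-96) are ordered by descending total
#' absolute exposure.
#'
#' Absolute exposures are the scaled rows of `H` (samples x k); for an exact
#' factorization a sample's absolute exposures sum to its total catalog
#' count. Relative exposures are absolute exposures row-normalised to sum 1.
#'
#' @inheritParams run_nmf
#' @param sig_prefix Prefix for signature labels (default `"Sig"`).
#' @return A list of class `signature_fit` with elements `signatures`
#'   (components x k matrix, columns sum to 1, attribute `"feature"` gives
#'   the per-component feature when known), `exposure_abs` and
#'   `exposure_rel` (samples x k), `consensus`, `objective(s)`.
#' @export
extract_signatures <- function(catalog, k, n_runs = 10, seed = 1L,
                               max_iter = 10000, tol = 1e-6,
                               sig_prefix = "Sig") {
  fit <- run_nmf(catalog, k, n_runs = n_runs, seed = seed,
                 max_iter = max_iter, tol = tol)
  scale <- colSums(fit$W)
  if (any(scale == 0)) stop("NMF produced an all-zero signature", call. = FALSE)
  W <- sweep(fit$W, 2, scale, "/")
  H <- fit$H * scale  # row a multiplied by scale[a]

  scheme <- attr(catalog, "scheme")
  features <- if (!is.null(scheme)) scheme$feature[match(rownames(W), scheme$label)]
              else NULL
  ord <- signature_order(W, H, features)
  W <- W[, ord, drop = FALSE]
  H <- H[ord, , drop = FALSE]
  labels <- paste0(sig_prefix, seq_len(k))
  colnames(W) <- labels
  rownames(H) <- labels

  exposure_abs <- t(H)
  rs <- rowSums(exposure_abs)
  exposure_rel <- exposure_abs / ifelse(rs == 0, 1, rs)
  if (!is.null(features)) attr(W, "feature") <- features
  structure(list(signatures = W, exposure_abs = exposure_abs,
                 exposure_rel = exposure_rel, consensus = fit$consensus,
                 objective = fit$objective, objectives = fit$objectives,
                 rank = k, seed = seed),
            class = "signature_fit")
}

# Deterministic signature ordering: ascending weighted-median SS bin when
# the SS feature is annotated (mirrors ranking by median altered-segment
# length), else descending total exposure. Ties resolved by column position.
signature_order <- function(W, H, features) {
  if (!is.null(features) && any(features == "SS")) {
    ss_rows <- which(features == "SS")
    key <- vapply(seq_len(ncol(W)), function(j) {
      w <- W[ss_rows, j]
      if (sum(w) == 0) return(Inf)
      w <- w / sum(w)
      which(cumsum(w) >= 0.5)[1L]  # weighted median bin index
    }, numeric(1))
    order(key, seq_len(ncol(W)))
  } else {
    order(-rowSums(H), seq_len(ncol(W)))
  }
}

#' @export
print.signature_fit <- function(x, ...) {
  cat("<signature_fit> rank", x$rank, "-", nrow(x$signatures), "components,",
      nrow(x$exposure_abs), "samples; KL objective",
      format(x$objective, digits = 6), "\n")
  invisible(x)
}

#' Normalise a signature profile matrix
#'
#' `"whole-signature"` divides each signature column by its sum.
#' `"within-feature"` divides, within each signature, every feature block by
#' the block sum so that feature contributions become comparable across
#' features (all-zero blocks are left at zero).
#'
#' @param sigs Signature matrix (components x k) with per-row feature
#'   annotation in attribute `"feature"` (required for within-feature mode),
#'   or a `signature_fit`.
#' @param mode `"within-feature"` or `"whole-signature"`.
#' @param features Optional explicit per-component feature vector.
#' @return The normalised signature matrix.
#' @export
normalize_signatures <- function(sigs,
                                 mode = c("within-feature", "whole-signature"),
                                 features = NULL) {
  mode <- match.arg(mode)
  if (inherits(sigs, "signature_fit")) sigs <- sigs$signatures
  W <- as.matrix(sigs)
  if (mode == "whole-signature") {
    s <- colSums(W)
    out <- sweep(W, 2, ifelse(s == 0, 1, s), "/")
  } else {
    features <- features %||% attr(sigs, "feature")
    if (is.null(features)) {
      stop("within-feature normalization requires per-component feature annotation",
           call. = FALSE)
    }
    out <- W
    for (f in unique(features)) {
      rows <- which(features == f)
      s <- colSums(W[rows, , drop = FALSE])
      out[rows, ] <- sweep(W[rows, , drop = FALSE], 2, ifelse(s == 0, 1, s), "/")
    }
  }
  attr(out, "feature") <- attr(sigs, "feature")
  out
}

#' Cosine similarity between two signature sets
#'
#' @param A,B Signature matrices (components x k) sharing identical component
#'   labels in identical order; `signature_fit` objects accepted.
#' @return Matrix of cosine similarities, signatures of `A` by signatures of
#'   `B`. Zero vectors have similarity 0 by convention.
#' @export
cosine_similarity_matrix <- function(A, B) {
  if (inherits(A, "signature_fit")) A <- A$signatures
  if (inherits(B, "signature_fit")) B <- B$signatures
  A <- as.matrix(A); B <- as.matrix(B)
  if (!identical(rownames(A), rownames(B))) {
    stop("component labels of the two signature sets differ; ",
         "signatures are only comparable on a fixed shared component set",
         call. = FALSE)
  }
  out <- matrix(0, ncol(A), ncol(B), dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A)))
    for (j in seq_len(ncol(B)))
      out[i, j] <- cosine_vec(A[, i], B[, j])
  out
}

#' Cluster samples on the NMF consensus matrix
#'
#' Average-linkage hierarchical clustering of the consensus dissimilarity
#' (1 - consensus), cut into `k` groups. Each group is annotated with its
#' enriched signature: the signature with the highest mean relative exposure
#' within the group (ties broken toward the lower signature index).
#'
#' @param consensus Symmetric consensus matrix in `[0, 1]`.
#' @param k Number of groups.
#' @param exposure_rel Relative exposure matrix (samples x signatures) in
#'   the consensus sample order.
#' @return List with `groups` (named integer vector) and `enriched`
#'   (signature label per group).
#' @export
consensus_cluster_samples <- function(consensus, k, exposure_rel) {
  n <- nrow(consensus)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - consensus), method = "average")
  groups <- stats::cutree(hc, k = k)
  enriched <- vapply(seq_len(k), function(g) {
    mean_exp <- colMeans(exposure_rel[groups == g, , drop = FALSE])
    colnames(exposure_rel)[which.max(mean_exp)]
  }, character(1))
  list(groups = groups, enriched = stats::setNames(enriched, seq_len(k)))
}
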