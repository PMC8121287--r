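#' Fit signature exposures for one catalog row
#'
#' Quantifies the activities of fixed signatures in a single sample by
#' solving the quadratic program `min ||W x - v||^2, x >= 0` (non-negative
#' least squares, Lawson-Hanson active set via [pracma::lsqnonneg()]).
#'
#' An optional simulated-annealing refinement pass (`refine = "anneal"`) can
#' polish the QP solution by random non-negative perturbations accepted under
#' a geometric cooling schedule; it never returns a worse fit than the QP
#' solution and is off by default (the QP optimum is already global for this
#' convex problem, so refinement only matters in pathological conditioning).
#'
#' @param catalog_row Non-negative component count vector; names, when
#'   present, must match the signature component labels.
#' @param sigs Signature matrix (components x k) or a `signature_fit`.
#' @param refine `"none"` (default) or `"anneal"`.
#' @param anneal_steps,anneal_seed Iterations and seed of the refinement
#'   pass.
#' @return List with `absolute` (the NNLS solution) and `relative`
#'   (`x / sum(x)`; all zero when the fit is all zero).
#' @examples
#' W <- diag(2); rownames(W) <- colnames(W) <- c("a", "b")
#' fit_exposures_qp(c(a = 3, b = 5), W)$absolute
#' @export
fit_exposures_qp <- function(catalog_row, sigs, refine = c("none", "anneal"),
                             anneal_steps = 2000, anneal_seed = 1L) {
  refine <- match.arg(refine)
  W <- if (inherits(sigs, "signature_fit")) sigs$signatures else as.matrix(sigs)
  v <- as.numeric(catalog_row)
  if (length(v) != nrow(W)) {
    stop("catalog row length does not match signature components", call. = FALSE)
  }
  if (!is.null(names(catalog_row)) && !is.null(rownames(W)) &&
      !identical(names(catalog_row), rownames(W))) {
    stop("component labels of catalog row and signatures differ", call. = FALSE)
  }
  if (any(v < 0)) stop("catalog row must be non-negative", call. = FALSE)
  if (any(colSums(abs(W)) == 0)) {
    stop("signature matrix has an all-zero column", call. = FALSE)
  }
  x <- pracma::lsqnonneg(W, v)$x
  x <- pmax(x, 0)
  if (refine == "anneal") x <- anneal_refine(W, v, x, anneal_steps,
                                             anneal_seed)
  names(x) <- colnames(W)
  total <- sum(x)
  list(absolute = x,
       relative = if (total > 0) x / total else x * 0)
}

# Simulated-annealing polish of a non-negative exposure vector: random
# coordinate perturbations under geometric cooling; the incumbent best
# solution is kept, so the result is never worse than the input.
anneal_refine <- function(W, v, x0, steps = 2000, seed = 1L) {
  obj <- function(x) sum((W %*% x - v)^2)
  with_seed(seed, {
    x <- best <- x0
    f_x <- f_best <- obj(x0)
    temp <- max(f_x, 1)
    scale <- max(x0, 1)
    for (s in seq_len(steps)) {
      cand <- x
      j <- sample.int(length(x), 1L)
      cand[j] <- max(0, cand[j] + stats::rnorm(1, 0, 0.05 * scale))
      f_cand <- obj(cand)
      if (f_cand < f_x || stats::runif(1) < exp((f_x - f_cand) / temp)) {
        x <- cand; f_x <- f_cand
      }
      if (f_x < f_best) { best <- x; f_best <- f_x }
      temp <- temp * 0.995
    }
    best
  })
}

#' Fit exposures for every sample of a catalog
#'
#' @param catalog Samples x components matrix.
#' @inheritParams fit_exposures_qp
#' @return List with `absolute` and `relative` exposure matrices
#'   (samples x k).
#' @export
fit_exposures <- function(catalog, sigs) {
  W <- if (inherits(sigs, "signature_fit")) sigs$signatures else as.matrix(sigs)
  res <- apply(as.matrix(catalog), 1, function(v) fit_exposures_qp(v, W),
               simplify = FALSE)
  list(absolute = do.call(rbind, lapply(res, `[[`, "absolute")),
       relative = do.call(rbind, lapply(res, `[[`, "relative")))
}

#' Bootstrap stability of single-sample exposures
#'
#' Resamples the sample's catalog `n_boot` times from a multinomial with the
#' observed component probabilities (total count preserved), refits
#' exposures for each bootstrap catalog, and summarises per-signature
#' instability as the RMSE between bootstrap and original relative
#' exposures. The presence p-value of a signature is the fraction of
#' bootstrap draws in which its relative exposure is at or below
#' `exposure_cutoff`: a small p-value means the exposure credibly exceeds
#' the cutoff.
#'
#' @inheritParams fit_exposures_qp
#' @param n_boot Number of bootstrap catalogs.
#' @param exposure_cutoff Relative exposure threshold defining "present".
#' @param seed Integer seed (results are fully reproducible).
#' @return A list of class `bootstrap_result`: `original` (absolute +
#'   relative exposures), `boot_rel` (n_boot x k), `rmse`, `p_value`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_stability <- function(catalog_row, sigs, n_boot = 1000,
                                exposure_cutoff = 0.01, seed = 1L) {
  W <- if (inherits(sigs, "signature_fit")) sigs$signatures else as.matrix(sigs)
  v <- as.numeric(catalog_row)
  n <- sum(v)
  if (n <= 0) stop("catalog row has zero total count", call. = FALSE)
  orig <- fit_exposures_qp(catalog_row, W)
  boot_rel <- with_seed(seed, {
    draws <- stats::rmultinom(n_boot, size = n, prob = v / n)
    t(apply(draws, 2, function(b) fit_exposures_qp(b, W)$relative))
  })
  colnames(boot_rel) <- colnames(W)
  rmse <- sqrt(colMeans((boot_rel -
    matrix(orig$relative, n_boot, ncol(W), byrow = TRUE))^2))
  p_value <- colMeans(boot_rel <= exposure_cutoff)
  structure(list(original = orig, boot_rel = boot_rel, rmse = rmse,
                 p_value = p_value, n_boot = n_boot, seed = seed),
            class = "bootstrap_result")
}

#' Cohort-level signature detection
#'
#' A tumor supports a signature when its bootstrap presence p-value is below
#' `p_cutoff` (its relative exposure credibly exceeds `exposure_cutoff`); a
#' signature is detected when strictly more than `min_tumors` tumors support
#' it.
#'
#' @param catalog Samples x components matrix (rows with zero totals are an
#'   error).
#' @inheritParams bootstrap_stability
#' @param p_cutoff Presence p-value cutoff.
#' @param min_tumors Detection requires more than this many supporting
#'   tumors.
#' @return List with `detected` (named logical), `support` (logical samples
#'   x k), `p_values` (samples x k), `n_support`.
#' @export
detect_signatures <- function(catalog, sigs, exposure_cutoff = 0.01,
                              p_cutoff = 0.05, min_tumors = 10,
                              n_boot = 1000, seed = 1L) {
  catalog <- as.matrix(catalog)
  if (nrow(catalog) == 0L) stop("empty cohort", call. = FALSE)
  W <- if (inherits(sigs, "signature_fit")) sigs$signatures else as.matrix(sigs)
  p_values <- t(vapply(seq_len(nrow(catalog)), function(i) {
    bootstrap_stability(catalog[i, ], W, n_boot = n_boot,
                        exposure_cutoff = exposure_cutoff,
                        seed = seed + i)$p_value
  }, numeric(ncol(W))))
  dimnames(p_values) <- list(rownames(catalog), colnames(W))
  support <- p_values < p_cutoff
  n_support <- colSums(support)
  list(detected = n_support > min_tumors, support = support,
       p_values = p_values, n_support = n_support)
}

#' Detection probability versus cohort sampling fraction
#'
#' Estimates, for each sampling fraction, the probability that a subsample
#' of the cohort (drawn without replacement) still detects every signature
#' under the [detect_signatures()] rule. Per-tumor bootstrap support is
#' computed once on the full cohort; each repetition re-applies the
#' cohort-level detection rule to the subsample.
#'
#' @inheritParams detect_signatures
#' @param fractions Sampling fractions in `(0, 1]`.
#' @param reps Repetitions per fraction.
#' @return `data.frame` with columns `fraction`, `n_sampled`,
#'   `detection_probability`.
#' @export
detection_probability_curve <- function(catalog, sigs, fractions,
                                        reps = 1000, seed = 1L,
                                        exposure_cutoff = 0.01,
                                        p_cutoff = 0.05, min_tumors = 10,
                                        n_boot = 1000) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("sampling fractions must lie in (0, 1]", call. = FALSE)
  }
  n <- nrow(catalog)
  if (any(floor(fractions * n) < 1)) {
    stop("smallest fraction subsamples fewer than one tumor", call. = FALSE)
  }
  det <- detect_signatures(catalog, sigs, exposure_cutoff = exposure_cutoff,
                           p_cutoff = p_cutoff, min_tumors = min_tumors,
                           n_boot = n_boot, seed = seed)
  prob <- with_seed(seed, vapply(sort(fractions), function(f) {
    size <- floor(f * n)
    hits <- vapply(seq_len(reps), function(r) {
      idx <- sample.int(n, size)
      all(colSums(det$support[idx, , drop = FALSE]) > min_tumors)
    }, logical(1))
    mean(hits)
  }, numeric(1)))
  data.frame(fraction = sort(fractions),
             n_sampled = floor(sort(fractions) * n),
             detection_probability = prob)
}
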