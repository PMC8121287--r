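# Small planted-factor catalogs keep the NMF tests fast and exactly checkable.
planted_catalog <- function(m = 30, n = 40, k = 2, seed = 42, scale = 50) {
  set.seed(seed)
  W0 <- matrix(0, m, k)
  block <- split(seq_len(m), cut(seq_len(m), k, labels = FALSE))
  for (j in seq_len(k)) W0[block[[j]], j] <- runif(length(block[[j]]), 0.5, 1)
  H0 <- matrix(runif(k * n, 0, scale), k, n)
  catalog <- t(W0 %*% H0)
  dimnames(catalog) <- list(paste0("s", seq_len(n)), paste0("c", seq_len(m)))
  list(catalog = catalog, W0 = W0, H0 = H0)
}

test_that("an exactly low-rank catalog is reconstructed to machine precision", {
  pc <- planted_catalog()
  fit <- run_nmf(pc$catalog, k = 2, n_runs = 5, seed = 1)
  rel_err <- sqrt(sum((t(pc$catalog) - fit$W %*% fit$H)^2)) /
    sqrt(sum(pc$catalog^2))
  expect_lt(rel_err, 1e-6)
})

test_that("NMF is deterministic given a seed and validates its inputs", {
  pc <- planted_catalog()
  f1 <- run_nmf(pc$catalog, 2, n_runs = 3, seed = 9)
  f2 <- run_nmf(pc$catalog, 2, n_runs = 3, seed = 9)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)

  expect_error(run_nmf(pc$catalog, 1, seed = 1), "rank")
  bad <- pc$catalog; bad[3, ] <- 0
  expect_error(run_nmf(bad, 2, seed = 1), "all-zero sample row.*s3")
})

test_that("the consensus matrix is symmetric with unit diagonal", {
  pc <- planted_catalog()
  fit <- run_nmf(pc$catalog, 2, n_runs = 5, seed = 1)
  expect_true(isSymmetric(fit$consensus))
  expect_equal(unname(diag(fit$consensus)), rep(1, nrow(pc$catalog)))
  expect_true(all(fit$consensus >= 0 & fit$consensus <= 1))
})

test_that("the KL objective is non-increasing across updates", {
  pc <- planted_catalog(seed = 3)
  noisy <- pc$catalog + matrix(rpois(length(pc$catalog), 2),
                               nrow(pc$catalog))
  fit <- run_nmf(noisy, 3, n_runs = 1, seed = 2, trace_objective = TRUE)
  diffs <- diff(fit$trace)
  expect_true(all(diffs <= 1e-8 * max(1, abs(fit$trace[1]))))
})

test_that("two duplicated sample blocks give perfect consensus at k = 2", {
  set.seed(4)
  a <- c(rpois(10, 20), rep(0, 10))
  b <- c(rep(0, 10), rpois(10, 20))
  catalog <- rbind(matrix(rep(a, 6), 6, byrow = TRUE),
                   matrix(rep(b, 6), 6, byrow = TRUE))
  dimnames(catalog) <- list(paste0("s", 1:12), paste0("c", 1:20))
  sv <- survey_ranks(catalog, 2, n_runs = 5, seed = 1)
  expect_equal(nrow(sv$summary), 1)
  expect_equal(sv$summary$cophenetic, 1)
  cons <- sv$consensus$k2
  expect_true(all(cons[1:6, 1:6] == 1))
  expect_true(all(cons[7:12, 7:12] == 1))
  expect_true(all(cons[1:6, 7:12] == 0))
})

test_that("extracted signatures recover planted factors up to scale", {
  pc <- planted_catalog(seed = 12)
  fit <- extract_signatures(pc$catalog, 2, n_runs = 5, seed = 1)
  expect_equal(unname(colSums(fit$signatures)), c(1, 1))
  W0n <- sweep(pc$W0, 2, colSums(pc$W0), "/")
  rownames(W0n) <- colnames(pc$catalog)
  cs <- cosine_similarity_matrix(W0n, fit$signatures)
  best <- apply(cs, 1, max)
  expect_true(all(best >= 0.99))
})

test_that("exposure scaling preserves the reconstruction and row-normalization", {
  pc <- planted_catalog(seed = 8)
  raw <- run_nmf(pc$catalog, 2, n_runs = 3, seed = 5)
  fit <- extract_signatures(pc$catalog, 2, n_runs = 3, seed = 5)
  # column-scaled W times inversely scaled H equals the raw product
  expect_equal(fit$signatures %*% t(fit$exposure_abs), raw$W %*% raw$H,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(rowSums(fit$exposure_rel)),
               rep(1, nrow(pc$catalog)))
  # near-exact factorization: absolute exposures sum to the catalog total
  expect_equal(unname(rowSums(fit$exposure_abs)),
               unname(rowSums(pc$catalog)), tolerance = 1e-3)
})

test_that("signature profile normalization handles feature blocks and zeros", {
  W <- matrix(c(2, 2, 0, 0, 1, 3), 3, 2)
  rownames(W) <- c("F1[a]", "F1[b]", "F2[a]")
  attr(W, "feature") <- c("F1", "F1", "F2")
  wf <- normalize_signatures(W, "within-feature")
  expect_equal(unname(wf[, 1]), c(0.5, 0.5, 0))    # zero block stays zero
  expect_false(anyNA(wf))
  ws <- normalize_signatures(W, "whole-signature")
  expect_equal(unname(colSums(ws)), c(1, 1))
})

test_that("cosine similarity matches closed forms and enforces shared components", {
  A <- cbind(s1 = c(1, 1, 0), s2 = c(1, 0, 0), s3 = c(0, 1, 0))
  rownames(A) <- paste0("c", 1:3)
  cs <- cosine_similarity_matrix(A, A)
  expect_equal(unname(diag(cs)), rep(1, 3))
  expect_equal(unname(cs["s2", "s3"]), 0)
  expect_equal(unname(cs["s1", "s2"]), 1 / sqrt(2))
  B <- A; rownames(B) <- paste0("x", 1:3)
  expect_error(cosine_similarity_matrix(A, B), "component labels")
})

test_that("consensus clustering recovers blocks and labels enrichment", {
  cons <- matrix(0, 6, 6)
  cons[1:3, 1:3] <- 1; cons[4:6, 4:6] <- 1
  dimnames(cons) <- list(paste0("s", 1:6), paste0("s", 1:6))
  expos <- rbind(matrix(rep(c(0.9, 0.1), 3), 3, byrow = TRUE),
                 matrix(rep(c(0.2, 0.8), 3), 3, byrow = TRUE))
  colnames(expos) <- c("Sig1", "Sig2")
  rownames(expos) <- paste0("s", 1:6)
  cl <- consensus_cluster_samples(cons, 2, expos)
  expect_equal(unname(cl$groups), rep(1:2, each = 3))
  expect_equal(unname(cl$enriched), c("Sig1", "Sig2"))
  cl_all <- consensus_cluster_samples(cons, 6, expos)
  expect_equal(length(unique(cl_all$groups)), 6)
  expect_error(consensus_cluster_samples(cons, 7, expos), "exceeds")
})
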