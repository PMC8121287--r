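well_conditioned_sigs <- function() {
  W <- cbind(c(0.6, 0.2, 0.1, 0.1), c(0.1, 0.6, 0.2, 0.1),
             c(0.1, 0.1, 0.2, 0.6))
  dimnames(W) <- list(paste0("c", 1:4), paste0("Sig", 1:3))
  W
}

test_that("identity signatures fit exactly and degenerate inputs behave", {
  W <- diag(2); dimnames(W) <- list(c("a", "b"), c("S1", "S2"))
  fit <- fit_exposures_qp(c(a = 3, b = 5), W)
  expect_equal(unname(fit$absolute), c(3, 5))
  fit0 <- fit_exposures_qp(c(a = 0, b = 0), W)
  expect_equal(unname(fit0$absolute), c(0, 0))
  expect_equal(unname(fit0$relative), c(0, 0))
  expect_error(fit_exposures_qp(c(x = 1, y = 1), W), "labels")
  expect_error(fit_exposures_qp(c(1, 1), cbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("planted exposures are recovered to 1e-6 relative error", {
  W <- well_conditioned_sigs()
  set.seed(17)
  for (i in 1:10) {
    x0 <- runif(3, 1, 100)
    v <- as.numeric(W %*% x0)
    x <- fit_exposures_qp(v, W)$absolute
    expect_lt(max(abs(x - x0) / x0), 1e-6)
  }
})

test_that("NNLS equals exhaustive grid search within grid resolution", {
  W <- well_conditioned_sigs()
  set.seed(23)
  step <- 0.01
  grid <- expand.grid(a = seq(0, 1, step), b = seq(0, 1, step))
  grid <- grid[grid$a + grid$b <= 1, ]
  grid$c <- 1 - grid$a - grid$b
  for (rep in 1:3) {
    v <- as.numeric(W %*% runif(3, 5, 50)) + rpois(4, 1)
    n <- sum(v)
    X <- t(as.matrix(grid)) * n          # 3 x n_grid candidate exposures
    resid <- colSums((W %*% X - v)^2)
    x_grid <- X[, which.min(resid)]
    x_qp <- fit_exposures_qp(v, W)$absolute
    # QP must be at least as good as the best grid point, and close to it
    expect_lte(sum((W %*% x_qp - v)^2), min(resid) + 1e-9)
    expect_lt(max(abs(x_qp - x_grid)), step * n + 1e-9)
  }
})

test_that("bootstrap of a pure catalog gives closed-form stability", {
  W <- diag(2); dimnames(W) <- list(c("a", "b"), c("S1", "S2"))
  bs <- bootstrap_stability(c(a = 100, b = 0), W, n_boot = 200, seed = 1)
  expect_equal(unname(bs$p_value), c(0, 1))
  expect_equal(unname(bs$rmse), c(0, 0))
  bs2 <- bootstrap_stability(c(a = 100, b = 0), W, n_boot = 200, seed = 1)
  expect_identical(bs$boot_rel, bs2$boot_rel)
  expect_error(bootstrap_stability(c(a = 0, b = 0), W), "zero total")
})

test_that("bootstrap RMSE shrinks like 1/sqrt(n)", {
  W <- well_conditioned_sigs()
  v <- as.numeric(W %*% c(30, 50, 20))
  v4 <- v * 4
  b1 <- bootstrap_stability(v, W, n_boot = 500, seed = 3)
  b4 <- bootstrap_stability(v4, W, n_boot = 500, seed = 3)
  ratio <- b4$rmse / b1$rmse
  expect_true(all(ratio > 0.35 & ratio < 0.65))
})

test_that("bootstrap relative exposures are unbiased at large n_boot", {
  W <- well_conditioned_sigs()
  v <- round(as.numeric(W %*% c(300, 500, 200)))
  bs <- bootstrap_stability(v, W, n_boot = 5000, seed = 7)
  expect_lt(max(abs(colMeans(bs$boot_rel) - bs$original$relative)), 0.01)
})

test_that("cohort detection follows the supporting-tumor rule", {
  W <- diag(3) + 0.05
  dimnames(W) <- list(paste0("c", 1:3), paste0("Sig", 1:3))
  pure1 <- matrix(rep(c(200, 0, 0), 20), 20, byrow = TRUE,
                  dimnames = list(paste0("t", 1:20), paste0("c", 1:3)))
  det <- detect_signatures(pure1, W, n_boot = 100, seed = 1)
  expect_true(det$detected[["Sig1"]])
  expect_false(any(det$detected[c("Sig2", "Sig3")]))

  single <- pure1[1, , drop = FALSE]
  det1 <- detect_signatures(single, W, min_tumors = 0, n_boot = 100, seed = 1)
  expect_true(det1$detected[["Sig1"]])
  expect_error(detect_signatures(pure1[0, , drop = FALSE], W), "empty cohort")
})

test_that("detection probability is monotone and reaches 1 at full sampling", {
  W <- diag(3)
  dimnames(W) <- list(paste0("c", 1:3), paste0("Sig", 1:3))
  set.seed(9)
  catalog <- do.call(rbind, lapply(1:45, function(i) {
    x <- c(20, 20, 20); x[(i %% 3) + 1] <- 400; x
  }))
  dimnames(catalog) <- list(paste0("t", 1:45), paste0("c", 1:3))
  curve <- detection_probability_curve(catalog, W,
                                       fractions = c(0.25, 0.5, 0.75, 1),
                                       reps = 200, seed = 2, n_boot = 100)
  expect_true(all(diff(curve$detection_probability) >= 0))
  expect_equal(curve$detection_probability[curve$fraction == 1], 1)
  # subsampling 11 tumors can never exceed the >10 supporting-tumor rule
  tiny <- detection_probability_curve(catalog, W, fractions = 0.2,
                                      reps = 50, seed = 2, n_boot = 100)
  expect_equal(tiny$detection_probability, 0)
  expect_error(detection_probability_curve(catalog, W, fractions = 1.2,
                                           reps = 10, seed = 1), "fractions")
})

test_that("annealing refinement never degrades the QP objective", {
  W <- well_conditioned_sigs()
  set.seed(31)
  for (i in 1:5) {
    v <- as.numeric(W %*% runif(3, 5, 50)) + rpois(4, 2)
    plain <- fit_exposures_qp(v, W)$absolute
    refined <- fit_exposures_qp(v, W, refine = "anneal",
                                anneal_steps = 500)$absolute
    expect_lte(sum((W %*% refined - v)^2), sum((W %*% plain - v)^2) + 1e-9)
  }
})
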