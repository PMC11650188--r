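test_that("signed split is an exact decomposition", {
  z <- matrix(c(1.5, -2.0), 1, 2, dimnames = list(NULL, c("roi_001", "roi_002")))
  sp <- split_signed(z)
  expect_equal(unname(sp$pos), matrix(c(1.5, 0), 1))
  expect_equal(unname(sp$neg), matrix(c(0, 2.0), 1))

  zneg <- matrix(-abs(rnorm(20)), 4, 5)
  expect_true(all(split_signed(zneg)$pos == 0))

  set.seed(1)
  zr <- matrix(rnorm(200), 20, 10)
  spr <- split_signed(zr)
  expect_equal(spr$pos - spr$neg, zr, tolerance = 1e-15)
})

test_that("NMF recovers planted factorizations", {
  pl <- planted_nonneg(n = 60, r = 30, k = 2, seed = 1)
  fm <- fit_nmf(pl$X, 2, seed = 1)
  rel_err <- norm(pl$X - fm$W %*% fm$F, "F") / norm(pl$X, "F")
  expect_lt(rel_err, 1e-3)
  expect_true(all(fm$W >= 0) && all(fm$F >= 0))
  expect_true(all(diff(fm$objective) <= 1e-10))
  expect_equal(fm$residual, pl$X - fm$W %*% fm$F, ignore_attr = TRUE)

  # rank-1 identifiability up to scale
  set.seed(2)
  u <- rgamma(40, 2); v <- rgamma(25, 2)
  fm1 <- fit_nmf(3 * outer(u, v), 1, seed = 1)
  expect_gt(cor(fm1$F[1, ], v), 0.999)

  expect_error(fit_nmf(matrix(-1, 4, 4), 2), "split_signed")
  expect_error(fit_nmf(matrix(1, 4, 4) + diag(4), 4), "smaller")
  expect_warning(fit_nmf(rbind(pl$X, 0), 2, seed = 1), "all-zero")
})

test_that("NMF is deterministic given a seed", {
  pl <- planted_nonneg(n = 40, r = 20, k = 3, noise = 0.3, seed = 3)
  f1 <- fit_nmf(pl$X, 3, seed = 9)
  f2 <- fit_nmf(pl$X, 3, seed = 9)
  expect_identical(f1$F, f2$F)
  expect_identical(f1$W, f2$W)
})

test_that("weight projection solves row-wise NNLS exactly", {
  set.seed(4)
  F0 <- matrix(rgamma(2 * 30, 2), 2, 30)
  W0 <- matrix(rgamma(12 * 2, 2), 12, 2)
  W_hat <- project_weights(F0, W0 %*% F0)
  expect_lt(max(abs(W_hat - W0)), 1e-6)

  expect_equal(unname(project_weights(F0, matrix(0, 3, 30))),
               matrix(0, 3, 2))

  pl <- planted_nonneg(n = 30, r = 20, k = 2, noise = 0.5, seed = 5)
  fm <- fit_nmf(pl$X, 2, seed = 1)
  W_proj <- project_weights(fm, pl$X)
  err_proj <- norm(pl$X - W_proj %*% fm$F, "F")
  err_train <- fm$objective[length(fm$objective)]
  expect_lte(err_proj, err_train + 1e-8)

  expect_error(project_weights(F0, matrix(1, 3, 10)), "mismatch")
})

test_that("generalizability error vanishes for exact low-rank input", {
  # disjoint-support factors and sparse weights (many near-anchor rows)
  # make the factorization identifiable, so held-out reconstruction is
  # exact in the noiseless limit
  set.seed(6)
  F0 <- rbind(c(rgamma(12, 2), rep(0, 12)), c(rep(0, 12), rgamma(12, 2)))
  W0 <- matrix(rgamma(60 * 2, 0.4), 60, 2)
  pl <- list(X = W0 %*% F0)
  ge_mean <- generalization_error(pl$X, 2, n_repeats = 3, seed = 1,
                                  form = "mean", tol = 1e-12,
                                  max_iter = 3000)
  expect_true(all(ge_mean$ge < 1e-3))
  ge_diff <- generalization_error(pl$X, 2, n_repeats = 3, seed = 1,
                                  form = "difference", tol = 1e-12,
                                  max_iter = 3000)
  expect_true(all(abs(ge_diff$ge) < 1e-3))
  expect_error(generalization_error(pl$X[1:6, ], 2), "at least 8")
  expect_error(generalization_error(pl$X, 24), "infeasible")
})

test_that("out-of-sample errors dominate in-sample errors on average", {
  sim <- simulate_deviation_matrix(100, 30, seed = 7)
  sp <- split_signed(sim$z)
  ge <- generalization_error(sp$pos, 2, n_repeats = 10, seed = 2)
  expect_gte(mean(ge$e12), mean(ge$e11))
  expect_gte(mean(ge$e21), mean(ge$e22))
})

test_that("select_k recovers the planted bank size", {
  sim <- simulate_deviation_matrix(150, 40, seed = 8)
  sp <- split_signed(sim$z)
  sel <- select_k(sp$pos, k_range = 2:5, n_repeats = 8, seed = 3)
  expect_equal(sel$k_best, 2)
  expect_s3_class(sel$ge, "ge_curve")
  expect_identical(attr(sel$ge, "k_best"), sel$k_best)
  expect_error(select_k(sp$pos, k_range = integer(0)), "empty")
})

test_that("Hungarian matching equals brute-force assignment and inverts permutations", {
  set.seed(9)
  f_a <- matrix(rgamma(4 * 30, 2), 4, 30,
                dimnames = list(paste0("a", 1:4), sprintf("roi_%03d", 1:30)))
  perm <- c(3, 1, 4, 2)
  f_b <- f_a[perm, ]
  rownames(f_b) <- paste0("b", 1:4)
  m <- match_factors(f_a, f_b)
  expect_equal(m$r, rep(1, 4), tolerance = 1e-12)
  # pairing inverts the permutation: a_i is matched with b_{perm^-1(i)}
  expect_equal(m$factor_b[match(paste0("a", perm), m$factor_a)],
               paste0("b", 1:4))

  # small perturbation leaves the pairing intact, equal to exhaustive search
  f_b2 <- f_a + matrix(rnorm(120, 0, 0.01), 4, 30)
  rownames(f_b2) <- paste0("b", 1:4)
  m2 <- match_factors(f_a, f_b2)
  bf <- brute_force_match(f_a, f_b2)
  expect_equal(match(m2$factor_b, paste0("b", 1:4)),
               bf[match(m2$factor_a, paste0("a", 1:4))])

  # random factor sets: optimal total correlation matches brute force
  f_c <- matrix(rgamma(4 * 30, 2), 4, 30)
  m3 <- match_factors(f_a, f_c)
  cm <- cor(t(f_a), t(f_c))
  bf3 <- brute_force_match(f_a, f_c)
  expect_equal(sum(m3$r), sum(cm[cbind(1:4, bf3)]), tolerance = 1e-12)

  expect_error(match_factors(f_a[, 1:2], f_c[, 1:2]), "3 regions")
})

test_that("variance explained matches an independent OLS solver", {
  sim <- simulate_deviation_matrix(40, 30, seed = 10)
  sp <- split_signed(sim$z)
  fp <- fit_nmf(sp$pos, 2, seed = 1)
  fn <- fit_nmf(sp$neg, 2, seed = 1)
  ve <- variance_explained(sim$z, fp, fn)

  zm <- devfactor:::region_matrix(sim$z)
  X <- cbind(1, t(rbind(fp$F, -fn$F)))
  manual <- vapply(seq_len(nrow(zm)), function(i) {
    y <- zm[i, ]
    beta <- solve(crossprod(X), crossprod(X, y))
    rss <- sum((y - X %*% beta)^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    1 - (1 - r2) * (length(y) - 1) / (length(y) - 4 - 1)
  }, numeric(1))
  expect_equal(ve$adj_r2, manual, tolerance = 1e-10)

  # exact linear combination -> adjusted R^2 = 1
  w <- matrix(rgamma(4, 2), 1)
  z_exact <- w[, 1:2, drop = FALSE] %*% fp$F - w[, 3:4, drop = FALSE] %*% fn$F
  colnames(z_exact) <- colnames(fp$F)
  ve1 <- variance_explained(z_exact, fp, fn)
  expect_equal(ve1$adj_r2, 1, tolerance = 1e-8)

  # residualized profile -> adjusted R^2 <= 0
  y <- zm[1, ]
  y_orth <- y - X %*% solve(crossprod(X), crossprod(X, y))
  z_orth <- matrix(y_orth, 1, dimnames = list(NULL, colnames(zm)))
  ve0 <- variance_explained(z_orth, fp, fn)
  expect_lte(ve0$adj_r2, 0)

  expect_error(variance_explained(zm[, 1:4], fp$F[, 1:4], fn$F[, 1:4]),
               "regions")
})

test_that("permutation p for variance explained uses add-one counting", {
  sim <- simulate_deviation_matrix(40, 24, seed = 11)
  res <- suppressWarnings(
    variance_explained_null(sim$z, 2, 2, n_perm = 199, seed = 1)
  )
  expect_length(res$null, 199)
  expect_true(res$p > 0 && res$p <= 1)
  # planted structure beats every shuffled refit: minimum attainable p
  expect_equal(res$p, 1 / 200)
  expect_error(variance_explained_null(sim$z, 2, 2, n_perm = 0), "n_perm")
})
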