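rand_atlas <- function(r = 60, p = 4, seed = 1) {
  set.seed(seed)
  m <- scale(matrix(rnorm(r * p), r, p))
  attr(m, "scaled:center") <- NULL
  attr(m, "scaled:scale") <- NULL
  colnames(m) <- paste0("receptor_", seq_len(p))
  rownames(m) <- sprintf("roi_%03d", seq_len(r))
  m
}

test_that("receptor models flag exact mixes and match normal equations", {
  X <- rand_atlas(60, 5, seed = 1)
  f <- drop(X[, 1:3] %*% c(1, -0.5, 2))
  res <- receptor_model(f, X, n_perm = 99, seed = 1)
  expect_gte(res$adj_r2, 0.999)
  expect_equal(res$p_perm, 1 / 100)

  set.seed(2)
  f2 <- f + rnorm(60)
  res2 <- receptor_model(f2, X, n_perm = 49, seed = 2)
  Xd <- cbind(1, X)
  beta <- solve(crossprod(Xd), crossprod(Xd, f2))
  expect_equal(res2$coefficients$estimate, as.numeric(beta),
               tolerance = 1e-10)

  # column reordering leaves the fit unchanged
  res3 <- receptor_model(f2, X[, 5:1], n_perm = 49, seed = 2)
  expect_equal(res3$adj_r2, res2$adj_r2, tolerance = 1e-10)

  # collinear columns are refused
  Xc <- cbind(X, receptor_dup = X[, 1])
  expect_error(receptor_model(f2, Xc, n_perm = 49), "collinear")
})

test_that("dominance is additive for orthogonal designs and matches enumeration", {
  # exactly orthonormal design with marginal R^2 of 0.4 and 0.2
  set.seed(3)
  # orthonormal basis of the centered space: include the intercept in the
  # QR so the remaining columns are exactly centered and mutually orthogonal
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(60 * 3), 60, 3))))[, 2:4]
  Qc <- Q
  y <- sqrt(0.4) * Qc[, 1] + sqrt(0.2) * Qc[, 2] + sqrt(0.4) * Qc[, 3]
  X2 <- Qc[, 1:2]
  colnames(X2) <- c("receptor_1", "receptor_2")
  rownames(X2) <- sprintf("roi_%03d", 1:60)
  dom <- dominance_analysis(setNames(y, rownames(X2)), X2)
  expect_equal(dom$dominance$total_dominance, c(0.4, 0.2),
               tolerance = 1e-10)

  # single predictor: dominance equals its R^2
  X1 <- X2[, 1, drop = FALSE]
  dom1 <- dominance_analysis(setNames(y, rownames(X2)), X1)
  expect_equal(dom1$dominance$total_dominance, dom1$full_r2,
               tolerance = 1e-12)

  # 4-predictor random design vs exhaustive lm() enumeration
  X4 <- rand_atlas(50, 4, seed = 4)
  set.seed(5)
  y4 <- drop(X4 %*% rnorm(4)) + rnorm(50)
  dom4 <- dominance_analysis(setNames(y4, rownames(X4)), X4)
  r2_of <- function(idx) {
    if (length(idx) == 0) return(0)
    summary(lm(y4 ~ X4[, idx, drop = FALSE]))$r.squared
  }
  subsets <- unlist(lapply(0:4, function(k) combn(4, k, simplify = FALSE)),
                    recursive = FALSE)
  ref <- vapply(1:4, function(j) {
    no_j <- Filter(function(s) !(j %in% s), subsets)
    inc <- vapply(no_j, function(s) r2_of(sort(c(s, j))) - r2_of(s),
                  numeric(1))
    sz <- vapply(no_j, length, numeric(1))
    mean(tapply(inc, sz, mean))
  }, numeric(1))
  expect_equal(dom4$dominance$total_dominance, ref, tolerance = 1e-10)
  expect_equal(sum(dom4$dominance$total_dominance), dom4$full_r2,
               tolerance = 1e-8)
})

test_that("dominance conserves the full R^2 across random designs", {
  for (s in 1:5) {
    X <- rand_atlas(40, 5, seed = 10 + s)
    set.seed(20 + s)
    y <- drop(X %*% rnorm(5)) + rnorm(40, 0, 2)
    dom <- dominance_analysis(setNames(y, rownames(X)), X)
    expect_equal(sum(dom$dominance$total_dominance), dom$full_r2,
                 tolerance = 1e-8)
    expect_true(all(dom$dominance$total_dominance > -1e-8))
  }
})

test_that("expression vectors average Z-scored genes", {
  set.seed(6)
  tab <- tibble::tibble(
    region = sprintf("roi_%03d", 1:20),
    gene_01 = rnorm(20), gene_02 = rnorm(20)
  )
  ev1 <- build_expression_vector(tab, "gene_01")
  expect_equal(ev1$expression, as.numeric(scale(tab$gene_01)),
               tolerance = 1e-12)

  tab$gene_02 <- -tab$gene_01
  ev2 <- build_expression_vector(tab)
  expect_true(all(abs(ev2$expression) < 1e-12))

  tab$gene_02 <- rnorm(20)
  ev3 <- build_expression_vector(tab)
  ref <- rowMeans(cbind(scale(tab$gene_01), scale(tab$gene_02)))
  expect_equal(ev3$expression, ref, tolerance = 1e-12)

  expect_error(build_expression_vector(tab, "gene_99"), "gene_99")
})

test_that("expression correlation recovers planted values", {
  net_factors <- generate_cohort(n_hc = 40, n_patients = 40,
                                 n_regions = 246, seed = 2)$truth$true_factors
  rs <- vapply(1:20, function(s) {
    mol <- generate_molecular_maps(net_factors, 8, 0.7, gene_corr = -0.4,
                                   seed = s)
    ev <- build_expression_vector(mol$expression)
    expression_correlation(net_factors[1, ], ev, n_perm = 49, seed = s)$r
  }, numeric(1))
  expect_true(all(abs(rs - (-0.4)) < 0.12))

  # exact negative: r = -1
  f <- setNames(rnorm(30), sprintf("roi_%03d", 1:30))
  ev <- tibble::tibble(region = names(f), expression = -f)
  expect_equal(expression_correlation(f, ev, n_perm = 19, seed = 1)$r, -1,
               tolerance = 1e-12)

  ev_const <- tibble::tibble(region = names(f), expression = rep(1, 30))
  expect_error(expression_correlation(f, ev_const, 19), "constant")
})
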