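make_groups <- function(n = 40, r = 6, shift = 0, seed = 1) {
  set.seed(seed)
  vals_c <- matrix(rnorm(n * r), n, r)
  vals_p <- matrix(rnorm(n * r) + shift, n, r)
  colnames(vals_c) <- colnames(vals_p) <- sprintf("roi_%03d", 1:r)
  list(
    controls = dplyr::bind_cols(
      tibble::tibble(subject_id = paste0("c", 1:n), age = runif(n, 20, 60),
                     sex = sample(0:1, n, TRUE),
                     site = sample(c("s1", "s2"), n, TRUE),
                     fd = runif(n, 0.05, 0.3)),
      tibble::as_tibble(vals_c)
    ),
    patients = dplyr::bind_cols(
      tibble::tibble(subject_id = paste0("p", 1:n), age = runif(n, 20, 60),
                     sex = sample(0:1, n, TRUE),
                     site = sample(c("s1", "s2"), n, TRUE),
                     fd = runif(n, 0.05, 0.3)),
      tibble::as_tibble(vals_p)
    )
  )
}

test_that("covariate-free group map reduces to the textbook two-sample t", {
  g <- make_groups(seed = 2)
  gm <- group_difference_map(g$patients, g$controls, covariates = character())
  ref <- vapply(sprintf("roi_%03d", 1:6), function(rg) {
    unname(stats::t.test(g$patients[[rg]], g$controls[[rg]],
                         var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(gm$t, unname(ref), tolerance = 1e-10)
  expect_true(all(gm$p_fdr >= gm$p))
})

test_that("a planted uniform negative shift gives all-negative t", {
  g <- make_groups(n = 60, shift = -1, seed = 3)
  gm <- group_difference_map(g$patients, g$controls)
  expect_true(all(gm$t < 0))
})

test_that("null group maps control the FDR across seeds", {
  fp <- vapply(1:20, function(s) {
    g <- make_groups(n = 30, r = 25, shift = 0, seed = 100 + s)
    gm <- group_difference_map(g$patients, g$controls)
    mean(gm$p_fdr < 0.05)
  }, numeric(1))
  expect_lte(mean(fp), 0.05)
})

test_that("factors_explain_map matches normal equations and flags exact fits", {
  set.seed(4)
  factors <- matrix(rgamma(3 * 40, 2), 3, 40,
                    dimnames = list(NULL, sprintf("roi_%03d", 1:40)))
  beta <- c(2, -1, 0.5)
  tvec <- drop(t(factors) %*% beta) + 0.3
  tm <- tibble::tibble(region = colnames(factors), t = tvec)
  res <- factors_explain_map(tm, factors, n_perm = 99, seed = 1)
  expect_equal(res$adj_r2, 1, tolerance = 1e-10)
  expect_equal(res$p_perm, 1 / 100)
  X <- cbind(1, t(factors))
  beta_ref <- solve(crossprod(X), crossprod(X, tvec))
  expect_equal(res$coefficients$estimate, as.numeric(beta_ref),
               tolerance = 1e-8)

  # affine rescaling of a factor leaves adjusted R^2 unchanged
  tm2 <- tibble::tibble(region = colnames(factors),
                        t = tvec + rnorm(40, 0, 0.5))
  r_a <- factors_explain_map(tm2, factors, n_perm = 49, seed = 2)$adj_r2
  factors_s <- factors
  factors_s[1, ] <- 3.7 * factors_s[1, ] + 2
  r_b <- factors_explain_map(tm2, factors_s, n_perm = 49, seed = 2)$adj_r2
  expect_equal(r_a, r_b, tolerance = 1e-10)

  expect_error(factors_explain_map(tm[1:4, ], factors[, 1:4]), "regions")
})

test_that("composition contrasts and correlations behave on planted effects", {
  set.seed(5)
  n <- 500
  W <- matrix(rgamma(n * 3, 2), n, 3, dimnames = list(NULL, paste0("f", 1:3)))
  clin <- tibble::tibble(
    age = runif(n, 20, 60), sex = sample(0:1, n, TRUE),
    site = sample(c("s1", "s2"), n, TRUE), fd = runif(n, 0.05, 0.3),
    hamd = 0.3 * scale(W[, 1])[, 1] + rnorm(n),
    grp = sample(c("treated", "untreated"), n, TRUE)
  )
  cc <- composition_association(W, clin, type = "correlation",
                                score_var = "hamd")
  expect_gt(cc$r[1], 0)
  expect_lt(cc$p_fdr[1], 0.05)

  ct <- composition_association(W, clin, type = "contrast",
                                group_var = "grp",
                                covariates = c("age", "sex", "site", "fd"))
  expect_equal(sign(ct$cohens_d), sign(ct$t))
  expect_true(all(ct$p_fdr >= ct$p))

  # identical groups (same rows duplicated) -> t = 0, d = 0
  Wd <- rbind(W[1:20, ], W[1:20, ])
  clin_d <- tibble::tibble(grp = rep(c("a", "b"), each = 20))
  ct0 <- composition_association(Wd, clin_d, type = "contrast",
                                 group_var = "grp")
  expect_equal(ct0$t, rep(0, 3), tolerance = 1e-10)
  expect_equal(ct0$cohens_d, rep(0, 3), tolerance = 1e-10)

  expect_error(
    composition_association(W, clin, type = "contrast", group_var = "hamd"),
    "binary"
  )
})

test_that("group labels independent of compositions rarely reach significance", {
  hits <- vapply(1:50, function(s) {
    set.seed(300 + s)
    W <- matrix(rgamma(60 * 3, 2), 60, 3)
    clin <- tibble::tibble(grp = sample(c("a", "b"), 60, TRUE))
    if (min(table(clin$grp)) < 3) return(0L)
    ct <- composition_association(W, clin, type = "contrast",
                                  group_var = "grp")
    as.integer(any(ct$p_fdr < 0.05))
  }, integer(1))
  expect_lte(sum(hits), 10)
})
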