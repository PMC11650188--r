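# Helper: control table with one region following a known generative rule.
gp_table <- function(n, value_fn, seed = 1, age = NULL) {
  set.seed(seed)
  if (is.null(age)) age <- runif(n, 20, 70)
  sex <- sample(0:1, n, replace = TRUE)
  tibble::tibble(
    subject_id = as.character(seq_len(n)), age = age, sex = sex,
    roi_001 = value_fn(age, sex)
  )
}

test_that("a noiseless linear age trend is learned almost exactly", {
  train <- gp_table(80, function(a, s) 0.5 + 0.02 * a, seed = 1)
  m <- fit_normative(train, restarts = 2, maxit = 100)
  test <- gp_table(60, function(a, s) 0.5 + 0.02 * a, seed = 2,
                   age = runif(60, 25, 65))
  pred <- devfactor:::normative_predict(m, test)
  mse <- mean((pred$roi_001$mean - test$roi_001)^2)
  expect_lt(mse, 1e-4)
})

test_that("pure-noise region shows standardized MSE near 1", {
  train <- gp_table(250, function(a, s) rnorm(length(a)), seed = 3)
  m <- fit_normative(train, restarts = 2, maxit = 60)
  test <- gp_table(250, function(a, s) rnorm(length(a)), seed = 4)
  pred <- devfactor:::normative_predict(m, test)
  smse <- mean((pred$roi_001$mean - test$roi_001)^2) / var(test$roi_001)
  expect_gt(smse, 0.85)
  expect_lt(smse, 1.15)
})

test_that("fitting preconditions are enforced", {
  small <- gp_table(10, function(a, s) a)
  expect_error(fit_normative(small), "30 controls")
  const <- gp_table(40, function(a, s) rep(1, length(a)))
  expect_error(fit_normative(const), "constant")
})

test_that("deviation scores center, scale, and refuse mismatched regions", {
  train <- gp_table(60, function(a, s) 1 + 0.01 * a + 0.3 * s +
                      rnorm(length(a), 0, 0.3), seed = 5)
  m <- fit_normative(train, restarts = 1, maxit = 60)
  subj <- train[1:3, ]
  pred <- devfactor:::normative_predict(m, subj)$roi_001

  # value at the predictive mean -> Z = 0
  subj$roi_001 <- pred$mean
  z0 <- deviation_scores(m, subj)
  expect_equal(z0$roi_001, rep(0, 3))

  # value at mean + 2.6 total predictive SD -> Z = 2.6 exactly
  subj$roi_001 <- pred$mean + 2.6 * sqrt(pred$var + pred$noise_var)
  z26 <- deviation_scores(m, subj)
  expect_equal(z26$roi_001, rep(2.6, 3), tolerance = 1e-12)

  bad <- dplyr::rename(subj, roi_099 = "roi_001")
  expect_error(deviation_scores(m, bad), "roi_099")

  far <- subj
  far$age <- c(95, 96, 97)
  expect_warning(deviation_scores(m, far), "training range")
})

test_that("evaluation schemes return per-region standardized MSE", {
  b <- small_bundle(seed = 51, n_regions = 10, n_hc = 150, n_patients = 30,
                    site_loc_sd = 0, site_scale_sd = 0)
  ev <- evaluate_normative(b$hc, "kfold", k = 5, repeats = 2, seed = 1,
                           restarts = 1, maxit = 40)
  expect_equal(nrow(ev), 10)
  expect_true(all(ev$smse >= 0))
  expect_identical(attr(ev, "scheme"), "kfold")

  # noiseless linear-trend region: smse far below the noise benchmark
  lin <- gp_table(60, function(a, s) 0.2 + 0.015 * a, seed = 6)
  ev_lin <- evaluate_normative(lin, "kfold", k = 5, repeats = 1, seed = 2,
                               restarts = 1, maxit = 60)
  expect_lt(ev_lin$smse, 0.05)

  # pure-noise region: smse near 1
  noise <- gp_table(120, function(a, s) rnorm(length(a)), seed = 7)
  ev_noise <- evaluate_normative(noise, "kfold", k = 5, repeats = 1,
                                 seed = 3, restarts = 1, maxit = 40)
  expect_gt(ev_noise$smse, 0.8)
  expect_lt(ev_noise$smse, 1.2)

  ev_loso <- evaluate_normative(b$hc, "leave_one_site_out",
                                restarts = 1, maxit = 40)
  expect_equal(nrow(ev_loso), 10)
  # site-free generator: the two schemes agree on calibration
  expect_true(all(abs(ev_loso$smse - ev$smse) < 0.1))

  other <- small_bundle(seed = 52, n_regions = 10, n_hc = 50, n_patients = 30,
                        site_loc_sd = 0, site_scale_sd = 0)
  ev_cd <- evaluate_normative(b$hc, "cross_dataset", other = other$hc,
                              restarts = 1, maxit = 40)
  expect_equal(nrow(ev_cd), 10)
  bad <- dplyr::select(other$hc, -"roi_008")
  expect_error(evaluate_normative(b$hc, "cross_dataset", other = bad),
               "region")
})

test_that("extreme-deviation overlap counts patients per tail", {
  z <- matrix(c(3.0, -3.0, 1.0, 2.7), ncol = 1,
              dimnames = list(NULL, "roi_001"))
  ov <- extreme_deviation_overlap(z, 2.6)
  expect_equal(ov$overlap_pos, 0.5)
  expect_equal(ov$overlap_neg, 0.25)

  z0 <- matrix(0, 5, 3, dimnames = list(NULL, c("roi_001", "roi_002", "roi_003")))
  ov0 <- extreme_deviation_overlap(z0)
  expect_true(all(ov0$overlap_pos == 0) && all(ov0$overlap_neg == 0))

  # overlap is non-increasing in the threshold
  set.seed(8)
  zr <- matrix(rnorm(600), 30, 20,
               dimnames = list(NULL, sprintf("roi_%03d", 1:20)))
  ths <- c(1, 1.5, 2, 2.6, 3)
  tot <- vapply(ths, function(th) {
    o <- extreme_deviation_overlap(zr, th)
    mean(o$overlap_pos + o$overlap_neg)
  }, numeric(1))
  expect_true(all(diff(tot) <= 0))

  expect_error(extreme_deviation_overlap(zr[0, , drop = FALSE]), "empty")
})

test_that("GP predictive means agree with an independent GP implementation", {
  skip_if_not_installed("kernlab")
  train <- gp_table(80, function(a, s) sin(a / 8) + 0.3 * s +
                      rnorm(length(a), 0, 0.2), seed = 9)
  m <- fit_normative(train, restarts = 2, maxit = 100)
  pred <- devfactor:::normative_predict(m, train)$roi_001
  kl <- kernlab::gausspr(x = cbind(train$age, train$sex), y = train$roi_001,
                         variance.model = FALSE)
  ref <- as.numeric(kernlab::predict(kl, cbind(train$age, train$sex)))
  # both models should track the same smooth trend
  expect_gt(cor(pred$mean, ref), 0.98)
})
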