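test_that("generate_cohort honors shape contracts and is reproducible", {
  b <- generate_cohort(n_hc = 60, n_patients = 60, n_regions = 60,
                       n_sites = 3, k_pos = 2, k_neg = 2, n_subtypes = 4,
                       noise_sd = 0.5, seed = 7)
  expect_equal(nrow(b$patients), 60)
  expect_length(region_cols(b$patients), 60)
  expect_equal(dim(b$truth$true_factors), c(4, 60))
  expect_true(all(b$truth$true_factors >= 0))
  expect_true(all(b$truth$true_weights >= 0))
  expect_true(all(table(b$truth$true_subtype_labels) >= 2))
  expect_setequal(region_cols(b$hc), region_cols(b$gmv))
  expect_setequal(region_cols(b$hc), b$receptors$region)

  b2 <- generate_cohort(n_hc = 60, n_patients = 60, n_regions = 60,
                        n_sites = 3, k_pos = 2, k_neg = 2, n_subtypes = 4,
                        noise_sd = 0.5, seed = 7)
  expect_identical(b, b2)

  expect_error(generate_cohort(n_hc = 0), "n_hc")
  expect_error(generate_cohort(noise_sd = -1), "noise_sd")
  expect_error(generate_cohort(n_regions = 5), "n_regions")
})

test_that("planted deviations reconstruct exactly in the noise-free limit", {
  b <- generate_cohort(n_hc = 40, n_patients = 40, n_regions = 12,
                       noise_sd = 1e-9, deviation_scale = 1,
                       site_loc_sd = 0, site_scale_sd = 0, seed = 3)
  signal <- devfactor:::normative_signal(b$truth$curves,
                                         b$patients$age, b$patients$sex)
  observed_dev <- devfactor:::region_matrix(b$patients) - signal
  expect_lt(max(abs(observed_dev - b$truth$deviations)), 1e-8)

  k_pos <- 2
  wf <- b$truth$true_weights[, 1:2] %*% b$truth$true_factors[1:2, ] -
    b$truth$true_weights[, 3:4] %*% b$truth$true_factors[3:4, ]
  expect_equal(unname(b$truth$deviations), unname(wf), tolerance = 1e-12)
})

test_that("synthetic SC network is symmetric, block-structured, hub-planted", {
  net <- generate_sc_network(60, 4, 0.8, 0.1, seed = 1)
  w <- unclass(net)
  expect_true(isSymmetric(unname(w)))
  expect_true(all(diag(w) == 0))
  expect_true(all(w >= 0))

  # brute-force within/between averaging over all region pairs
  modules <- attr(net, "modules")
  same <- outer(modules, modules, "==") & upper.tri(w)
  diff <- (!outer(modules, modules, "==")) & upper.tri(w)
  expect_gt(mean(w[same]), mean(w[diff]))

  net0 <- generate_sc_network(60, 4, 0.8, 0, seed = 2)
  expect_equal(n_components(unclass(net0)), 4)

  expect_error(generate_sc_network(60, 4, 0.2, 0.5), "exceed")
})

test_that("molecular maps carry the planted receptor R2 and gene correlation", {
  b <- small_bundle(n_regions = 60)
  mol <- generate_molecular_maps(b$truth$true_factors, n_receptors = 8,
                                 target_r2 = 0.7, gene_corr = -0.4, seed = 3)
  expect_equal(dim(as.matrix(mol$receptors[-1])), c(60, 8))
  expect_equal(nrow(mol$expression), 60)
  expect_equal(dim(mol$receptor_coeffs), c(4, 8))

  # near-noiseless limit: refitting the factor on its generating receptors
  mol99 <- generate_molecular_maps(b$truth$true_factors, n_receptors = 8,
                                   target_r2 = 0.99, seed = 5)
  X <- as.matrix(mol99$receptors[-1])
  gen <- which(mol99$receptor_coeffs[1, ] > 0)
  f1 <- b$truth$true_factors[1, ]
  r2 <- summary(lm(f1 ~ X[, gen]))$r.squared
  expect_gte(r2, 0.95)

  expect_error(generate_molecular_maps(b$truth$true_factors, 8,
                                       target_r2 = 1.2), "target_r2")
})

test_that("zero gene_corr yields near-zero expression correlation at R = 246", {
  b <- generate_cohort(n_hc = 40, n_patients = 40, n_regions = 246, seed = 1)
  rs <- vapply(1:20, function(s) {
    mol <- generate_molecular_maps(b$truth$true_factors, 8,
                                   target_r2 = 0.7, gene_corr = 0, seed = s)
    ev <- build_expression_vector(mol$expression)
    cor(ev$expression, b$truth$true_factors[1, ])
  }, numeric(1))
  expect_true(all(abs(rs) < 0.1))
})

test_that("subtype recovery improves with mixture-mean separation", {
  ari_at <- function(sep) {
    mean(vapply(1:20, function(s) {
      sim <- simulate_deviation_matrix(120, 20, seed = s,
                                       subtype_separation = sep)
      km <- kmeans(sim$truth$true_weights, centers = 4, nstart = 5)
      adjusted_rand(km$cluster, sim$truth$true_subtype_labels)
    }, numeric(1)))
  }
  aris <- vapply(c(0.5, 3, 8), ari_at, numeric(1))
  expect_true(all(diff(aris) >= -0.02))  # non-decreasing up to MC jitter
  expect_gt(aris[3], aris[1])
})

test_that("write_bundle produces the expected delimited files", {
  b <- small_bundle(n_regions = 12, n_hc = 40, n_patients = 30)
  dir <- withr::local_tempdir()
  files <- write_bundle(b, dir)
  expect_true(all(file.exists(files)))
  hc_in <- read.delim(file.path(dir, "hc.tsv"))
  expect_equal(nrow(hc_in), 40)
  expect_length(grep("^roi_", names(hc_in)), 12)
})
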