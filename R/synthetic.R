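# Synthetic cohorts with planted ground truth.
#
# The generator emulates the data model the analysis assumes: regional
# values in controls follow a smooth age curve with a sex offset and
# per-site location/scale batch effects; patient values add a deviation
# built as a non-negative weighted sum of positive factors minus negative
# factors, expressed in normative-noise units so that downstream Z-scores
# carry the planted factor structure directly.

#' Generate a synthetic cohort bundle with planted ground truth
#'
#' Builds matched control and patient cohort tables, a gray-matter-volume
#' table for structural-covariance construction, receptor and gene-expression
#' maps, and the ground truth used to validate every downstream stage.
#'
#' Controls follow, per region, a smooth normative curve in age (linear trend
#' plus one low-frequency sinusoid with random phase) with an additive sex
#' offset, per-site location/scale effects, and Gaussian noise. Patients add
#' a deviation `deviation_scale * (W_pos F_pos - W_neg F_neg)`: factor
#' loadings are non-negative with near-disjoint regional supports, and
#' patient weights are drawn from an `n_subtypes`-component mixture that
#' defines the planted subtypes. A HAMD-like severity score is a linear
#' function of the weights, clipped to the scale range 0-52.
#'
#' @param n_hc,n_patients Numbers of controls and patients.
#' @param n_regions Number of brain regions (>= 10).
#' @param n_sites Number of acquisition sites.
#' @param k_pos,k_neg Numbers of planted positive / negative factors.
#' @param n_subtypes Number of planted patient subtypes (<= n_patients / 4).
#' @param noise_sd Observation noise SD on the raw regional values (> 0).
#' @param seed Integer seed; the bundle is fully reproducible from it.
#' @param subtype_separation Distance between subtype weight means, in units
#'   of the within-subtype weight SD. Default 3 (moderately separated).
#' @param deviation_scale Scale of patient deviations in raw units. Defaults
#'   to `noise_sd`, so deviations sit at their weight-times-loading size in
#'   Z-score units after normative standardization.
#' @param site_loc_sd,site_scale_sd SDs of the per-site additive offsets and
#'   log multiplicative noise scales. Set both to 0 for site-free data.
#' @param age_range Age range (years) subjects are drawn from.
#' @return A `synthetic_bundle`: list with cohort tables `hc` and
#'   `patients`, `gmv`, `receptors`, `expression`, the `truth` list
#'   (factors, weights, subtype labels, site effects, clinical coefficients,
#'   epicenters, receptor coefficients, gene correlation target) and `seed`.
#' @export
generate_cohort <- function(n_hc = 200, n_patients = 200, n_regions = 60,
                            n_sites = 3, k_pos = 2, k_neg = 2,
                            n_subtypes = 4, noise_sd = 0.5, seed = 1,
                            subtype_separation = 3,
                            deviation_scale = NULL,
                            site_loc_sd = 0.3, site_scale_sd = 0.15,
                            age_range = c(18, 65)) {
  n_hc <- check_count(n_hc, "n_hc")
  n_patients <- check_count(n_patients, "n_patients")
  n_regions <- check_count(n_regions, "n_regions", min = 10L)
  n_sites <- check_count(n_sites, "n_sites")
  k_pos <- check_count(k_pos, "k_pos")
  k_neg <- check_count(k_neg, "k_neg")
  n_subtypes <- check_count(n_subtypes, "n_subtypes")
  noise_sd <- check_positive(noise_sd, "noise_sd")
  if (n_subtypes > n_patients / 4) {
    abort("`n_subtypes` must be at most n_patients / 4")
  }
  deviation_scale <- deviation_scale %||% noise_sd
  regions <- roi_labels(n_regions)
  k_tot <- k_pos + k_neg

  with_seed(seed, {
    curves <- random_region_curves(n_regions)
    site_shift <- list(
      offset = matrix(rnorm(n_sites * n_regions, 0, site_loc_sd),
                      n_sites, n_regions,
                      dimnames = list(paste0("site", seq_len(n_sites)), regions)),
      log_scale = matrix(rnorm(n_sites * n_regions, 0, site_scale_sd),
                         n_sites, n_regions,
                         dimnames = list(paste0("site", seq_len(n_sites)), regions))
    )

    fac <- planted_factors(k_tot, n_regions)
    truth_factors <- fac$loadings
    rownames(truth_factors) <- c(
      if (k_pos > 0) paste0("pos_", seq_len(k_pos)),
      if (k_neg > 0) paste0("neg_", seq_len(k_neg))
    )
    colnames(truth_factors) <- regions

    wts <- planted_weights(n_patients, k_tot, n_subtypes, subtype_separation)

    hc_demo <- random_demographics(n_hc, n_sites, age_range, prefix = "hc")
    pat_demo <- random_demographics(n_patients, n_sites, age_range, prefix = "pat")

    hc_signal <- normative_signal(curves, hc_demo$age, hc_demo$sex)
    pat_signal <- normative_signal(curves, pat_demo$age, pat_demo$sex)

    pos_idx <- seq_len(k_pos)
    neg_idx <- k_pos + seq_len(k_neg)
    dev_z <- wts$W[, pos_idx, drop = FALSE] %*% truth_factors[pos_idx, , drop = FALSE] -
      wts$W[, neg_idx, drop = FALSE] %*% truth_factors[neg_idx, , drop = FALSE]
    deviations <- deviation_scale * dev_z

    hc_vals <- apply_site_noise(hc_signal, hc_demo$site, site_shift, noise_sd)
    pat_vals <- apply_site_noise(pat_signal + deviations, pat_demo$site,
                                 site_shift, noise_sd)
    colnames(hc_vals) <- regions
    colnames(pat_vals) <- regions

    clinical_effect <- seq(2.5, 0.5, length.out = k_tot)
    hamd <- pmin(pmax(8 + drop(wts$W %*% clinical_effect) +
                        rnorm(n_patients, 0, 3), 0), 52)
    duration <- pmax(0.25, 2 + 1.5 * wts$W[, min(2L, k_tot)] +
                       rnorm(n_patients, 0, 1.5))
    onset_age <- pmax(pat_demo$age - duration, 12)

    hc <- dplyr::bind_cols(
      tibble(
        subject_id = hc_demo$id, age = hc_demo$age, sex = hc_demo$sex,
        site = hc_demo$site, group = "hc",
        fd = runif(n_hc, 0.05, 0.3)
      ),
      as_tibble(hc_vals)
    )
    patients <- dplyr::bind_cols(
      tibble(
        subject_id = pat_demo$id, age = pat_demo$age, sex = pat_demo$sex,
        site = pat_demo$site, group = "patient",
        fd = runif(n_patients, 0.05, 0.3),
        hamd = hamd, duration = duration, onset_age = onset_age,
        episode = sample(c("first", "recurrent"), n_patients, replace = TRUE),
        medicated = sample(0:1, n_patients, replace = TRUE)
      ),
      as_tibble(pat_vals)
    )

    gmv <- generate_gmv_table(n_hc, fac$modules, fac$hubs, age_range)

    mol <- generate_molecular_maps(truth_factors,
                                   n_receptors = max(8L, 2L * k_tot),
                                   target_r2 = 0.7, gene_corr = -0.4,
                                   seed = child_seed(seed, "molecular"))

    truth <- list(
      true_factors = truth_factors,
      true_weights = wts$W,
      true_subtype_labels = wts$labels,
      subtype_means = wts$means,
      site_shift = site_shift,
      clinical_effect = clinical_effect,
      epicenter_regions = fac$hubs,
      factor_modules = fac$modules,
      deviations = deviations,
      deviation_scale = deviation_scale,
      curves = curves,
      receptor_coeffs = mol$receptor_coeffs,
      gene_corr_target = attr(mol$expression, "gene_corr_target")
    )

    structure(
      list(hc = hc, patients = patients, gmv = gmv,
           receptors = mol$receptors, expression = mol$expression,
           truth = truth, seed = seed),
      class = "synthetic_bundle"
    )
  })
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle>\n")
  cat(sprintf("  controls: %d  patients: %d  regions: %d  sites: %d\n",
              nrow(x$hc), nrow(x$patients), length(region_cols(x$hc)),
              length(unique(x$hc$site))))
  cat(sprintf("  planted factors: %d  subtypes: %d  seed: %d\n",
              nrow(x$truth$true_factors),
              length(unique(x$truth$true_subtype_labels)), x$seed))
  invisible(x)
}

# Per-region smooth normative curves: intercept, linear age trend, one
# low-frequency sinusoid (period 40-80 y, random phase), additive sex offset.
random_region_curves <- function(n_regions) {
  list(
    b0 = rnorm(n_regions, 1, 0.2),
    b_age = rnorm(n_regions, 0, 0.15),
    amp = runif(n_regions, 0.05, 0.15),
    period = runif(n_regions, 40, 80),
    phase = runif(n_regions, 0, 2 * pi),
    b_sex = rnorm(n_regions, 0, 0.08)
  )
}

# Evaluate curves at given ages/sexes: n x R signal matrix.
normative_signal <- function(curves, age, sex) {
  a <- (age - 50) / 30
  outer(rep(1, length(age)), curves$b0) +
    outer(a, curves$b_age) +
    t(curves$amp * sin(2 * pi * outer(curves$period, age, function(p, g) g / p) +
                         curves$phase)) +
    outer(sex, curves$b_sex)
}

random_demographics <- function(n, n_sites, age_range, prefix) {
  site_levels <- paste0("site", seq_len(n_sites))
  site <- sample(rep(site_levels, length.out = n))
  list(
    id = sprintf("%s_%04d", prefix, seq_len(n)),
    age = runif(n, age_range[1], age_range[2]),
    sex = sample(0:1, n, replace = TRUE),
    site = site
  )
}

apply_site_noise <- function(signal, site, site_shift, noise_sd) {
  idx <- match(site, rownames(site_shift$offset))
  n <- nrow(signal); r <- ncol(signal)
  eps <- matrix(rnorm(n * r, 0, noise_sd), n, r)
  signal + site_shift$offset[idx, , drop = FALSE] +
    exp(site_shift$log_scale[idx, , drop = FALSE]) * eps
}

# Non-negative factor loadings with near-disjoint supports: regions are
# partitioned into k blocks; within its block a factor loads U(0.5, 1)
# with one hub region at the maximum loading 1; zero elsewhere.
planted_factors <- function(k, n_regions) {
  blocks <- sort(rep_len(seq_len(k), n_regions))
  loadings <- matrix(0, k, n_regions)
  hubs <- integer(k)
  for (j in seq_len(k)) {
    idx <- which(blocks == j)
    loadings[j, idx] <- runif(length(idx), 0.5, 0.95)
    hub <- sample(idx, 1L)
    loadings[j, hub] <- 1
    hubs[j] <- hub
  }
  list(loadings = loadings, modules = blocks, hubs = hubs)
}

# Subtype-structured non-negative weights: mixture means sit at a baseline
# with one coordinate boosted by `separation` within-subtype SDs.
planted_weights <- function(n, k, n_subtypes, separation,
                            baseline = 1.5, sd_within = 0.4) {
  labels <- sort(rep_len(seq_len(n_subtypes), n))
  means <- matrix(baseline, n_subtypes, k)
  for (s in seq_len(n_subtypes)) {
    means[s, ((s - 1L) %% k) + 1L] <- baseline + separation * sd_within
  }
  W <- means[labels, , drop = FALSE] +
    matrix(rnorm(n * k, 0, sd_within), n, k)
  W <- pmax(W, 0)
  list(W = W, labels = labels, means = means)
}

# Gray-matter volume table with module-structured covariance: each subject
# has one latent score per module; region volumes load on their module's
# latent with the hub loading highest, plus age/age^2/sex effects.
generate_gmv_table <- function(n, modules, hubs, age_range) {
  n_regions <- length(modules)
  k <- max(modules)
  age <- runif(n, age_range[1], age_range[2])
  sex <- sample(0:1, n, replace = TRUE)
  a <- (age - 50) / 30
  loading <- runif(n_regions, 0.5, 0.9)
  loading[hubs] <- 1.2
  latent <- matrix(rnorm(n * k), n, k)
  vol <- 3 + outer(a, rnorm(n_regions, -0.2, 0.05)) +
    outer(a^2, rnorm(n_regions, -0.05, 0.02)) +
    outer(sex, rnorm(n_regions, 0.1, 0.05)) +
    latent[, modules, drop = FALSE] * rep(loading, each = n) +
    matrix(rnorm(n * n_regions, 0, 0.5), n, n_regions)
  colnames(vol) <- roi_labels(n_regions)
  dplyr::bind_cols(
    tibble(subject_id = sprintf("gmv_%04d", seq_len(n)),
           age = age, sex = sex),
    as_tibble(vol)
  )
}

#' Generate a synthetic structural-covariance network with planted hubs
#'
#' Builds a symmetric non-negative region-by-region weight matrix with
#' block (module) structure: pairs within a module receive heavy weights,
#' pairs across modules light ones, and each module carries one designated
#' hub region with the strongest within-module connections.
#'
#' @param n_regions Number of regions.
#' @param n_modules Number of modules (>= 2).
#' @param within_weight Mean weight of within-module edges, in (0, 1].
#' @param between_weight Mean weight of between-module edges, in \[0, 1);
#'   must be smaller than `within_weight`.
#' @param seed Integer seed.
#' @return An `sc_network` object (see [build_sc_network()]) with
#'   attributes `modules` (module index per region) and `hubs` (planted hub
#'   region index per module).
#' @export
generate_sc_network <- function(n_regions = 60, n_modules = 4,
                                within_weight = 0.8, between_weight = 0.1,
                                seed = 1) {
  n_regions <- check_count(n_regions, "n_regions", min = 4L)
  n_modules <- check_count(n_modules, "n_modules", min = 2L)
  if (!is.numeric(within_weight) || within_weight <= 0 || within_weight > 1) {
    abort("`within_weight` must lie in (0, 1]")
  }
  if (!is.numeric(between_weight) || between_weight < 0 || between_weight >= 1) {
    abort("`between_weight` must lie in [0, 1)")
  }
  if (within_weight <= between_weight) {
    abort("`within_weight` must exceed `between_weight`")
  }
  regions <- roi_labels(n_regions)

  with_seed(seed, {
    modules <- sort(rep_len(seq_len(n_modules), n_regions))
    strength <- runif(n_regions, 0.6, 0.9)
    hubs <- integer(n_modules)
    for (m in seq_len(n_modules)) {
      idx <- which(modules == m)
      hub <- sample(idx, 1L)
      strength[hub] <- 1
      hubs[m] <- hub
    }
    same <- outer(modules, modules, "==")
    base <- ifelse(same, within_weight, between_weight)
    w <- base * outer(strength, strength)
    jitter <- matrix(runif(n_regions^2, 0.9, 1.1), n_regions)
    jitter <- (jitter + t(jitter)) / 2
    w <- pmin(pmax(w * jitter, 0), 1)
    w[base == 0] <- 0
    diag(w) <- 0
    dimnames(w) <- list(regions, regions)
    new_sc_network(w, covariates = character(),
                   modules = modules, hubs = hubs)
  })
}

#' Construct a factor map with a planted epicenter
#'
#' Given a synthetic structural-covariance network from
#' [generate_sc_network()], builds a non-negative regional factor map whose
#' largest value sits on the designated module's hub and whose module
#' neighbors carry the next-largest values, so that the hub is the planted
#' epicenter (high own value and high neighbor statistic).
#'
#' @param network An `sc_network` from [generate_sc_network()].
#' @param module Module index whose hub becomes the epicenter.
#' @param seed Integer seed for the off-module background values.
#' @return Named numeric vector of regional factor values; attribute
#'   `epicenter` holds the planted hub region index.
#' @export
planted_epicenter_factor <- function(network, module = 1L, seed = 1) {
  modules <- attr(network, "modules")
  hubs <- attr(network, "hubs")
  if (is.null(modules) || is.null(hubs)) {
    abort("`network` must come from generate_sc_network() (planted modules required)")
  }
  module <- check_count(module, "module")
  w <- unclass(network)
  with_seed(seed, {
    f <- runif(nrow(w), 0, 0.2)
    idx <- which(modules == module)
    f[idx] <- runif(length(idx), 0.55, 0.9)
    f[hubs[module]] <- 1
    names(f) <- rownames(w)
    attr(f, "epicenter") <- hubs[module]
    f
  })
}

#' Generate receptor-density and gene-expression maps tied to factors
#'
#' Receptor maps are built so that a known subset of receptors linearly
#' reconstructs each factor with population R-squared `target_r2`: the
#' receptors are split round-robin across factors and each receptor in a
#' factor's group equals the standardized factor plus independent noise
#' whose variance is chosen so the group jointly attains `target_r2`. The
#' expression table carries `n_genes` genes whose averaged Z-scored profile
#' correlates with the first factor at `gene_corr` (exactly, by
#' orthogonalized construction, before the small per-gene noise).
#'
#' @param true_factors K x R non-negative factor loading matrix (rows are
#'   factors, columns regions; rownames/colnames used for labeling).
#' @param n_receptors Number of receptor maps (>= K).
#' @param target_r2 Population R-squared of the factor on its generating
#'   receptor group, in (0, 1).
#' @param gene_corr Target Pearson correlation between the averaged
#'   expression vector and the first factor, in (-1, 1).
#' @param seed Integer seed.
#' @param n_genes Number of genes in the expression table.
#' @return List with `receptors` (tibble: region + one column per receptor,
#'   Z-scored, with attribute `class_labels` assigning each receptor to the
#'   excitatory or inhibitory class), `expression` (tibble: region + gene
#'   columns; attributes `gene_corr_target`, `target_factor`), and
#'   `receptor_coeffs` (K x n_receptors ground-truth mixing matrix).
#' @export
generate_molecular_maps <- function(true_factors, n_receptors = 8,
                                    target_r2 = 0.7, gene_corr = -0.4,
                                    seed = 1, n_genes = 14) {
  if (!is.matrix(true_factors)) true_factors <- as.matrix(true_factors)
  k <- nrow(true_factors)
  r <- ncol(true_factors)
  n_receptors <- check_count(n_receptors, "n_receptors", min = k)
  if (!is.numeric(target_r2) || target_r2 <= 0 || target_r2 >= 1) {
    abort("`target_r2` must lie strictly inside (0, 1)")
  }
  if (!is.numeric(gene_corr) || gene_corr <= -1 || gene_corr >= 1) {
    abort("`gene_corr` must lie strictly inside (-1, 1)")
  }
  regions <- colnames(true_factors) %||% roi_labels(r)
  fnames <- rownames(true_factors) %||% paste0("factor_", seq_len(k))

  with_seed(seed, {
    f_std <- t(apply(true_factors, 1L, function(x) (x - mean(x)) / sd(x)))
    group <- rep_len(seq_len(k), n_receptors)
    coeffs <- matrix(0, k, n_receptors,
                     dimnames = list(fnames, paste0("receptor_", seq_len(n_receptors))))
    X <- matrix(0, r, n_receptors)
    for (j in seq_len(n_receptors)) {
      g <- group[j]
      p_g <- sum(group == g)
      sigma <- sqrt(p_g * (1 / target_r2 - 1))
      X[, j] <- f_std[g, ] + rnorm(r, 0, sigma)
      coeffs[g, j] <- 1 / p_g
    }
    X <- scale(X)[, , drop = FALSE]
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
    colnames(X) <- paste0("receptor_", seq_len(n_receptors))
    receptors <- dplyr::bind_cols(tibble(region = regions), as_tibble(X))
    attr(receptors, "class_labels") <- setNames(
      rep_len(c("excitatory", "inhibitory"), n_receptors), colnames(X)
    )

    # expression target: exact-sample-correlation construction against factor 1
    target <- f_std[1L, ]
    noise <- rnorm(r)
    noise <- resid(lm(noise ~ target))
    noise <- noise / sd(noise) * sd(target)
    e <- gene_corr * target + sqrt(1 - gene_corr^2) * noise
    genes <- vapply(seq_len(n_genes), function(g) e + rnorm(r, 0, 0.3),
                    numeric(r))
    colnames(genes) <- sprintf("gene_%02d", seq_len(n_genes))
    expression <- dplyr::bind_cols(tibble(region = regions), as_tibble(genes))
    attr(expression, "gene_corr_target") <- gene_corr
    attr(expression, "target_factor") <- fnames[1L]

    list(receptors = receptors, expression = expression,
         receptor_coeffs = coeffs)
  })
}

#' Simulate a deviation matrix with planted factor structure
#'
#' Shortcut that skips the raw-cohort and normative-modeling stages:
#' returns patient-by-region deviation Z-scores built directly as
#' `W_pos F_pos - W_neg F_neg` plus unit-scale Gaussian noise, which is
#' what the normative stage produces from the full generator up to
#' estimation error. Used to exercise the factorization machinery.
#'
#' @inheritParams generate_cohort
#' @param noise_sd Noise SD on the Z-scale (the normative standardization
#'   makes residual noise unit scale, so the default is 1).
#' @return List with `z` (a deviation-score tibble as from
#'   [deviation_scores()]) and `truth` (factors, weights, subtype labels).
#' @export
simulate_deviation_matrix <- function(n_patients = 200, n_regions = 60,
                                      k_pos = 2, k_neg = 2, n_subtypes = 4,
                                      noise_sd = 1, subtype_separation = 3,
                                      seed = 1) {
  n_patients <- check_count(n_patients, "n_patients")
  n_regions <- check_count(n_regions, "n_regions", min = 10L)
  regions <- roi_labels(n_regions)
  k_tot <- k_pos + k_neg
  with_seed(seed, {
    fac <- planted_factors(k_tot, n_regions)
    loadings <- fac$loadings
    rownames(loadings) <- c(
      if (k_pos > 0) paste0("pos_", seq_len(k_pos)),
      if (k_neg > 0) paste0("neg_", seq_len(k_neg))
    )
    colnames(loadings) <- regions
    wts <- planted_weights(n_patients, k_tot, n_subtypes, subtype_separation)
    pos_idx <- seq_len(k_pos)
    neg_idx <- k_pos + seq_len(k_neg)
    z <- wts$W[, pos_idx, drop = FALSE] %*% loadings[pos_idx, , drop = FALSE] -
      wts$W[, neg_idx, drop = FALSE] %*% loadings[neg_idx, , drop = FALSE] +
      matrix(rnorm(n_patients * n_regions, 0, noise_sd), n_patients, n_regions)
    colnames(z) <- regions
    zt <- dplyr::bind_cols(
      tibble(subject_id = sprintf("pat_%04d", seq_len(n_patients))),
      as_tibble(z)
    )
    class(zt) <- c("deviation_matrix", class(zt))
    list(
      z = zt,
      truth = list(true_factors = loadings, true_weights = wts$W,
                   true_subtype_labels = wts$labels,
                   epicenter_regions = fac$hubs, factor_modules = fac$modules)
    )
  })
}

#' Write a synthetic bundle as delimited text
#'
#' Writes `hc.tsv`, `patients.tsv`, `gmv.tsv`, `receptors.tsv`,
#' `expression.tsv` and `truth.json` into `dir`.
#'
#' @param bundle A `synthetic_bundle` from [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(hc = "hc.tsv", patients = "patients.tsv", gmv = "gmv.tsv",
             receptors = "receptors.tsv", expression = "expression.tsv")
  for (nm in names(files)) {
    write.table(bundle[[nm]], file.path(dir, files[[nm]]),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- bundle$truth
  truth$curves <- NULL
  json <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, json, digits = NA, auto_unbox = TRUE)
  invisible(c(file.path(dir, files), json))
}
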