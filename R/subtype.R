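# Gaussian-mixture subtyping of factor compositions, BIC model selection,
# adjusted Rand validation, and subtype profiling.

#' Fit patient subtypes with a Gaussian mixture over factor compositions
#'
#' Fits full-covariance Gaussian mixtures by EM for every candidate
#' component count and selects the count minimizing
#' `BIC = -2 loglik + n_params log(N)`; ties go to the smaller count.
#' Initialization uses model-based hierarchical agglomeration (mclust),
#' which is deterministic, so repeated fits reproduce exactly.
#'
#' @param w Compositions (patients x factors matrix or `factor_model`).
#' @param candidate_range Candidate subtype counts (default 2:10).
#' @param seed Integer seed (recorded; the fit itself is deterministic).
#' @param standardize Standardize compositions before fitting (default
#'   FALSE: compositions are used raw).
#' @return A `subtype_model`: `labels` (per patient), `responsibilities`,
#'   `s` (selected count), `bic` tibble over the candidate range,
#'   mixture parameters, and the fitted mclust object.
#' @export
fit_subtypes <- function(w, candidate_range = 2:10, seed = 1,
                         standardize = FALSE) {
  if (inherits(w, "factor_model")) w <- w$W
  w <- as.matrix(w)
  n <- nrow(w)
  if (length(candidate_range) == 0L) abort("empty candidate range")
  if (n < max(candidate_range)) {
    abort("fewer patients than the largest candidate subtype count")
  }
  if (n < 10 * max(candidate_range)) {
    warn("fewer than 10 patients per candidate component; selection may be unstable")
  }
  center <- colMeans(w); scl <- apply(w, 2L, sd)
  wx <- if (standardize) scale(w) else w

  fits <- with_seed(seed, {
    lapply(candidate_range, function(g) {
      suppressWarnings(
        tryCatch(mclust::Mclust(wx, G = g, modelNames = "VVV",
                                verbose = FALSE),
                 error = function(e) NULL)
      )
    })
  })
  bic <- tibble(
    s = as.integer(candidate_range),
    loglik = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$loglik),
    n_params = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else
      mclust::nMclustParams(.x$modelName, d = ncol(wx), G = .x$G)),
    bic = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else -.x$bic)
  )
  if (all(is.na(bic$bic))) abort("no mixture fit converged")
  s_best <- bic$s[which.min(bic$bic)]   # which.min takes first on ties
  best <- fits[[match(s_best, candidate_range)]]

  structure(
    list(
      fit = best, s = s_best, bic = bic,
      labels = as.integer(best$classification),
      responsibilities = best$z,
      means = best$parameters$mean,
      mixing = best$parameters$pro,
      standardize = standardize, center = center, scale = scl,
      seed = seed
    ),
    class = "subtype_model"
  )
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("<subtype_model>\n")
  cat(sprintf("  selected subtypes: %d (BIC over %d-%d)\n",
              x$s, min(x$bic$s), max(x$bic$s)))
  cat("  sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Assign new patients to fitted subtypes
#'
#' Maximum-posterior component assignment under the fitted mixture.
#'
#' @param model A `subtype_model`.
#' @param w_new Compositions (patients x factors) with the model's
#'   dimensionality.
#' @return List with `labels` and `responsibilities`.
#' @export
predict_subtypes <- function(model, w_new) {
  if (inherits(w_new, "factor_model")) w_new <- w_new$W
  w_new <- as.matrix(w_new)
  d <- nrow(model$fit$parameters$mean)
  if (ncol(w_new) != d) {
    abort(sprintf("model expects %d factors, got %d", d, ncol(w_new)))
  }
  wx <- if (model$standardize) {
    scale(w_new, center = model$center, scale = model$scale)
  } else {
    w_new
  }
  pr <- predict(model$fit, newdata = wx)
  list(labels = as.integer(pr$classification), responsibilities = pr$z)
}

#' Adjusted Rand index between two partitions
#'
#' Permutation-model-adjusted Rand index computed from the contingency
#' table: 1 for identical partitions (up to label renaming), about 0 for
#' independent ones.
#'
#' @param labels_a,labels_b Equal-length label vectors (>= 2 items).
#' @return A single number, at most 1.
#' @export
adjusted_rand <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort("label vectors differ in length")
  }
  if (length(labels_a) < 2L) abort("need at least 2 items")
  tab <- table(labels_a, labels_b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Profile subtypes against controls and on clinical variables
#'
#' Per subtype, a covariate-adjusted region-wise t map versus controls
#' with Bonferroni correction at `0.05 / n_regions`; clinical variables
#' are compared between every subtype pair with two-sample t tests,
#' BH-FDR-corrected across all pairs and variables, with a one-way
#' omnibus test per variable for context.
#'
#' @param patients Patient cohort table.
#' @param controls Control cohort table.
#' @param labels Integer subtype label per patient.
#' @param covariates Covariates for the t maps (default age, sex, site,
#'   fd).
#' @param clinical_vars Clinical column names to contrast (default
#'   `c("hamd", "duration")`).
#' @return A `subtype_profile`: `t_maps` (named list of `group_map`
#'   tibbles with `p_bonf` and `sig_bonf` columns), `clinical` contrasts
#'   tibble, `omnibus` tibble, `sizes`.
#' @export
subtype_profiles <- function(patients, controls, labels,
                             covariates = c("age", "sex", "site", "fd"),
                             clinical_vars = c("hamd", "duration")) {
  labels <- as.integer(labels)
  if (length(labels) != nrow(patients)) {
    abort("`labels` must have one entry per patient")
  }
  sizes <- table(labels)
  if (any(sizes < 5L)) {
    abort(sprintf("subtype(s) with < 5 patients: %s",
                  paste(names(sizes)[sizes < 5L], collapse = ", ")))
  }
  if (any(sizes < 20L)) warn("subtype(s) with < 20 patients; maps will be noisy")
  n_regions <- length(region_cols(patients))

  t_maps <- lapply(sort(unique(labels)), function(s) {
    gm <- group_difference_map(patients[labels == s, , drop = FALSE],
                               controls, covariates)
    gm$p_bonf <- pmin(gm$p * n_regions, 1)
    gm$sig_bonf <- gm$p < 0.05 / n_regions
    gm
  })
  names(t_maps) <- paste0("subtype_", sort(unique(labels)))

  subs <- sort(unique(labels))
  clinical_vars <- intersect(clinical_vars, names(patients))
  pairs <- if (length(subs) >= 2L) utils::combn(subs, 2L, simplify = FALSE) else list()
  rows <- purrr::map(clinical_vars, function(v) {
    purrr::map(pairs, function(pr) {
      xa <- patients[[v]][labels == pr[1]]
      xb <- patients[[v]][labels == pr[2]]
      tt <- stats::t.test(xa, xb, var.equal = TRUE)
      tibble(variable = v, subtype_a = pr[1], subtype_b = pr[2],
             t = unname(tt$statistic), p = tt$p.value,
             mean_a = mean(xa), mean_b = mean(xb))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(rows)) rows$p_fdr <- bh_adjust(rows$p)

  omnibus <- purrr::map(clinical_vars, function(v) {
    a <- stats::oneway.test(patients[[v]] ~ factor(labels), var.equal = TRUE)
    tibble(variable = v, f_statistic = unname(a$statistic),
           p = a$p.value)
  }) |> dplyr::bind_rows()

  structure(
    list(t_maps = t_maps, clinical = rows, omnibus = omnibus,
         sizes = as.integer(sizes), bonferroni_alpha = 0.05 / n_regions),
    class = "subtype_profile"
  )
}
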