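# Gaussian-process normative modeling of regional values on age and sex.
#
# Per region, an exact GP regression with kernel
#   k = sf^2 * exp(-(da^2 / (2 la^2)) - (ds^2 / (2 ls^2))) + sl^2 * a a' + sn^2 I
# (squared-exponential over standardized age and the binary sex input with
# its own length scale, plus a linear age term and white noise) is fitted
# by maximizing the marginal likelihood with analytic gradients (L-BFGS-B,
# fixed-seed restarts). Deviation Z-scores divide the centered observation
# by the full predictive SD, predictive variance plus noise variance.

# ---- GP engine ------------------------------------------------------------

gp_kernel_parts <- function(a1, s1, a2, s2) {
  list(
    d2a = outer(a1, a2, "-")^2,
    d2s = outer(s1, s2, "-")^2,
    lin = outer(a1, a2)
  )
}

gp_kernel <- function(parts, th) {
  sf2 <- exp(2 * th[1]); la2 <- exp(2 * th[2]); ls2 <- exp(2 * th[3])
  sl2 <- exp(2 * th[4])
  kse <- sf2 * exp(-0.5 * (parts$d2a / la2 + parts$d2s / ls2))
  list(kse = kse, k = kse + sl2 * parts$lin)
}

# Negative marginal log-likelihood and its gradient in the log parameters.
gp_nll <- function(th, parts, y) {
  n <- length(y)
  sn2 <- exp(2 * th[5])
  km <- gp_kernel(parts, th)
  K <- km$k + diag(sn2 + 1e-8, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, 5)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)

  Kinv <- chol2inv(L)
  A <- tcrossprod(alpha) - Kinv            # dL/dK = 0.5 * A (for loglik)
  la2 <- exp(2 * th[2]); ls2 <- exp(2 * th[3]); sl2 <- exp(2 * th[4])
  dk <- list(
    2 * km$kse,
    km$kse * (parts$d2a / la2),
    km$kse * (parts$d2s / ls2),
    2 * sl2 * parts$lin,
    diag(2 * sn2, n)
  )
  grad <- -0.5 * vapply(dk, function(D) sum(A * D), numeric(1))
  list(value = nll, grad = grad)
}

# Fit one region: restarts over fixed initializations, best marginal
# likelihood kept (ties by restart order through strict improvement).
gp_fit_region <- function(a, s, y, restarts = 3L, maxit = 100L) {
  parts <- gp_kernel_parts(a, s, a, s)
  inits <- list(
    log(c(1, 1, 1, 0.5, 0.5)),
    log(c(0.5, 2, 3, 1, 1)),
    log(c(1.5, 0.5, 1, 0.1, 0.3))
  )[seq_len(min(restarts, 3L))]
  if (restarts > 3L) {
    extra <- with_seed(restarts, lapply(seq_len(restarts - 3L), function(i) {
      runif(5, -1.5, 0.5)
    }))
    inits <- c(inits, extra)
  }
  best <- NULL
  for (th0 in inits) {
    fit <- tryCatch(
      optim(th0,
            fn = function(th) gp_nll(th, parts, y)$value,
            gr = function(th) gp_nll(th, parts, y)$grad,
            method = "L-BFGS-B", lower = -6, upper = 4,
            control = list(maxit = maxit)),
      error = function(e) NULL
    )
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) abort("GP hyperparameter optimization failed")
  th <- best$par
  n <- length(y)
  K <- gp_kernel(parts, th)$k + diag(exp(2 * th[5]) + 1e-8, n)
  L <- chol(K)
  list(theta = th, alpha = backsolve(L, forwardsolve(t(L), y)), L = L,
       a = a, s = s, nll = best$value)
}

# Predictive mean and latent variance at new inputs.
gp_predict_region <- function(fit, a_new, s_new) {
  th <- fit$theta
  parts <- gp_kernel_parts(a_new, s_new, fit$a, fit$s)
  ks <- gp_kernel(parts, th)$k                    # m x n
  mean <- drop(ks %*% fit$alpha)
  v <- forwardsolve(t(fit$L), t(ks))              # n x m
  kss <- exp(2 * th[1]) + exp(2 * th[4]) * a_new^2
  var <- pmax(kss - colSums(v^2), 1e-12)
  list(mean = mean, var = var, noise_var = exp(2 * th[5]))
}

# Refit the noise variance on the full cohort (1-D marginal-likelihood
# search, other hyperparameters fixed) and condition on all observations.
gp_condition_full <- function(theta, a, s, y) {
  parts <- gp_kernel_parts(a, s, a, s)
  k_sig <- gp_kernel(parts, theta)$k
  n <- length(y)
  nll_noise <- function(ln_sn) {
    K <- k_sig + diag(exp(2 * ln_sn) + 1e-8, n)
    L <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(L)) return(1e10)
    alpha <- backsolve(L, forwardsolve(t(L), y))
    0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  }
  opt <- stats::optimize(nll_noise, c(-6, 2), tol = 1e-4)
  th <- theta
  th[5] <- opt$minimum
  K <- k_sig + diag(exp(2 * th[5]) + 1e-8, n)
  L <- chol(K)
  list(theta = th, alpha = backsolve(L, forwardsolve(t(L), y)), L = L,
       a = a, s = s, nll = opt$objective)
}

# ---- Module surface -------------------------------------------------------

#' Fit per-region Gaussian-process normative models on healthy controls
#'
#' For every region column a GP regression of the regional value on age and
#' sex is fitted by marginal-likelihood optimization. Values and ages are
#' standardized internally; the returned model predicts on the original
#' scale.
#'
#' @param hc Control cohort table with numeric `age`, binary `sex` and
#'   `roi_*` region columns. At least 30 controls are required.
#' @param restarts Number of optimizer restarts per region (default 3,
#'   fixed initializations).
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param hyper_subsample For large cohorts, optimize the kernel
#'   hyperparameters on an age-stratified subsample of this size, then
#'   re-optimize the noise variance on the full cohort (one-dimensional
#'   marginal-likelihood search) and condition the GP on all controls.
#'   Cuts the cubic cost of hyperparameter search while keeping the noise
#'   estimate -- which drives Z calibration -- at full precision. `NULL`
#'   (default) optimizes everything on the full cohort.
#' @return A `normative_model` with one fitted regressor per region, the
#'   estimated observation-noise variance, and the training covariate
#'   ranges used to flag extrapolation at scoring time.
#' @export
fit_normative <- function(hc, restarts = 3L, maxit = 100L,
                          hyper_subsample = NULL) {
  if (nrow(hc) < 30L) {
    abort("need >= 30 controls for stable GP hyperparameters")
  }
  if (!is.numeric(hc$age)) abort("`age` column must be numeric")
  sex <- hc$sex
  if (!all(sex %in% c(0, 1))) abort("`sex` column must be binary 0/1")
  y_all <- region_matrix(hc)
  const <- apply(y_all, 2L, var) == 0
  if (any(const)) {
    abort(sprintf("constant region(s): %s",
                  paste(colnames(y_all)[const], collapse = ", ")))
  }
  age_center <- mean(hc$age); age_scale <- sd(hc$age)
  a <- (hc$age - age_center) / age_scale
  s <- as.numeric(sex)
  n <- nrow(hc)

  sub_idx <- NULL
  if (!is.null(hyper_subsample) && hyper_subsample < n) {
    m_sub <- check_count(hyper_subsample, "hyper_subsample", min = 30L)
    sub_idx <- order(hc$age)[unique(round(seq(1, n, length.out = m_sub)))]
  }

  fits <- lapply(seq_len(ncol(y_all)), function(j) {
    y <- y_all[, j]
    my <- mean(y); sy <- sd(y)
    ys <- (y - my) / sy
    if (is.null(sub_idx)) {
      fit <- gp_fit_region(a, s, ys, restarts = restarts, maxit = maxit)
    } else {
      sub <- gp_fit_region(a[sub_idx], s[sub_idx], ys[sub_idx],
                           restarts = restarts, maxit = maxit)
      fit <- gp_condition_full(sub$theta, a, s, ys)
    }
    fit$y_center <- my
    fit$y_scale <- sy
    fit
  })
  names(fits) <- colnames(y_all)

  structure(
    list(
      fits = fits, regions = colnames(y_all),
      age_center = age_center, age_scale = age_scale,
      age_range = range(hc$age), n_train = nrow(hc)
    ),
    class = "normative_model"
  )
}

#' @export
print.normative_model <- function(x, ...) {
  cat("<normative_model>\n")
  cat(sprintf("  regions: %d  controls: %d  age range: %.1f-%.1f\n",
              length(x$regions), x$n_train, x$age_range[1], x$age_range[2]))
  invisible(x)
}

# Predict mean / total predictive variance (original scale) for a table.
normative_predict <- function(model, table, regions = model$regions) {
  a <- (table$age - model$age_center) / model$age_scale
  s <- as.numeric(table$sex)
  out <- lapply(regions, function(rg) {
    fit <- model$fits[[rg]]
    p <- gp_predict_region(fit, a, s)
    list(mean = p$mean * fit$y_scale + fit$y_center,
         var = p$var * fit$y_scale^2,
         noise_var = p$noise_var * fit$y_scale^2)
  })
  names(out) <- regions
  out
}

#' Deviation Z-scores of subjects under a normative model
#'
#' For each subject and region, `Z = (observed - predictive mean) /
#' sqrt(predictive variance + noise variance)`: the standardized departure
#' from the control-derived normative distribution. Positive Z means a
#' higher regional value than expected for controls of that age and sex.
#'
#' @param model A `normative_model` from [fit_normative()].
#' @param subjects Cohort table with the same region columns.
#' @return A `deviation_matrix` tibble: `subject_id` plus one Z column per
#'   region.
#' @export
deviation_scores <- function(model, subjects) {
  regions <- region_cols(subjects)
  if (!setequal(regions, model$regions)) {
    off <- c(setdiff(regions, model$regions), setdiff(model$regions, regions))
    abort(sprintf("region mismatch between model and table: %s",
                  paste(off, collapse = ", ")))
  }
  rng <- model$age_range
  pad <- 0.1 * diff(rng)
  if (any(subjects$age < rng[1] - pad | subjects$age > rng[2] + pad)) {
    warn("some subjects' ages fall outside the training range by more than 10%")
  }
  y <- region_matrix(subjects, model$regions)
  pred <- normative_predict(model, subjects)
  z <- vapply(model$regions, function(rg) {
    p <- pred[[rg]]
    (y[, rg] - p$mean) / sqrt(p$var + p$noise_var)
  }, numeric(nrow(subjects)))
  z <- matrix(z, nrow = nrow(subjects),
              dimnames = list(NULL, model$regions))
  out <- dplyr::bind_cols(
    tibble(subject_id = subjects$subject_id %||% as.character(seq_len(nrow(subjects)))),
    as_tibble(z)
  )
  class(out) <- c("deviation_matrix", class(out))
  out
}

#' Evaluate normative-model calibration by cross-validation
#'
#' Computes the per-region standardized mean squared error (test MSE
#' divided by the variance of the test observations; 1 is the
#' irreducible-noise benchmark, values below 1 indicate predictive signal)
#' under one of three schemes: repeated k-fold, leave-one-site-out, or
#' cross-dataset application.
#'
#' @param hc Control cohort table used for training.
#' @param scheme One of `"kfold"`, `"leave_one_site_out"`,
#'   `"cross_dataset"`.
#' @param k,repeats Fold count and repeat count for `"kfold"`.
#' @param other Validation control table for `"cross_dataset"`.
#' @param seed Integer seed controlling fold assignment.
#' @param restarts,maxit GP fitting controls (see [fit_normative()]).
#' @return A `normative_eval` tibble with one row per region (`region`,
#'   `smse`), carrying the scheme and repeat count as attributes.
#' @export
evaluate_normative <- function(hc,
                               scheme = c("kfold", "leave_one_site_out",
                                          "cross_dataset"),
                               k = 10L, repeats = 1L, other = NULL, seed = 1,
                               restarts = 3L, maxit = 100L) {
  scheme <- match.arg(scheme)
  regions <- region_cols(hc)
  smse_region <- function(train, test) {
    m <- fit_normative(train, restarts = restarts, maxit = maxit)
    y <- region_matrix(test, m$regions)
    pred <- normative_predict(m, test)
    vapply(m$regions, function(rg) {
      obs <- y[, rg]
      mean((obs - pred[[rg]]$mean)^2) / var(obs)
    }, numeric(1))
  }

  if (scheme == "kfold") {
    k <- check_count(k, "k", min = 2L)
    repeats <- check_count(repeats, "repeats")
    acc <- with_seed(seed, {
      out <- matrix(0, repeats * k, length(regions))
      row <- 0L
      for (rep_i in seq_len(repeats)) {
        folds <- sample(rep_len(seq_len(k), nrow(hc)))
        for (f in seq_len(k)) {
          row <- row + 1L
          out[row, ] <- smse_region(hc[folds != f, , drop = FALSE],
                                    hc[folds == f, , drop = FALSE])
        }
      }
      out
    })
    smse <- colMeans(acc)
  } else if (scheme == "leave_one_site_out") {
    sites <- unique(hc$site)
    if (length(sites) < 2L) abort("leave-one-site-out needs >= 2 sites")
    acc <- vapply(sites, function(s) {
      smse_region(hc[hc$site != s, , drop = FALSE],
                  hc[hc$site == s, , drop = FALSE])
    }, numeric(length(regions)))
    smse <- rowMeans(acc)
  } else {
    if (is.null(other)) abort("`other` table required for cross_dataset")
    if (!setequal(region_cols(other), regions)) {
      abort("cross_dataset: region columns differ between tables")
    }
    smse <- smse_region(hc, other)
  }

  out <- tibble(region = regions, smse = as.numeric(smse))
  class(out) <- c("normative_eval", class(out))
  attr(out, "scheme") <- scheme
  attr(out, "repeats") <- if (scheme == "kfold") repeats else 1L
  out
}

#' Per-region extreme-deviation overlap across patients
#'
#' The proportion of patients whose deviation exceeds the extreme threshold
#' in each region, separately for supra-normal (`Z > threshold`) and
#' infra-normal (`Z < -threshold`) deviations. The default threshold 2.6
#' corresponds to a per-tail normal probability below 0.005.
#'
#' @param z A `deviation_matrix` (or any table of Z columns).
#' @param threshold Positive extreme-deviation threshold (default 2.6).
#' @return Tibble with `region`, `overlap_pos`, `overlap_neg` (both in
#'   \[0, 1\]); attribute `max_overlap` holds the headline maximum.
#' @export
extreme_deviation_overlap <- function(z, threshold = 2.6) {
  threshold <- check_positive(threshold, "threshold")
  zm <- as_dev_matrix(z)
  if (nrow(zm) == 0L) abort("empty deviation matrix")
  pos <- colMeans(zm > threshold)
  neg <- colMeans(zm < -threshold)
  out <- tibble(region = colnames(zm),
                overlap_pos = as.numeric(pos),
                overlap_neg = as.numeric(neg))
  attr(out, "max_overlap") <- max(pos, neg)
  attr(out, "threshold") <- threshold
  out
}
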