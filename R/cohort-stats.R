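# Group-level difference maps, factor-to-map multilinear models with
# permutation significance, and clinical associations of compositions.

# Build the design matrix for covariate-adjusted group models: numeric
# covariates as-is, categorical (e.g. site) dummy-coded.
stats_design <- function(df, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow(df), 0L))
  }
  covariate_design(df, covariates)
}

#' Region-wise group-difference map with covariate control
#'
#' Per region, fits `value ~ group + covariates` by OLS on the pooled
#' patient + control table and reports the t statistic and two-sided p of
#' the group coefficient (patients minus controls), with
#' Benjamini-Hochberg adjustment across regions. This is the regression
#' form of a two-sample t test controlling for covariates; with no
#' covariates it reduces to the textbook pooled-variance t test.
#'
#' @param patients,controls Cohort tables sharing region columns.
#' @param covariates Covariate column names (categorical ones, e.g.
#'   `site`, are dummy-coded). Default `c("age", "sex", "site", "fd")`.
#' @return A `group_map` tibble: `region`, `t`, `p`, `p_fdr`; attributes
#'   `df` (residual degrees of freedom) and `covariates`.
#' @export
group_difference_map <- function(patients, controls,
                                 covariates = c("age", "sex", "site", "fd")) {
  regions <- region_cols(patients)
  if (!setequal(regions, region_cols(controls))) {
    abort("patients and controls have different region columns")
  }
  shared <- intersect(names(patients), names(controls))
  pooled <- dplyr::bind_rows(patients[shared], controls[shared])
  group <- c(rep(1, nrow(patients)), rep(0, nrow(controls)))
  xc <- stats_design(pooled, covariates)
  X <- cbind(intercept = 1, group = group, xc)
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank-deficient (a covariate may be constant or collinear)")
  }
  y <- region_matrix(pooled, regions)
  beta <- solve(crossprod(X), crossprod(X, y))
  df_res <- nrow(X) - ncol(X)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  se_scale <- sqrt(xtx_inv[2, 2])
  res <- y - X %*% beta
  sigma <- sqrt(colSums(res^2) / df_res)
  tval <- beta[2, ] / (sigma * se_scale)
  p <- 2 * pt(-abs(tval), df = df_res)
  out <- tibble(region = regions, t = as.numeric(tval), p = as.numeric(p),
                p_fdr = bh_adjust(p))
  class(out) <- c("group_map", class(out))
  attr(out, "df") <- df_res
  attr(out, "covariates") <- covariates
  out
}

#' Multilinear model of a group-difference map on factor maps
#'
#' Regresses the unthresholded regional t-statistic vector on the signed
#' factor maps (intercept included) and assesses the model by permutation:
#' the response vector is shuffled across regions, the model refitted, and
#' the observed adjusted R-squared compared against the null.
#'
#' @param t_map A `group_map` (or tibble with `region` and `t`).
#' @param factors Signed factor maps: matrix (factors x regions) or a
#'   `factor_model`; pass positive-bank loadings as-is and negative-bank
#'   loadings negated, or use [signed_factor_maps()].
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @return An `association_result` list: `adj_r2`, `r2`, `f_statistic`,
#'   `p_perm`, `coefficients` tibble, `n_perm`.
#' @export
factors_explain_map <- function(t_map, factors, n_perm = 1000L, seed = 1) {
  if (inherits(factors, "factor_model")) factors <- factors$F
  tvec <- t_map$t
  regions <- t_map$region
  if (!is.null(colnames(factors))) {
    if (!setequal(colnames(factors), regions)) {
      abort("factor maps and t map cover different regions")
    }
    factors <- factors[, regions, drop = FALSE]
  }
  k <- nrow(factors)
  r <- length(tvec)
  if (r <= k + 1L) abort("need more regions than factors + 1")
  n_perm <- check_count(n_perm, "n_perm")

  fit_stat <- function(y) {
    s <- suppressWarnings(summary(lm(y ~ t(factors))))
    c(adj = s$adj.r.squared, r2 = s$r.squared)
  }
  obs <- fit_stat(tvec)
  f_stat <- (obs["r2"] / k) / ((1 - obs["r2"]) / (r - k - 1))
  null <- with_seed(child_seed(seed, "fem_null"), {
    vapply(seq_len(n_perm), function(i) fit_stat(sample(tvec))["adj"],
           numeric(1))
  })
  coefs <- coef(lm(tvec ~ t(factors)))
  out <- list(
    adj_r2 = unname(obs["adj"]), r2 = unname(obs["r2"]),
    f_statistic = unname(f_stat),
    df = c(k, r - k - 1),
    p_perm = (1 + sum(null >= obs["adj"])) / (1 + n_perm),
    coefficients = tibble(
      term = c("(Intercept)", rownames(factors) %||% paste0("factor_", seq_len(k))),
      estimate = as.numeric(coefs)
    ),
    n_perm = n_perm, null = null
  )
  class(out) <- "association_result"
  out
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result>\n")
  cat(sprintf("  adjusted R^2 = %.3f  F(%d, %d) = %.2f  permutation p = %.4g\n",
              x$adj_r2, x$df[1], x$df[2], x$f_statistic, x$p_perm))
  invisible(x)
}

#' Signed factor maps from positive and negative banks
#'
#' Stacks positive-bank loadings as-is and negative-bank loadings with a
#' negative sign, giving the signed spatial maps used when relating
#' factors to signed quantities (t maps, deviation vectors).
#'
#' @param f_pos,f_neg `factor_model`s or loading matrices.
#' @return Matrix (factors x regions) with rownames `pos_*` / `neg_*`.
#' @export
signed_factor_maps <- function(f_pos, f_neg = NULL) {
  fp <- if (inherits(f_pos, "factor_model")) f_pos$F else f_pos
  fn <- if (inherits(f_neg, "factor_model")) f_neg$F else f_neg
  rownames(fp) <- paste0("pos_", seq_len(nrow(fp)))
  out <- fp
  if (!is.null(fn)) {
    rownames(fn) <- paste0("neg_", seq_len(nrow(fn)))
    out <- rbind(fp, -fn)
  }
  out
}

#' Associations between factor compositions and clinical variables
#'
#' Two modes. `contrast`: per factor, OLS of the composition on a binary
#' group variable plus covariates; reports the group t statistic, Cohen's
#' d derived from it (`d = 2 t / sqrt(df)`), and BH-FDR across factors.
#' `correlation`: Pearson correlation of each factor composition with a
#' numeric score, analytic two-sided p, Fisher-z confidence interval, and
#' BH-FDR across factors.
#'
#' @param w Compositions matrix (patients x factors) or a `factor_model`.
#' @param clinical Per-patient table aligned with the rows of `w`.
#' @param type `"contrast"` or `"correlation"`.
#' @param group_var Binary grouping column for contrasts.
#' @param score_var Numeric score column for correlations.
#' @param covariates Covariates controlled in contrasts.
#' @return A `composition_contrast` tibble (`factor`, `t`, `cohens_d`,
#'   `p`, `p_fdr`) or a correlation tibble (`factor`, `r`, `conf_low`,
#'   `conf_high`, `p`, `p_fdr`).
#' @export
composition_association <- function(w, clinical,
                                    type = c("contrast", "correlation"),
                                    group_var = NULL, score_var = NULL,
                                    covariates = character()) {
  type <- match.arg(type)
  if (inherits(w, "factor_model")) w <- w$W
  w <- as.matrix(w)
  if (nrow(w) != nrow(clinical)) {
    abort("`w` and `clinical` must have the same number of rows")
  }
  fnames <- colnames(w) %||% paste0("factor_", seq_len(ncol(w)))

  if (type == "contrast") {
    if (is.null(group_var)) abort("`group_var` required for contrasts")
    g <- clinical[[group_var]]
    lv <- sort(unique(as.character(g)))
    if (length(lv) != 2L) abort(sprintf("'%s' must be binary", group_var))
    if (min(table(g)) < 3L) abort("each group needs at least 3 members")
    gnum <- as.numeric(as.character(g) == lv[2])
    xc <- stats_design(clinical, covariates)
    X <- cbind(1, gnum, xc)
    df_res <- nrow(X) - ncol(X)
    xtx_inv <- chol2inv(chol(crossprod(X)))
    beta <- solve(crossprod(X), crossprod(X, w))
    res <- w - X %*% beta
    sigma <- sqrt(colSums(res^2) / df_res)
    denom <- sigma * sqrt(xtx_inv[2, 2])
    tval <- ifelse(denom > 0, beta[2, ] / denom, 0)
    p <- 2 * pt(-abs(tval), df = df_res)
    p[tval == 0] <- 1
    out <- tibble(
      factor = fnames, t = as.numeric(tval),
      cohens_d = as.numeric(2 * tval / sqrt(df_res)),
      p = as.numeric(p), p_fdr = bh_adjust(p)
    )
    class(out) <- c("composition_contrast", class(out))
    attr(out, "df") <- df_res
    attr(out, "contrast") <- paste(lv[2], "vs", lv[1])
    out
  } else {
    if (is.null(score_var)) abort("`score_var` required for correlations")
    score <- clinical[[score_var]]
    if (!is.numeric(score)) abort(sprintf("'%s' must be numeric", score_var))
    rows <- lapply(seq_along(fnames), function(j) {
      ct <- cor_test_vec(w[, j], score)
      tibble(factor = fnames[j], r = ct$r,
             conf_low = ct$conf_low, conf_high = ct$conf_high,
             p = ct$p, n = ct$n)
    })
    out <- dplyr::bind_rows(rows)
    out$p_fdr <- bh_adjust(out$p)
    attr(out, "score_var") <- score_var
    out
  }
}
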