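# Receptor/transporter multilinear models with dominance analysis, and
# spatial correlation with averaged gene expression.

# Coerce a receptor atlas to a regions x P matrix plus metadata.
as_receptor_matrix <- function(atlas) {
  if (is.data.frame(atlas)) {
    stopifnot("region" %in% names(atlas))
    m <- as.matrix(as.data.frame(atlas)[setdiff(names(atlas), "region")])
    rownames(m) <- atlas$region
    attr(m, "class_labels") <- attr(atlas, "class_labels")
    return(m)
  }
  atlas
}

#' Multilinear model of a factor map on receptor density maps
#'
#' OLS of the regional factor values on all receptor maps, with adjusted
#' R-squared, F statistic, and a permutation p obtained by shuffling the
#' factor map across regions. When a list of factor maps is supplied, the
#' permutation p-values are BH-FDR-corrected across factors.
#'
#' @param factor Regional map (named numeric vector or `region`/`value`
#'   tibble), or a named list of such maps.
#' @param atlas Receptor atlas: tibble with `region` plus one Z-scored
#'   column per receptor (see [generate_molecular_maps()]), or a matrix.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return For a single map, an `association_result` (see
#'   [factors_explain_map()]); for a list, a tibble with one row per
#'   factor (`factor`, `adj_r2`, `f_statistic`, `p_perm`, `p_fdr`) and the
#'   per-factor results in attribute `models`.
#' @export
receptor_model <- function(factor, atlas, n_perm = 1000L, seed = 1) {
  X <- as_receptor_matrix(atlas)
  if (is.list(factor) && !is.data.frame(factor)) {
    fits <- purrr::imap(factor, function(f, nm) {
      receptor_model(f, atlas, n_perm = n_perm,
                     seed = child_seed(seed, paste0("receptor_", nm)))
    })
    out <- tibble(
      factor = names(fits),
      adj_r2 = purrr::map_dbl(fits, "adj_r2"),
      f_statistic = purrr::map_dbl(fits, "f_statistic"),
      p_perm = purrr::map_dbl(fits, "p_perm")
    )
    out$p_fdr <- bh_adjust(out$p_perm)
    attr(out, "models") <- fits
    return(out)
  }

  f <- as_region_vector(factor, rownames(X))
  r <- length(f); p <- ncol(X)
  if (r <= p + 1L) abort("need more regions than receptors + 1")
  kap <- kappa(cbind(1, X), exact = TRUE)
  if (kap > 1e8) {
    abort("receptor columns are near-collinear (condition number > 1e8)")
  }
  n_perm <- check_count(n_perm, "n_perm")

  fit_stat <- function(y) {
    s <- suppressWarnings(summary(lm(y ~ X)))
    c(adj = s$adj.r.squared, r2 = s$r.squared)
  }
  obs <- fit_stat(f)
  f_stat <- (obs["r2"] / p) / ((1 - obs["r2"]) / (r - p - 1))
  null <- with_seed(child_seed(seed, "receptor_null"), {
    vapply(seq_len(n_perm), function(i) fit_stat(sample(f))["adj"], numeric(1))
  })
  coefs <- coef(lm(f ~ X))
  out <- list(
    adj_r2 = unname(obs["adj"]), r2 = unname(obs["r2"]),
    f_statistic = unname(f_stat), df = c(p, r - p - 1),
    p_perm = (1 + sum(null >= obs["adj"])) / (1 + n_perm),
    coefficients = tibble(term = c("(Intercept)", colnames(X)),
                          estimate = as.numeric(coefs)),
    n_perm = n_perm, null = null
  )
  class(out) <- "association_result"
  out
}

# R^2 of y on the predictor subset encoded by bitmask, via the correlation
# matrix (all variables standardized once up front).
.subset_r2_table <- function(y, X) {
  p <- ncol(X)
  S <- cor(cbind(y, X))
  ryx <- S[1, -1]
  Rxx <- S[-1, -1, drop = FALSE]
  r2 <- numeric(2^p)
  for (mask in 1:(2^p - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(p - 1))) > 0)
    r2[mask + 1] <- drop(crossprod(
      ryx[idx], solve(Rxx[idx, idx, drop = FALSE], ryx[idx])
    ))
  }
  r2
}

#' Dominance analysis of receptor predictors
#'
#' Shapley-style decomposition of the full-model R-squared: every subset
#' model is fitted, and each predictor's total dominance is the average
#' over subset sizes of its mean incremental R-squared when added to each
#' subset not containing it. Total dominance values sum to the full-model
#' R-squared. Class sums (excitatory / inhibitory) are reported when the
#' atlas carries class labels.
#'
#' @inheritParams receptor_model
#' @param predictor_subset Optional receptor names to restrict to (the
#'   exhaustive enumeration requires at most 20 predictors).
#' @return A `dominance_result`: tibble `dominance` (`receptor`,
#'   `total_dominance`, and `class` when available), `full_r2`,
#'   `full_adj_r2`, `class_sums`.
#' @export
dominance_analysis <- function(factor, atlas, predictor_subset = NULL) {
  X <- as_receptor_matrix(atlas)
  classes <- attr(X, "class_labels")
  if (!is.null(predictor_subset)) {
    missing <- setdiff(predictor_subset, colnames(X))
    if (length(missing)) {
      abort(sprintf("receptor(s) not in atlas: %s",
                    paste(missing, collapse = ", ")))
    }
    X <- X[, predictor_subset, drop = FALSE]
  }
  p <- ncol(X)
  if (p > 20L) {
    abort("more than 20 predictors: pass `predictor_subset` to restrict the enumeration")
  }
  f <- as_region_vector(factor, rownames(X))
  r <- length(f)
  if (r <= p + 1L) abort("need more regions than predictors + 1")

  r2 <- .subset_r2_table(f, X)
  full_r2 <- r2[2^p]
  bits <- bitwShiftL(1L, 0:(p - 1))
  masks <- 0:(2^p - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bits) > 0), numeric(1))

  total <- numeric(p)
  for (j in seq_len(p)) {
    without_j <- masks[bitwAnd(masks, bits[j]) == 0]
    inc <- r2[bitwOr(without_j, bits[j]) + 1] - r2[without_j + 1]
    sz <- sizes[without_j + 1]
    by_size <- tapply(inc, sz, mean)
    total[j] <- mean(by_size)
  }

  dom <- tibble(receptor = colnames(X), total_dominance = total)
  class_sums <- NULL
  if (!is.null(classes)) {
    dom$class <- unname(classes[dom$receptor])
    class_sums <- tapply(dom$total_dominance, dom$class, sum)
  }
  adj <- 1 - (1 - full_r2) * (r - 1) / (r - p - 1)
  out <- list(dominance = dom, full_r2 = full_r2, full_adj_r2 = adj,
              class_sums = class_sums)
  class(out) <- "dominance_result"
  out
}

#' @export
print.dominance_result <- function(x, ...) {
  cat("<dominance_result>\n")
  cat(sprintf("  full-model R^2 = %.3f (adjusted %.3f); dominance sum = %.3f\n",
              x$full_r2, x$full_adj_r2, sum(x$dominance$total_dominance)))
  print(dplyr::arrange(x$dominance, dplyr::desc(.data$total_dominance)),
        n = 5)
  invisible(x)
}

#' Average Z-scored expression vector over a gene set
#'
#' Z-scores each requested gene's expression across regions, then averages
#' over genes, giving one expression value per region.
#'
#' @param expr_table Tibble with `region` plus one column per gene.
#' @param genes Gene column names to include (default: all gene columns).
#' @return Tibble with `region` and `expression`.
#' @export
build_expression_vector <- function(expr_table, genes = NULL) {
  gene_cols <- setdiff(names(expr_table), "region")
  genes <- genes %||% gene_cols
  missing <- setdiff(genes, gene_cols)
  if (length(missing)) {
    abort(sprintf("gene(s) not in table: %s", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(as.data.frame(expr_table)[genes])
  z <- scale(m)
  tibble(region = expr_table$region, expression = rowMeans(z))
}

#' Spatial correlation between a factor map and gene expression
#'
#' Pearson correlation across regions with a Fisher-z confidence interval
#' and a permutation p (expression vector shuffled across regions). For a
#' list of factor maps, permutation p-values are BH-FDR-corrected across
#' factors.
#'
#' @param factor Regional map, or named list of maps.
#' @param expr Expression vector: tibble with `region` and `expression`
#'   (from [build_expression_vector()]) or a named numeric vector.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return For one map: tibble row with `r`, `conf_low`, `conf_high`,
#'   `p_perm`. For a list: tibble with one row per factor plus `p_fdr`.
#' @export
expression_correlation <- function(factor, expr, n_perm = 1000L, seed = 1) {
  e <- if (is.data.frame(expr)) {
    setNames(expr$expression, expr$region)
  } else {
    expr
  }
  if (sd(e) == 0) abort("expression vector is constant")
  if (is.list(factor) && !is.data.frame(factor)) {
    rows <- purrr::imap(factor, function(f, nm) {
      res <- expression_correlation(f, expr, n_perm = n_perm,
                                    seed = child_seed(seed, paste0("expr_", nm)))
      dplyr::mutate(res, factor = nm, .before = 1)
    })
    out <- dplyr::bind_rows(rows)
    out$p_fdr <- bh_adjust(out$p_perm)
    return(out)
  }
  f <- as_region_vector(factor, names(e))
  if (length(f) < 10L) abort("need at least 10 regions")
  n_perm <- check_count(n_perm, "n_perm")
  ct <- cor_test_vec(f, e)
  null <- with_seed(child_seed(seed, "expr_null"), {
    vapply(seq_len(n_perm), function(i) cor(f, sample(e)), numeric(1))
  })
  tibble(
    r = ct$r, conf_low = ct$conf_low, conf_high = ct$conf_high,
    p_perm = (1 + sum(abs(null) >= abs(ct$r))) / (1 + n_perm),
    n_perm = n_perm
  )
}
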