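# broom-style tidy()/glance() methods for the fitted objects.

#' Tidy a factor model into long format
#'
#' @param x A `factor_model`.
#' @param what `"loadings"` (factor x region values) or `"weights"`
#'   (patient compositions).
#' @param ... Unused.
#' @return Long tibble: `factor`, `region`, `loading` — or `subject_id`,
#'   `factor`, `weight`.
#' @export
tidy.factor_model <- function(x, what = c("loadings", "weights"), ...) {
  what <- match.arg(what)
  if (what == "loadings") {
    loadings_tibble(x) |>
      tidyr::pivot_longer(-"factor", names_to = "region",
                          values_to = "loading")
  } else {
    dplyr::bind_cols(
      tibble(subject_id = rownames(x$W) %||% as.character(seq_len(nrow(x$W)))),
      as_tibble(x$W)
    ) |>
      tidyr::pivot_longer(-"subject_id", names_to = "factor",
                          values_to = "weight")
  }
}

#' One-row summary of a factor model
#' @param x A `factor_model`.
#' @param ... Unused.
#' @return Tibble with `k`, `n_patients`, `n_regions`, `final_objective`,
#'   `n_iter`, `n_dropped`.
#' @export
glance.factor_model <- function(x, ...) {
  tibble(
    k = x$k, n_patients = nrow(x$W), n_regions = ncol(x$F),
    final_objective = x$objective[length(x$objective)],
    n_iter = length(x$objective) - 1L,
    n_dropped = length(x$dropped)
  )
}

#' Representative regions of each factor
#'
#' The top share of regions by loading per factor (default the top 10%,
#' rounded up so the set is never empty).
#'
#' @param fm A `factor_model` or loading matrix.
#' @param top Proportion of regions to keep per factor.
#' @return Tibble: `factor`, `region`, `loading`, ordered by loading.
#' @export
representative_regions <- function(fm, top = 0.1) {
  f <- if (inherits(fm, "factor_model")) fm$F else fm
  n_top <- ceiling(top * ncol(f))
  purrr::map_dfr(seq_len(nrow(f)), function(i) {
    ord <- order(f[i, ], decreasing = TRUE)[seq_len(n_top)]
    tibble(factor = rownames(f)[i] %||% paste0("factor_", i),
           region = colnames(f)[ord], loading = f[i, ord])
  })
}

#' @export
tidy.subtype_model <- function(x, ...) {
  tibble(
    subject_id = rownames(x$responsibilities) %||%
      as.character(seq_along(x$labels)),
    subtype = x$labels,
    responsibility = vapply(seq_along(x$labels), function(i) {
      x$responsibilities[i, x$labels[i]]
    }, numeric(1))
  )
}

#' @export
glance.subtype_model <- function(x, ...) {
  tibble(
    s = x$s,
    bic = x$bic$bic[match(x$s, x$bic$s)],
    loglik = x$bic$loglik[match(x$s, x$bic$s)],
    n = length(x$labels)
  )
}

#' @export
glance.association_result <- function(x, ...) {
  tibble(adj_r2 = x$adj_r2, r2 = x$r2, f_statistic = x$f_statistic,
         df_model = x$df[1], df_residual = x$df[2], p_perm = x$p_perm,
         n_perm = x$n_perm)
}

#' @export
tidy.association_result <- function(x, ...) x$coefficients

#' @export
tidy.dominance_result <- function(x, ...) x$dominance

#' @export
glance.dominance_result <- function(x, ...) {
  tibble(full_r2 = x$full_r2, full_adj_r2 = x$full_adj_r2,
         dominance_sum = sum(x$dominance$total_dominance))
}

#' @export
tidy.combat_params <- function(x, ...) {
  purrr::map_dfr(seq_along(x$site_levels), function(i) {
    tibble(site = x$site_levels[i],
           region = names(x$grand_mean) %||%
             paste0("roi_", seq_along(x$grand_mean)),
           gamma_star = x$gamma_star[i, ],
           delta_star = x$delta_star[i, ])
  })
}
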