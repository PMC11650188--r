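# Structural-covariance network construction, the neighbor-deviation
# statistic D_i, and epicenter-likelihood rankings.

new_sc_network <- function(w, covariates = character(), modules = NULL,
                           hubs = NULL) {
  stopifnot(isSymmetric(unname(w)), all(w >= 0), all(diag(w) == 0))
  structure(w, class = "sc_network", covariates = covariates,
            modules = modules, hubs = hubs)
}

#' @export
print.sc_network <- function(x, ...) {
  w <- unclass(x)
  cat("<sc_network>\n")
  cat(sprintf("  regions: %d  edges > 0: %d  mean positive weight: %.3f\n",
              nrow(w), sum(w > 0) / 2, mean(w[w > 0])))
  invisible(x)
}

#' Build a structural-covariance network from regional volumes
#'
#' Residualizes each region's gray-matter volumes on age, age squared and
#' sex across subjects, correlates the residual profiles for every region
#' pair (Pearson), sets negative correlations to zero and zeroes the
#' diagonal.
#'
#' @param gmv Subjects x regions volume table with `age` and `sex` columns
#'   plus `roi_*` region columns; >= 30 subjects required.
#' @return An `sc_network`: symmetric non-negative matrix with zero
#'   diagonal; attribute `covariates` records the adjustment.
#' @export
build_sc_network <- function(gmv) {
  if (nrow(gmv) < 30L) abort("need >= 30 subjects to estimate covariance")
  y <- region_matrix(gmv)
  if (any(apply(y, 2L, var) == 0)) {
    abort("constant region volume column(s); correlation undefined")
  }
  a <- gmv$age
  X <- cbind(1, a, a^2, as.numeric(gmv$sex))
  res <- y - X %*% solve(crossprod(X), crossprod(X, y))
  w <- cor(res)
  w[w < 0] <- 0
  diag(w) <- 0
  new_sc_network(w, covariates = c("age", "age^2", "sex"))
}

as_region_vector <- function(f, regions = NULL) {
  if (is.data.frame(f)) {
    stopifnot(all(c("region", "value") %in% names(f)) ||
                ncol(f) == 2L)
    v <- f[[setdiff(names(f), "region")[1]]]
    names(v) <- f$region
    f <- v
  }
  f <- drop(f)
  if (!is.null(regions) && !is.null(names(f))) {
    if (!setequal(names(f), regions)) {
      abort("factor map regions do not match the network")
    }
    f <- f[regions]
  }
  f
}

#' Neighbor-deviation statistic D over a structural-covariance network
#'
#' For each region i, `D_i = (1/N_i) * sum_j SC_ij * F_j` over the
#' positively connected neighbors j (self-connections excluded; `N_i` is
#' the neighbor count). The Pearson correlation between the regional
#' values F and D quantifies network constraint on the map.
#'
#' @param factor Regional factor map: named numeric vector (names = region
#'   labels) or a two-column `region`/`value` tibble.
#' @param sc An `sc_network`.
#' @param normalize Divide the neighbor sum by the neighbor count
#'   (`"count"`, default) or by the summed connection strength
#'   (`"strength"`).
#' @return List with `d` (tibble: `region`, `d`, `n_neighbors`),
#'   `r` (correlation between F and D), `conf_low`, `conf_high`, and
#'   `isolated` (regions with no neighbors, excluded from the correlation).
#' @export
neighbor_deviation <- function(factor, sc,
                               normalize = c("count", "strength")) {
  normalize <- match.arg(normalize)
  w <- unclass(sc)
  f <- as_region_vector(factor, rownames(w))
  n_i <- rowSums(w > 0)
  denom <- if (normalize == "count") n_i else rowSums(w)
  d <- unname(as.numeric(w %*% f) / ifelse(denom > 0, denom, NA_real_))
  isolated <- rownames(w)[n_i == 0]
  ok <- n_i > 0
  ct <- if (sum(ok) >= 3L) {
    cor_test_vec(f[ok], d[ok])
  } else {
    warn("fewer than 3 connected regions; F-D correlation undefined")
    list(r = NA_real_, conf_low = NA_real_, conf_high = NA_real_,
         p = NA_real_)
  }
  list(
    d = tibble(region = rownames(w), d = d, n_neighbors = as.integer(n_i)),
    r = ct$r, conf_low = ct$conf_low, conf_high = ct$conf_high,
    p = ct$p, isolated = isolated
  )
}

#' Epicenter-likelihood ranking of regions for a factor map
#'
#' Ranks regions by their own factor value and by their neighbor statistic
#' D (both ascending, average ranks on ties); the epicenter likelihood of
#' a region is the mean of the two ranks, so high-likelihood regions carry
#' high values themselves and sit next to high-valued neighbors. A
#' permutation null (factor values shuffled across regions, D and
#' likelihoods recomputed) yields per-region p-values with add-one
#' smoothing.
#'
#' @inheritParams neighbor_deviation
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @param normalize Divide the neighbor sum by the neighbor count
#'   (`"count"`, default) or by the summed connection strength
#'   (`"strength"`).
#' @return An `epicenter_result` tibble: `region`, `f`, `d`,
#'   `likelihood` (mean rank, in \[1, R\]), `p_perm`; attributes `n_perm`,
#'   `seed`, `r_fd` (F-D correlation).
#' @export
epicenter_ranking <- function(factor, sc, n_perm = 1000L, seed = 1,
                              normalize = c("count", "strength")) {
  n_perm <- check_count(n_perm, "n_perm")
  normalize <- match.arg(normalize)
  w <- unclass(sc)
  f <- as_region_vector(factor, rownames(w))
  n_i <- rowSums(w > 0)
  denom <- if (normalize == "count") n_i else rowSums(w)
  if (any(n_i == 0)) {
    warn("isolated region(s) present; their likelihood uses only the value rank")
  }

  likelihood_of <- function(fv) {
    d <- unname(as.numeric(w %*% fv) / ifelse(denom > 0, denom, NA_real_))
    fr <- rank(unname(fv))
    lk <- (fr + rank(d, na.last = "keep")) / 2
    lk[is.na(lk)] <- fr[is.na(lk)]
    lk
  }
  obs <- likelihood_of(f)
  exceed <- rep(0L, length(f))
  with_seed(child_seed(seed, "epicenter_null"), {
    for (i in seq_len(n_perm)) {
      nullv <- likelihood_of(sample(f))
      exceed <- exceed + (nullv >= obs)
    }
  })
  d <- as.numeric(w %*% f) / ifelse(denom > 0, denom, NA_real_)
  nd <- neighbor_deviation(f, sc)
  out <- tibble(
    region = rownames(w), f = as.numeric(f), d = d,
    likelihood = obs,
    p_perm = (1 + exceed) / (1 + n_perm)
  )
  class(out) <- c("epicenter_result", class(out))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- seed
  attr(out, "r_fd") <- nd$r
  out
}
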