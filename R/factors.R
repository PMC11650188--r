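# Non-negative factorization of deviation matrices: signed split, HALS
# NMF with NNDSVD initialization, split-half generalizability error for
# rank selection, Hungarian factor matching, and variance explained.

as_dev_matrix <- function(z) {
  if (is.matrix(z)) {
    storage.mode(z) <- "double"
    return(z)
  }
  region_matrix(z)
}

#' Split a deviation matrix into non-negative signed banks
#'
#' NMF requires non-negative input, so supra- and infra-normal deviations
#' are separated: `pos = max(Z, 0)`, `neg = max(-Z, 0)`; by construction
#' `pos - neg` reconstructs `Z` exactly.
#'
#' @param z Deviation matrix (a `deviation_matrix` tibble or numeric matrix).
#' @return List with non-negative matrices `pos` and `neg` (patients x
#'   regions, dimnames preserved).
#' @export
split_signed <- function(z) {
  zm <- as_dev_matrix(z)
  list(pos = pmax(zm, 0), neg = pmax(-zm, 0))
}

# NNDSVD initialization (non-negative double SVD); zero entries filled with
# a small positive constant so no component starts dead.
nndsvd_init <- function(x, k) {
  s <- svd(x, nu = k, nv = k)
  n <- nrow(x); r <- ncol(x)
  W <- matrix(0, n, k)
  F <- matrix(0, k, r)
  W[, 1] <- sqrt(s$d[1]) * abs(s$u[, 1])
  F[1, ] <- sqrt(s$d[1]) * abs(s$v[, 1])
  if (k > 1) {
    for (j in 2:k) {
      u <- s$u[, j]; v <- s$v[, j]
      up <- pmax(u, 0); un <- pmax(-u, 0)
      vp <- pmax(v, 0); vn <- pmax(-v, 0)
      nup <- sqrt(sum(up^2)); nun <- sqrt(sum(un^2))
      nvp <- sqrt(sum(vp^2)); nvn <- sqrt(sum(vn^2))
      termp <- nup * nvp; termn <- nun * nvn
      if (termp >= termn && termp > 0) {
        W[, j] <- sqrt(s$d[j] * termp) * up / nup
        F[j, ] <- sqrt(s$d[j] * termp) * vp / nvp
      } else if (termn > 0) {
        W[, j] <- sqrt(s$d[j] * termn) * un / nun
        F[j, ] <- sqrt(s$d[j] * termn) * vn / nvn
      }
    }
  }
  eps <- mean(x) / 100
  W[W <= 0] <- eps
  F[F <= 0] <- eps
  list(W = W, F = F)
}

#' Fit a non-negative matrix factorization
#'
#' Minimizes the Frobenius reconstruction error `||X - W F||` over
#' non-negative `W` (n x k) and `F` (k x r) by HALS coordinate-block
#' updates. The first restart starts from the NNDSVD initialization;
#' further restarts use seeded random initializations; the best final
#' objective is kept, ties resolved by restart order.
#'
#' @param x Non-negative matrix (patients x regions), or a table with
#'   `roi_*` columns. Rows that are entirely zero are dropped with a
#'   warning (recorded in the result).
#' @param k Factor count, `k < min(n, r)`.
#' @param seed Integer seed (controls random restarts).
#' @param n_restarts Number of initializations (default 3).
#' @param max_iter,tol HALS iteration cap and relative objective tolerance.
#' @return A `factor_model`: non-negative loadings `F` (k x regions),
#'   compositions `W` (patients x k), `residual = X - W F`, the objective
#'   trace of the winning restart (monotone non-increasing), dropped row
#'   ids, and the seed.
#' @export
fit_nmf <- function(x, k, seed = 1, n_restarts = 3L,
                    max_iter = 500L, tol = 1e-6) {
  xm <- as_dev_matrix(x)
  if (any(xm < 0)) {
    abort("input has negative entries; use split_signed() first")
  }
  k <- check_count(k, "k")
  if (k >= min(dim(xm))) {
    abort(sprintf("k = %d must be smaller than min(n, r) = %d",
                  k, min(dim(xm))))
  }
  zero_rows <- rowSums(xm) == 0
  dropped <- rownames(xm)[zero_rows] %||% which(zero_rows)
  if (any(zero_rows)) {
    warn(sprintf("dropping %d all-zero row(s) before factorization",
                 sum(zero_rows)))
    xm <- xm[!zero_rows, , drop = FALSE]
  }

  inits <- vector("list", n_restarts)
  inits[[1]] <- nndsvd_init(xm, k)
  if (n_restarts > 1) {
    for (i in 2:n_restarts) {
      inits[[i]] <- with_seed(child_seed(seed, paste0("nmf_restart_", i)), {
        list(W = matrix(runif(nrow(xm) * k, 0, max(xm)), nrow(xm), k),
             F = matrix(runif(k * ncol(xm), 0, 1), k, ncol(xm)))
      })
    }
  }
  best <- NULL
  for (init in inits) {
    fit <- .nmf_hals_cpp(xm, init$W, init$F, as.integer(max_iter), tol)
    obj <- fit$objective[length(fit$objective)]
    if (is.null(best) || obj < best$final) {
      best <- list(fit = fit, final = obj)
    }
  }
  W <- best$fit$W
  F <- best$fit$F
  fnames <- paste0("factor_", seq_len(k))
  dimnames(F) <- list(fnames, colnames(xm))
  dimnames(W) <- list(rownames(xm), fnames)
  structure(
    list(F = F, W = W, residual = xm - W %*% F,
         objective = best$fit$objective,
         dropped = if (any(zero_rows)) dropped else character(),
         k = k, seed = seed),
    class = "factor_model"
  )
}

#' @export
print.factor_model <- function(x, ...) {
  cat("<factor_model>\n")
  cat(sprintf("  factors: %d  patients: %d  regions: %d\n",
              x$k, nrow(x$W), ncol(x$F)))
  cat(sprintf("  final objective (Frobenius): %.4g after %d iterations\n",
              x$objective[length(x$objective)], length(x$objective) - 1L))
  invisible(x)
}

#' Project new rows onto fitted factors by non-negative least squares
#'
#' Solves, per row of `x`, `min ||x_i - w F||` over `w >= 0`
#' (Lawson-Hanson NNLS), yielding out-of-sample factor compositions.
#'
#' @param f A `factor_model` or a k x regions non-negative loading matrix.
#' @param x Non-negative matrix (rows x regions) to project.
#' @return Non-negative weights matrix (rows x k).
#' @export
project_weights <- function(f, x) {
  if (inherits(f, "factor_model")) f <- f$F
  xm <- as_dev_matrix(x)
  if (ncol(xm) != ncol(f)) {
    abort(sprintf("region count mismatch: factors have %d, data has %d",
                  ncol(f), ncol(xm)))
  }
  ft <- t(f)
  W <- t(apply(xm, 1L, function(row) pracma::lsqnonneg(ft, row)$x))
  W <- matrix(W, nrow = nrow(xm))
  dimnames(W) <- list(rownames(xm), rownames(f))
  W
}

#' Split-half generalizability error for a candidate factor count
#'
#' Patients are split at random into two halves; an NMF is fitted on each
#' half; in-sample mean absolute reconstruction errors (`e11`, `e22`) and
#' out-of-sample errors obtained by projecting the held-out half onto the
#' other half's factors (`e12`, `e21`) are recorded. The generalizability
#' error per repeat is the mean out-of-sample excess
#' `GE = ((e12 - e11) + (e21 - e22)) / 2` (`form = "difference"`, the
#' default: it penalizes factor counts that fit the training half but not
#' the held-out half, giving the interior minimum used for rank
#' selection), or the plain mean out-of-sample error `(e12 + e21) / 2`
#' (`form = "mean"`, which is non-increasing in `k` because a larger
#' non-negative cone always reconstructs held-out rows at least as well).
#'
#' @param x Non-negative matrix (patients x regions).
#' @param k Candidate factor count.
#' @param n_repeats Number of random splits.
#' @param seed Integer seed; repeat `i` uses a child seed so the same
#'   splits are reused across candidate `k` values in [select_k()].
#' @param form GE definition, `"difference"` (default) or `"mean"`.
#' @param n_restarts,max_iter,tol NMF fitting controls.
#' @return Tibble with one row per repeat: `k`, `repeat_id`, `e11`, `e12`,
#'   `e21`, `e22`, `ge`.
#' @export
generalization_error <- function(x, k, n_repeats = 20L, seed = 1,
                                 form = c("difference", "mean"),
                                 n_restarts = 2L, max_iter = 300L,
                                 tol = 1e-6) {
  form <- match.arg(form)
  xm <- as_dev_matrix(x)
  n <- nrow(xm)
  if (n < 8L) abort("need at least 8 rows so both halves support fitting")
  if (k >= min(floor(n / 2), ncol(xm))) {
    abort(sprintf("k = %d infeasible for half-splits of %d rows", k, n))
  }
  n_repeats <- check_count(n_repeats, "n_repeats")

  rows <- purrr::map(seq_len(n_repeats), function(rep_i) {
    idx1 <- with_seed(child_seed(seed, paste0("ge_split_", rep_i)),
                      sample(n, floor(n / 2)))
    x1 <- xm[idx1, , drop = FALSE]
    x2 <- xm[-idx1, , drop = FALSE]
    m1 <- fit_nmf(x1, k, seed = child_seed(seed, paste0("ge_fit1_", rep_i)),
                  n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    m2 <- fit_nmf(x2, k, seed = child_seed(seed, paste0("ge_fit2_", rep_i)),
                  n_restarts = n_restarts, max_iter = max_iter, tol = tol)
    e11 <- mean(abs(m1$residual))
    e22 <- mean(abs(m2$residual))
    e12 <- mean(abs(x2 - project_weights(m1, x2) %*% m1$F))
    e21 <- mean(abs(x1 - project_weights(m2, x1) %*% m2$F))
    ge <- if (form == "mean") (e12 + e21) / 2 else
      ((e12 - e11) + (e21 - e22)) / 2
    tibble(k = k, repeat_id = rep_i,
           e11 = e11, e12 = e12, e21 = e21, e22 = e22, ge = ge)
  })
  dplyr::bind_rows(rows)
}

#' Select the factor count by minimum generalizability error
#'
#' Runs [generalization_error()] over a candidate range (the same random
#' splits are reused for every candidate) and returns the count with the
#' lowest repeat-mean GE; ties are broken toward the smaller count.
#'
#' @inheritParams generalization_error
#' @param k_range Candidate factor counts (default 2:10).
#' @return List with `k_best` and `ge` (a `ge_curve` tibble of all
#'   repeats; attribute `k_best`).
#' @export
select_k <- function(x, k_range = 2:10, n_repeats = 20L, seed = 1,
                     form = c("difference", "mean"), n_restarts = 2L,
                     max_iter = 300L, tol = 1e-6) {
  if (length(k_range) == 0L) abort("`k_range` must not be empty")
  form <- match.arg(form)
  curve <- dplyr::bind_rows(lapply(k_range, function(k) {
    generalization_error(x, k, n_repeats = n_repeats, seed = seed,
                         form = form, n_restarts = n_restarts,
                         max_iter = max_iter, tol = tol)
  }))
  means <- curve |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(ge = mean(.data$ge), .groups = "drop") |>
    dplyr::arrange(.data$k)
  k_best <- means$k[which.min(means$ge)]
  class(curve) <- c("ge_curve", class(curve))
  attr(curve, "k_best") <- k_best
  attr(curve, "form") <- form
  list(k_best = k_best, ge = curve)
}

#' Match two factor sets by the Hungarian algorithm
#'
#' Pairs rows of two loading matrices to maximize the total spatial Pearson
#' correlation (linear sum assignment). Per-pair correlations get analytic
#' two-sided p-values with Benjamini-Hochberg correction.
#'
#' @param f_a,f_b Loading matrices (factors x regions) or `factor_model`s.
#'   If the factor counts differ, the smaller set is matched and the
#'   unmatched factors of the larger set are reported.
#' @return A `factor_match` tibble: `factor_a`, `factor_b`, `r`, `p`,
#'   `p_fdr`; attribute `unmatched` lists unmatched factors.
#' @export
match_factors <- function(f_a, f_b) {
  if (inherits(f_a, "factor_model")) f_a <- f_a$F
  if (inherits(f_b, "factor_model")) f_b <- f_b$F
  if (ncol(f_a) != ncol(f_b)) abort("factor sets have different region counts")
  if (ncol(f_a) < 3L) abort("need at least 3 regions to correlate factors")
  swap <- nrow(f_a) > nrow(f_b)
  a <- if (swap) f_b else f_a
  b <- if (swap) f_a else f_b
  cmat <- cor(t(a), t(b))            # nrow(a) x nrow(b), nrow(a) <= nrow(b)
  pairing <- clue::solve_LSAP(cmat + 1, maximum = TRUE)
  ia <- seq_len(nrow(a))
  ib <- as.integer(pairing)
  r <- cmat[cbind(ia, ib)]
  n <- ncol(a)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  names_a <- rownames(a) %||% paste0("factor_", ia)
  names_b <- rownames(b) %||% paste0("factor_", seq_len(nrow(b)))
  out <- tibble(
    factor_a = if (swap) names_b[ib] else names_a,
    factor_b = if (swap) names_a else names_b[ib],
    r = as.numeric(r), p = p, p_fdr = bh_adjust(p)
  )
  class(out) <- c("factor_match", class(out))
  attr(out, "unmatched") <- setdiff(names_b, names_b[ib])
  out
}

#' Per-patient variance in deviations explained by the factors
#'
#' For each patient, an ordinary least-squares regression of the signed
#' deviation vector (one observation per region) on the signed factor maps
#' (positive-bank loadings entered as-is, negative-bank loadings with
#' negative sign, plus an intercept); the adjusted R-squared summarizes how
#' much of the patient's deviation profile the shared factors capture.
#'
#' @param z Deviation matrix (signed).
#' @param f_pos,f_neg Positive / negative bank `factor_model`s or loading
#'   matrices (either may be NULL if that bank is absent).
#' @return Tibble with `subject_id` and `adj_r2`; attributes `mean` and
#'   `sd` give the cohort summary.
#' @export
variance_explained <- function(z, f_pos, f_neg = NULL) {
  zm <- as_dev_matrix(z)
  fp <- if (inherits(f_pos, "factor_model")) f_pos$F else f_pos
  fn <- if (inherits(f_neg, "factor_model")) f_neg$F else f_neg
  maps <- rbind(fp, if (!is.null(fn)) -fn)
  if (ncol(maps) != ncol(zm)) abort("factor banks and Z differ in regions")
  k <- nrow(maps)
  r <- ncol(zm)
  if (r <= k + 1L) abort("need more regions than factors + 1 for adjusted R^2")
  X <- cbind(1, t(maps))
  qrX <- qr(X)
  y <- t(zm)                                  # regions x patients
  res <- y - qr.fitted(qrX, y)
  ss_res <- colSums(res^2)
  ss_tot <- colSums(scale(y, scale = FALSE)^2)
  r2 <- 1 - ss_res / ss_tot
  adj <- 1 - (1 - r2) * (r - 1) / (r - k - 1)
  out <- tibble(
    subject_id = rownames(zm) %||% as.character(seq_len(nrow(zm))),
    adj_r2 = as.numeric(adj)
  )
  attr(out, "mean") <- mean(adj)
  attr(out, "sd") <- sd(adj)
  out
}

#' Permutation null for the variance explained by factors
#'
#' Each permutation shuffles the region entries independently within every
#' patient row, re-runs the signed split and NMF at the given bank sizes,
#' and records the mean adjusted R-squared; the p-value uses the
#' add-one-smoothed counting formula `p = (1 + #(null >= observed)) /
#' (1 + n_perm)`.
#'
#' @param z Deviation matrix.
#' @param k_pos,k_neg Bank sizes.
#' @param n_perm Number of permutations (>= 1; values below 100 give a
#'   coarse p floor and trigger a warning).
#' @param seed Integer seed.
#' @param n_restarts NMF restarts per refit (default 1 for speed).
#' @return List with `p`, `observed` (mean adjusted R-squared), and the
#'   `null` vector.
#' @export
variance_explained_null <- function(z, k_pos, k_neg, n_perm = 200L, seed = 1,
                                    n_restarts = 1L) {
  n_perm <- check_count(n_perm, "n_perm")
  if (n_perm < 100L) warn("n_perm < 100 gives a coarse permutation p floor")
  zm <- as_dev_matrix(z)

  mean_r2 <- function(m) {
    sp <- split_signed(m)
    fp <- fit_nmf(sp$pos, k_pos, seed = seed, n_restarts = n_restarts)
    fn <- fit_nmf(sp$neg, k_neg, seed = seed, n_restarts = n_restarts)
    attr(variance_explained(m, fp, fn), "mean")
  }

  observed <- mean_r2(zm)
  null <- with_seed(child_seed(seed, "ve_null"), {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- t(apply(zm, 1L, sample))
      mean_r2(shuffled)
    }, numeric(1))
  })
  list(p = (1 + sum(null >= observed)) / (1 + n_perm),
       observed = observed, null = null)
}
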