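# Shared helpers: cohort-table column conventions, validation, seeding.

# Reserved non-region columns recognised in cohort tables.
.covariate_cols <- c(
  "subject_id", "age", "sex", "site", "group", "fd",
  "hamd", "duration", "onset_age", "episode", "medicated", "subtype"
)

#' Region columns of a cohort table
#'
#' Cohort tables are tibbles with one row per subject: demographic /
#' clinical columns plus one numeric column per brain region. Region
#' columns are all columns whose name starts with `"roi_"`.
#'
#' @param x A cohort table (data frame).
#' @return Character vector of region column names, in table order.
#' @export
region_cols <- function(x) {
  grep("^roi_", names(x), value = TRUE)
}

# Extract the subjects x regions numeric matrix from a cohort table.
region_matrix <- function(x, regions = region_cols(x)) {
  if (length(regions) == 0L) {
    abort("no region columns (named 'roi_*') found in table")
  }
  m <- as.matrix(as.data.frame(x)[, regions, drop = FALSE])
  storage.mode(m) <- "double"
  if (!is.null(x[["subject_id"]])) rownames(m) <- as.character(x[["subject_id"]])
  m
}

# Replace region columns of a cohort table with the columns of `m`.
set_region_matrix <- function(x, m) {
  regions <- region_cols(x)
  stopifnot(ncol(m) == length(regions))
  x[regions] <- as.data.frame(m)
  x
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    abort(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

# Derive a reproducible child seed from a root seed and a stage label.
# Kept below 2^31 so it is always a valid R integer.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

roi_labels <- function(n_regions) {
  sprintf("roi_%03d", seq_len(n_regions))
}

# Benjamini-Hochberg adjustment; thin wrapper kept for a single call site name.
bh_adjust <- function(p) p.adjust(p, method = "BH")

# Pearson correlation with analytic two-sided p and Fisher-z CI.
cor_test_vec <- function(x, y, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("need at least 3 complete observations for a correlation")
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  z <- atanh(min(max(r, -1 + 1e-15), 1 - 1e-15))
  hw <- qnorm(1 - (1 - conf) / 2) / sqrt(n - 3)
  list(r = r, p = p, conf_low = tanh(z - hw), conf_high = tanh(z + hw), n = n)
}
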