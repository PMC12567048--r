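#' Winsorize a numeric vector at symmetric quantiles
#'
#' Clamps extreme values to quantile bounds to limit outlier influence.
#' With `per_tail = FALSE` (default) `fraction` is the total trimmed mass,
#' split symmetrically: values below the `fraction/2` quantile are raised to
#' it and values above the `1 - fraction/2` quantile lowered to it. With
#' `per_tail = TRUE`, `fraction` is clamped in each tail. Quantiles use
#' linear (type-7) interpolation. The defaults used for NTRK genes are a
#' total mass of 0.15 for NTRK1/NTRK3 and 0.30 for NTRK2.
#'
#' @param x Numeric vector with at least 3 finite values (NAs pass through).
#' @param fraction Trimmed mass in `[0, 0.5)`.
#' @param per_tail If `TRUE`, apply `fraction` per tail rather than in total.
#'
#' @return Numeric vector, same length and order as `x`.
#' @export
#'
#' @examples
#' winsorize(1:10, fraction = 0.2)
winsorize <- function(x, fraction = 0.15, per_tail = FALSE) {
  stopifnot(is.numeric(x), length(fraction) == 1, fraction >= 0, fraction < 0.5)
  finite <- is.finite(x)
  if (sum(finite) < 3) abort("winsorize needs at least 3 finite values")
  if (fraction == 0) return(x)
  tail_frac <- if (per_tail) fraction else fraction / 2
  lo <- quantile(x[finite], tail_frac, type = 7, names = FALSE)
  hi <- quantile(x[finite], 1 - tail_frac, type = 7, names = FALSE)
  out <- x
  out[finite & x < lo] <- lo
  out[finite & x > hi] <- hi
  out
}

#' Zero-to-one (min-max) normalization
#'
#' Affine map sending the minimum to 0 and the maximum to 1. A constant
#' vector maps to all 0.5 by convention (the midpoint carries no ordering
#' information either way).
#'
#' @param x Numeric vector with at least 2 finite values (NAs pass through).
#'
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  stopifnot(is.numeric(x))
  finite <- is.finite(x)
  if (sum(finite) < 2) abort("minmax_normalize needs at least 2 finite values")
  rng <- range(x[finite])
  out <- x
  if (rng[1] == rng[2]) {
    out[finite] <- 0.5
  } else {
    out[finite] <- (x[finite] - rng[1]) / (rng[2] - rng[1])
  }
  out
}

#' Median dichotomization into high/low labels
#'
#' Labels a value "high" iff it exceeds the cutoff (default: the median of
#' `x`). Ties at the cutoff are labelled "low", so an all-constant vector is
#' all "low" and for an odd number of distinct values exactly
#' `floor(n / 2)` are "high".
#'
#' @param x Numeric vector.
#' @param cutoff Dichotomization cutoff; defaults to `median(x, na.rm=TRUE)`.
#'
#' @return Factor with levels `low`, `high` (NA preserved).
#' @export
#'
#' @examples
#' dichotomize(c(0.1, 0.4, 0.6, 0.9))
dichotomize <- function(x, cutoff = NULL) {
  stopifnot(is.numeric(x))
  cutoff <- cutoff %||% median(x, na.rm = TRUE)
  factor(ifelse(x > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Rank-based Gaussian (two-step) normalization
#'
#' The two-step transform used when continuous data cannot be normalised
#' directly: values are converted to fractional mid-ranks
#' `(rank - 0.5) / n` and then mapped through the inverse standard-normal
#' quantile function. The output is monotone in the input and tied inputs
#' receive equal outputs.
#'
#' @param x Numeric vector with at least 3 finite values (NAs pass through).
#'
#' @return Numeric vector of normal scores.
#' @export
normalize_to_gaussian <- function(x) {
  stopifnot(is.numeric(x))
  finite <- is.finite(x)
  n <- sum(finite)
  if (n < 3) abort("normalize_to_gaussian needs at least 3 finite values")
  out <- rep(NA_real_, length(x))
  r <- rank(x[finite], ties.method = "average")
  out[finite] <- qnorm((r - 0.5) / n)
  out
}

#' Pool two cohorts into a single analysis table
#'
#' Row-binds two per-sample tables (already winsorized and normalized
#' within cohort) and adds/retains a cohort indicator column for use as a
#' regression covariate. Duplicate sample identifiers across cohorts are an
#' error.
#'
#' @param cohort_a,cohort_b Per-sample data frames sharing a sample id
#'   column.
#' @param labels Length-2 character vector of cohort labels.
#' @param id_col Name of the sample identifier column (default "sample").
#' @param cohort_col Name of the cohort indicator column to create
#'   (default "cohort").
#'
#' @return A tibble with all rows of both cohorts and the cohort column.
#'   Columns present in only one cohort are kept and filled with NA.
#' @export
#' @seealso [cohort_bias()] for the pooled-cohort bias report.
pool_cohorts <- function(cohort_a, cohort_b, labels = c("A", "B"),
                         id_col = "sample", cohort_col = "cohort") {
  stopifnot(is.data.frame(cohort_a), is.data.frame(cohort_b), length(labels) == 2)
  if (!id_col %in% names(cohort_a) || !id_col %in% names(cohort_b)) {
    abort(paste0("Both cohorts must carry the id column '", id_col, "'"))
  }
  dup <- intersect(cohort_a[[id_col]], cohort_b[[id_col]])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample ids across cohorts: ",
                 paste(utils::head(dup, 5), collapse = ", ")))
  }
  a <- dplyr::mutate(tibble::as_tibble(cohort_a), !!cohort_col := labels[[1]])
  b <- dplyr::mutate(tibble::as_tibble(cohort_b), !!cohort_col := labels[[2]])
  dplyr::bind_rows(a, b)
}

#' Cohort-bias report for a pooled table
#'
#' Tests each requested variable for a difference between cohorts: one-way
#' ANOVA for numeric variables and the chi-square test for categorical
#' ones. Used after pooling to decide which downstream analyses need the
#' cohort covariate.
#'
#' @param pooled Pooled per-sample tibble (see [pool_cohorts()]).
#' @param variables Character vector of column names to test; defaults to
#'   every column other than the id and cohort columns.
#' @param cohort_col Name of the cohort indicator column.
#' @param id_col Name of the sample id column.
#'
#' @return A tibble with one row per variable: `variable`, `test`
#'   (`"anova"` or `"chi_square"`), `statistic`, `p_value`, `n_used`.
#' @export
cohort_bias <- function(pooled, variables = NULL, cohort_col = "cohort",
                        id_col = "sample") {
  stopifnot(is.data.frame(pooled), cohort_col %in% names(pooled))
  variables <- variables %||% setdiff(names(pooled), c(id_col, cohort_col))
  purrr::map_dfr(variables, function(v) {
    x <- pooled[[v]]
    g <- pooled[[cohort_col]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; g <- g[keep]
    if (is.numeric(x)) {
      fit <- summary(aov(x ~ factor(g)))[[1]]
      tibble::tibble(
        variable = v, test = "anova",
        statistic = fit[["F value"]][1], p_value = fit[["Pr(>F)"]][1],
        n_used = length(x)
      )
    } else {
      tab <- table(factor(x), factor(g))
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (nrow(tab) < 2 || ncol(tab) < 2) {
        return(tibble::tibble(variable = v, test = "chi_square",
                              statistic = NA_real_, p_value = NA_real_,
                              n_used = length(x)))
      }
      ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
      tibble::tibble(
        variable = v, test = "chi_square",
        statistic = unname(ct$statistic), p_value = ct$p.value,
        n_used = length(x)
      )
    }
  })
}
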