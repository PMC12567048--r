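#' Spearman rank correlation with tie correction
#'
#' Computes Spearman's rho as the Pearson correlation of mid-ranks (the
#' tie-corrected definition). The p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom;
#' for `n < 10` with no ties, an exact permutation p-value is computed by
#' full enumeration instead.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the paired numeric variables.
#'
#' @return One-row tibble: `rho`, `p_value`, `n_used`, `method`. A constant
#'   vector yields `rho = NA` (undefined) with a warning-free missing
#'   result.
#' @export
#'
#' @examples
#' d <- data.frame(a = 1:20, b = (1:20)^2)
#' spearman_test(d, a, b)
spearman_test <- function(data, x, y) {
  stopifnot(is.data.frame(data))
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 4) abort("spearman_test needs at least 4 complete pairs")
  if (sd(xv) == 0 || sd(yv) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_,
                          n_used = n, method = "undefined (constant input)"))
  }
  rx <- rank(xv); ry <- rank(yv)
  rho <- cor(rx, ry)
  has_ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  if (n < 10 && !has_ties) {
    perms <- permutations_of(n)
    null_rho <- apply(perms, 1, function(p) cor(rank(xv), rank(yv[p])))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  tibble::tibble(rho = rho, p_value = min(p, 1), n_used = n, method = method)
}

# All permutations of 1..n as a matrix (n! rows); n <= 9 by construction.
permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Chi-square test of association between two categorical variables
#'
#' Pearson chi-square on the cross-tabulation after dropping empty margins,
#' without continuity correction. Cells with expected count below 5 are
#' flagged rather than silently tolerated.
#'
#' @param data A data frame.
#' @param x,y Column names (tidy-eval) of the categorical variables, or
#'   pass a pre-built contingency matrix via `table`.
#' @param table Optional r x c matrix of non-negative integer counts; when
#'   given, `data`/`x`/`y` are ignored.
#'
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_used`,
#'   `min_expected`, `low_expected_cells`. The expected-count matrix is
#'   attached as attribute `"expected"`.
#' @export
chisq_assoc <- function(data = NULL, x = NULL, y = NULL, table = NULL) {
  if (is.null(table)) {
    stopifnot(is.data.frame(data))
    xv <- dplyr::pull(data, {{ x }})
    yv <- dplyr::pull(data, {{ y }})
    keep <- !is.na(xv) & !is.na(yv)
    tab <- base::table(factor(xv[keep]), factor(yv[keep]))
  } else {
    if (any(table < 0) || any(table != round(table))) {
      abort("contingency table must hold non-negative integer counts")
    }
    tab <- as.table(table)
  }
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("degenerate contingency table: need >= 2 non-empty rows and columns")
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- tibble::tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n_used = sum(tab),
    min_expected = min(ct$expected),
    low_expected_cells = sum(ct$expected < 5)
  )
  attr(out, "expected") <- ct$expected
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate, capped
#' at 1, returned in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#'
#' @return Numeric vector of adjusted values, same length and order.
#' @export
#'
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("p must be numeric")
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Group-difference test for a continuous variable over discrete groups
#'
#' `method = "anova"` performs one-way ANOVA on group means (for normalised
#' continuous variables); `method = "median_test"` performs the K-sample
#' median test — a chi-square test on counts above/at-or-below the pooled
#' median — for variables that cannot be normalised.
#'
#' @param data A data frame.
#' @param value,group Column names (tidy-eval) of the continuous variable
#'   and the grouping labels.
#' @param method `"anova"` or `"median_test"`.
#'
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `n_used`.
#' @export
group_difference <- function(data, value, group, method = c("anova", "median_test")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(data))
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  keep <- is.finite(v) & !is.na(g)
  v <- v[keep]; g <- droplevels(g[keep])
  if (nlevels(g) < 2) abort("group_difference needs at least 2 groups")
  if (method == "anova") {
    if (any(base::table(g) < 2)) abort("anova needs >= 2 observations per group")
    fit <- summary(aov(v ~ g))[[1]]
    tibble::tibble(
      test = "anova",
      statistic = fit[["F value"]][1],
      df = fit[["Df"]][1],
      p_value = fit[["Pr(>F)"]][1],
      n_used = length(v)
    )
  } else {
    m <- median(v)
    above <- v > m
    tab <- base::table(above, g)
    if (nrow(tab) < 2) {
      # all values on one side of the pooled median (massive ties): no signal
      return(tibble::tibble(test = "median_test", statistic = 0,
                            df = nlevels(g) - 1, p_value = 1, n_used = length(v)))
    }
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    tibble::tibble(
      test = "median_test",
      statistic = unname(ct$statistic),
      df = unname(ct$parameter),
      p_value = ct$p.value,
      n_used = length(v)
    )
  }
}

#' Multiple linear regression with collinearity reporting
#'
#' Ordinary least squares of a continuous outcome on a set of terms (the
#' deregulation model: expression on methylation, copy number, fusion score
#' and cohort indicator). Collinear columns are detected, dropped and
#' reported; a rank-deficient design after dropping is an error.
#'
#' @param data A data frame holding outcome and terms.
#' @param formula Model formula, e.g. `expr ~ methylation + cna + cohort`.
#'
#' @return An object of class `"deregulation_fit"`; see [tidy()] for
#'   per-term coefficients (B) and p-values, [glance()] for adjusted R2,
#'   the overall F statistic and model p-value.
#' @export
#'
#' @examples
#' d <- data.frame(y = rnorm(50), x = rnorm(50))
#' fit <- fit_linear(d, y ~ x)
#' tidy(fit)
#' glance(fit)
fit_linear <- function(data, formula) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  mm <- model.matrix(formula, mf)
  if (nrow(mm) <= ncol(mm) + 1) abort("fit_linear needs n > number of terms + 1")
  qr_mm <- qr(mm)
  dropped <- character(0)
  if (qr_mm$rank < ncol(mm)) {
    keep_idx <- qr_mm$pivot[seq_len(qr_mm$rank)]
    dropped <- colnames(mm)[-keep_idx]
    if (!"(Intercept)" %in% colnames(mm)[keep_idx]) {
      abort("design matrix rank-deficient beyond repair (intercept collinear)")
    }
    warn(paste0("Dropped collinear term(s): ", paste(dropped, collapse = ", ")))
  }
  fit <- lm(formula, data = data, na.action = stats::na.omit)
  structure(
    list(fit = fit, dropped = dropped, formula = formula,
         n_used = length(fit$residuals)),
    class = "deregulation_fit"
  )
}

#' Binary logistic regression with separation detection
#'
#' Maximum-likelihood logistic fit with Wald p-values, used to test whether
#' an association (for instance gene-high status vs a clinical feature)
#' survives adjustment for the cohort indicator. Complete or
#' quasi-complete separation is detected and flagged on the returned
#' object.
#'
#' @param data A data frame.
#' @param formula Model formula with a two-level outcome (logical, 0/1, or
#'   a two-level factor such as the low/high labels from [dichotomize()]).
#'
#' @return An object of class `"deregulation_fit"` (family binomial) with
#'   an added `separation` flag; [tidy()] and [glance()] apply.
#' @export
fit_logistic <- function(data, formula) {
  stopifnot(is.data.frame(data), inherits(formula, "formula"))
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.omit)
  yv <- stats::model.response(mf)
  if (is.factor(yv)) yv <- as.integer(yv) - 1L
  if (is.logical(yv)) yv <- as.integer(yv)
  if (length(unique(yv)) < 2) abort("fit_logistic: outcome has a single class")
  if (nrow(mf) <= ncol(mf)) abort("fit_logistic needs n > number of terms")
  separation <- FALSE
  withCallingHandlers(
    fit <- glm(formula, data = data, family = binomial(), na.action = stats::na.omit),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!separation) {
    pr <- stats::fitted(fit)
    separation <- any(pr < 1e-10 | pr > 1 - 1e-10)
  }
  if (separation) {
    warn("Possible (quasi-)separation detected; Wald p-values unreliable")
  }
  structure(
    list(fit = fit, dropped = character(0), formula = formula,
         n_used = length(fit$residuals), separation = separation),
    class = "deregulation_fit"
  )
}

#' @export
print.deregulation_fit <- function(x, ...) {
  kind <- if (inherits(x$fit, "glm")) "logistic" else "linear"
  cat("<deregulation_fit> ", kind, " model, n = ", x$n_used, "\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @rdname fit_linear
#' @param x A `deregulation_fit` object.
#' @param ... Unused.
#' @method tidy deregulation_fit
#' @export
tidy.deregulation_fit <- function(x, ...) {
  sm <- summary(x$fit)
  co <- sm$coefficients
  pcol <- if (inherits(x$fit, "glm")) "Pr(>|z|)" else "Pr(>|t|)"
  tibble::tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    statistic = unname(co[, 3]),
    p_value = unname(co[, pcol])
  )
}

#' @rdname fit_linear
#' @method glance deregulation_fit
#' @export
glance.deregulation_fit <- function(x, ...) {
  if (inherits(x$fit, "glm")) {
    sm <- summary(x$fit)
    return(tibble::tibble(
      null_deviance = sm$null.deviance, deviance = sm$deviance,
      aic = sm$aic, n_used = x$n_used,
      separation = isTRUE(x$separation)
    ))
  }
  sm <- summary(x$fit)
  fstat <- sm$fstatistic
  tibble::tibble(
    adjusted_r2 = sm$adj.r.squared,
    r2 = sm$r.squared,
    f_statistic = unname(fstat[1]),
    model_p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n_used = x$n_used,
    dropped_terms = paste(x$dropped, collapse = ",")
  )
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Standard 1-df log-rank comparison of two survival distributions with
#' Kaplan-Meier step curves, as used for overall and disease-free survival
#' between expression-high and expression-low subsets.
#'
#' @param data A data frame.
#' @param time,event,group Column names (tidy-eval): positive follow-up
#'   times, event indicators (logical or 0/1; 1 = event), and a two-level
#'   grouping.
#'
#' @return An object of class `"km_logrank"` with elements `chi_square`,
#'   `p_value`, `df`, `curves` (tibble of per-group step curves) and
#'   `n_used`; [glance()] returns the test, [tidy()] the curves, and
#'   [autoplot()] draws them.
#' @export
km_logrank <- function(data, time, event, group) {
  stopifnot(is.data.frame(data))
  tv <- dplyr::pull(data, {{ time }})
  ev <- dplyr::pull(data, {{ event }})
  gv <- factor(dplyr::pull(data, {{ group }}))
  keep <- is.finite(tv) & !is.na(ev) & !is.na(gv)
  tv <- tv[keep]; ev <- as.integer(as.logical(ev[keep])); gv <- droplevels(gv[keep])
  if (any(tv <= 0)) abort("survival times must be positive")
  if (nlevels(gv) != 2) abort("km_logrank compares exactly two groups")
  if (sum(ev) == 0) abort("no events observed; log-rank undefined")
  sd_fit <- survival::survdiff(survival::Surv(tv, ev) ~ gv)
  sf <- survival::survfit(survival::Surv(tv, ev) ~ gv)
  strata_labels <- sub("^gv=", "", rep(names(sf$strata), sf$strata))
  curves <- tibble::tibble(
    group = strata_labels,
    time = sf$time,
    n_risk = sf$n.risk,
    n_event = sf$n.event,
    survival = sf$surv
  )
  structure(
    list(
      chi_square = unname(sd_fit$chisq),
      df = length(sd_fit$n) - 1,
      p_value = pchisq(unname(sd_fit$chisq), df = length(sd_fit$n) - 1,
                       lower.tail = FALSE),
      observed = unname(sd_fit$obs), expected = unname(sd_fit$exp),
      curves = curves, n_used = length(tv)
    ),
    class = "km_logrank"
  )
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("<km_logrank> X^2 = ", format(x$chi_square, digits = 4),
      " (", x$df, " df), p = ", format(x$p_value, digits = 3),
      ", n = ", x$n_used, "\n", sep = "")
  invisible(x)
}

#' @rdname km_logrank
#' @param x A `km_logrank` object.
#' @param ... Unused.
#' @method tidy km_logrank
#' @export
tidy.km_logrank <- function(x, ...) x$curves

#' @rdname km_logrank
#' @method glance km_logrank
#' @export
glance.km_logrank <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df,
                 p_value = x$p_value, n_used = x$n_used)
}

#' @rdname km_logrank
#' @param object A `km_logrank` object.
#' @method autoplot km_logrank
#' @export
autoplot.km_logrank <- function(object, ...) {
  anchor <- dplyr::distinct(
    dplyr::mutate(object$curves, time = 0, survival = 1, n_event = 0),
    .data$group, .keep_all = TRUE
  )
  dat <- dplyr::bind_rows(anchor, object$curves)
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$survival,
                                    colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Time", y = "Survival probability",
      subtitle = sprintf("Log-rank X^2 = %.3f, p = %.3g",
                         object$chi_square, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Clinicopathological association battery with FDR control
#'
#' Runs the chi-square association of one dichotomized marker (for example
#' `ntrk1_high` or `nfs2_high`) against each requested clinical variable,
#' median-dichotomizing continuous variables first, and applies
#' Benjamini-Hochberg correction within the block. Missing clinical values
#' are handled pairwise-complete, with the per-test denominator reported.
#'
#' @param data Per-sample tibble.
#' @param marker Name (string) of the two-level marker column.
#' @param variables Character vector of clinical variable columns.
#' @param continuous_as `"dichotomized"` (default: median split via
#'   [dichotomize()]) or `"anova"` (one-way ANOVA of the continuous value
#'   over marker levels).
#'
#' @return Tibble with one row per variable: `marker`, `variable`, `test`,
#'   `statistic`, `p_value`, `fdr`, `n_used`.
#' @export
association_block <- function(data, marker, variables,
                              continuous_as = c("dichotomized", "anova")) {
  continuous_as <- match.arg(continuous_as)
  stopifnot(is.data.frame(data), marker %in% names(data),
            all(variables %in% names(data)))
  res <- purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    m <- data[[marker]]
    if (is.numeric(x) && continuous_as == "anova") {
      keep <- is.finite(x) & !is.na(m)
      d <- tibble::tibble(value = x[keep], group = m[keep])
      gd <- group_difference(d, value, group, method = "anova")
      return(tibble::tibble(marker = marker, variable = v, test = "anova",
                            statistic = gd$statistic, p_value = gd$p_value,
                            n_used = gd$n_used))
    }
    if (is.numeric(x)) x <- dichotomize(x)
    keep <- !is.na(x) & !is.na(m)
    tab <- base::table(factor(x[keep]), factor(m[keep]))
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2 || ncol(tab) < 2) {
      return(tibble::tibble(marker = marker, variable = v, test = "chi_square",
                            statistic = NA_real_, p_value = NA_real_,
                            n_used = sum(keep)))
    }
    cs <- chisq_assoc(table = unclass(tab))
    tibble::tibble(marker = marker, variable = v, test = "chi_square",
                   statistic = cs$statistic, p_value = cs$p_value,
                   n_used = cs$n_used)
  })
  dplyr::mutate(res, fdr = bh_adjust(.data$p_value), .after = "p_value")
}
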