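## Phylogenetically independent contrasts and the correlation/regression
## suite used to relate male m to female f across populations: PIC with
## polytomy-adjusted degrees of freedom, through-origin correlation of
## positivized contrasts, OLS and reduced-major-axis regression, rank
## correlation, and alpha-threshold stepwise selection.

#' Standardized independent contrasts of one trait
#'
#' Felsenstein's algorithm: at each internal node the contrast is the
#' difference between the daughter values divided by the square root of
#' the summed (extended) branch lengths. Polytomies are resolved into
#' zero-length ladders (deterministically), and every zero-length internal
#' branch is counted so downstream tests can reduce their degrees of
#' freedom accordingly; for standardization only, zero branch lengths are
#' inflated to `1e-8 * tree height`.
#'
#' @param tree a rooted `phylo`; branch lengths must be >= 0.
#' @param traits named numeric vector (names = tip labels), or a
#'   `trait_table`-style data frame column selected via `trait`.
#' @param trait column name when `traits` is a data frame with a
#'   `population` column.
#' @return object of class `contrast_set`: `contrasts` (named by node id),
#'   `node_ids`, `n_zero_branches`, `positivized = FALSE`.
#' @export
independent_contrasts <- function(tree, traits, trait = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(traits)) {
    if (is.null(trait)) stop_invalid("specify which trait column to use")
    traits <- setNames(traits[[trait]], traits$population)
  }
  if (is.null(names(traits)) ||
      !all(tree$tip.label %in% names(traits)) ||
      any(is.na(traits[tree$tip.label])))
    stop_invalid("every tip needs a non-missing trait value")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop_invalid("tree must have non-negative branch lengths")
  if (!ape::is.rooted(tree)) stop_invalid("tree must be rooted")
  x <- as.numeric(traits[tree$tip.label])
  names(x) <- tree$tip.label
  n_edge_before <- nrow(tree$edge)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  ht <- max(ape::node.depth.edgelength(tree))
  if (ht <= 0) stop_invalid("tree has zero height")
  internal <- tree$edge[, 2] > length(tree$tip.label)
  n_zero <- sum(internal & tree$edge.length <= 1e-12)
  eps <- 1e-8 * ht
  tree$edge.length[tree$edge.length <= 1e-12] <- eps
  pics <- ape::pic(x, tree, scaled = TRUE, var.contrasts = FALSE)
  structure(list(contrasts = pics,
                 node_ids = as.integer(names(pics)),
                 n_zero_branches = n_zero,
                 n_edges_added = nrow(tree$edge) - n_edge_before,
                 positivized = FALSE),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat(sprintf("contrast_set: %d contrasts, %d zero-length internal branch(es)%s\n",
              length(x$contrasts), x$n_zero_branches,
              if (x$positivized) ", positivized" else ""))
  invisible(x)
}

#' Positivize a pair of contrast sets
#'
#' Contrast signs are arbitrary, so each pair `(x_i, y_i)` is multiplied
#' by `sign(x_i)` (pairs with `x_i = 0` are left unchanged); afterwards
#' all x contrasts are non-negative. Through-origin correlation is
#' unaffected.
#'
#' @param cs_x,cs_y `contrast_set`s of the two traits on the same tree
#'   (same node order).
#' @return object of class `paired_contrasts` with `x`, `y`,
#'   `n_zero_branches`, `positivized = TRUE`.
#' @export
positivize <- function(cs_x, cs_y) {
  stopifnot(inherits(cs_x, "contrast_set"), inherits(cs_y, "contrast_set"))
  if (length(cs_x$contrasts) != length(cs_y$contrasts) ||
      !identical(cs_x$node_ids, cs_y$node_ids))
    stop_invalid("contrast sets must come from the same tree (same nodes)")
  s <- sign(cs_x$contrasts)
  s[s == 0] <- 1
  structure(list(x = unname(cs_x$contrasts * s),
                 y = unname(cs_y$contrasts * s),
                 node_ids = cs_x$node_ids,
                 n_zero_branches = max(cs_x$n_zero_branches,
                                       cs_y$n_zero_branches),
                 positivized = TRUE),
            class = "paired_contrasts")
}

new_regression_result <- function(method, slope, intercept, correlation,
                                  t = NA_real_, df = NA_real_,
                                  p = NA_real_, n = NA_integer_) {
  structure(list(method = method, slope = slope, intercept = intercept,
                 correlation = correlation, t = t, df = df,
                 p_value = p, n = n),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  int <- if (is.na(x$intercept)) "" else sprintf("%.4g + ", x$intercept)
  cat(sprintf("%s: y = %s%.4g x; r = %.4f, t = %.3f, df = %g, p = %.4g (n = %d)\n",
              x$method, int, x$slope, x$correlation, x$t, x$df, x$p_value,
              x$n))
  invisible(x)
}

#' Through-origin correlation of paired contrasts
#'
#' `r = sum(x y) / sqrt(sum(x^2) sum(y^2))`, tested with
#' `t = r sqrt(df) / sqrt(1 - r^2)` where
#' `df = (n_contrasts - 1) - n_zero_branches`: one df is lost to the
#' through-origin constraint and one per zero-length internal branch
#' introduced by polytomy resolution. Two-sided p by default; the
#' coevolution hypothesis (m tracks f) is directional, so a one-sided
#' option is provided.
#'
#' @param pairs a [positivize()]d `paired_contrasts` (or a list with
#'   numeric `x`, `y` and optional `n_zero_branches`).
#' @param one_sided logical; if `TRUE`, the upper-tail p for positive
#'   association.
#' @return a `regression_result` (method `"ols-origin"`) whose slope is
#'   the through-origin OLS slope of y on x.
#' @export
pic_correlation <- function(pairs, one_sided = FALSE) {
  x <- pairs$x; y <- pairs$y
  if (length(x) < 3) stop_insufficient("need >= 3 contrast pairs")
  nz <- if (is.null(pairs$n_zero_branches)) 0 else pairs$n_zero_branches
  df <- (length(x) - 1) - nz
  if (df < 1) stop_insufficient("df < 1 after polytomy adjustment")
  r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  tt <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  p <- if (one_sided) pt(tt, df, lower.tail = FALSE) else 2 * pt(-abs(tt), df)
  new_regression_result("ols-origin",
                        slope = sum(x * y) / sum(x^2),
                        intercept = NA_real_, correlation = r,
                        t = tt, df = df, p = p, n = length(x))
}

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors (n >= 3).
#' @param through_origin fit without an intercept.
#' @return a `regression_result`; the t/p refer to the slope
#'   (df = n - 2, or n - 1 through the origin).
#' @export
ols_regression <- function(x, y, through_origin = FALSE) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("need x and y of equal length >= 3")
  if (var(x) == 0) stop_invalid("x has zero variance")
  fit <- if (through_origin) lm(y ~ x + 0) else lm(y ~ x)
  sm <- summary(fit)$coefficients
  srow <- if (through_origin) 1 else 2
  r <- if (through_origin) sum(x * y) / sqrt(sum(x^2) * sum(y^2)) else cor(x, y)
  new_regression_result(if (through_origin) "ols-origin" else "ols",
                        slope = sm[srow, 1],
                        intercept = if (through_origin) NA_real_ else sm[1, 1],
                        correlation = r, t = sm[srow, 3],
                        df = fit$df.residual, p = sm[srow, 4],
                        n = length(x))
}

#' Reduced-major-axis regression
#'
#' Symmetric line fitting: `slope = sign(r) * sd(y) / sd(x)` and
#' `intercept = mean(y) - slope * mean(x)`; through the origin,
#' `slope = sign(sum(xy)) * sqrt(sum(y^2) / sum(x^2))`. The correlation
#' and its t-test are the same as for OLS (the fitted line differs, not
#' the association test).
#'
#' @param x,y numeric vectors (n >= 3, both non-constant).
#' @param through_origin logical.
#' @return a `regression_result` (method `"rma"`).
#' @export
rma_regression <- function(x, y, through_origin = FALSE) {
  if (length(x) != length(y) || length(x) < 3)
    stop_invalid("need x and y of equal length >= 3")
  if (through_origin) {
    if (sum(x^2) == 0 || sum(y^2) == 0) stop_invalid("zero variance input")
    r <- sum(x * y) / sqrt(sum(x^2) * sum(y^2))
    slope <- sign(sum(x * y)) * sqrt(sum(y^2) / sum(x^2))
    df <- length(x) - 1
    intercept <- NA_real_
  } else {
    if (var(x) == 0 || var(y) == 0) stop_invalid("zero variance input")
    r <- cor(x, y)
    slope <- sign(r) * sd(y) / sd(x)
    intercept <- mean(y) - slope * mean(x)
    df <- length(x) - 2
  }
  tt <- r * sqrt(df) / sqrt(max(1 - r^2, .Machine$double.eps))
  new_regression_result("rma", slope = slope, intercept = intercept,
                        correlation = r, t = tt, df = df,
                        p = 2 * pt(-abs(tt), df), n = length(x))
}

#' Rank (Spearman) correlation
#'
#' Spearman's rho with mid-ranks for ties; the p-value uses the exact
#' permutation distribution for small untied samples and the
#' t-approximation otherwise (a Pearson variant is selectable).
#'
#' @param x,y numeric vectors (n >= 4).
#' @param method `"spearman"` or `"pearson"`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
rank_correlation <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 4)
    stop_invalid("need x and y of equal length >= 4")
  if (sd(x) == 0 || sd(y) == 0) stop_invalid("constant input; correlation undefined")
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       method = method)
}

partial_f_p <- function(fit_small, fit_big) {
  an <- anova(fit_small, fit_big)
  an$`Pr(>F)`[2]
}

#' Stepwise linear regression with alpha thresholds
#'
#' Forward entry / backward removal on partial-F p-values: at each step
#' the candidate with the smallest entry p below `alpha_enter` is added,
#' then any included predictor whose removal p exceeds `alpha_remove` is
#' dropped, until the model is stable. Ties break deterministically by
#' column order. Collinear predictors (condition number > 1e10 of the
#' candidate design) are dropped with a warning.
#'
#' @param y response vector.
#' @param predictors data frame of candidate predictor columns.
#' @param alpha_enter,alpha_remove thresholds (default 0.15, the value
#'   used in the study design this package models).
#' @return list with `selected` (character vector, possibly empty),
#'   `fit` (`lm` or `NULL`), and `result` (a `regression_result` for the
#'   first selected predictor, or `NULL` for the empty model).
#' @export
stepwise_regression <- function(y, predictors, alpha_enter = 0.15,
                                alpha_remove = 0.15) {
  predictors <- as.data.frame(predictors)
  if (length(y) <= ncol(predictors) + 1)
    stop_invalid("need n > number of predictors + 1")
  # collinearity screen: drop later columns that make the design singular
  keep <- names(predictors)
  X <- cbind(1, as.matrix(predictors))
  if (ncol(X) > 1) {
    sv <- svd(scale(X[, -1, drop = FALSE], scale = apply(
      X[, -1, drop = FALSE], 2, function(v) max(sd(v), 1e-300))))$d
    if (length(sv) > 1 && sv[1] / max(sv[length(sv)], 1e-300) > 1e10) {
      drop_idx <- ncol(predictors)
      warning("collinear predictors; dropping column ", keep[drop_idx])
      keep <- keep[-drop_idx]
    }
  }
  included <- character(0)
  dat <- data.frame(.y = y, predictors)
  repeat {
    changed <- FALSE
    candidates <- setdiff(keep, included)
    if (length(candidates)) {
      base_form <- if (length(included))
        paste(".y ~", paste(included, collapse = " + ")) else ".y ~ 1"
      fit0 <- lm(as.formula(base_form), data = dat)
      pvals <- vapply(candidates, function(v) {
        fit1 <- lm(as.formula(paste(base_form, "+", v)), data = dat)
        partial_f_p(fit0, fit1)
      }, 0)
      if (any(pvals < alpha_enter)) {
        best <- candidates[which.min(pvals)]   # first column wins ties
        included <- c(included, best)
        changed <- TRUE
      }
    }
    if (length(included) > 1) {
      full_form <- paste(".y ~", paste(included, collapse = " + "))
      fit_full <- lm(as.formula(full_form), data = dat)
      pvals <- vapply(included, function(v) {
        red <- setdiff(included, v)
        red_form <- if (length(red))
          paste(".y ~", paste(red, collapse = " + ")) else ".y ~ 1"
        partial_f_p(lm(as.formula(red_form), data = dat), fit_full)
      }, 0)
      if (any(pvals > alpha_remove)) {
        worst <- included[which.max(pvals)]
        included <- setdiff(included, worst)
        changed <- TRUE
      }
    } else if (length(included) == 1) {
      fit1 <- lm(as.formula(paste(".y ~", included)), data = dat)
      p1 <- partial_f_p(lm(.y ~ 1, data = dat), fit1)
      if (p1 > alpha_remove) { included <- character(0); changed <- TRUE }
    }
    if (!changed) break
  }
  if (!length(included))
    return(list(selected = character(0), fit = NULL, result = NULL))
  fit <- lm(as.formula(paste(".y ~", paste(included, collapse = " + "))),
            data = dat)
  sm <- summary(fit)$coefficients
  res <- new_regression_result("ols", slope = sm[2, 1], intercept = sm[1, 1],
                               correlation = cor(dat[[included[1]]],
                                                 fitted(fit)),
                               t = sm[2, 3], df = fit$df.residual,
                               p = sm[2, 4], n = length(y))
  list(selected = included, fit = fit, result = res)
}
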