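#' Multivariable Cochran's Q, H-squared, and I-squared
#'
#' Measures how much the per-SNP outcome effects scatter around the fitted MR
#' model beyond what their sampling errors explain. `q` is the weighted
#' residual sum of squares `sum_j w_j (by_j - fitted_j)^2` with the same
#' inverse-variance weights as the fit; `h2 = q / df` with
#' `df = J - K` (minus 1 with an intercept); `i2 = max(0, (q - df) / q) * 100`
#' is the percent of variation attributable to heterogeneity. Under
#' homogeneity Q is approximately chi-squared on `df`, so H-squared near 1
#' and I-squared near 0 indicate a well-specified fixed-effect model.
#'
#' @param panel an `mr_panel`.
#' @param theta fitted exposure coefficients (length K).
#' @param with_intercept whether the fit estimated an intercept.
#' @param intercept the fitted intercept (when `with_intercept`).
#' @return object of class `het_result`: list with `q`, `df`, `h2`, `i2`,
#'   `category` (see [categorize_i2]) and `annotation`.
#' @export
cochran_q <- function(panel, theta, with_intercept = FALSE, intercept = 0) {
  stopifnot(inherits(panel, "mr_panel"),
            length(theta) == length(panel$exposures))
  J <- n_snps(panel)
  df <- J - length(theta) - as.integer(with_intercept)
  if (df <= 0) {
    stop("cochran_q: no residual degrees of freedom (J = ", J, ")",
         call. = FALSE)
  }
  fitted <- as.numeric(panel$B %*% theta) +
    if (with_intercept) intercept else 0
  w <- 1 / panel$se_y^2
  q <- sum(w * (panel$by - fitted)^2)
  h2 <- q / df
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  cat_ <- categorize_i2(i2)
  structure(list(q = q, df = df, h2 = h2, i2 = i2,
                 category = cat_$category, annotation = cat_$annotation,
                 p_q = stats::pchisq(q, df, lower.tail = FALSE)),
            class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("Q = %.3f on %d df (H2 = %.2f, I2 = %.1f%%, %s%s)\n",
              x$q, x$df, x$h2, x$i2, x$category,
              if (nzchar(x$annotation)) paste0("; ", x$annotation) else ""))
  invisible(x)
}

#' Categorize an I-squared percentage
#'
#' Maps I-squared onto three labels using the conventional meta-analysis
#' reference values 25/50/75: `[0, 25)` low, `[25, 75)` moderate, `[75, 100)`
#' high. Because the reference scale has four anchor points but three labels
#' are reported, values in `[50, 75)` additionally carry a
#' `"moderate to high"` annotation.
#'
#' @param i2 I-squared in percent, in `[0, 100)`.
#' @return list with `category` (`"low"`, `"moderate"`, `"high"`) and
#'   `annotation` (`""` or `"moderate to high"`).
#' @export
categorize_i2 <- function(i2) {
  stopifnot(i2 >= 0, i2 < 100)
  category <- if (i2 < 25) "low" else if (i2 < 75) "moderate" else "high"
  annotation <- if (i2 >= 50 && i2 < 75) "moderate to high" else ""
  list(category = category, annotation = annotation)
}
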