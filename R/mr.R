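#' Convert a log-OR effect and SE to an odds ratio with 95% CI
#'
#' @param theta causal effect on the log-OR scale.
#' @param se_theta its standard error (must be positive).
#' @param z normal quantile for the interval (1.96 for 95%).
#' @return list with `or` and `ci95 = c(low, high)`.
#' @export
to_odds_ratio <- function(theta, se_theta, z = 1.96) {
  stopifnot(se_theta > 0)
  list(or = exp(theta),
       ci95 = c(exp(theta - z * se_theta), exp(theta + z * se_theta)))
}

.mr_estimate_row <- function(exposure, method, theta, se_theta, pvalue,
                             n_snps, intercept = NA_real_,
                             se_intercept = NA_real_, p_intercept = NA_real_,
                             i2 = NA_real_, z = 1.96) {
  ci <- to_odds_ratio(theta, se_theta, z)
  data.frame(exposure = exposure, method = method,
             theta = theta, se_theta = se_theta, pvalue = pvalue,
             or = ci$or, ci_low = ci$ci95[1], ci_high = ci$ci95[2],
             n_snps = n_snps, i2 = i2,
             intercept = intercept, se_intercept = se_intercept,
             p_intercept = p_intercept,
             stringsAsFactors = FALSE)
}

#' Single-SNP Wald-ratio MR estimate
#'
#' The causal effect from one instrument is the ratio of the SNP-outcome
#' effect to the SNP-exposure effect, `theta = by / bx`. The 95% CI
#' propagates outcome uncertainty only: the per-allele log-OR interval
#' `by +/- z * se_y` is divided by `bx` (endpoints reordered when `bx < 0`)
#' and exponentiated. The p-value equals the outcome-association p
#' (two-sided normal on `by / se_y`), which the first-order interval implies.
#' A delta-method variant additionally propagating exposure uncertainty is
#' available via `se_x`.
#'
#' @param by SNP-outcome effect (log-OR).
#' @param se_y its standard error.
#' @param bx SNP-exposure effect (nonzero).
#' @param se_x optional SNP-exposure SE; when supplied, `se_theta` uses the
#'   first-order delta method `sqrt(se_y^2 / bx^2 + by^2 se_x^2 / bx^4)` and
#'   the CI/p are based on it.
#' @param exposure,z labels and the CI quantile.
#' @return one-row data frame of class `mr_result` (columns `exposure`,
#'   `method`, `theta`, `se_theta`, `pvalue`, `or`, `ci_low`, `ci_high`,
#'   `n_snps`, `i2`, intercept columns `NA`).
#' @export
wald_ratio <- function(by, se_y, bx, se_x = NULL, exposure = "exposure",
                       z = 1.96) {
  stopifnot(se_y > 0)
  if (bx == 0) stop("wald_ratio: exposure effect bx is zero", call. = FALSE)
  theta <- by / bx
  if (is.null(se_x)) {
    se_theta <- se_y / abs(bx)
    ci <- sort(c((by - z * se_y) / bx, (by + z * se_y) / bx))
    pvalue <- 2 * stats::pnorm(-abs(by / se_y))
    out <- .mr_estimate_row(exposure, "wald", theta, se_theta, pvalue, 1L)
    out$ci_low <- exp(ci[1])
    out$ci_high <- exp(ci[2])
  } else {
    se_theta <- sqrt(se_y^2 / bx^2 + by^2 * se_x^2 / bx^4)
    pvalue <- 2 * stats::pnorm(-abs(theta / se_theta))
    out <- .mr_estimate_row(exposure, "wald", theta, se_theta, pvalue, 1L)
  }
  class(out) <- c("mr_result", "data.frame")
  out
}

# Weighted least squares on the panel's inverse-variance weights.
# Returns coefficients, SEs (fixed or multiplicative random-effects), t-based
# p-values, the weighted RSS and residual df.
.wls_fit <- function(X, y, w, se_scaling = c("multiplicative", "fixed")) {
  se_scaling <- match.arg(se_scaling)
  J <- nrow(X)
  p <- ncol(X)
  if (J <= p) {
    stop("insufficient instruments: J = ", J, " SNPs for ", p,
         " coefficient(s); need J > ", p, call. = FALSE)
  }
  sw <- sqrt(w)
  Xw <- X * sw
  yw <- y * sw
  qrX <- qr(Xw)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, p)]]
    stop("collinear exposures in weighted design: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  XtX_inv <- chol2inv(chol(crossprod(Xw)))
  beta <- XtX_inv %*% crossprod(Xw, yw)
  resid_w <- yw - Xw %*% beta
  rss <- sum(resid_w^2)
  df <- J - p
  phi <- if (se_scaling == "multiplicative") max(1, rss / df) else 1
  se <- sqrt(diag(XtX_inv) * phi)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df = df)
  list(coef = as.numeric(beta), se = as.numeric(se),
       pvalue = as.numeric(pval), rss = rss, df = df, phi = phi,
       names = colnames(X))
}

#' Multivariable inverse-variance-weighted MR
#'
#' Regresses the SNP-outcome log-OR on the J x K matrix of SNP-exposure
#' effects with no intercept, weighting each SNP by the inverse variance of
#' its outcome log-OR (`w_j = 1 / se_y_j^2`). Each coefficient is the causal
#' effect of its exposure on the outcome per unit exposure, holding the other
#' modeled exposures fixed. By default standard errors use multiplicative
#' random-effects scaling — inflated by `max(1, sqrt(RSS_w / (J - K)))` — so
#' that between-SNP heterogeneity widens the intervals but can never shrink
#' them below the fixed-effect ones; p-values are two-sided from the t
#' distribution on `J - K` df. Multivariable I-squared from [cochran_q] is
#' attached to every row.
#'
#' @param panel an `mr_panel` from [harmonize].
#' @param se_scaling `"multiplicative"` (default) or `"fixed"`.
#' @return data frame of class `mr_result`, one row per exposure
#'   (`method = "ivw_multi"`, or `"ivw_uni"` when K = 1).
#' @export
ivw_multivariable <- function(panel,
                              se_scaling = c("multiplicative", "fixed")) {
  se_scaling <- match.arg(se_scaling)
  stopifnot(inherits(panel, "mr_panel"))
  K <- length(panel$exposures)
  if (any(colSums(abs(panel$B)) == 0)) {
    stop("ivw_multivariable: all-zero exposure column", call. = FALSE)
  }
  w <- 1 / panel$se_y^2
  fit <- .wls_fit(panel$B, panel$by, w, se_scaling)
  het <- cochran_q(panel, fit$coef, with_intercept = FALSE)
  method <- if (K == 1) "ivw_uni" else "ivw_multi"
  out <- do.call(rbind, lapply(seq_len(K), function(k) {
    .mr_estimate_row(panel$exposures[k], method, fit$coef[k], fit$se[k],
                     fit$pvalue[k], n_snps(panel), i2 = het$i2)
  }))
  class(out) <- c("mr_result", "data.frame")
  attr(out, "heterogeneity") <- het
  out
}

#' Univariable inverse-variance-weighted MR
#'
#' [ivw_multivariable] restricted to a single exposure column: zero-intercept
#' weighted regression of the outcome log-OR on one exposure's effects.
#' With J = 1 instrument no residual df remain for regression inference, so
#' the fit reduces exactly to the [wald_ratio] on that SNP.
#'
#' @param panel an `mr_panel`; if it has several exposures, `exposure` picks
#'   one.
#' @param exposure exposure name or index (default the first).
#' @param se_scaling as in [ivw_multivariable].
#' @return one-row `mr_result` data frame.
#' @export
ivw_univariable <- function(panel, exposure = 1L,
                            se_scaling = c("multiplicative", "fixed")) {
  se_scaling <- match.arg(se_scaling)
  p1 <- panel_exposure(panel, exposure)
  if (n_snps(p1) == 1L) {
    out <- wald_ratio(p1$by[1], p1$se_y[1], p1$B[1, 1],
                      exposure = p1$exposures[1])
    out$method <- "ivw_uni"
    return(out)
  }
  ivw_multivariable(p1, se_scaling)
}

#' Multivariable MR-Egger regression for one exposure of interest
#'
#' Orients the panel so the exposure of interest has non-negative SNP effects
#' (see [orient_to_exposure]), then fits the same weighted regression as
#' [ivw_multivariable] with a free intercept. The intercept estimates the
#' average direct (exposure-independent) effect of the instruments on the
#' outcome — directional pleiotropy — and its t test (`J - K - 1` df) is the
#' pleiotropy test; the slope for the exposure of interest is the
#' pleiotropy-adjusted causal effect. Because orientation is defined per
#' exposure, a full per-exposure Egger table is produced by calling this once
#' per exposure (see [egger_table]).
#'
#' @param panel an `mr_panel`.
#' @param exposure exposure of interest, name or index.
#' @param se_scaling as in [ivw_multivariable].
#' @return one-row `mr_result` data frame (`method = "egger_multi"`) with
#'   `intercept`, `se_intercept`, `p_intercept` filled.
#' @export
egger_multivariable <- function(panel, exposure = 1L,
                                se_scaling = c("multiplicative", "fixed")) {
  se_scaling <- match.arg(se_scaling)
  stopifnot(inherits(panel, "mr_panel"))
  k <- if (is.character(exposure)) match(exposure, panel$exposures)
       else as.integer(exposure)
  K <- length(panel$exposures)
  oriented <- orient_to_exposure(panel, k)
  X <- cbind(`(intercept)` = 1, oriented$B)
  w <- 1 / oriented$se_y^2
  fit <- .wls_fit(X, oriented$by, w, se_scaling)
  het <- cochran_q(oriented, fit$coef[-1], with_intercept = TRUE,
                   intercept = fit$coef[1])
  out <- .mr_estimate_row(panel$exposures[k], "egger_multi",
                          fit$coef[k + 1], fit$se[k + 1], fit$pvalue[k + 1],
                          n_snps(panel),
                          intercept = fit$coef[1], se_intercept = fit$se[1],
                          p_intercept = fit$pvalue[1], i2 = het$i2)
  class(out) <- c("mr_result", "data.frame")
  attr(out, "heterogeneity") <- het
  out
}

#' Per-exposure MR-Egger table
#'
#' Runs [egger_multivariable] once per exposure, re-orienting the panel to
#' each exposure in turn, and binds the rows.
#'
#' @inheritParams egger_multivariable
#' @return `mr_result` data frame with one row per exposure.
#' @export
egger_table <- function(panel, se_scaling = c("multiplicative", "fixed")) {
  se_scaling <- match.arg(se_scaling)
  out <- do.call(rbind, lapply(seq_along(panel$exposures), function(k) {
    egger_multivariable(panel, k, se_scaling)
  }))
  class(out) <- c("mr_result", "data.frame")
  out
}

#' Write an MR estimates table as TSV
#'
#' Columns mirror the reporting layout of multivariable MR tables: exposure,
#' method, OR, CI bounds, P, I-squared, intercept and its P, and the number
#' of instruments.
#'
#' @param x an `mr_result` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mr_result <- function(x, path) {
  stopifnot(inherits(x, "mr_result") || is.data.frame(x))
  cols <- c("gene", "exposure", "method", "or", "ci_low", "ci_high",
            "pvalue", "i2", "intercept", "p_intercept", "n_snps", "theta",
            "se_theta", "significant")
  .write_delim(as.data.frame(x)[intersect(cols, names(x))], path)
}
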