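# Correlation statistics: Spearman rank correlation, simple linear
# regression, Fisher-z confidence intervals, two-sided p-values and post-hoc
# power for the 3 x 7 grid of DXA parameters (BMC, BMD, vBMD) against
# mechanical parameters (E, e_Y, sigma_y, epsilon_y, e_F, sigma_f, epsilon_f).

#' Spearman rank correlation
#'
#' Pearson correlation of the average-ranked data (ties receive average
#' ranks). Returns `NA` with a warning when either variable's ranks have zero
#' variance (all values tied), where the correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length (>= 3), no missing values.
#' @return Correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: filter pairwise first",
                                 call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("undefined correlation: zero rank variance")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Simple linear regression of y on x
#'
#' Ordinary least squares, with the Pearson correlation and its square (the
#' coefficient of determination of the simple regression).
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` needs nonzero
#'   variance.
#' @return List with `slope`, `intercept`, `pearson_r`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0) stop("degenerate design: zero variance in `x`",
                              call. = FALSE)
  slope <- stats::cov(x, y) / stats::var(x)
  r <- if (stats::sd(y) == 0) 0 else stats::cor(x, y)
  list(slope = slope, intercept = mean(y) - slope * mean(x),
       pearson_r = r, r_squared = r^2)
}

#' Fisher-z confidence interval for a correlation
#'
#' z = atanh(r) is treated as normal with standard error 1/sqrt(n - 3); the
#' interval endpoints are back-transformed with tanh. No small-sample
#' correction is applied.
#'
#' @param r Observed correlation, |r| < 1.
#' @param n Number of pairs, >= 4.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @return List with `ci_low`, `ci_high`.
#' @export
fisher_ci <- function(r, n, confidence = 0.95) {
  check_r_n(r, n)
  if (confidence <= 0 || confidence >= 1) {
    stop("`confidence` must be in (0, 1)", call. = FALSE)
  }
  hw <- stats::qnorm((1 + confidence) / 2) / sqrt(n - 3)
  z <- atanh(r)
  list(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Two-sided p-value for a correlation
#'
#' Uses t = r * sqrt(n - 2) / sqrt(1 - r^2) on n - 2 degrees of freedom.
#'
#' @inheritParams fisher_ci
#' @return Two-sided p-value.
#' @export
correlation_p_value <- function(r, n) {
  check_r_n(r, n)
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Post-hoc power of a correlation test
#'
#' Fisher-z normal approximation: with zeta = atanh(rho), the two-sided test
#' at level alpha rejects with probability
#' Phi(|zeta| sqrt(n-3) - z_{1-alpha/2}) + Phi(-|zeta| sqrt(n-3) - z_{1-alpha/2}).
#' At rho = 0 this reduces to alpha (the size of the test).
#'
#' @param rho Assumed population correlation, |rho| < 1.
#' @param n Number of pairs, >= 4.
#' @param alpha Significance level in (0, 1); default 0.05.
#' @return Power in \[0, 1\].
#' @export
correlation_power <- function(rho, n, alpha = 0.05) {
  check_r_n(rho, n)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  shift <- abs(atanh(rho)) * sqrt(n - 3)
  stats::pnorm(shift - za) + stats::pnorm(-shift - za)
}

check_r_n <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1) {
    stop("correlation must satisfy |r| < 1 (degenerate otherwise)",
         call. = FALSE)
  }
  if (!is.finite(n) || n < 4) {
    stop("need at least n = 4 pairs", call. = FALSE)
  }
  invisible(NULL)
}

#' Correlation table of DXA parameters against mechanical parameters
#'
#' Joins the per-specimen DXA summaries and mechanical summaries on
#' `specimen_id` and computes, for every cell of the 3 x 7 grid (BMC, BMD,
#' vBMD against modulus, energy at yield, yield stress, yield strain, energy
#' at failure, failure stress, failure strain): Spearman rho (the headline
#' correlation, with its Fisher-z CI, two-sided p and post-hoc power) and the
#' simple linear regression of the mechanical parameter on the DXA parameter
#' (slope, intercept, Pearson r, r^2, for interpolation). Missing values are
#' removed pairwise per cell and the per-cell n is reported; cells with fewer
#' than 4 complete pairs carry `NA` statistics.
#'
#' @param dxa Tibble from [derive_dxa()].
#' @param mech Tibble from [summarize_mechanics()] rows.
#' @param confidence CI level (default 0.95).
#' @param alpha Significance level for the power column (default 0.05).
#' @param adjust `"none"` (default; no multiplicity adjustment is applied
#'   across the 21 cells) or `"holm"` to Holm-adjust the 21 p-values.
#' @return Tibble with one row per cell: `dxa_parameter`,
#'   `mechanical_parameter`, `n`, `spearman_rho`, `pearson_r`, `r_squared`,
#'   `ci_low`, `ci_high`, `p_two_sided`, `power`, `slope`, `intercept`.
#' @export
build_correlation_table <- function(dxa, mech, confidence = 0.95,
                                    alpha = 0.05,
                                    adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  orphans <- setdiff(union(dxa$specimen_id, mech$specimen_id),
                     intersect(dxa$specimen_id, mech$specimen_id))
  if (length(orphans) == nrow(dxa) + nrow(mech)) {
    stop(sprintf("no joinable specimen ids; orphans: %s",
                 paste(orphans, collapse = ", ")), call. = FALSE)
  }
  joined <- merge(as.data.frame(dxa), as.data.frame(mech),
                  by = "specimen_id")
  dxa_cols <- c(BMC = "bmc_mean", BMD = "bmd_mean", vBMD = "vbmd_mean")
  mech_cols <- c(E = "modulus", e_Y = "energy_yield", sigma_y = "yield_stress",
                 epsilon_y = "yield_strain", e_F = "energy_failure",
                 sigma_f = "failure_stress", epsilon_f = "failure_strain")
  rows <- vector("list", length(dxa_cols) * length(mech_cols))
  k <- 0L
  for (i in seq_along(dxa_cols)) {
    for (j in seq_along(mech_cols)) {
      x <- joined[[dxa_cols[i]]]
      y <- joined[[mech_cols[j]]]
      ok <- is.finite(x) & is.finite(y)
      k <- k + 1L
      rows[[k]] <- correlation_cell(
        names(dxa_cols)[i], names(mech_cols)[j], x[ok], y[ok],
        confidence, alpha)
    }
  }
  out <- do.call(rbind, rows)
  if (adjust == "holm") {
    out$p_two_sided <- stats::p.adjust(out$p_two_sided, method = "holm")
  }
  out
}

correlation_cell <- function(dxa_name, mech_name, x, y, confidence, alpha) {
  n <- length(x)
  na_row <- fast_tbl(
    dxa_parameter = dxa_name, mechanical_parameter = mech_name, n = n,
    spearman_rho = NA_real_, pearson_r = NA_real_, r_squared = NA_real_,
    ci_low = NA_real_, ci_high = NA_real_, p_two_sided = NA_real_,
    power = NA_real_, slope = NA_real_, intercept = NA_real_
  )
  if (n < 4L) {
    message(sprintf("cell %s vs %s: only %d complete pairs (< 4); skipped",
                    dxa_name, mech_name, n))
    return(na_row)
  }
  rho <- suppressWarnings(spearman_rho(x, y))
  fit <- linear_regression(x, y)
  if (!is.finite(rho) || abs(rho) >= 1) {
    na_row$pearson_r <- fit$pearson_r
    na_row$r_squared <- fit$r_squared
    na_row$slope <- fit$slope
    na_row$intercept <- fit$intercept
    return(na_row)
  }
  ci <- fisher_ci(rho, n, confidence)
  fast_tbl(
    dxa_parameter = dxa_name, mechanical_parameter = mech_name, n = n,
    spearman_rho = rho, pearson_r = fit$pearson_r,
    r_squared = fit$r_squared,
    ci_low = ci$ci_low, ci_high = ci$ci_high,
    p_two_sided = correlation_p_value(rho, n),
    power = correlation_power(rho, n, alpha),
    slope = fit$slope, intercept = fit$intercept
  )
}
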