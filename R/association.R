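#' Squared Pearson correlation
#'
#' @param x,y Numeric vectors of equal length (n >= 3, non-constant).
#' @return `cor(x, y)^2` in \[0, 1\].
#' @export
pearson_r2 <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  stats::cor(x, y)^2
}

#' Ordinary least-squares line
#'
#' Simple regression of `y` on `x`; applied to profile summaries
#' (`x = mean_indel_size`, `y = mean_mh`) the slope is in bp of microhomology
#' per bp of indel size.
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `residuals`, `r2`, `n` and the
#'   underlying `fit`.
#' @export
fit_line <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  fit <- stats::lm(y ~ x, data = data.frame(x = x[ok], y = y[ok]))
  co <- stats::coef(fit)
  list(slope = unname(co["x"]), intercept = unname(co["(Intercept)"]),
       residuals = stats::residuals(fit),
       r2 = summary(fit)$r.squared, n = sum(ok), fit = fit)
}

#' Chi-squared test on nested linear models
#'
#' Fits reduced and full models by least squares (an intercept is always
#' included) and compares them on the deviance scale: the residual
#' sum-of-squares difference is divided by the full model's dispersion
#' estimate (residual variance) and referred to a chi-squared distribution
#' with `df_reduced - df_full` degrees of freedom. `deviance_delta` is
#' reported as full minus reduced (non-positive: the richer model never fits
#' worse). A full model that adds no information (e.g. a duplicated column)
#' gives `p = 1`.
#'
#' @param y Response vector.
#' @param x_reduced,x_full Design matrices (without intercept); every column
#'   of `x_reduced` must also be a column of `x_full`.
#' @return List of class `association_result`: `p_value`, `deviance_delta`,
#'   `df_pair` (residual df of full and reduced model), `r2` (full model),
#'   `slope`/`intercept` of the full fit, `n`, and both `lm` fits.
#' @export
nested_model_test <- function(y, x_reduced, x_full) {
  x_reduced <- as.matrix(x_reduced)
  x_full <- as.matrix(x_full)
  stopifnot(is.numeric(y), nrow(x_reduced) == length(y),
            nrow(x_full) == length(y))
  nested <- apply(x_reduced, 2L, function(col) {
    any(apply(x_full, 2L, function(fc) isTRUE(all.equal(unname(col),
                                                        unname(fc)))))
  })
  if (!all(nested)) {
    stop("designs are not nested: column(s) ",
         paste(which(!nested), collapse = ", "),
         " of x_reduced are absent from x_full")
  }
  dr <- as.data.frame(x_reduced)
  names(dr) <- sprintf("r%d", seq_len(ncol(dr)))
  df_ <- as.data.frame(x_full)
  names(df_) <- sprintf("f%d", seq_len(ncol(df_)))
  fit_r <- stats::lm(y ~ ., data = cbind(y = y, dr))
  fit_f <- stats::lm(y ~ ., data = cbind(y = y, df_))
  rss_r <- sum(stats::residuals(fit_r)^2)
  rss_f <- sum(stats::residuals(fit_f)^2)
  dfr <- stats::df.residual(fit_r)
  dff <- stats::df.residual(fit_f)
  ddf <- dfr - dff
  dispersion <- rss_f / dff
  p <- if (ddf <= 0L) 1 else
    stats::pchisq((rss_r - rss_f) / dispersion, df = ddf, lower.tail = FALSE)
  co <- stats::coef(fit_f)
  structure(
    list(p_value = p, deviance_delta = rss_f - rss_r,
         df_pair = c(full = dff, reduced = dfr),
         r2 = summary(fit_f)$r.squared,
         slope = unname(co[-1L]), intercept = unname(co[1L]),
         n = length(y), fit_reduced = fit_r, fit_full = fit_f),
    class = "association_result"
  )
}

#' @export
print.association_result <- function(x, ...) {
  cat("<association_result> p = ", signif(x$p_value, 3),
      ", deviance delta = ", signif(x$deviance_delta, 4),
      ", residual df = ", x$df_pair[["full"]], ", ", x$df_pair[["reduced"]],
      ", R^2(full) = ", signif(x$r2, 3), "\n", sep = "")
  invisible(x)
}
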