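#' Simple linear regression with R-squared
#'
#' Ordinary least squares `y ~ x` reporting the regression equation and the
#' coefficient of determination, the descriptive statistic used for the
#' laminar structure-function correlations. Points with absolute
#' studentized residual above 3 are flagged (reported, never removed).
#'
#' @param x,y numeric vectors, length >= 3, `x` not constant.
#' @param predictor,response names carried into the result.
#' @param layer optional layer label carried into the result.
#' @return list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `n`, `predictor`, `response`, `layer`,
#'   `outlier_flag` (logical vector).
#' @export
linfit <- function(x, y, predictor = "x", response = "y", layer = NA) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete observations")
  if (stats::sd(x) == 0) stop("degenerate fit: x is constant")
  fit <- stats::lm(y ~ x)
  r2 <- if (stats::sd(y) == 0) {
    warning("constant response; R-squared reported as 0")
    0
  } else 1 - sum(stats::resid(fit)^2) / sum((y - mean(y))^2)
  stud <- tryCatch(stats::rstudent(fit), error = function(e)
    rep(NA_real_, length(x)))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    n = length(x),
    predictor = predictor, response = response, layer = layer,
    outlier_flag = !is.na(stud) & abs(stud) > 3),
    class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("<linfit> %s = %.4g * %s %+.4g   R^2 = %.4f   (n = %d%s)\n",
              x$response, x$slope, x$predictor, x$intercept, x$r_squared,
              x$n,
              if (is.na(x$layer)) "" else paste0(", layer ", x$layer)))
  invisible(x)
}

#' R-squared grid over layers and predictor/response pairs
#'
#' Fits [linfit()] in every (layer, predictor, response) cell of a cohort
#' table and returns the grid of coefficients of determination, the input
#' of the structure-function heatmaps. Cells whose layer has fewer than 3
#' complete observations are reported as `NA` (absent), not zero.
#'
#' @param cohort data.frame with a `layer` column plus the named predictor
#'   and response columns.
#' @param predictors,responses character vectors of column names.
#' @param layers layers to fit; default all present.
#' @return data.frame with `layer`, `predictor`, `response`, `r_squared`,
#'   `slope`, `n`.
#' @export
r2_matrix <- function(cohort, predictors, responses,
                      layers = unique(cohort$layer)) {
  missing_cols <- setdiff(c("layer", predictors, responses), names(cohort))
  if (length(missing_cols))
    stop("cohort table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  grid <- expand.grid(layer = layers, predictor = predictors,
                      response = responses, stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sub <- cohort[cohort$layer == g$layer, , drop = FALSE]
    x <- sub[[g$predictor]]; y <- sub[[g$response]]
    fit <- tryCatch(linfit(x, y, g$predictor, g$response, g$layer),
                    error = function(e) NULL)
    data.frame(layer = g$layer, predictor = g$predictor,
               response = g$response,
               r_squared = if (is.null(fit)) NA_real_ else fit$r_squared,
               slope = if (is.null(fit)) NA_real_ else fit$slope,
               n = sum(is.finite(x) & is.finite(y)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
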