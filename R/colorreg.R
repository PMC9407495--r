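#' Fit a flavonoid content on CIELAB color axes
#'
#' Ordinary least squares of an analyte content (mg/g) on peel color
#' coordinates, by default the chromatic axes a* and b* in raw CIELAB units
#' (no standardization). \eqn{R = \sqrt{R^2}} and
#' \eqn{F = (R^2/k) / ((1-R^2)/(n-k-1))}.
#'
#' @param table A [sample_table()] with color columns.
#' @param response Analyte code.
#' @param predictors Color axes, default \code{c("a", "b")}; \code{"L"} may
#'   be added.
#' @param include_intercept Keep the intercept (default TRUE).
#' @return Object of class \code{"color_regression"}: \code{coefficients},
#'   \code{intercept}, \code{R}, \code{R2}, \code{F}, \code{n}, \code{k},
#'   \code{p_value}, \code{residuals}, \code{fitted}.
#' @export
#' @examples
#' out <- generate_samples(default_synth_config())
#' fit_color_regression(out$table, "Y_QI")
fit_color_regression <- function(table, response, predictors = c("a", "b"),
                                 include_intercept = TRUE) {
  df <- as.data.frame(table)
  missing_vars <- setdiff(c(response, predictors), names(df))
  if (length(missing_vars))
    stop("lookup error: unknown variable code(s): ",
         paste(missing_vars, collapse = ", "))
  df <- df[stats::complete.cases(df[c(response, predictors)]), ]
  n <- nrow(df); k <- length(predictors)
  if (n <= k + 1) stop("need n > k + 1 observations, have ", n)
  X <- as.matrix(df[predictors])
  y <- df[[response]]
  if (qr(cbind(if (include_intercept) 1, X))$rank < k + include_intercept)
    stop("singularity error: color predictors are affinely dependent")
  if (stats::sd(y) == 0) {
    co <- stats::setNames(rep(0, k), predictors)
    return(structure(list(response = response, coefficients = co,
                          intercept = if (include_intercept) y[1] else 0,
                          R = 0, R2 = 0, F = 0, n = n, k = k,
                          p_value = NA_real_,
                          residuals = rep(0, n), fitted = y),
                     class = "color_regression"))
  }
  fml <- if (include_intercept) y ~ X else y ~ X - 1
  fit <- stats::lm(fml)
  cf <- stats::coef(fit)
  co <- stats::setNames(cf[grep("^X", names(cf))], predictors)
  R2 <- summary(fit)$r.squared
  Fv <- if (R2 < 1) (R2 / k) / ((1 - R2) / (n - k - 1)) else Inf
  structure(list(response = response, coefficients = co,
                 intercept = if (include_intercept) unname(cf["(Intercept)"]) else 0,
                 R = sqrt(R2), R2 = R2, F = Fv, n = n, k = k,
                 p_value = if (is.finite(Fv))
                   stats::pf(Fv, k, n - k - 1, lower.tail = FALSE) else 0,
                 residuals = unname(stats::resid(fit)),
                 fitted = unname(stats::fitted(fit))),
            class = "color_regression")
}

#' @export
print.color_regression <- function(x, digits = 3, ...) {
  eq <- paste0(sprintf("%+.3f", x$coefficients),
               names(x$coefficients), "*", collapse = " ")
  cat(x$response, " = ", eq, sprintf(" %+.3f", x$intercept), "\n", sep = "")
  cat(sprintf("R = %.3f  R2 = %.3f  F = %.3f  (n = %d, k = %d)\n",
              x$R, x$R2, x$F, x$n, x$k))
  invisible(x)
}

#' Predict analyte content from a color triple
#'
#' Linear evaluation of a fitted color regression; predictions are not
#' clipped, and a negative predicted content triggers a warning since
#' contents are physically nonnegative.
#'
#' @param model A \code{"color_regression"}.
#' @param color Named list or vector with the axes the model uses
#'   (e.g. \code{c(a = 10, b = 20)}).
#' @return Predicted content in mg/g.
#' @export
predict_content <- function(model, color) {
  stopifnot(inherits(model, "color_regression"))
  axes <- names(model$coefficients)
  if (!all(axes %in% names(color)))
    stop("color must provide axes: ", paste(axes, collapse = ", "))
  pred <- model$intercept +
    sum(model$coefficients * as.numeric(unlist(color)[axes]))
  if (pred < 0)
    warning("negative predicted content (", round(pred, 3),
            " mg/g) for ", model$response)
  pred
}

#' Fit color regressions for a set of analytes
#'
#' @param table A [sample_table()] with color columns.
#' @param responses Analyte codes (default: all analytes present).
#' @param predictors Color axes to use.
#' @param r2_flag Models with \eqn{R^2} below this are flagged (kept, not
#'   dropped).
#' @return A list of \code{"color_regression"} objects; attribute
#'   \code{"summary"} holds a one-row-per-model data.frame (response,
#'   equation, R, R2, F, flagged).
#' @export
regression_table <- function(table, responses = NULL,
                             predictors = c("a", "b"), r2_flag = 0) {
  if (is.null(responses))
    responses <- intersect(analyte_catalog()$code, names(table))
  models <- lapply(responses, function(rr)
    fit_color_regression(table, rr, predictors))
  names(models) <- responses
  summ <- do.call(rbind, lapply(models, function(m)
    data.frame(response = m$response,
               equation = paste0("y = ",
                 paste0(sprintf("%+.3f", m$coefficients),
                        names(m$coefficients), "*", collapse = " "),
                 sprintf(" %+.3f", m$intercept)),
               R = m$R, R2 = m$R2, F = m$F, flagged = m$R2 < r2_flag,
               stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  attr(models, "summary") <- summ
  models
}
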