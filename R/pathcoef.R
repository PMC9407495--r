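#' Stepwise screening of candidate predictors
#'
#' Classic forward stepwise with backward checks, the screening convention
#' of SPSS-style regression: at each step the candidate with the smallest
#' partial-F p-value enters if that p-value is below \code{p_enter}; any
#' included variable whose coefficient p-value rises above \code{p_remove}
#' is then removed. Ties break on candidate list order; the loop stops when
#' no entry or removal is possible.
#'
#' @param table A [sample_table()] (rows with missing values among the
#'   involved variables are dropped listwise).
#' @param response Response variable code.
#' @param candidates Candidate predictor codes.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be >= p_enter.
#' @return Object of class \code{"stepwise_trace"}: data.frame \code{steps}
#'   (action, variable, p) and \code{final_set}.
#' @export
stepwise_select <- function(table, response, candidates,
                            p_enter = 0.05, p_remove = 0.10) {
  if (p_enter > p_remove)
    stop("parameter error: p_enter must be <= p_remove")
  df <- as.data.frame(table)
  missing_vars <- setdiff(c(response, candidates), names(df))
  if (length(missing_vars))
    stop("lookup error: unknown variable code(s): ",
         paste(missing_vars, collapse = ", "))
  df <- df[stats::complete.cases(df[c(response, candidates)]),
           c(response, candidates), drop = FALSE]
  n <- nrow(df)

  included <- character(0)
  steps <- data.frame(action = character(0), variable = character(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  coef_p <- function(vars) {
    fml <- stats::reformulate(vars, response)
    s <- summary(stats::lm(fml, data = df))$coefficients
    p <- s[-1, 4]
    stats::setNames(p, vars)
  }
  repeat {
    pool <- setdiff(candidates, included)
    if (n <= length(included) + 3) pool <- character(0)
    entered <- FALSE
    if (length(pool)) {
      pe <- vapply(pool, function(v) coef_p(c(included, v))[[v]], numeric(1))
      best <- which.min(pe)  # first index on ties = candidate order
      if (pe[best] < p_enter) {
        included <- c(included, pool[best])
        steps <- rbind(steps, data.frame(action = "enter",
                                         variable = pool[best],
                                         p = unname(pe[best])))
        entered <- TRUE
      }
    }
    removed <- FALSE
    while (length(included) > 0) {
      pr <- coef_p(included)
      worst <- which.max(pr)
      if (pr[worst] > p_remove) {
        steps <- rbind(steps, data.frame(action = "remove",
                                         variable = included[worst],
                                         p = unname(pr[worst])))
        included <- included[-worst]
        removed <- TRUE
      } else break
    }
    if (!entered && !removed) break
  }
  structure(list(steps = steps, final_set = included,
                 response = response, n = n),
            class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  cat("Stepwise screening for", x$response, "(n =", x$n, ")\n")
  if (nrow(x$steps)) print(x$steps) else cat("  no variable entered\n")
  cat("final set:", if (length(x$final_set))
    paste(x$final_set, collapse = ", ") else "(empty)", "\n")
  invisible(x)
}

#' Decision coefficient of a predictor in path analysis
#'
#' The ranking index \eqn{D = 2 P r - P^2}, where \eqn{P} is the
#' predictor's direct path coefficient and \eqn{r} its correlation with the
#' response. Positive values mark net promoting factors, negative values
#' net inhibiting factors.
#'
#' @param direct Direct path coefficient P (standardized).
#' @param r_xy Correlation of the predictor with the response.
#' @return The decision coefficient (vectorized).
#' @export
#' @examples
#' decision_coefficient(-0.720, -0.720)  # 0.5184
decision_coefficient <- function(direct, r_xy) {
  2 * direct * r_xy - direct^2
}

#' Decompose predictor-response correlations into path coefficients
#'
#' Direct path coefficients are the standardized regression coefficients
#' \eqn{P} solving \eqn{R_{xx} P = r_{xy}}; the indirect effect of
#' predictor i routed through co-predictor j is \eqn{r_{ij} P_j}, so each
#' correlation decomposes exactly as
#' \eqn{r_{xy,i} = P_i + \sum_{j \ne i} r_{ij} P_j}.
#'
#' Either a sample table (raw data) or printed correlation-level inputs
#' (\code{r_xy} plus \code{R_xx}) can be supplied, so published path tables
#' can be checked without raw data.
#'
#' @param table A [sample_table()]; ignored when \code{r_xy} is given.
#' @param response Response code (label only in correlation mode).
#' @param predictors Predictor codes.
#' @param r_xy Optional vector of predictor-response correlations.
#' @param R_xx Optional predictor intercorrelation matrix.
#' @param n Sample size (used for coefficient p-values; taken from the
#'   table in data mode).
#' @return Object of class \code{"path_analysis"}: per-predictor
#'   \code{r_xy}, \code{direct}, \code{indirect} matrix (entry i,j is the
#'   effect of i via j), \code{indirect_total}, \code{decision},
#'   \code{significance}, plus \code{R_xx}.
#' @export
path_decompose <- function(table = NULL, response, predictors,
                           r_xy = NULL, R_xx = NULL, n = NULL) {
  k <- length(predictors)
  stopifnot(k >= 1)
  if (is.null(r_xy)) {
    df <- as.data.frame(table)
    missing_vars <- setdiff(c(response, predictors), names(df))
    if (length(missing_vars))
      stop("lookup error: unknown variable code(s): ",
           paste(missing_vars, collapse = ", "))
    df <- df[stats::complete.cases(df[c(response, predictors)]), ]
    n <- nrow(df)
    r_xy <- vapply(predictors, function(v) stats::cor(df[[v]], df[[response]]),
                   numeric(1))
    R_xx <- stats::cor(as.matrix(df[predictors]))
  } else {
    r_xy <- stats::setNames(as.numeric(r_xy), predictors)
    if (k == 1 && is.null(R_xx)) R_xx <- matrix(1, 1, 1)
    R_xx <- as.matrix(R_xx)
    dimnames(R_xx) <- list(predictors, predictors)
  }
  ev <- eigen(R_xx, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev))
    stop("collinearity error: predictor correlation matrix {",
         paste(predictors, collapse = ", "), "} is singular")
  direct <- drop(solve(R_xx, r_xy))
  names(direct) <- predictors
  indirect <- R_xx * rep(direct, each = k)   # entry (i,j) = r_ij * P_j
  diag(indirect) <- 0
  dimnames(indirect) <- list(predictors, predictors)
  indirect_total <- rowSums(indirect)
  decision <- decision_coefficient(direct, r_xy)
  sig <- rep(NA_real_, k)
  if (!is.null(n) && n > k + 1) {
    # t-test of the standardized coefficient via its OLS standard error
    R2 <- sum(direct * r_xy)
    se2 <- diag(solve(R_xx)) * (1 - R2) / (n - k - 1)
    se2[se2 < 0] <- NA
    tt <- direct / sqrt(se2)
    sig <- 2 * stats::pt(-abs(tt), df = n - k - 1)
  }
  if (any(abs(direct) > 1))
    warning("direct path coefficient(s) exceed 1 in magnitude (",
            paste(predictors[abs(direct) > 1], collapse = ", "),
            "): strong predictor collinearity")
  structure(list(response = response, predictors = predictors,
                 r_xy = r_xy, direct = direct, indirect = indirect,
                 indirect_total = indirect_total, decision = decision,
                 significance = stats::setNames(sig, predictors),
                 R_xx = R_xx, n = n),
            class = "path_analysis")
}

#' @export
print.path_analysis <- function(x, digits = 3, ...) {
  cat("Path analysis for response", x$response, "\n")
  print(round(data.frame(r = x$r_xy, direct = x$direct,
                         indirect_total = x$indirect_total,
                         decision = x$decision, p = x$significance),
              digits))
  invisible(x)
}

#' Rank predictors by decision coefficient
#'
#' @param result A \code{"path_analysis"}.
#' @return A data.frame sorted by decision coefficient (descending, stable)
#'   with columns \code{code}, \code{decision} and \code{interpretation}
#'   (\code{promoting} / \code{inhibiting} / \code{neutral}).
#' @export
rank_factors <- function(result) {
  stopifnot(inherits(result, "path_analysis"))
  ord <- order(-result$decision)  # stable: ties keep input order
  d <- result$decision[ord]
  data.frame(code = result$predictors[ord], decision = unname(d),
             interpretation = ifelse(d > 0, "promoting",
                                     ifelse(d < 0, "inhibiting", "neutral")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Published-layout path table
#'
#' One row per predictor with the correlation, direct coefficient,
#' per-mediator indirect columns, total indirect, decision coefficient and
#' p-value, mirroring the customary path-analysis table layout.
#'
#' @param result A \code{"path_analysis"}.
#' @return A data.frame.
#' @export
path_table <- function(result) {
  stopifnot(inherits(result, "path_analysis"))
  k <- length(result$predictors)
  out <- data.frame(response = result$response, factor = result$predictors,
                    r = unname(result$r_xy), direct = unname(result$direct),
                    stringsAsFactors = FALSE)
  if (k > 1)
    for (j in result$predictors)
      out[[paste0("via_", j)]] <- ifelse(result$predictors == j, NA,
                                         result$indirect[, j])
  out$indirect_total <- unname(result$indirect_total)
  out$decision <- unname(result$decision)
  out$p <- unname(result$significance)
  out
}
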