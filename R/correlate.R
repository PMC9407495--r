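#' Pearson correlation matrix with significance flags
#'
#' Pairwise-complete Pearson correlations among the selected variables, with
#' two-sided p-values from the exact t reference distribution,
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom. No
#' multiple-testing correction is applied: flags mark raw per-pair
#' significance (\code{"**"} for p < 0.01, \code{"*"} for 0.01 <= p < 0.05,
#' strict inequalities). Constant columns yield undefined correlations,
#' reported as \code{NA} with a warning.
#'
#' @param table A [sample_table()] (or plain data.frame).
#' @param variables Codes of numeric columns to correlate.
#' @param alphas Two significance levels, \code{c(star, double_star)}.
#' @return An object of class \code{"correlation_result"}: list with
#'   \code{variables}, symmetric matrices \code{r}, \code{p}, \code{n}
#'   (pairwise-complete counts) and \code{flags}.
#' @export
#' @examples
#' out <- generate_samples(default_synth_config())
#' cr <- pearson_matrix(out$table, c("X_AMT", "Y_QI", "b"))
#' cr$flags
pearson_matrix <- function(table, variables, alphas = c(0.05, 0.01)) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop("lookup error: unknown variable code(s): ",
         paste(missing_vars, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[variables])
  storage.mode(X) <- "double"
  k <- length(variables)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  n <- matrix(0L, k, k, dimnames = list(variables, variables))
  warned <- character(0)
  for (i in seq_len(k)) for (j in i:k) {
    ok <- stats::complete.cases(X[, c(i, j)])
    nn <- sum(ok)
    n[i, j] <- n[j, i] <- nn
    if (nn < 3) next
    xi <- X[ok, i]; xj <- X[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) {
      warned <- union(warned, variables[c(i, j)][c(stats::sd(xi) == 0,
                                                   stats::sd(xj) == 0)])
      next
    }
    rij <- stats::cor(xi, xj)
    r[i, j] <- r[j, i] <- rij
    if (i == j) { p[i, j] <- 0; next }
    tt <- rij * sqrt((nn - 2) / max(1 - rij^2, .Machine$double.eps))
    pij <- 2 * stats::pt(-abs(tt), df = nn - 2)
    p[i, j] <- p[j, i] <- pij
  }
  if (length(warned))
    warning("constant column(s), correlations undefined: ",
            paste(warned, collapse = ", "))
  res <- structure(list(variables = variables, r = r, p = p, n = n,
                        flags = NULL, alphas = alphas),
                   class = "correlation_result")
  flag_significance(res, alphas)
}

#' Fill the star flags of a correlation result
#'
#' @param result A \code{"correlation_result"}.
#' @param alphas \code{c(star_level, double_star_level)}; boundary p equal
#'   to a level is not significant.
#' @return The result with its \code{flags} matrix filled with
#'   \code{""}, \code{"*"} or \code{"**"}.
#' @export
flag_significance <- function(result, alphas = c(0.05, 0.01)) {
  stopifnot(inherits(result, "correlation_result"),
            length(alphas) == 2, alphas[1] > alphas[2])
  p <- result$p
  fl <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  fl[!is.na(p) & p < alphas[1]] <- "*"
  fl[!is.na(p) & p < alphas[2]] <- "**"
  diag(fl) <- ""
  result$flags <- fl
  result$alphas <- alphas
  result
}

#' @export
print.correlation_result <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations over", length(x$variables),
      "variables (n:", min(x$n[upper.tri(x$n)]), "-",
      max(x$n[upper.tri(x$n)]), ")\n")
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"),
                     " ", x$flags),
              nrow(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(m, quote = FALSE)
  invisible(x)
}

#' Long-format view of a correlation result
#'
#' @param result A \code{"correlation_result"}.
#' @return A data.frame with columns \code{var1}, \code{var2}, \code{r},
#'   \code{p}, \code{n}, \code{flag}, one row per unordered pair.
#' @export
correlation_long <- function(result) {
  v <- result$variables
  idx <- which(upper.tri(result$r), arr.ind = TRUE)
  data.frame(var1 = v[idx[, 1]], var2 = v[idx[, 2]],
             r = result$r[idx], p = result$p[idx], n = result$n[idx],
             flag = result$flags[idx],
             row.names = NULL, stringsAsFactors = FALSE)
}
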