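#' Specify a structural equation path model over observed variables
#'
#' Directed regressions among measured variables, with free covariances
#' allowed between exogenous variables (variables that receive no
#' regression). Each endogenous variable gets a free residual variance and
#' each exogenous variable a free variance. Latent variables are out of
#' scope: the model is an observed-variable path model.
#'
#' @param variables Ordered character vector of variable codes.
#' @param regressions Two-column data.frame (\code{source}, \code{target}),
#'   one row per free directed coefficient; the graph must be acyclic.
#' @param covariances Optional two-column data.frame (\code{v1}, \code{v2})
#'   of free covariances between exogenous variables. Default: all
#'   exogenous pairs free (the usual path-analysis convention).
#' @return Object of class \code{"sem_spec"}.
#' @export
#' @examples
#' sem_spec(c("X", "M", "Y"),
#'          data.frame(source = c("X", "M"), target = c("M", "Y")))
sem_spec <- function(variables, regressions,
                     covariances = NULL) {
  regressions <- as.data.frame(regressions, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target") %in% names(regressions)))
  bad <- setdiff(unique(c(regressions$source, regressions$target)), variables)
  if (length(bad))
    stop("edge endpoint(s) not among declared variables: ",
         paste(bad, collapse = ", "))
  endo <- unique(regressions$target)
  exo <- setdiff(variables, endo)
  # acyclicity by repeated sink elimination
  edges <- regressions
  nodes <- variables
  repeat {
    sinks <- setdiff(nodes, edges$source)
    if (!length(sinks)) break
    nodes <- setdiff(nodes, sinks)
    edges <- edges[!(edges$target %in% sinks), , drop = FALSE]
    if (!nrow(edges)) break
  }
  if (nrow(edges) > 0)
    stop("cyclic specification: ",
         paste(paste(edges$source, "->", edges$target), collapse = "; "))
  if (is.null(covariances)) {
    covariances <- if (length(exo) > 1) {
      cmb <- utils::combn(exo, 2)
      data.frame(v1 = cmb[1, ], v2 = cmb[2, ], stringsAsFactors = FALSE)
    } else data.frame(v1 = character(0), v2 = character(0))
  } else {
    covariances <- as.data.frame(covariances, stringsAsFactors = FALSE)
    names(covariances)[1:2] <- c("v1", "v2")
    bad <- setdiff(unique(unlist(covariances[1:2])), variables)
    if (length(bad))
      stop("covariance endpoint(s) not declared: ", paste(bad, collapse = ", "))
  }
  structure(list(variables = variables, regressions = regressions,
                 covariances = covariances, exogenous = exo,
                 endogenous = intersect(variables, endo)),
            class = "sem_spec")
}

#' Parse a path-model text grammar
#'
#' One statement per line: \code{"SRC -> DST"} for a regression,
#' \code{"A ~~ B"} for a free covariance. Blank lines and \code{#} comments
#' are ignored; variables are collected in order of first appearance unless
#' given.
#'
#' @param text Character scalar or vector of lines.
#' @param variables Optional explicit variable ordering.
#' @return A [sem_spec()].
#' @export
parse_sem_spec <- function(text, variables = NULL) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n"))
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  reg <- cov <- list()
  for (ln in lines) {
    if (grepl("->", ln, fixed = TRUE)) {
      pp <- trimws(strsplit(ln, "->", fixed = TRUE)[[1]])
      reg[[length(reg) + 1]] <- pp
    } else if (grepl("~~", ln, fixed = TRUE)) {
      pp <- trimws(strsplit(ln, "~~", fixed = TRUE)[[1]])
      cov[[length(cov) + 1]] <- pp
    } else stop("unparseable model line: \"", ln, "\"")
  }
  reg <- if (length(reg)) data.frame(source = vapply(reg, `[`, "", 1),
                                     target = vapply(reg, `[`, "", 2))
         else data.frame(source = character(0), target = character(0))
  covd <- if (length(cov)) data.frame(v1 = vapply(cov, `[`, "", 1),
                                      v2 = vapply(cov, `[`, "", 2))
          else NULL
  if (is.null(variables))
    variables <- unique(c(t(as.matrix(reg[, c("source", "target")])),
                          if (!is.null(covd)) t(as.matrix(covd))))
  sem_spec(variables, reg, covd)
}

# free-parameter table: type beta (target~source), psi (cov), var
sem_parameters <- function(spec) {
  pars <- data.frame(type = character(0), row = character(0),
                     col = character(0), stringsAsFactors = FALSE)
  if (nrow(spec$regressions))
    pars <- rbind(pars, data.frame(type = "beta",
                                   row = spec$regressions$target,
                                   col = spec$regressions$source))
  if (nrow(spec$covariances))
    pars <- rbind(pars, data.frame(type = "psi",
                                   row = spec$covariances$v1,
                                   col = spec$covariances$v2))
  pars <- rbind(pars, data.frame(type = "var", row = spec$variables,
                                 col = spec$variables))
  pars$label <- ifelse(pars$type == "beta",
                       paste0(pars$row, "~", pars$col),
                       ifelse(pars$type == "psi",
                              paste0(pars$row, "~~", pars$col),
                              paste0("V(", pars$row, ")")))
  pars
}

#' Model-implied covariance matrix
#'
#' Assembles \eqn{\Sigma(\theta) = (I - A)^{-1} \Psi (I - A)^{-T}} from the
#' structural coefficient matrix A (entry target,source) and the residual
#' (co)variance matrix \eqn{\Psi}.
#'
#' @param spec A [sem_spec()].
#' @param theta Named numeric vector over the spec's free parameters
#'   (labels \code{"T~S"}, \code{"A~~B"}, \code{"V(X)"}), or unnamed in
#'   parameter-table order.
#' @return Symmetric implied covariance matrix.
#' @export
implied_covariance <- function(spec, theta) {
  pars <- sem_parameters(spec)
  if (length(theta) != nrow(pars))
    stop("theta has ", length(theta), " values; spec has ", nrow(pars),
         " free parameters")
  if (!is.null(names(theta))) theta <- theta[pars$label]
  v <- spec$variables
  p <- length(v)
  A <- Psi <- matrix(0, p, p, dimnames = list(v, v))
  for (i in seq_len(nrow(pars))) {
    th <- theta[[i]]
    if (pars$type[i] == "beta") A[pars$row[i], pars$col[i]] <- th
    else if (pars$type[i] == "psi") {
      Psi[pars$row[i], pars$col[i]] <- th
      Psi[pars$col[i], pars$row[i]] <- th
    } else Psi[pars$row[i], pars$col[i]] <- th
  }
  IA <- solve(diag(p) - A)
  Sigma <- IA %*% Psi %*% t(IA)
  dimnames(Sigma) <- list(v, v)
  (Sigma + t(Sigma)) / 2
}

ml_discrepancy <- function(S, Sigma) {
  p <- nrow(S)
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ld_sigma <- 2 * sum(log(diag(ch)))
  ld_s <- determinant(S, logarithm = TRUE)$modulus
  val <- ld_sigma + sum(diag(S %*% chol2inv(ch))) - as.numeric(ld_s) - p
  if (!is.finite(val)) 1e10 else val
}

num_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- xm <- x; xp[i] <- x[i] + h; xm[i] <- x[i] - h
    (fn(xp) - fn(xm)) / (2 * h)
  }, numeric(1))
}

#' Fit a structural equation model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' \eqn{F = \ln|\Sigma(\theta)| + tr(S\Sigma(\theta)^{-1}) - \ln|S| - p}
#' by quasi-Newton iteration (variances on the log scale) from
#' least-squares start values; \eqn{\chi^2 = (n-1) F} at the optimum
#' (Wishart-likelihood convention). Standard errors come from the inverse
#' expected information; Wald two-sided p-values annotate the edges.
#'
#' @param data A [sample_table()] or data.frame (listwise-complete rows
#'   over the spec's variables are used), or \code{NULL} when
#'   \code{sample_cov} is given.
#' @param spec A [sem_spec()].
#' @param sample_cov Optional sample covariance matrix over the spec's
#'   variables.
#' @param n Sample size (required with \code{sample_cov}).
#' @return Object of class \code{"sem_fit"}: estimates, standardized
#'   estimates, standard errors, p-values, implied and sample covariance,
#'   chi2/df/CMIN-DF/RMSEA/GFI/AGFI, per-endogenous R2 and a convergence
#'   flag.
#' @export
fit_sem <- function(data = NULL, spec, sample_cov = NULL, n = NULL) {
  stopifnot(inherits(spec, "sem_spec"))
  v <- spec$variables
  if (is.null(sample_cov)) {
    df <- as.data.frame(data)
    missing_vars <- setdiff(v, names(df))
    if (length(missing_vars))
      stop("lookup error: variable(s) absent from data: ",
           paste(missing_vars, collapse = ", "))
    df <- df[stats::complete.cases(df[v]), v, drop = FALSE]
    n <- nrow(df)
    S <- stats::cov(as.matrix(df))
  } else {
    if (is.null(n)) stop("n is required with sample_cov")
    S <- as.matrix(sample_cov)[v, v]
  }
  p <- length(v)
  if (n <= p) stop("need n > number of variables (n = ", n, ", p = ", p, ")")
  if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("input error: sample covariance is not positive definite")

  pars <- sem_parameters(spec)
  m <- nrow(pars)
  if (n < 5 * m)
    warning("small sample: n = ", n, " < 5 x ", m, " free parameters")

  # least-squares start: per-endogenous OLS from S, sample moments elsewhere
  start <- numeric(m)
  resid_var <- stats::setNames(diag(S), v)
  for (tv in spec$endogenous) {
    preds <- spec$regressions$source[spec$regressions$target == tv]
    b <- solve(S[preds, preds, drop = FALSE], S[preds, tv])
    start[pars$type == "beta" & pars$row == tv] <-
      b[match(pars$col[pars$type == "beta" & pars$row == tv], preds)]
    resid_var[tv] <- max(S[tv, tv] - sum(b * S[preds, tv]), 1e-4 * S[tv, tv])
  }
  start[pars$type == "var"] <- resid_var[pars$row[pars$type == "var"]]
  if (any(pars$type == "psi"))
    start[pars$type == "psi"] <- S[cbind(pars$row[pars$type == "psi"],
                                         pars$col[pars$type == "psi"])]

  is_var <- pars$type == "var"
  to_opt <- function(theta) { theta[is_var] <- log(theta[is_var]); theta }
  from_opt <- function(x) { x[is_var] <- exp(x[is_var]); x }
  obj <- function(x) ml_discrepancy(S, implied_covariance(spec, from_opt(x)))

  run <- function(x0) stats::optim(x0, obj, method = "BFGS",
                                   control = list(maxit = 1000,
                                                  reltol = 1e-14))
  opt <- run(to_opt(start))
  grad_norm <- sqrt(sum(num_gradient(obj, opt$par)^2))
  if (grad_norm >= 1e-6) {
    set.seed(0)
    for (try in 1:5) {   # jittered restarts on non-convergence
      alt <- run(opt$par + stats::rnorm(m, 0, 0.05))
      if (alt$value <= opt$value) opt <- alt
      grad_norm <- sqrt(sum(num_gradient(obj, opt$par)^2))
      if (grad_norm < 1e-6) break
    }
  }
  converged <- grad_norm < 1e-6
  if (!converged)
    warning("SEM did not converge (gradient norm ", signif(grad_norm, 3), ")")

  theta <- stats::setNames(from_opt(opt$par), pars$label)
  Sigma <- implied_covariance(spec, theta)
  Fmin <- max(opt$value, 0)
  chi2 <- (n - 1) * Fmin
  df <- p * (p + 1) / 2 - m
  idx <- fit_indices(chi2, df, n, S, Sigma, m)

  # expected information on the natural parametrization
  se <- pv <- stats::setNames(rep(NA_real_, m), pars$label)
  info <- tryCatch({
    Sinv <- solve(Sigma)
    dS <- lapply(seq_len(m), function(i) {
      h <- max(1e-6, 1e-6 * abs(theta[i]))
      tp <- tm <- theta; tp[i] <- theta[i] + h; tm[i] <- theta[i] - h
      (implied_covariance(spec, tp) - implied_covariance(spec, tm)) / (2 * h)
    })
    I <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in i:m)
      I[i, j] <- I[j, i] <-
        (n - 1) / 2 * sum(diag(Sinv %*% dS[[i]] %*% Sinv %*% dS[[j]]))
    solve(I)
  }, error = function(e) NULL)
  if (!is.null(info)) {
    d <- diag(info); d[d < 0] <- NA
    se[] <- sqrt(d)
    pv[] <- 2 * stats::pnorm(-abs(theta / se))
  }

  # R2 per endogenous under the implied covariance
  r2 <- vapply(spec$endogenous, function(tv)
    1 - theta[[paste0("V(", tv, ")")]] / Sigma[tv, tv], numeric(1))

  fit <- structure(list(spec = spec, estimates = theta, se = se, p_values = pv,
                        standardized = NULL, implied_cov = Sigma,
                        sample_cov = S, n = n, chi2 = chi2, df = df,
                        cmin_df = idx[["cmin_df"]], rmsea = idx[["rmsea"]],
                        gfi = idx[["gfi"]], agfi = idx[["agfi"]],
                        r2 = r2, converged = converged,
                        grad_norm = grad_norm),
                   class = "sem_fit")
  standardize_fit(fit)
}

#' Fit indices for a covariance structure model
#'
#' \code{cmin_df} = chi2/df; \code{rmsea} =
#' \eqn{\sqrt{\max(\chi^2 - df, 0)/(df (n-1))}}; \code{gfi} =
#' \eqn{1 - tr[(\Sigma^{-1}(S-\Sigma))^2] / tr[(\Sigma^{-1}S)^2]};
#' \code{agfi} = \eqn{1 - [p(p+1)/(2 df)](1 - gfi)}. With df = 0 the
#' chi-square-based indices are undefined and returned as \code{NA}.
#'
#' @param chi2 Model chi-square.
#' @param df Model degrees of freedom.
#' @param n Sample size.
#' @param sample_cov,implied_cov Sample and implied covariance matrices.
#' @param free_params Number of free parameters (unused beyond checking).
#' @return Named vector \code{c(cmin_df, rmsea, gfi, agfi)}.
#' @export
fit_indices <- function(chi2, df, n, sample_cov, implied_cov, free_params) {
  stopifnot(df >= 0, n >= 2)
  S <- as.matrix(sample_cov); Sigma <- as.matrix(implied_cov)
  p <- nrow(S)
  W <- solve(Sigma)
  gfi <- 1 - sum(diag((W %*% (S - Sigma)) %*% (W %*% (S - Sigma)))) /
    sum(diag((W %*% S) %*% (W %*% S)))
  if (df > 0) {
    cmin_df <- chi2 / df
    rmsea <- sqrt(max(chi2 - df, 0) / (df * (n - 1)))
    agfi <- 1 - (p * (p + 1) / (2 * df)) * (1 - gfi)
  } else {
    cmin_df <- rmsea <- agfi <- NA_real_
  }
  c(cmin_df = cmin_df, rmsea = rmsea, gfi = gfi, agfi = agfi)
}

#' Standardize a fitted path model
#'
#' Each coefficient is multiplied by sd(source)/sd(target) under the
#' model-implied covariance; covariances become correlations and residual
#' variances fractions of the target's implied variance.
#'
#' @param fit A \code{"sem_fit"}.
#' @return The fit with its \code{standardized} vector filled.
#' @export
standardize_fit <- function(fit) {
  stopifnot(inherits(fit, "sem_fit"))
  pars <- sem_parameters(fit$spec)
  sds <- sqrt(diag(fit$implied_cov))
  if (any(sds <= 0)) stop("standardization error: zero implied variance")
  std <- fit$estimates
  for (i in seq_len(nrow(pars))) {
    if (pars$type[i] == "beta")
      std[i] <- fit$estimates[i] * sds[pars$col[i]] / sds[pars$row[i]]
    else if (pars$type[i] == "psi")
      std[i] <- fit$estimates[i] / (sds[pars$row[i]] * sds[pars$col[i]])
    else
      std[i] <- fit$estimates[i] / sds[pars$row[i]]^2
  }
  fit$standardized <- std
  fit
}

#' @export
print.sem_fit <- function(x, digits = 3, ...) {
  cat("SEM fit over", length(x$spec$variables), "variables, n =", x$n,
      if (!x$converged) " [NOT CONVERGED]", "\n")
  cat(sprintf("chi2 = %.3f on df = %d  CMIN/DF = %.3f  RMSEA = %.3f  GFI = %.3f  AGFI = %.3f\n",
              x$chi2, x$df,
              if (is.na(x$cmin_df)) NA else x$cmin_df,
              if (is.na(x$rmsea)) NA else x$rmsea, x$gfi,
              if (is.na(x$agfi)) NA else x$agfi))
  print(round(data.frame(estimate = x$estimates, std = x$standardized,
                         se = x$se, p = x$p_values), digits))
  invisible(x)
}

#' Fig-style edge table of a fitted model
#'
#' @param fit A \code{"sem_fit"}.
#' @return Data.frame (source, target, standardized, p, stars) over the
#'   regression edges.
#' @export
sem_edge_table <- function(fit) {
  pars <- sem_parameters(fit$spec)
  b <- pars$type == "beta"
  pv <- fit$p_values[b]
  data.frame(source = pars$col[b], target = pars$row[b],
             standardized = unname(fit$standardized[b]), p = unname(pv),
             stars = ifelse(is.na(pv), "",
                            ifelse(pv < 0.01, "**",
                                   ifelse(pv < 0.05, "*", "ns"))),
             stringsAsFactors = FALSE)
}

#' Direct, indirect and total standardized effects
#'
#' With B the standardized coefficient matrix, total effects are read from
#' \eqn{(I-B)^{-1} - I}; the indirect effect is total minus the direct
#' edge; per-mediator contributions attribute each multi-edge path to its
#' first intermediate node, so for a single-mediator chain the contribution
#' is the product of the two standardized edge coefficients and the
#' contributions always sum to the indirect effect.
#'
#' @param fit A \code{"sem_fit"} (standardized), or a data.frame of edges
#'   (source, target, value) for direct use on known path values.
#' @return Object of class \code{"effects_table"}: data.frame with columns
#'   source, target, direct, indirect, total; attribute
#'   \code{"mediators"} holds the per-mediator contribution list.
#' @export
#' @examples
#' edges <- data.frame(source = c("X_AMAT", "X_MAW", "Y_CGC"),
#'                     target = c("Y_CGC", "Y_CGC", "a"),
#'                     value = c(-0.50, 0.41, 0.88))
#' effects_decomposition(edges)
effects_decomposition <- function(fit) {
  edges <- if (inherits(fit, "sem_fit")) {
    pars <- sem_parameters(fit$spec)
    b <- pars$type == "beta"
    data.frame(source = pars$col[b], target = pars$row[b],
               value = unname(fit$standardized[b]), stringsAsFactors = FALSE)
  } else {
    ed <- as.data.frame(fit, stringsAsFactors = FALSE)
    stopifnot(all(c("source", "target", "value") %in% names(ed)))
    ed
  }
  vars <- unique(c(edges$source, edges$target))
  p <- length(vars)
  B <- matrix(0, p, p, dimnames = list(vars, vars))
  B[cbind(match(edges$target, vars), match(edges$source, vars))] <- edges$value
  IB <- tryCatch(solve(diag(p) - B),
                 error = function(e)
                   stop("cyclicity/identification error: (I - B) is singular"))
  total <- IB - diag(p)      # entry (target, source)
  out <- expand.grid(source = vars, target = vars,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- out[out$source != out$target, ]
  out$direct <- B[cbind(match(out$target, vars), match(out$source, vars))]
  out$total <- total[cbind(match(out$target, vars), match(out$source, vars))]
  out$indirect <- out$total - out$direct
  rownames(out) <- NULL
  med <- lapply(seq_len(nrow(out)), function(i) {
    s <- out$source[i]; t <- out$target[i]
    first <- edges[edges$source == s & edges$target != t, , drop = FALSE]
    contrib <- stats::setNames(
      vapply(seq_len(nrow(first)), function(j)
        first$value[j] * total[t, first$target[j]], numeric(1)),
      first$target)
    contrib[contrib != 0]
  })
  names(med) <- paste(out$source, "->", out$target)
  out <- out[, c("source", "target", "direct", "indirect", "total")]
  attr(out, "mediators") <- med
  class(out) <- c("effects_table", "data.frame")
  out
}

#' Look up one source-target effect
#'
#' @param effects An \code{"effects_table"}.
#' @param source,target Variable codes.
#' @return List with \code{direct}, \code{indirect}, \code{total} and the
#'   named per-mediator \code{contributions}.
#' @export
effect_of <- function(effects, source, target) {
  i <- which(effects$source == source & effects$target == target)
  if (!length(i))
    return(list(direct = 0, indirect = 0, total = 0,
                contributions = numeric(0)))
  list(direct = effects$direct[i], indirect = effects$indirect[i],
       total = effects$total[i],
       contributions = attr(effects, "mediators")[[paste(source, "->", target)]])
}

#' Select fitted models by fit-index thresholds
#'
#' Strict inequalities: CMIN/DF below, RMSEA below, AGFI above their
#' thresholds. Models whose chi-square indices are undefined (df = 0) fail
#' selection; input order is preserved.
#'
#' @param fits List of \code{"sem_fit"} objects.
#' @param cmin_df_max,rmsea_max,agfi_min Thresholds (defaults 1, 0.08, 0.9).
#' @return The accepted sublist, with attribute \code{"accepted"} giving
#'   the logical selection vector.
#' @export
select_models <- function(fits, cmin_df_max = 1, rmsea_max = 0.08,
                          agfi_min = 0.9) {
  if (inherits(fits, "sem_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) {
    isTRUE(f$converged) && !is.na(f$cmin_df) && !is.na(f$rmsea) &&
      !is.na(f$agfi) && f$cmin_df < cmin_df_max && f$rmsea < rmsea_max &&
      f$agfi > agfi_min
  }, logical(1))
  out <- fits[ok]
  attr(out, "accepted") <- ok
  out
}
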