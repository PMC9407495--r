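#' Synthetic sample tables with known causal structure
#'
#' The generator realizes the causal chain the structural equation models
#' assume: altitude (exogenous driver) -> annual climate factors ->
#' flavonoid contents -> CIELAB peel color, with optional direct
#' climate -> color edges. All structural equations are linear with
#' independent Gaussian noise, built in standardized units (every variable
#' unit population variance when noise SDs are left automatic) and then
#' mapped to presentation units by fixed per-variable affine scales, which
#' leaves every correlation and standardized path untouched.
#'
#' @name synth
NULL

#' Default synthetic-data configuration
#'
#' Six geographic groups occupying contiguous altitude bands over
#' 201--2188 m, 26 samples in total. Temperature-like factors load
#' negatively on altitude and wind-like factors positively; the color
#' equations are seeded from the study-scale standardized coefficients
#' (peonidin 3-O-glucoside -> L* 0.75, maximum wind -> L* 0.21,
#' cyanidin 3-O-glucoside driven by annual mean maximum temperature -0.50
#' and maximum wind 0.41, quercitrin -> b* -0.77), with the remaining
#' magnitudes chosen to keep every standardized variance below one.
#' Noise SDs set to \code{NA} are resolved automatically so each variable
#' has unit variance in standardized units.
#'
#' @param seed Integer seed stored in the config; [generate_samples()] uses
#'   it for all randomness.
#' @return A list of class \code{"synth_config"}.
#' @export
#' @examples
#' cfg <- default_synth_config()
#' sum(cfg$samples_per_group)  # 26
default_synth_config <- function(seed = 1L) {
  an <- analyte_catalog()$code
  cl <- climate_catalog()$code
  ax <- color_axes()

  climate_slope <- c(X_AMT = -0.85, X_AMAT = -0.85, X_AMIT = -0.80,
                     X_RH = -0.45, X_AAP = -0.50, X_MW = 0.50,
                     X_MAW = 0.55, X_EW = 0.45, X_ASD = 0.35, X_ASP = 0.40)

  fl <- matrix(0, length(an), length(cl), dimnames = list(an, cl))
  fl["Y_HY", "X_RH"] <- -0.72
  fl["Y_LU", "X_ASD"] <- -0.40
  fl["Y_KP", "X_AMAT"] <- -0.20
  fl["Y_QI", c("X_AMT", "X_MW")] <- c(-0.44, -0.30)
  fl["Y_C", "X_AMT"] <- -0.20
  fl["Y_RU", "X_ASD"] <- 0.25
  fl["Y_CA", "X_MAW"] <- 0.52
  fl["Y_QU", "X_AMT"] <- -0.30
  fl["Y_HE", "X_AMAT"] <- 0.21
  fl["Y_AP", c("X_AMAT", "X_ASD")] <- c(-0.72, -0.52)
  fl["Y_PH", c("X_MAW", "X_ASD")] <- c(0.71, -0.70)
  fl["Y_PG", c("X_AMAT", "X_MAW")] <- c(-0.45, 0.45)
  fl["Y_CGT", "X_AMIT"] <- -0.39
  fl["Y_CGC", c("X_AMAT", "X_MAW")] <- c(-0.50, 0.41)
  fl["Y_CSA", "X_AMAT"] <- -0.56

  cd <- matrix(0, length(ax), length(cl), dimnames = list(ax, cl))
  cd["L", "X_MAW"] <- 0.21
  cd["a", c("X_AMAT", "X_MAW")] <- c(-0.15, 0.12)
  cd["b", c("X_AAP", "X_AMT")] <- c(0.16, 0.10)

  cf <- matrix(0, length(ax), length(an), dimnames = list(ax, an))
  cf["L", "Y_PG"] <- 0.75
  cf["a", "Y_CGC"] <- 0.75
  cf["b", "Y_QI"] <- -0.77

  scales <- rbind(
    data.frame(variable = cl,
               center = c(12, 18, 6, 60, 600, 2, 8, 15, 2000, 50),
               scale = c(3, 3, 3, 8, 150, 0.4, 1.2, 2, 300, 8)),
    data.frame(variable = an,
               center = c(14, 1.8, 1.6, 20, 8, 7.5, 8, 1.8, 4.3, 2.6,
                          5.3, 5.4, 8.5, 8.3, 6.6),
               scale = c(2, 0.25, 0.2, 3, 1.2, 1, 1.2, 0.25, 0.6, 0.4,
                         0.8, 0.8, 1.2, 1.2, 1)),
    data.frame(variable = ax, center = c(83, 10, 15), scale = c(2.5, 4, 4))
  )

  structure(list(
    n_groups = 6L,
    samples_per_group = c(5L, 4L, 4L, 4L, 4L, 5L),
    altitude_range = c(201, 2188),
    seed = as.integer(seed),
    climate_slope = climate_slope,
    climate_noise_sd = stats::setNames(rep(NA_real_, length(cl)), cl),
    flavonoid_loadings = fl,
    flavonoid_noise_sd = stats::setNames(rep(NA_real_, length(an)), an),
    color_direct_climate = cd,
    color_flavonoid_loadings = cf,
    color_noise_sd = stats::setNames(rep(NA_real_, length(ax)), ax),
    scales = scales
  ), class = "synth_config")
}

validate_synth_config <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (any(config$samples_per_group < 1))
    stop("config error: samples_per_group must be >= 1")
  if (diff(config$altitude_range) <= 0)
    stop("config error: altitude_range must satisfy min < max")
  sds <- c(config$climate_noise_sd, config$flavonoid_noise_sd,
           config$color_noise_sd)
  if (any(sds < 0, na.rm = TRUE))
    stop("config error: noise SDs must be >= 0")
  invisible(config)
}

# Resolve NA noise SDs to the unit-variance completion and return the
# standardized (unit altitude variance) covariance over
# (altitude, climate, flavonoids, color). The structural coefficient matrix
# is strictly lower-triangular in the causal order, so the reduced form is
# Sigma = (I - A)^-1 Psi (I - A)^-T.
synth_model_matrices <- function(config) {
  validate_synth_config(config)
  an <- rownames(config$flavonoid_loadings)
  cl <- names(config$climate_slope)
  ax <- rownames(config$color_direct_climate)
  vars <- c("altitude", cl, an, ax)
  p <- length(vars)
  A <- matrix(0, p, p, dimnames = list(vars, vars))
  A[cl, "altitude"] <- config$climate_slope
  A[an, cl] <- config$flavonoid_loadings
  A[ax, cl] <- config$color_direct_climate
  A[ax, an] <- config$color_flavonoid_loadings

  psi <- stats::setNames(numeric(p), vars)
  psi["altitude"] <- 1
  noise <- c(config$climate_noise_sd, config$flavonoid_noise_sd,
             config$color_noise_sd)
  # walk variables in causal order; each auto SD completes variance to 1
  Sigma <- matrix(0, p, p, dimnames = list(vars, vars))
  Sigma["altitude", "altitude"] <- 1
  for (v in c(cl, an, ax)) {
    parents <- vars[A[v, ] != 0]
    expl <- if (length(parents))
      drop(A[v, parents, drop = FALSE] %*% Sigma[parents, parents] %*%
             t(A[v, parents, drop = FALSE]))
    else 0
    sd_v <- noise[[v]]
    if (is.na(sd_v)) {
      if (expl >= 1)
        stop("config error: explained standardized variance of '", v,
             "' is ", round(expl, 3), " >= 1; no unit-variance completion")
      sd_v <- sqrt(1 - expl)
    }
    psi[v] <- sd_v^2
    cov_vp <- drop(Sigma[, vars, drop = FALSE] %*% A[v, ])
    Sigma[, v] <- Sigma[v, ] <- cov_vp
    Sigma[v, v] <- expl + sd_v^2
  }
  list(vars = vars, A = A, psi = psi, Sigma = Sigma,
       noise_sd = stats::setNames(sqrt(psi), vars))
}

#' Model-implied correlation matrix of a synthetic configuration
#'
#' Closed-form correlation matrix over altitude, climate factors, flavonoids
#' and color axes implied by the linear-Gaussian generator (invariant to the
#' presentation-unit scales).
#'
#' @param config A [default_synth_config()]-style configuration.
#' @return A symmetric correlation matrix.
#' @export
synth_implied_correlation <- function(config = default_synth_config()) {
  Sigma <- synth_model_matrices(config)$Sigma
  stats::cov2cor(Sigma)
}

#' Generate a synthetic sample table with ground truth
#'
#' Deterministic given \code{config$seed}. Groups occupy contiguous altitude
#' bands; within a band altitudes are uniform, so the marginal altitude
#' distribution is uniform over \code{altitude_range}.
#'
#' @param config A [default_synth_config()]-style configuration.
#' @return A list with elements \code{table} (a [sample_table()]) and
#'   \code{truth} (class \code{"synth_truth"}: standardized structural
#'   paths, the implied correlation matrix, and the implied
#'   climate-to-color per-mediator indirect effects).
#' @export
#' @examples
#' out <- generate_samples(default_synth_config(seed = 7))
#' nrow(out$table)
generate_samples <- function(config = default_synth_config()) {
  mm <- synth_model_matrices(config)
  an <- rownames(config$flavonoid_loadings)
  cl <- names(config$climate_slope)
  ax <- rownames(config$color_direct_climate)

  sizes <- rep_len(config$samples_per_group, config$n_groups)
  n <- sum(sizes)
  lo <- config$altitude_range[1]; hi <- config$altitude_range[2]
  edges <- seq(lo, hi, length.out = config$n_groups + 1)

  set.seed(config$seed)
  group <- rep(paste0("G", seq_len(config$n_groups)), sizes)
  altitude <- unlist(lapply(seq_len(config$n_groups), function(g)
    sort(stats::runif(sizes[g], edges[g], edges[g + 1]))))
  z_alt <- (altitude - (lo + hi) / 2) / ((hi - lo) / sqrt(12))

  std <- matrix(NA_real_, n, length(mm$vars),
                dimnames = list(NULL, mm$vars))
  std[, "altitude"] <- z_alt
  for (v in c(cl, an, ax)) {
    parents <- mm$vars[mm$A[v, ] != 0]
    mu <- if (length(parents))
      drop(std[, parents, drop = FALSE] %*% mm$A[v, parents]) else rep(0, n)
    eps <- if (mm$noise_sd[[v]] > 0) stats::rnorm(n, 0, mm$noise_sd[[v]]) else 0
    std[, v] <- mu + eps
  }

  df <- data.frame(sample_id = sprintf("S%02d", seq_len(n)), group = group,
                   altitude = altitude, stringsAsFactors = FALSE)
  sc <- config$scales
  for (v in c(cl, an, ax)) {
    i <- match(v, sc$variable)
    df[[v]] <- sc$center[i] + sc$scale[i] * std[, v]
  }
  tab <- sample_table(df)

  # standardized structural paths under the implied variances
  sds <- sqrt(diag(mm$Sigma))
  idx <- which(mm$A != 0, arr.ind = TRUE)
  paths <- data.frame(
    source = mm$vars[idx[, 2]], target = mm$vars[idx[, 1]],
    value = mm$A[idx] * sds[idx[, 2]] / sds[idx[, 1]],
    stringsAsFactors = FALSE)
  paths <- paths[order(match(paths$target, mm$vars),
                       match(paths$source, mm$vars)), ]
  rownames(paths) <- NULL

  ind <- do.call(rbind, lapply(cl, function(cc) do.call(rbind, lapply(ax,
    function(aa) {
      med <- an[config$flavonoid_loadings[, cc] != 0 &
                config$color_flavonoid_loadings[aa, ] != 0]
      if (!length(med)) return(NULL)
      p1 <- paths$value[match(paste(cc, med), paste(paths$source, paths$target))]
      p2 <- paths$value[match(paste(med, aa), paste(paths$source, paths$target))]
      data.frame(climate = cc, axis = aa, mediator = med, value = p1 * p2,
                 stringsAsFactors = FALSE)
    }))))

  truth <- structure(list(standardized_paths = paths,
                          implied_correlation = stats::cov2cor(mm$Sigma),
                          implied_indirects = ind),
                     class = "synth_truth")
  list(table = tab, truth = truth)
}

#' Direct, indirect and total causal effect in a synthetic truth
#'
#' Effects are path sums over the generating DAG in standardized units: the
#' direct effect is the single edge coefficient (0 when absent), the
#' indirect effect is the sum over all directed multi-edge paths of the
#' products of their edge coefficients, and total = direct + indirect.
#'
#' @param truth A \code{"synth_truth"} from [generate_samples()].
#' @param source,target Variable codes known to the truth.
#' @return Named numeric vector \code{c(direct, indirect, total)}.
#' @export
truth_effects <- function(truth, source, target) {
  paths <- truth$standardized_paths
  known <- unique(c(paths$source, paths$target))
  if (!source %in% known || !target %in% known)
    stop("lookup error: unknown code(s): ",
         paste(setdiff(c(source, target), known), collapse = ", "))
  direct <- sum(paths$value[paths$source == source & paths$target == target])
  total <- sum_path_products(paths, source, target)
  c(direct = direct, indirect = total - direct, total = total)
}

# sum of edge-coefficient products over all directed source->target paths
sum_path_products <- function(paths, source, target) {
  if (source == target) return(1)
  out <- paths[paths$source == source, ]
  if (!nrow(out)) return(0)
  sum(vapply(seq_len(nrow(out)), function(i)
    out$value[i] * sum_path_products(paths, out$target[i], target),
    numeric(1)))
}
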