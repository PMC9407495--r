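test_that("decision coefficient reproduces the published path table cells", {
  # D = 2 P r - P^2 against internally consistent printed cells (3 d.p.)
  cells <- rbind(
    c(P = -0.720, r = -0.720, D = 0.518),   # hyperoside ~ humidity
    c(P = -0.729, r = -0.729, D = 0.531),   # lightness ~ mean max temp
    c(P = -0.723, r = -0.470, D = 0.157),   # apigenin ~ mean max temp
    c(P = -0.523, r = -0.173, D = -0.093),  # apigenin ~ sunshine duration
    c(P = -0.476, r = -0.476, D = 0.227),   # cyanidin glucoside ~ max temp
    c(P = -0.559, r = -0.559, D = 0.312))   # cyanidin syringic ~ max temp
  for (i in seq_len(nrow(cells)))
    expect_equal(round(decision_coefficient(cells[[i, "P"]], cells[[i, "r"]]), 3),
                 cells[[i, "D"]])
  # single-predictor algebra: P = r gives D = r^2
  expect_equal(decision_coefficient(0.6, 0.6), 0.36)
})

test_that("correlation-level decomposition reproduces the two-predictor block", {
  # apigenin on (mean max temperature, sunshine duration); the predictor
  # intercorrelation -0.484 is recovered from printed indirect / direct
  pa <- path_decompose(response = "Y_AP",
                       predictors = c("X_AMAT", "X_ASD"),
                       r_xy = c(-0.470, -0.173),
                       R_xx = matrix(c(1, -0.484, -0.484, 1), 2))
  expect_equal(round(unname(pa$direct), 3), c(-0.723, -0.523))
  expect_equal(round(unname(pa$indirect_total), 3), c(0.253, 0.350))
  expect_equal(round(unname(pa$decision), 3), c(0.157, -0.093))
  # exact reconstruction identity
  expect_equal(unname(pa$direct + pa$indirect_total), c(-0.470, -0.173),
               tolerance = 1e-12)
  # orthogonal predictors: P = r, indirect = 0
  pa2 <- path_decompose(response = "y", predictors = c("x1", "x2"),
                        r_xy = c(0.4, -0.2), R_xx = diag(2))
  expect_equal(unname(pa2$direct), c(0.4, -0.2))
  expect_equal(unname(pa2$indirect_total), c(0, 0))
})

test_that("r = direct + total indirect holds to machine precision (property)", {
  set.seed(33)
  for (rep in 1:1000) {
    k <- sample(1:6, 1)
    R <- random_corr(k)
    beta <- rnorm(k)
    r_xy <- drop(R %*% beta)   # consistent correlation system
    pa <- suppressWarnings(
      path_decompose(response = "y", predictors = paste0("x", 1:k),
                     r_xy = r_xy, R_xx = R))
    expect_equal(unname(pa$direct + pa$indirect_total), unname(r_xy),
                 tolerance = 1e-10)
    expect_equal(unname(pa$direct), beta, tolerance = 1e-8)
  }
})

test_that("direct coefficients equal standardized OLS from raw data", {
  set.seed(12)
  n <- 80
  df <- data.frame(sample_id = paste0("s", 1:n), Y_HY = seq_len(n),
                   X_AMT = rnorm(n), X_RH = rnorm(n))
  df$X_ASD <- 0.5 * df$X_AMT + rnorm(n)
  df$L <- 2 - 0.8 * df$X_AMT + 0.4 * df$X_RH + rnorm(n)
  preds <- c("X_AMT", "X_RH", "X_ASD")
  pa <- path_decompose(sample_table(df), "L", preds)
  # oracle: normal equations on z-scored data
  Z <- scale(as.matrix(df[preds])); zy <- scale(df$L)
  beta_std <- unname(drop(solve(crossprod(Z), crossprod(Z, zy))))
  expect_equal(unname(pa$direct), beta_std, tolerance = 1e-8)
  # indirect (i,j) = r_ij * P_j
  expect_equal(pa$indirect["X_AMT", "X_ASD"],
               cor(df$X_AMT, df$X_ASD) * pa$direct[["X_ASD"]])
  # |P| > 1 triggers a collinearity warning (r = 0.9 between predictors
  # with very different response correlations forces |P| > 1)
  expect_warning(path_decompose(response = "L", predictors = c("x1", "x2"),
                                r_xy = c(0.9, 0.1),
                                R_xx = matrix(c(1, 0.9, 0.9, 1), 2)),
                 "collinearity")
})

test_that("singular predictor sets are refused with the offending set named", {
  R <- matrix(c(1, 1, 1, 1), 2)
  expect_error(path_decompose(response = "y", predictors = c("a", "b"),
                              r_xy = c(0.5, 0.5), R_xx = R),
               "collinearity.*a, b")
})

test_that("factor ranking sorts by decision coefficient with stable ties", {
  pa <- path_decompose(response = "Y_AP", predictors = c("X_AMAT", "X_ASD"),
                       r_xy = c(-0.470, -0.173),
                       R_xx = matrix(c(1, -0.484, -0.484, 1), 2))
  rk <- rank_factors(pa)
  expect_equal(rk$code, c("X_AMAT", "X_ASD"))
  expect_equal(rk$interpretation, c("promoting", "inhibiting"))
  pa2 <- path_decompose(response = "y", predictors = c("x1", "x2"),
                        r_xy = c(0.3, 0.3), R_xx = diag(2))
  expect_equal(rank_factors(pa2)$code, c("x1", "x2"))  # input order on ties
  pa3 <- path_decompose(response = "y", predictors = "x1",
                        r_xy = 0.5, R_xx = matrix(1))
  expect_equal(nrow(rank_factors(pa3)), 1L)
})

test_that("stepwise screening recovers a single true predictor", {
  # a 0.8 standardized effect at n = 100 is found essentially always;
  # spurious co-entries occur at the per-candidate entry rate (about
  # 1 - 0.95^9 across the nine null candidates), which is inherent to
  # per-coefficient entry testing
  hits <- 0L; extras <- integer(100)
  for (r in 1:100) {
    cfg <- single_effect_config(2000 + r)
    cfg$n_groups <- 5L; cfg$samples_per_group <- 20L
    tab <- generate_samples(cfg)$table
    tr <- stepwise_select(tab, "Y_HY", climate_catalog()$code)
    if ("X_RH" %in% tr$final_set) hits <- hits + 1L
    extras[r] <- length(setdiff(tr$final_set, "X_RH"))
  }
  expect_gte(hits, 95L)
  expect_lt(mean(extras), 1)
})

test_that("stepwise on pure noise enters candidates at about the entry rate", {
  # with 10 independent null candidates the final set is empty with
  # probability ~0.95^10 = 0.60; each candidate is kept in ~5% of runs
  empty <- 0L
  kept <- integer(0)
  for (r in 1:100) {
    cfg <- single_effect_config(5000 + r, effect = 0)
    cfg$n_groups <- 5L; cfg$samples_per_group <- 20L
    tab <- generate_samples(cfg)$table
    tr <- stepwise_select(tab, "Y_HY", climate_catalog()$code)
    if (length(tr$final_set) == 0) empty <- empty + 1L
    kept <- c(kept, tr$final_set)
  }
  expect_gte(empty, 45L)            # binomial(100, 0.60) lower band
  expect_lt(length(kept) / (100 * 10), 0.10)  # per-candidate null rate
  cfg <- single_effect_config(1)
  tab <- generate_samples(cfg)$table
  expect_error(stepwise_select(tab, "Y_HY", climate_catalog()$code,
                               p_enter = 0.10, p_remove = 0.05),
               "parameter error")
  # p_enter = p_remove = 1 includes everything; p_enter -> 0 selects none
  tr_all <- stepwise_select(tab, "Y_HY", c("X_RH", "X_AMT", "X_MW"),
                            p_enter = 1, p_remove = 1)
  expect_setequal(tr_all$final_set, c("X_RH", "X_AMT", "X_MW"))
  tr_none <- stepwise_select(tab, "Y_HY", climate_catalog()$code,
                             p_enter = 1e-12, p_remove = 1e-12)
  expect_length(tr_none$final_set, 0L)
})
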