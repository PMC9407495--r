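fig4c_spec <- function() parse_sem_spec("
  X_AMAT -> Y_CGC
  X_MAW  -> Y_CGC
  Y_CGC  -> a
  X_AMAT -> a
  X_MAW  -> a
  X_AMAT ~~ X_MAW")

test_that("model grammar and acyclicity checks work", {
  sp <- fig4c_spec()
  expect_s3_class(sp, "sem_spec")
  expect_setequal(sp$exogenous, c("X_AMAT", "X_MAW"))
  expect_setequal(sp$endogenous, c("Y_CGC", "a"))
  expect_error(parse_sem_spec("A -> B\nB -> A"), "cyclic")
  expect_error(parse_sem_spec("A -+ B"), "unparseable")
  expect_error(sem_spec(c("A"), data.frame(source = "A", target = "Z")),
               "not among declared")
})

test_that("implied covariance matches closed forms and a simulation oracle", {
  sp <- sem_spec(c("X", "Y"), data.frame(source = "X", target = "Y"))
  # single edge beta with unit variances: cov(X, Y) = beta
  Sig <- implied_covariance(sp, c("Y~X" = 0.6, "V(X)" = 1, "V(Y)" = 1))
  expect_equal(Sig["X", "Y"], 0.6)
  expect_equal(Sig["Y", "Y"], 1 + 0.36)
  # all edges zero: diagonal of variances (plus exogenous covariances)
  Sig0 <- implied_covariance(sp, c("Y~X" = 0, "V(X)" = 2, "V(Y)" = 3))
  expect_equal(Sig0, diag(c(X = 2, Y = 3)), ignore_attr = TRUE)
  expect_error(implied_covariance(sp, c(1, 2)), "free parameters")
  # Monte-Carlo oracle on a 3-variable chain
  sp3 <- sem_spec(c("X", "M", "Y"),
                  data.frame(source = c("X", "M"), target = c("M", "Y")))
  th <- c("M~X" = 0.8, "Y~M" = -0.5, "V(X)" = 1, "V(M)" = 0.5, "V(Y)" = 2)
  Sig3 <- implied_covariance(sp3, th)
  set.seed(99)
  n <- 1e6
  X <- rnorm(n); M <- 0.8 * X + rnorm(n, 0, sqrt(0.5))
  Y <- -0.5 * M + rnorm(n, 0, sqrt(2))
  expect_lt(max(abs(cov(cbind(X, M, Y)) - Sig3)), 0.01)
})

test_that("saturated and just-identified models fit perfectly", {
  out <- generate_samples(default_synth_config(15))
  sat <- sem_spec(c("X_AMAT", "X_MAW", "Y_CGC"),
                  data.frame(source = character(0), target = character(0)))
  fs <- suppressWarnings(fit_sem(out$table, sat))  # small-n warning expected
  expect_equal(fs$chi2, 0, tolerance = 1e-8)
  expect_lt(max(abs(fs$implied_cov - fs$sample_cov)), 1e-8)
  expect_equal(fs$df, 0L)
  expect_true(is.na(fs$cmin_df) && is.na(fs$rmsea))
  expect_equal(fs$gfi, 1, tolerance = 1e-8)
  # just-identified mediation triangle: df = 0, chi2 ~ 0 for any data
  ji <- sem_spec(c("X_AMT", "Y_QI", "b"),
                 data.frame(source = c("X_AMT", "Y_QI", "X_AMT"),
                            target = c("Y_QI", "b", "b")))
  fj <- suppressWarnings(fit_sem(out$table, ji))
  expect_equal(fj$df, 0L)
  expect_lt(fj$chi2, 1e-6)
})

test_that("fit indices follow their closed forms", {
  S <- diag(3)
  idx <- fit_indices(chi2 = 4, df = 2, n = 101, S, S, free_params = 4)
  expect_equal(unname(idx["rmsea"]), sqrt(2 / 200))
  expect_equal(unname(idx["cmin_df"]), 2)
  expect_equal(unname(idx["gfi"]), 1)
  expect_equal(unname(idx["agfi"]), 1)
  # chi2 <= df clamps rmsea at zero
  expect_equal(unname(fit_indices(1.5, 2, 50, S, S, 4)["rmsea"]), 0)
  # df = 0: chi-square indices undefined
  idx0 <- fit_indices(0, 0, 50, S, S, 6)
  expect_true(is.na(idx0["cmin_df"]) && is.na(idx0["rmsea"]))
})

test_that("standardization is scale invariant and matches pre-standardized data", {
  cfg <- default_synth_config(23)
  cfg$n_groups <- 5L; cfg$samples_per_group <- 60L
  tab <- generate_samples(cfg)$table
  sp <- fig4c_spec()
  f1 <- fit_sem(tab, sp)
  tab2 <- tab
  tab2$Y_CGC <- tab2$Y_CGC * 2          # double one variable's scale
  tab2$a <- tab2$a / 5 + 100
  f2 <- fit_sem(tab2, sp)
  expect_equal(f2$standardized, f1$standardized, tolerance = 1e-6)
  expect_equal(f2$chi2, f1$chi2, tolerance = 1e-6)
  # pre-standardized data: standardized == unstandardized estimates
  zt <- tab
  for (v in c("X_AMAT", "X_MAW", "Y_CGC", "a")) zt[[v]] <- scale(zt[[v]])[, 1]
  fz <- fit_sem(zt, sp)
  b <- grepl("~", names(fz$estimates), fixed = TRUE)
  expect_equal(fz$estimates[b], fz$standardized[b], tolerance = 1e-6)
})

test_that("adding a free parameter never increases chi2 (nesting)", {
  out <- generate_samples(default_synth_config(31))
  base <- parse_sem_spec("
    X_AMAT -> Y_CGC
    Y_CGC -> a
    X_AMAT ~~ X_MAW
    X_MAW -> Y_PG", variables = c("X_AMAT", "X_MAW", "Y_CGC", "Y_PG", "a"))
  bigger <- parse_sem_spec("
    X_AMAT -> Y_CGC
    X_MAW -> Y_CGC
    Y_CGC -> a
    X_AMAT -> a
    X_AMAT ~~ X_MAW
    X_MAW -> Y_PG", variables = c("X_AMAT", "X_MAW", "Y_CGC", "Y_PG", "a"))
  f1 <- suppressWarnings(fit_sem(out$table, base))
  f2 <- suppressWarnings(fit_sem(out$table, bigger))
  expect_lte(f2$chi2, f1$chi2 + 1e-6)
})

test_that("effect decomposition matches exhaustive path enumeration", {
  # published a*-model chain: indirect = product of standardized edges
  edges_a <- data.frame(source = c("X_AMAT", "X_MAW", "Y_CGC", "X_AMAT",
                                   "X_MAW"),
                        target = c("Y_CGC", "Y_CGC", "a", "a", "a"),
                        value = c(-0.50, 0.41, 0.88, -0.46, 0.36))
  ef <- effects_decomposition(edges_a)
  amat <- effect_of(ef, "X_AMAT", "a")
  expect_equal(round(amat$indirect, 2), -0.44)
  expect_equal(amat$total, -0.46 + (-0.50) * 0.88, tolerance = 1e-12)
  maw <- effect_of(ef, "X_MAW", "a")
  expect_equal(round(maw$indirect, 2), 0.36)
  # lightness model: 0.45 * 0.75 = 0.3375, printed as 0.34
  edges_l <- data.frame(source = c("X_MAW", "Y_PG", "X_MAW"),
                        target = c("Y_PG", "L", "L"),
                        value = c(0.45, 0.75, 0.21))
  efl <- effects_decomposition(edges_l)
  mawl <- effect_of(efl, "X_MAW", "L")
  expect_equal(mawl$indirect, 0.3375, tolerance = 1e-12)
  expect_equal(mawl$total, 0.5475, tolerance = 1e-12)
  expect_equal(unname(mawl$contributions["Y_PG"]), 0.3375)
  # absent pair: all-zero effect
  none <- effect_of(efl, "Y_PG", "X_MAW")
  expect_equal(c(none$direct, none$indirect, none$total), c(0, 0, 0))
  # random acyclic graphs against a brute-force path-product oracle
  set.seed(55)
  for (rep in 1:25) {
    p <- sample(3:6, 1)
    vars <- paste0("v", 1:p)
    idx <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
    keep <- sample(nrow(idx), max(2, rbinom(1, nrow(idx), 0.6)))
    edges <- data.frame(source = vars[idx[keep, 1]],
                        target = vars[idx[keep, 2]],
                        value = round(runif(length(keep), -0.9, 0.9), 2))
    ef <- effects_decomposition(edges)
    for (i in sample(nrow(ef), min(6, nrow(ef)))) {
      tot <- brute_path_sum(edges, ef$source[i], ef$target[i])
      expect_equal(ef$total[i], tot, tolerance = 1e-10)
      expect_equal(ef$direct[i] + ef$indirect[i], tot, tolerance = 1e-10)
      contribs <- attr(ef, "mediators")[[paste(ef$source[i], "->",
                                               ef$target[i])]]
      expect_equal(sum(contribs), ef$indirect[i], tolerance = 1e-10)
    }
  }
})

test_that("model selection applies strict thresholds in order", {
  mk <- function(cmin, rmsea, agfi, conv = TRUE)
    list(converged = conv, cmin_df = cmin, rmsea = rmsea, agfi = agfi)
  fits <- list(mk(0.8, 0.05, 0.95),    # accepted
               mk(1.5, 0.05, 0.95),    # chi2/df too high
               mk(1.0, 0.08, 0.9),     # boundary values rejected
               mk(NA, NA, NA),         # df = 0 never passes
               mk(0.5, 0.02, 0.99))
  sel <- select_models(fits)
  expect_equal(attr(sel, "accepted"), c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_length(sel, 2L)
})

test_that("fitting recovers standardized paths on generated data", {
  # single-replicate sanity at n = 500 (the full 200-replicate study runs
  # in the acceptance suite)
  cfg <- default_synth_config(400)
  cfg$n_groups <- 5L; cfg$samples_per_group <- 100L
  fit <- fit_sem(generate_samples(cfg)$table, fig4c_spec())
  expect_true(fit$converged)
  truth <- c("Y_CGC~X_AMAT" = -0.50, "Y_CGC~X_MAW" = 0.41,
             "a~Y_CGC" = 0.75, "a~X_AMAT" = -0.15, "a~X_MAW" = 0.12)
  expect_lt(max(abs(fit$standardized[names(truth)] - truth)), 0.12)
  # edge table carries stars for the strong paths
  et <- sem_edge_table(fit)
  expect_equal(et$stars[et$source == "Y_CGC" & et$target == "a"], "**")
})

test_that("defective inputs are rejected", {
  out <- generate_samples(default_synth_config(2))
  sp <- fig4c_spec()
  expect_error(fit_sem(out$table[1:3, ], sp), "n > number of variables")
  S_bad <- matrix(1, 4, 4,
                  dimnames = rep(list(c("X_AMAT", "X_MAW", "Y_CGC", "a")), 2))
  expect_error(fit_sem(spec = sp, sample_cov = S_bad, n = 100),
               "positive definite")
  expect_error(fit_sem(spec = sp, sample_cov = diag(4)), "n is required")
})
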