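select_complete_matrix <- function(table, variables) {
  missing_vars <- setdiff(variables, names(table))
  if (length(missing_vars))
    stop("lookup error: unknown variable code(s): ",
         paste(missing_vars, collapse = ", "))
  X <- as.matrix(as.data.frame(table)[variables])
  storage.mode(X) <- "double"
  if (anyNA(X))
    stop("missing cells among selected variables; impute or subset first")
  rownames(X) <- if ("sample_id" %in% names(table)) table$sample_id
                 else as.character(seq_len(nrow(X)))
  X
}

#' Principal component analysis of a sample table
#'
#' Computed by singular value decomposition of the column-centered (and,
#' under \code{scaling = "unit_variance"}, column-standardized) data matrix.
#' Unit-variance scaling is the default because analyte contents span two
#' orders of magnitude and matches the scaling used for the clustered
#' heatmap. Component signs are fixed so the largest-magnitude loading of
#' each component is positive.
#'
#' @param table A [sample_table()].
#' @param variables Variable codes to include (no missing cells allowed).
#' @param scaling \code{"unit_variance"} (z-score columns) or
#'   \code{"center_only"} (covariance PCA).
#' @return Object of class \code{"pca_result"}: \code{loadings}
#'   (variables x components, orthonormal columns), \code{scores}
#'   (samples x components), \code{explained_pct}, \code{cumulative_pct}.
#' @export
#' @examples
#' pc <- run_pca(load_table1_fixture(), analyte_catalog()$code)
#' round(pc$explained_pct[1:2], 2)
run_pca <- function(table, variables,
                    scaling = c("unit_variance", "center_only")) {
  scaling <- match.arg(scaling)
  X <- select_complete_matrix(table, variables)
  if (nrow(X) < 2 || ncol(X) < 2)
    stop("PCA needs at least 2 samples and 2 variables")
  if (scaling == "unit_variance") {
    sds <- apply(X, 2, stats::sd)
    if (any(sds == 0))
      stop("constant column under unit_variance scaling: ",
           paste(colnames(X)[sds == 0], collapse = ", "))
    X <- scale(X, center = TRUE, scale = sds)
  } else {
    X <- scale(X, center = TRUE, scale = FALSE)
  }
  sv <- svd(X)
  ncomp <- sum(sv$d > max(sv$d) * 1e-12)
  d <- sv$d[seq_len(ncomp)]
  load <- sv$v[, seq_len(ncomp), drop = FALSE]
  scores <- X %*% load
  # sign convention: largest-|.| loading entry positive
  for (j in seq_len(ncomp)) {
    s <- sign(load[which.max(abs(load[, j])), j])
    load[, j] <- s * load[, j]
    scores[, j] <- s * scores[, j]
  }
  varj <- d^2 / (nrow(X) - 1)
  pct <- 100 * varj / sum(varj)
  dimnames(load) <- list(colnames(X), paste0("PC", seq_len(ncomp)))
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(ncomp)))
  structure(list(loadings = load, scores = scores,
                 explained_pct = stats::setNames(pct, colnames(load)),
                 cumulative_pct = stats::setNames(cumsum(pct), colnames(load)),
                 scaling = scaling),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("PCA (", x$scaling, "): ", nrow(x$scores), " samples, ",
      nrow(x$loadings), " variables\n", sep = "")
  print(round(utils::head(x$explained_pct, 5), 2))
  invisible(x)
}

#' Hierarchical clustering of samples on scaled analyte profiles
#'
#' Variables are z-scored (zero mean, unit variance) before Euclidean
#' distances are computed, the scaling convention of clustered metabolite
#' heatmaps. Merges use [stats::hclust()], whose tie handling is
#' deterministic given the input order.
#'
#' @param table A [sample_table()].
#' @param variables Variable codes (no missing cells).
#' @param metric Distance metric; Euclidean only.
#' @param linkage \code{"complete"} (default), \code{"ward"} (Ward D2) or
#'   \code{"average"}.
#' @return Object of class \code{"hca_result"}: \code{merge_tree} (an
#'   \code{hclust}), \code{order} (leaf ordering), \code{scaled_matrix}.
#' @export
run_hca <- function(table, variables, metric = "euclidean",
                    linkage = c("complete", "ward", "average")) {
  metric <- match.arg(metric)
  linkage <- match.arg(linkage)
  X <- select_complete_matrix(table, variables)
  if (nrow(X) < 2) stop("clustering needs at least 2 samples")
  Xs <- scale(X)
  Xs[, apply(X, 2, stats::sd) == 0] <- 0
  hc <- stats::hclust(stats::dist(Xs, method = metric),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  structure(list(merge_tree = hc, order = hc$labels[hc$order],
                 scaled_matrix = Xs, linkage = linkage),
            class = "hca_result")
}

#' Export a clustering as a newick string
#'
#' Merge heights become branch lengths (each child branch spans the height
#' difference between a node and its child, i.e. an ultrametric tree).
#'
#' @param result An \code{"hca_result"}.
#' @return A single newick string terminated by \code{";"}.
#' @export
export_newick <- function(result) {
  stopifnot(inherits(result, "hca_result"))
  phy <- ape::as.phylo(result$merge_tree)
  ape::write.tree(phy)
}

#' Leaf labels of each subtree, for topology comparison
#'
#' @param result An \code{"hca_result"}.
#' @param k Number of clusters to cut into.
#' @return A list of character vectors of sample ids.
#' @export
cut_clusters <- function(result, k) {
  grp <- stats::cutree(result$merge_tree, k = k)
  split(names(grp), grp)
}

#' Orthogonal projections to latent structures discriminant analysis
#'
#' Implements O-PLS with a single predictive component for a binary class:
#' the class vector is coded +1/-1 and centered; the predictive weight is
#' \eqn{w \propto X^T y}; each orthogonal component removes from X the part
#' of its loading orthogonal to \eqn{w}, so orthogonal scores have zero
#' covariance with the class; the predictive component is then fitted on
#' the deflated X. \code{r2x}/\code{r2y} are explained-variance fractions;
#' \code{q2} comes from stratified 7-fold cross-validation of the whole
#' procedure.
#'
#' @param table A [sample_table()].
#' @param variables Variable codes (column-wise z-scored internally).
#' @param classes Per-sample labels with exactly two levels, each with
#'   >= 2 members.
#' @param n_orth Number of orthogonal components (>= 0; 0 gives plain
#'   single-component PLS-DA).
#' @param n_folds Cross-validation folds (stratified).
#' @param seed Seed for the fold assignment.
#' @return Object of class \code{"oplsda_result"} with predictive and
#'   orthogonal scores/loadings, \code{r2x}, \code{r2y}, \code{q2} and the
#'   class coding.
#' @export
run_oplsda <- function(table, variables, classes, n_orth = 1L,
                       n_folds = 7L, seed = 1L) {
  X <- select_complete_matrix(table, variables)
  classes <- as.factor(classes)
  if (nlevels(classes) != 2)
    stop("OPLS-DA requires exactly two classes, got ", nlevels(classes))
  if (any(table(classes) < 2)) stop("each class needs >= 2 members")
  if (length(classes) != nrow(X)) stop("classes length != sample count")
  if (n_orth >= min(dim(X)) - 1)
    stop("n_orth must be below the rank of X")

  ctr <- colMeans(X); sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant column: ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X, ctr, sds)
  y <- ifelse(classes == levels(classes)[2], 1, -1)
  y <- y - mean(y)

  core <- opls_core(Xs, y, n_orth)
  ssx <- sum(Xs^2); ssy <- sum(y^2)
  yhat <- core$t_pred * core$b
  r2y <- 1 - sum((y - yhat)^2) / ssy
  modeled <- sum((core$t_pred %o% core$p_pred)^2) +
    if (n_orth > 0) sum((core$T_orth %*% t(core$P_orth))^2) else 0
  r2x <- modeled / ssx

  # stratified k-fold CV: refit scaling + model per training split
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(classes)) {
    i <- which(classes == lv)
    fold[i] <- sample(rep_len(seq_len(n_folds), length(i)))
  }
  press <- 0
  for (f in sort(unique(fold))) {
    tr <- fold != f; te <- !tr
    ctr_f <- colMeans(X[tr, , drop = FALSE])
    sds_f <- apply(X[tr, , drop = FALSE], 2, stats::sd)
    sds_f[sds_f == 0] <- 1
    ytr <- y[tr] - mean(y[tr])
    cf <- opls_core(scale(X[tr, , drop = FALSE], ctr_f, sds_f), ytr, n_orth)
    Xte <- scale(X[te, , drop = FALSE], ctr_f, sds_f)
    for (j in seq_len(n_orth)) {
      t_o <- Xte %*% cf$W_orth[, j]
      Xte <- Xte - t_o %*% t(cf$P_orth[, j])
    }
    pred <- drop(Xte %*% cf$w_pred) * cf$b + mean(y[tr])
    press <- press + sum((y[te] - pred)^2)
  }
  q2 <- 1 - press / ssy

  structure(list(
    predictive_scores = stats::setNames(drop(core$t_pred), rownames(X)),
    predictive_loadings = stats::setNames(drop(core$p_pred), colnames(X)),
    orthogonal_scores = core$T_orth, orthogonal_loadings = core$P_orth,
    r2x = r2x, r2y = r2y, q2 = q2,
    classes = classes, y = y, n_orth = n_orth),
    class = "oplsda_result")
}

# one predictive + n_orth orthogonal components (Trygg-Wold deflation)
opls_core <- function(Xs, y, n_orth) {
  p <- ncol(Xs)
  w <- drop(crossprod(Xs, y)); w <- w / sqrt(sum(w^2))
  W_orth <- P_orth <- matrix(0, p, max(n_orth, 1))
  T_orth <- matrix(0, nrow(Xs), max(n_orth, 1))
  if (n_orth > 0) for (j in seq_len(n_orth)) {
    t_ <- drop(Xs %*% w)
    p_ <- drop(crossprod(Xs, t_)) / sum(t_^2)
    w_o <- p_ - drop(crossprod(w, p_)) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) { n_orth <- j - 1; break }
    w_o <- w_o / nrm
    t_o <- drop(Xs %*% w_o)
    p_o <- drop(crossprod(Xs, t_o)) / sum(t_o^2)
    Xs <- Xs - t_o %o% p_o
    W_orth[, j] <- w_o; P_orth[, j] <- p_o; T_orth[, j] <- t_o
  }
  w_pred <- drop(crossprod(Xs, y)); w_pred <- w_pred / sqrt(sum(w_pred^2))
  t_pred <- drop(Xs %*% w_pred)
  p_pred <- drop(crossprod(Xs, t_pred)) / sum(t_pred^2)
  b <- sum(t_pred * y) / sum(t_pred^2)
  list(w_pred = w_pred, t_pred = t_pred, p_pred = p_pred, b = b,
       W_orth = W_orth[, seq_len(max(n_orth, 0)), drop = FALSE],
       P_orth = P_orth[, seq_len(max(n_orth, 0)), drop = FALSE],
       T_orth = T_orth[, seq_len(max(n_orth, 0)), drop = FALSE])
}

#' @export
print.oplsda_result <- function(x, ...) {
  cat("OPLS-DA: 1 predictive +", x$n_orth, "orthogonal component(s)\n")
  cat(sprintf("R2X = %.3f  R2Y = %.3f  Q2 = %.3f\n", x$r2x, x$r2y, x$q2))
  invisible(x)
}
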