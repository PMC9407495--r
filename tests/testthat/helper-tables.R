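# small in-code fixtures shared across tests

# minimal valid table: 4 samples, 2 analytes, color, one climate factor
tiny_table <- function() {
  sample_table(data.frame(
    sample_id = c("s1", "s2", "s3", "s4"),
    group = c("A", "A", "B", "B"),
    Y_HY = c(10, 12, 8, 9),
    Y_QI = c(20, 25, 15, 18),
    L = c(80, 82, 78, 79), a = c(5, 7, 3, 4), b = c(12, 10, 15, 14),
    X_AMT = c(10, 9, 14, 13),
    stringsAsFactors = FALSE))
}

# random positive-definite correlation matrix of dimension k
random_corr <- function(k) {
  A <- matrix(rnorm(k * (k + 2)), k + 2, k)
  stats::cov2cor(crossprod(A) / (k + 2))
}

# brute-force sum over all directed source->target paths of edge products
brute_path_sum <- function(edges, source, target) {
  if (source == target) return(1)
  out <- edges[edges$source == source, , drop = FALSE]
  if (!nrow(out)) return(0)
  sum(vapply(seq_len(nrow(out)), function(i)
    out$value[i] * brute_path_sum(edges, out$target[i], target), numeric(1)))
}

# naive agglomerative clustering returning sorted merge heights
brute_linkage_heights <- function(X, type = c("complete", "single")) {
  type <- match.arg(type)
  groups <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (j <= i) next
      dd <- D[groups[[i]], groups[[j]], drop = FALSE]
      h <- if (type == "complete") max(dd) else min(dd)
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  sort(heights)
}

# synthetic config with independent climate factors and a single true
# climate -> analyte effect (everything else pure noise)
single_effect_config <- function(seed, effect = 0.8,
                                 predictor = "X_RH", response = "Y_HY") {
  cfg <- default_synth_config(seed)
  cfg$climate_slope[] <- 0
  cfg$flavonoid_loadings[] <- 0
  cfg$flavonoid_loadings[response, predictor] <- effect
  cfg$color_direct_climate[] <- 0
  cfg$color_flavonoid_loadings[] <- 0
  cfg
}
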