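# Class-separability indices computed against ground-truth labels: mean
# Silhouette, Davies-Bouldin, Calinski-Harabasz, plus 2-D projections.

#' Z-score a feature matrix
#'
#' Per-column mean 0 / SD 1; constant columns become all-zero with a
#' warning. Missing entries are median-imputed per column first (columns
#' that are entirely missing become zero).
#'
#' @param X Numeric matrix or data.frame (>= 2 rows).
#' @return Standardized numeric matrix.
#' @export
zscore_table <- function(X) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 2)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas))
      X[nas, j] <- if (all(nas)) 0 else stats::median(X[!nas, j])
  }
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    warnf("constant column(s) set to zero: %s",
          paste(colnames(X)[sds == 0], collapse = ", "))
  centered <- sweep(X, 2, colMeans(X))
  sweep(centered, 2, ifelse(sds == 0, 1, sds), "/")
}

#' Mean Silhouette score
#'
#' For each sample, `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to its own class (self excluded) and `b` the smallest mean
#' distance to any other class; the index is the mean over samples.
#'
#' @param X Numeric matrix of features.
#' @param labels Class labels (>= 2 classes, every class >= 2 members).
#' @return Mean silhouette in `[-1, 1]`.
#' @export
silhouette_mean <- function(X, labels) {
  X <- as.matrix(X)
  y <- factor(labels)
  if (nlevels(y) < 2) stopf("need at least 2 classes")
  sizes <- table(y)
  if (any(sizes < 2))
    stopf("singleton class(es): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  D <- as.matrix(stats::dist(X))
  n <- nrow(X)
  s <- vapply(seq_len(n), function(i) {
    own <- y == y[i]
    a <- sum(D[i, own]) / (sum(own) - 1)
    b <- min(vapply(levels(y)[levels(y) != y[i]],
                    function(cl) mean(D[i, y == cl]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over classes of the worst-case ratio
#' `(s_i + s_j) / d(c_i, c_j)` with `s` the mean Euclidean distance to the
#' class centroid and `d` the centroid distance. Singleton classes are
#' allowed (dispersion 0); coincident centroids are an error.
#'
#' @param X Numeric matrix of features.
#' @param labels Class labels (>= 2 classes).
#' @return DBI value (>= 0); lower is better separated.
#' @export
davies_bouldin <- function(X, labels) {
  X <- as.matrix(X)
  y <- factor(labels)
  k <- nlevels(y)
  if (k < 2) stopf("need at least 2 classes")
  cents <- do.call(rbind, lapply(levels(y), function(cl)
    colMeans(X[y == cl, , drop = FALSE])))
  s <- vapply(seq_len(k), function(i) {
    rows <- X[y == levels(y)[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cents[i, ])^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(cents))
  ratios <- matrix(NA_real_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    if (dc[i, j] == 0)
      stopf("coincident centroids for classes '%s' and '%s'",
            levels(y)[i], levels(y)[j])
    ratios[i, j] <- (s[i] + s[j]) / dc[i, j]
  }
  mean(apply(ratios, 1, max, na.rm = TRUE))
}

#' Calinski-Harabasz index
#'
#' `[trace(B) / (k - 1)] / [trace(W) / (n - k)]` with `B` and `W` the
#' between- and within-class scatter about centroids.
#'
#' @param X Numeric matrix of features.
#' @param labels Class labels; needs `n > k >= 2`.
#' @return CHI value (>= 0); `Inf` (with warning) on zero within-scatter.
#' @export
calinski_harabasz <- function(X, labels) {
  X <- as.matrix(X)
  y <- factor(labels)
  n <- nrow(X)
  k <- nlevels(y)
  if (!(n > k && k >= 2)) stopf("need n > k >= 2 (n = %d, k = %d)", n, k)
  gmean <- colMeans(X)
  trB <- 0
  trW <- 0
  for (cl in levels(y)) {
    rows <- X[y == cl, , drop = FALSE]
    cent <- colMeans(rows)
    trB <- trB + nrow(rows) * sum((cent - gmean)^2)
    trW <- trW + sum(sweep(rows, 2, cent)^2)
  }
  if (trW == 0) {
    warnf("zero within-class scatter: index infinite")
    return(Inf)
  }
  (trB / (k - 1)) / (trW / (n - k))
}

#' 2-D projection of a feature matrix
#'
#' `"pca"`: scores on the top-2 eigenvectors of the covariance of the
#' standardized matrix (deterministic up to sign). `"tsne"`: a
#' seed-reproducible exact t-SNE (quadratic in `n`, intended for
#' visualization of modest cohorts); a custom embedding function can be
#' supplied via `engine` (called as `engine(X, seed)`), the embedding being
#' deliberately pluggable.
#'
#' @param X Numeric matrix or data.frame (>= 3 rows).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Integer seed (used by t-SNE).
#' @param perplexity t-SNE perplexity (default 30, clamped to `(n - 1) / 3`).
#' @param engine Optional custom embedding function for `"tsne"`.
#' @return An `n x 2` coordinate matrix.
#' @export
project_2d <- function(X, method = c("pca", "tsne"), seed = 1,
                       perplexity = 30, engine = NULL) {
  method <- match.arg(method)
  X <- zscore_table(X)
  if (nrow(X) < 3) stopf("need at least 3 rows")
  if (method == "pca") {
    pc <- stats::prcomp(X, center = FALSE, scale. = FALSE)
    return(pc$x[, 1:2, drop = FALSE])
  }
  if (!is.null(engine)) return(engine(X, seed))
  .tsne_exact(X, seed = seed, perplexity = perplexity)
}

# minimal exact t-SNE (symmetric SNE with Student-t low-dim kernel)
.tsne_exact <- function(X, seed = 1, perplexity = 30, n_iter = 400,
                        eta = 100, momentum = 0.8) {
  n <- nrow(X)
  perplexity <- min(perplexity, floor((n - 1) / 3))
  if (perplexity < 2) perplexity <- 2
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {        # binary search for per-point bandwidth
    beta <- 1
    lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { beta <- beta / 2; next }
      H <- log(sp) + beta * sum(di * p) / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p / sum(p)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  V <- matrix(0, n, 2)
  Pex <- P * 4                    # early exaggeration
  for (iter in seq_len(n_iter)) {
    Pit <- if (iter <= 100) Pex else P
    num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pit - Q) * num
    grad <- 4 * (diag(rowSums(L)) - L) %*% Y
    V <- momentum * V - eta * grad
    Y <- Y + V
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Separability report for a feature table
#'
#' Computes the three indices on the z-scored feature matrix (gender
#' already 0/1, missing values median-imputed inside [zscore_table()]) for
#' the table's labels.
#'
#' @param table Feature data.frame with a `Group` label column.
#' @param scheme_name Tag recorded in the report.
#' @param standardize Z-score before computing (default TRUE; recorded in
#'   the report so reproduction attempts are auditable).
#' @param label_col Name of the label column.
#' @return Object of class `separability_report`.
#' @export
separability_report <- function(table, scheme_name = "unspecified",
                                standardize = TRUE, label_col = "Group") {
  sl <- .split_features_label(table, label_col)
  X <- as.matrix(sl$X)
  if (standardize) X <- zscore_table(X)
  structure(list(scheme = scheme_name,
                 silhouette_mean = silhouette_mean(X, sl$y),
                 davies_bouldin = davies_bouldin(X, sl$y),
                 calinski_harabasz = calinski_harabasz(X, sl$y),
                 n_samples = nrow(X), n_features = ncol(X),
                 standardization = if (standardize) "zscore" else "none"),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("Separability report (%s; %d samples x %d features, %s):\n",
              x$scheme, x$n_samples, x$n_features, x$standardization))
  cat(sprintf("  mean Silhouette:    %8.4f\n", x$silhouette_mean))
  cat(sprintf("  Davies-Bouldin:     %8.4f\n", x$davies_bouldin))
  cat(sprintf("  Calinski-Harabasz:  %8.4f\n", x$calinski_harabasz))
  invisible(x)
}
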