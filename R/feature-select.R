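# Feature ranking: plug-in mutual information, greedy MRMR (MIQ/MID), and
# multi-class ReliefF.

#' Plug-in mutual information of two discrete vectors
#'
#' MI in bits (log base 2) from the joint contingency table.
#'
#' @param x,y Discrete vectors of equal length (>= 2).
#' @return Mutual information in bits (>= 0 up to floating point).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stopf("length mismatch: %d vs %d",
                                    length(x), length(y))
  if (length(x) < 2) stopf("need at least 2 observations")
  tab <- table(x, y)
  p <- tab / sum(tab)
  px <- rowSums(p)
  py <- colSums(p)
  ind <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / ind[nz]))
}

#' Equal-frequency discretization
#'
#' Bins a continuous vector into (up to) `bins` classes by quantile cuts;
#' invariant under strictly monotone transforms of the input.
#'
#' @param x Numeric vector.
#' @param bins Number of bins (default 10).
#' @return Integer bin codes.
#' @export
discretize_ef <- function(x, bins = 10) {
  if (length(unique(x)) <= bins) return(match(x, sort(unique(x))))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               na.rm = TRUE, type = 1))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

.split_features_label <- function(table, label_col = "Group") {
  if (!label_col %in% names(table))
    stopf("table lacks a '%s' label column", label_col)
  list(X = table[, setdiff(names(table), label_col), drop = FALSE],
       y = factor(table[[label_col]]))
}

#' MRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance selection on
#' equal-frequency-discretized features: the first pick maximizes relevance
#' `MI(f; label)`; each later pick maximizes the MIQ quotient
#' relevance / mean MI to the already-selected set (or the MID difference
#' when `scheme = "mid"`). Ties break by column order.
#'
#' @param table Feature data.frame with a `Group` label column.
#' @param k Number of features to return.
#' @param scheme `"miq"` (default, quotient) or `"mid"` (difference).
#' @param bins Discretization bins for the MI estimates.
#' @param label_col Name of the label column.
#' @return Object of class `ranked_features`: ordered names, selection
#'   scores, method tag, `k`.
#' @export
mrmr_rank <- function(table, k, scheme = c("miq", "mid"), bins = 10,
                      label_col = "Group") {
  scheme <- match.arg(scheme)
  sl <- .split_features_label(table, label_col)
  X <- sl$X
  p <- ncol(X)
  if (k > p) stopf("k = %d exceeds the %d available features", k, p)
  disc <- lapply(X, discretize_ef, bins = bins)
  rel <- vapply(disc, mutual_information, numeric(1), y = sl$y)

  selected <- integer(0)
  scores <- numeric(0)
  # pairwise feature MI cache, filled lazily
  mi_cache <- matrix(NA_real_, p, p)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_len(p), selected)
    crit <- vapply(cand, function(j) {
      if (!length(selected)) return(rel[j])
      red <- vapply(selected, function(s) {
        if (is.na(mi_cache[j, s]))
          mi_cache[j, s] <<- mi_cache[s, j] <<-
            mutual_information(disc[[j]], disc[[s]])
        mi_cache[j, s]
      }, numeric(1))
      if (scheme == "miq") rel[j] / max(mean(red), 1e-12)
      else rel[j] - mean(red)
    }, numeric(1))
    pick <- cand[which.max(crit)]        # which.max takes first on ties
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
  }
  structure(list(features = names(X)[selected], scores = scores,
                 method = paste0("mrmr-", scheme), k = k),
            class = "ranked_features")
}

#' ReliefF feature ranking
#'
#' Standard multi-class ReliefF: features range-normalized to `[0, 1]`,
#' every observation used as an anchor, `neighbors` nearest hits and
#' nearest misses per other class (range-normalized Manhattan distance),
#' miss terms weighted by class priors renormalized over the non-anchor
#' classes. Top-`k` features by weight.
#'
#' @param table Feature data.frame with a `Group` label column.
#' @param k Number of features to return.
#' @param neighbors Nearest hits/misses per class (default 10).
#' @param label_col Name of the label column.
#' @return Object of class `ranked_features` (with full `weights` kept).
#' @export
relieff_rank <- function(table, k, neighbors = 10, label_col = "Group") {
  sl <- .split_features_label(table, label_col)
  X <- as.matrix(sl$X)
  y <- sl$y
  n <- nrow(X)
  p <- ncol(X)
  if (k > p) stopf("k = %d exceeds the %d available features", k, p)
  small <- table(y) < neighbors + 1
  if (any(small))
    stopf("class(es) smaller than neighbors + 1: %s",
          paste(names(small)[small], collapse = ", "))
  rng <- apply(X, 2, function(v) diff(range(v)))
  rng[rng == 0] <- 1
  Xn <- sweep(sweep(X, 2, apply(X, 2, min)), 2, rng, "/")

  classes <- levels(y)
  prior <- table(y) / n
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  diag(D) <- Inf
  W <- numeric(p)
  for (i in seq_len(n)) {
    ci <- y[i]
    hits <- order(D[i, y == ci])[seq_len(neighbors)]
    hit_idx <- which(y == ci)[hits]
    W <- W - colMeans(abs(Xn[hit_idx, , drop = FALSE] -
                            rep(Xn[i, ], each = neighbors)))
    for (cl in setdiff(classes, as.character(ci))) {
      ms <- order(D[i, y == cl])[seq_len(neighbors)]
      miss_idx <- which(y == cl)[ms]
      wcl <- prior[[cl]] / (1 - prior[[as.character(ci)]])
      W <- W + wcl * colMeans(abs(Xn[miss_idx, , drop = FALSE] -
                                    rep(Xn[i, ], each = neighbors)))
    }
  }
  W <- W / n
  ord <- order(W, decreasing = TRUE)
  structure(list(features = colnames(X)[ord[seq_len(k)]],
                 scores = unname(W[ord[seq_len(k)]]),
                 weights = stats::setNames(W, colnames(X)),
                 method = "relieff", k = k),
            class = "ranked_features")
}

#' @export
print.ranked_features <- function(x, ...) {
  cat(sprintf("Top %d features (%s):\n", x$k, x$method))
  for (i in seq_len(x$k))
    cat(sprintf("  %2d. %-16s %.4f\n", i, x$features[i], x$scores[i]))
  invisible(x)
}
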