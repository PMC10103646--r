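#' Build an individuals-by-CNVRs dosage matrix
#'
#' Subsets a CNVR set by type: `"deletions"` takes kinds deletion and
#' both, `"duplications"` takes duplication and both, `"both"` takes
#' both-type regions only, `"all"` takes everything.  Values are the
#' per-CNVR mean copy numbers.
#'
#' @param cnvrs a `cnvr_set`.
#' @param subset one of `"all"`, `"deletions"`, `"duplications"`, `"both"`.
#' @return numeric matrix, samples x CNVRs, with a `subset` attribute.
#' @export
build_cnvr_matrix <- function(cnvrs,
                              subset = c("all", "deletions", "duplications", "both")) {
  subset <- match.arg(subset)
  kinds <- switch(subset,
                  all = CNVR_KINDS,
                  deletions = c("deletion", "both"),
                  duplications = c("duplication", "both"),
                  both = "both")
  idx <- which(cnvrs$regions$kind %in% kinds)
  if (length(idx) < 2) stop_invalid("fewer than 2 CNVRs in subset '%s'", subset)
  m <- t(cnvrs$cn[idx, , drop = FALSE])
  colnames(m) <- sprintf("%s:%d-%d", cnvrs$regions$chrom[idx],
                         cnvrs$regions$start[idx], cnvrs$regions$end[idx])
  attr(m, "subset") <- subset
  m
}

#' PCA of a CNVR dosage matrix
#'
#' Columns are mean-centred and, with `scale = TRUE`, divided by their
#' standard deviation (zero-variance columns dropped, count reported in
#' the result).  Coordinates come from the eigendecomposition of the
#' sample covariance of the processed matrix; the variance explained by
#' each component is its eigenvalue over the trace.  Each component's
#' loading vector is oriented so its sum is non-negative, making
#' coordinates reproducible across platforms.  A matrix with identical
#' rows has zero total variance and yields all-zero coordinates.
#'
#' @param mat samples x CNVRs matrix (from [build_cnvr_matrix()]).
#' @param k number of components (capped at `min(n - 1, n_columns)`).
#' @param scale divide columns by their standard deviation (default TRUE).
#' @return object of class `cnvr_pca`: list with `coordinates` (samples x
#'   k), `variance_explained`, `loadings`, `dropped_columns`.
#' @export
cnvr_pca <- function(mat, k = 10L, scale = TRUE) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 2) stop_invalid("PCA needs at least 2 individuals")
  X <- scale(mat, center = TRUE, scale = FALSE)
  dropped <- 0L
  if (scale) {
    sds <- apply(X, 2L, sd)
    keep <- sds > 0
    dropped <- sum(!keep)
    X <- sweep(X[, keep, drop = FALSE], 2L, sds[keep], "/")
  }
  k <- min(k, n - 1L, ncol(X))
  total <- sum(X^2)
  if (total == 0 || ncol(X) == 0) {
    k <- max(k, 1L)
    return(structure(list(
      coordinates = matrix(0, n, k, dimnames = list(rownames(mat),
                                                    paste0("PC", seq_len(k)))),
      variance_explained = rep(0, k),
      loadings = matrix(0, max(ncol(X), 1L), k),
      dropped_columns = dropped), class = "cnvr_pca"))
  }
  sv <- svd(X, nu = 0, nv = k)
  v <- sv$v
  flip <- colSums(v) < 0
  v[, flip] <- -v[, flip]
  coords <- X %*% v
  dimnames(coords) <- list(rownames(mat), paste0("PC", seq_len(k)))
  structure(list(
    coordinates = coords,
    variance_explained = (sv$d[seq_len(k)]^2) / total,
    loadings = v,
    dropped_columns = dropped
  ), class = "cnvr_pca")
}

#' @export
print.cnvr_pca <- function(x, ...) {
  cat(sprintf("cnvr_pca: %d individuals, %d components; PC1 %.2f%% of variance\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$variance_explained[1]))
  invisible(x)
}

#' Classify individuals by the sign of PC1
#'
#' Utility for structure-recovery checks: assigns each individual to one
#' of two groups by the sign of its first principal coordinate and
#' returns the best-matching accuracy against true labels (label
#' permutation resolved by taking the better of the two assignments).
#'
#' @param pca a `cnvr_pca`.
#' @param labels true two-level grouping, in the row order of the
#'   coordinates.
#' @return fraction of individuals correctly classified.
#' @export
pc1_label_accuracy <- function(pca, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2) stop_invalid("labels must have exactly 2 levels")
  pred <- pca$coordinates[, 1] >= 0
  acc <- mean(pred == (labels == levels(labels)[1]))
  max(acc, 1 - acc)
}
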