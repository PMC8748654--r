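# Principal component analysis via singular value decomposition, with a
# fixed sign convention, plus robust score-based outlier flagging.

#' Principal component analysis
#'
#' PCA of a centered/scaled data matrix by singular value decomposition.
#' Components are ordered by decreasing explained variance.  Sign
#' convention: each loading vector is oriented so its largest-magnitude
#' entry is positive, making the output deterministic.
#'
#' @param X Numeric matrix (samples in rows), already centered/scaled (see
#'   [transform_scale()]).
#' @param n_components Number of components; truncated to the matrix rank
#'   with a warning if larger.
#' @return List of class `lipid_pca` with `scores`, `loadings`,
#'   `explained_variance` (fractions) and `sdev`.
#' @export
fit_pca <- function(X, n_components = 2) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), n_components >= 1)
  sv <- svd(X)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * max(sv$d, 1)
  rank <- sum(pos)
  if (n_components > rank) {
    warning("requested ", n_components, " components but rank is ", rank,
            "; truncated")
    n_components <- rank
  }
  k <- seq_len(n_components)
  loadings <- sv$v[, k, drop = FALSE]
  # orient: largest-magnitude loading entry positive
  for (j in seq_along(k)) {
    imax <- which.max(abs(loadings[, j]))
    if (loadings[imax, j] < 0) {
      loadings[, j] <- -loadings[, j]
      sv$u[, k[j]] <- -sv$u[, k[j]]
    }
  }
  scores <- sv$u[, k, drop = FALSE] %*% diag(sv$d[k], nrow = length(k))
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", k)
  ev <- sv$d^2 / sum(sv$d^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[k], sdev = sv$d / sqrt(max(1, nrow(X) - 1))),
            class = "lipid_pca")
}

#' @export
print.lipid_pca <- function(x, ...) {
  cat("PCA:", nrow(x$scores), "samples,", ncol(x$scores), "components\n")
  cat("explained variance:",
      paste0(round(100 * x$explained_variance, 1), "%", collapse = ", "), "\n")
  invisible(x)
}

#' Flag potential outlier samples from PCA scores
#'
#' Computes robust z-scores (median/MAD) on the first two principal
#' component scores and flags samples with |z| above `z_max` on either
#' component.  Flags are advisory: nothing is removed.
#'
#' @param X Preprocessed (transformed/scaled) matrix.
#' @param samples Optional metadata; sample ids are taken from its
#'   `sample_id` column, else from the matrix row names.
#' @param z_max Robust z-score threshold (default 5).
#' @return Data frame of flagged samples with columns `sample_id`,
#'   `component`, `z`.
#' @export
pca_outlier_flags <- function(X, samples = NULL, z_max = 5) {
  p <- fit_pca(X, n_components = min(2, ncol(X), nrow(X) - 1))
  ids <- if (!is.null(samples) && "sample_id" %in% names(samples))
    samples$sample_id else rownames(X)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(X)))
  flags <- list()
  for (j in seq_len(ncol(p$scores))) {
    sc <- p$scores[, j]
    mad_j <- stats::mad(sc)
    if (mad_j == 0) next
    z <- (sc - stats::median(sc)) / mad_j
    hit <- which(abs(z) > z_max)
    if (length(hit))
      flags[[length(flags) + 1L]] <- data.frame(
        sample_id = ids[hit], component = paste0("PC", j), z = z[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(flags))
    return(data.frame(sample_id = character(0), component = character(0),
                      z = numeric(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, flags)
  rownames(res) <- NULL
  res
}
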