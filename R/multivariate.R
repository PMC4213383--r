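#' Mean-center and Pareto-scale a sample-by-variable matrix
#'
#' Each column is mean-centered and divided by the square root of its
#' standard deviation (Pareto scaling, damping the dominance of intense
#' features while keeping some magnitude information). Constant columns
#' become all-zero and are flagged; missing values are mean-imputed per
#' column (flagged) before scaling. `mode = "auto"` divides by the full
#' standard deviation (unit-variance autoscaling) instead.
#'
#' @param m numeric matrix, samples in rows, variables (feature groups) in
#'   columns.
#' @param mode `"pareto"` (default) or `"auto"`.
#' @return list of class `scaled_matrix`: `matrix`, `center`, `scale`,
#'   `constant_cols`, `imputed_cols`, `mode`.
#' @export
pareto_scale <- function(m, mode = c("pareto", "auto")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  imputed <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    na <- is.na(m[, j])
    if (any(na)) {
      imputed[j] <- TRUE
      m[na, j] <- mean(m[!na, j])
      if (all(na)) m[, j] <- 0
    }
  }
  center <- colMeans(m)
  sds <- apply(m, 2, stats::sd)
  constant <- sds == 0
  scale <- if (mode == "pareto") sqrt(sds) else sds
  scale[constant] <- 1
  out <- sweep(sweep(m, 2, center, `-`), 2, scale, `/`)
  out[, constant] <- 0
  structure(list(matrix = out, center = center, scale = scale,
                 constant_cols = which(constant), imputed_cols = which(imputed),
                 mode = mode),
            class = "scaled_matrix")
}

#' Principal component analysis of a scaled matrix
#'
#' Singular value decomposition of the (already centered and scaled)
#' matrix, with a deterministic sign convention: for each component the
#' largest-magnitude loading is made positive.
#'
#' @param scaled a `scaled_matrix` from [pareto_scale()], or a plain
#'   centered matrix.
#' @param k number of components, at most `min(nrow - 1, ncol)`.
#' @return list of class `pca_model`: `scores` (samples x k), `loadings`
#'   (variables x k, orthonormal columns), `explained` (variance
#'   fractions, non-increasing, summing to <= 1).
#' @export
run_pca <- function(scaled, k = 2) {
  m <- if (inherits(scaled, "scaled_matrix")) scaled$matrix else as.matrix(scaled)
  kmax <- min(nrow(m) - 1, ncol(m))
  if (k < 1 || k > kmax) {
    stop("k must lie in [1, ", kmax, "] for a ", nrow(m), " x ", ncol(m),
         " matrix")
  }
  sv <- svd(m, nu = k, nv = k)
  flip <- vapply(seq_len(k), function(j) {
    v <- sv$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  loadings <- sweep(sv$v, 2, flip, `*`)
  scores <- sweep(sv$u %*% diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- rownames(m)
  rownames(loadings) <- colnames(m)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings,
                 explained = sv$d^2 / sum(sv$d^2), k = k),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("pca_model:", nrow(x$scores), "samples,", x$k, "components\n")
  cat("  explained variance:",
      paste(sprintf("PC%d %.1f%%", seq_len(x$k),
                    100 * x$explained[seq_len(x$k)]), collapse = ", "), "\n")
  invisible(x)
}
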