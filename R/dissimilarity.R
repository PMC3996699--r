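#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' Abundance mode computes sum(|x - y|) / sum(x + y); binary mode applies
#' the same formula to presence/absence indicators, which equals the
#' Sorensen dissimilarity. Bounded in [0, 1], 0 for identical vectors, 1
#' for disjoint supports.
#'
#' @param x,y non-negative numeric vectors of equal length
#' @param mode `"abundance"` or `"binary"`
#' @return dissimilarity in [0, 1]
#' @export
bray_curtis <- function(x, y, mode = c("abundance", "binary")) {
  mode <- match.arg(mode)
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  if (mode == "binary") {
    x <- as.numeric(x > 0)
    y <- as.numeric(y > 0)
  }
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero; dissimilarity undefined")
  sum(abs(x - y)) / denom
}

#' Pairwise Bray-Curtis dissimilarity matrix
#'
#' Computes all pairwise sample dissimilarities of a relative-abundance
#' table, optionally restricted to a feature subset (e.g. phylotypes of one
#' family); subset rows are re-normalized within the subset before
#' abundance-mode computation so the comparison is compositional within the
#' group.
#'
#' @param rel relative-abundance matrix, features x samples
#' @param mode `"abundance"` or `"binary"`
#' @param feature_subset optional character vector of feature row names
#' @return object of class `dissimilarity_matrix`: list with the symmetric
#'   `matrix` (zero diagonal, values in [0,1]), `mode`, and `samples`
#' @export
dissimilarity_matrix <- function(rel, mode = c("abundance", "binary"),
                                 feature_subset = NULL) {
  mode <- match.arg(mode)
  rel <- as.matrix(rel)
  if (ncol(rel) < 2) stop("need at least 2 samples")
  if (!is.null(feature_subset)) {
    miss <- setdiff(feature_subset, rownames(rel))
    if (length(miss)) stop("feature subset rows not found: ",
                           paste(miss, collapse = ", "))
    rel <- rel[feature_subset, , drop = FALSE]
    if (nrow(rel) == 0) stop("empty feature subset")
    tot <- colSums(rel)
    if (any(tot == 0)) {
      stop("sample(s) with zero abundance within subset: ",
           paste(colnames(rel)[tot == 0], collapse = ", "))
    }
    if (mode == "abundance") rel <- sweep(rel, 2, tot, "/")
  }
  d <- vegan::vegdist(t(rel), method = "bray", binary = (mode == "binary"))
  m <- as.matrix(d)
  dimnames(m) <- list(colnames(rel), colnames(rel))
  structure(list(matrix = m, mode = mode, samples = colnames(rel)),
            class = "dissimilarity_matrix")
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix (Bray-Curtis, %s mode): %d samples\n",
              x$mode, length(x$samples)))
  cat(sprintf("  range %.3f-%.3f\n", min(x$matrix[upper.tri(x$matrix)]),
              max(x$matrix[upper.tri(x$matrix)])))
  invisible(x)
}

#' Group-wise dissimilarity summaries
#'
#' Mean within-group dissimilarity per group and the mean dissimilarity of
#' every group's samples to a baseline group's samples. Both summaries are
#' emitted because either convention is used for longitudinal designs.
#'
#' @param d a `dissimilarity_matrix`
#' @param groups factor/vector of group labels (e.g. sampling day), one per
#'   sample in `d$samples` order
#' @param baseline label of the baseline group (e.g. day 1)
#' @return data.frame with group, mean_within, mean_vs_baseline, n
#' @export
dissimilarity_summary <- function(d, groups, baseline = NULL) {
  stopifnot(inherits(d, "dissimilarity_matrix"),
            length(groups) == length(d$samples))
  groups <- as.character(groups)
  if (is.null(baseline)) baseline <- sort(unique(groups))[1]
  m <- d$matrix
  out <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    within <- if (length(idx) >= 2) {
      sub <- m[idx, idx, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    bidx <- which(groups == baseline)
    vs <- if (g == baseline) within else mean(m[idx, bidx, drop = FALSE])
    data.frame(group = g, mean_within = within, mean_vs_baseline = vs,
               n = length(idx), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' PCA by eigendecomposition of a correlation matrix
#'
#' Standardizes each variable (mean 0, sd 1 with denominator n - 1),
#' eigendecomposes the resulting correlation matrix with a symmetric
#' solver, and projects the standardized data onto the eigenvectors to
#' obtain scores. Zero-variance variables are removed with a warning before
#' standardization. Eigenvector sign is pinned so each loading column's
#' largest-magnitude entry is positive.
#'
#' @param x numeric matrix, samples (rows) x variables (columns)
#' @return object of class `cor_pca`: scores (samples x components),
#'   loadings (variables x components, orthonormal columns), eigenvalues
#'   (non-increasing, summing to the number of variables), and
#'   prop_variance
#' @export
pca <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples")
  sds <- apply(x, 2, stats::sd)
  degen <- sds == 0 | !is.finite(sds)
  if (any(degen)) {
    warning("removing zero-variance variable(s): ",
            paste(colnames(x)[degen], collapse = ", "))
    x <- x[, !degen, drop = FALSE]
  }
  if (ncol(x) < 2) stop("fewer than 2 non-degenerate variables")
  z <- scale(x, center = TRUE, scale = TRUE)   # sd with denominator n-1
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  vals <- pmax(eig$values, 0)                   # clip tiny negative roundoff
  load <- eig$vectors
  # deterministic sign: largest-|.| entry of each column positive
  for (j in seq_len(ncol(load))) {
    k <- which.max(abs(load[, j]))
    if (load[k, j] < 0) load[, j] <- -load[, j]
  }
  scores <- z %*% load
  pcn <- paste0("PC", seq_along(vals))
  dimnames(load) <- list(colnames(x), pcn)
  dimnames(scores) <- list(rownames(x), pcn)
  structure(list(scores = scores, loadings = load, eigenvalues = vals,
                 prop_variance = vals / sum(vals), n = nrow(x)),
            class = "cor_pca")
}

#' @export
print.cor_pca <- function(x, ...) {
  k <- min(5, length(x$eigenvalues))
  cat(sprintf("Correlation-matrix PCA: %d samples, %d variables\n",
              x$n, nrow(x$loadings)))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues[1:k]), collapse = " "),
      if (length(x$eigenvalues) > k) "..." else "", "\n")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$prop_variance[1:k]), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.cor_pca <- function(object, ...) {
  data.frame(component = colnames(object$loadings),
             eigenvalue = object$eigenvalues,
             prop_variance = object$prop_variance,
             cum_variance = cumsum(object$prop_variance))
}

#' @export
plot.cor_pca <- function(x, components = c(1, 2), groups = NULL, ...) {
  s <- x$scores[, components, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  lab <- sprintf("PC%d (%.1f%%)", components, 100 * x$prop_variance[components])
  plot(s, col = col, pch = 19, xlab = lab[1], ylab = lab[2], ...)
  invisible(x)
}
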