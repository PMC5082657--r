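#' Build the VanRaden genomic relationship matrix
#'
#' With marker codes `M` (lines x markers, -1/0/1 scale) and allele
#' frequencies `p_i` recomputed from the input matrix, the i'th column of
#' `P` is `2 (p_i - 0.5)`, `Z = M - P`, and
#' `G = Z Z' / (2 * sum(p_i (1 - p_i)))`. Frequencies come from the data, so
#' the columns of `Z` have mean zero and `G` is invariant to flipping which
#' allele is counted at any marker.
#'
#' @param m a `marker_matrix` with no missing values (see
#'   [impute_missing()]), or a numeric lines x markers matrix on the
#'   -1/0/1 scale.
#' @return object of class `grm`: list with `values` (line x line matrix),
#'   `line_ids`, `denominator` (`2 sum p q`), `p` (allele frequencies).
#' @export
#' @examples
#' m <- matrix(c(-1, 1, -1, 1), 2, 2, dimnames = list(c("A", "B"), NULL))
#' build_grm(m)$values  # opposite homozygotes: 2 on the diagonal, -2 off
build_grm <- function(m) {
  v <- if (inherits(m, "marker_matrix")) m$values else as.matrix(m)
  if (anyNA(v)) stop("marker matrix has missing values; impute first")
  if (nrow(v) < 2) stop("need at least 2 lines")
  p <- (colMeans(v) + 1) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero denominator")
  Z <- sweep(v, 2, 2 * (p - 0.5))
  G <- tcrossprod(Z) / denom
  structure(list(values = G, line_ids = rownames(v),
                 denominator = denom, p = p),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("Genomic relationship matrix:", length(x$line_ids), "lines; mean diagonal",
      round(mean(diag(x$values)), 3), "\n")
  invisible(x)
}

## Factor G = L L' by eigendecomposition, dropping the null space. G from
## data-derived allele frequencies is always singular (the centered Z gives
## G 1 = 0), so the mixed model is fitted on the reparameterization
## g = L a with a ~ N(0, I sigma2_g): the likelihood and BLUPs are exactly
## those of g ~ N(0, G sigma2_g), with no inverse of G required.
grm_factor <- function(g, tol = 1e-10) {
  G <- if (inherits(g, "grm")) g$values else g
  ed <- eigen(G, symmetric = TRUE)
  keep <- ed$values > tol * max(ed$values)
  if (!any(keep)) stop("G has no positive eigenvalues")
  L <- ed$vectors[, keep, drop = FALSE] %*% diag(sqrt(ed$values[keep]),
                                                 sum(keep))
  rownames(L) <- rownames(G)
  L
}

#' Principal component analysis of the relationship matrix
#'
#' Column-centers `G` (optionally not) and takes its singular value
#' decomposition, as `prcomp` does. Proportions of variance are eigenvalues
#' over their total.
#'
#' @param g a `grm`.
#' @param k number of components to return scores for.
#' @param center center the columns of `G` first (default TRUE).
#' @return object of class `grm_pca`: list with `eigenvalues` (descending),
#'   `proportion` (variance proportions), `scores` (line x k).
#' @export
grm_pca <- function(g, k = 10, center = TRUE) {
  stopifnot(inherits(g, "grm"))
  n <- length(g$line_ids)
  if (k > n) stop("k exceeds the number of lines")
  pc <- stats::prcomp(g$values, center = center, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- pc$x[, seq_len(k), drop = FALSE]
  rownames(scores) <- g$line_ids
  structure(list(eigenvalues = ev, proportion = ev / sum(ev),
                 scores = scores, center = center),
            class = "grm_pca")
}

#' @export
print.grm_pca <- function(x, ...) {
  cat("PCA of G:", length(x$eigenvalues), "components; PC1",
      sprintf("%.1f%%", 100 * x$proportion[1]), "PC2",
      sprintf("%.1f%%", 100 * x$proportion[2]), "\n")
  invisible(x)
}

#' Hierarchical clustering order of lines from the relationship matrix
#'
#' Converts `G` to squared genomic distances
#' `d(i, j) = G(i,i) + G(j,j) - 2 G(i,j)` and clusters with complete
#' linkage, giving the leaf order a relationship heat map would use.
#'
#' @param g a `grm`.
#' @return list with `order` (line ids in leaf order), `merge`, `height`
#'   (the `hclust` merge table), `hclust` (the full object).
#' @export
cluster_order <- function(g) {
  stopifnot(inherits(g, "grm"))
  G <- g$values
  d2 <- outer(diag(G), diag(G), "+") - 2 * G
  d2[d2 < 0] <- 0  # numerical guard
  hc <- stats::hclust(stats::as.dist(d2), method = "complete")
  list(order = g$line_ids[hc$order], merge = hc$merge,
       height = hc$height, hclust = hc)
}
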