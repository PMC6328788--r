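#' Biomarker counts as a distance matrix
#'
#' Uses the number of high-quality pairwise biomarkers verbatim as the
#' dissimilarity between two tumor localizations: many discriminating
#' features mean distinct mutation landscapes, none means
#' indistinguishable (distance zero). No transform is applied.
#'
#' @param counts a \linkS4class{PairCountMatrix}, or a symmetric
#'   numeric matrix with matching dimnames.
#' @return a \code{\link[stats]{dist}} object over localization labels.
#' @export
biomarkerDistance <- function(counts) {
  m <- if (is(counts, "PairCountMatrix")) pairCounts(counts) else counts
  if (!is.matrix(m) || !isSymmetric(unname(m)))
    stop("counts must be a symmetric matrix")
  stats::as.dist(m)
}

#' Ward.D2 agglomerative clustering
#'
#' Hierarchical clustering under Ward's criterion on untransformed
#' dissimilarities: at each step the pair of clusters at minimum
#' distance is merged at a height equal to that distance, and distances
#' to every other cluster k are updated by the Ward.D2 Lance-Williams
#' rule d(ij,k) = sqrt(((ni+nk) d(i,k)^2 + (nj+nk) d(j,k)^2 -
#' nk d(i,j)^2) / (ni+nj+nk)). Ties are broken by the lexicographically
#' smallest pair of cluster representative labels, so the merge
#' sequence is reproducible and invariant under input permutation.
#'
#' @param d a \code{\link[stats]{dist}} object or symmetric numeric
#'   matrix with at least two labels.
#' @return an object of class \code{hclust} (plottable, convertible
#'   with \code{as.dendrogram} or \code{ape::as.phylo}).
#' @export
wardD2 <- function(d) {
  m <- if (inherits(d, "dist")) as.matrix(d) else d
  if (!is.matrix(m) || nrow(m) != ncol(m) || !isSymmetric(unname(m)))
    stop("d must be a dist object or symmetric matrix")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  n <- nrow(m)
  if (n < 2L) stop("need at least two labels")

  size <- rep(1L, n)
  id <- -seq_len(n)            # hclust convention: leaves negative
  rep_lab <- labels            # lexicographic representative per cluster
  active <- seq_len(n)
  D <- m
  diag(D) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))

  for (step in seq_len(n - 1L)) {
    best <- NULL
    for (a in seq_along(active)) {
      if (a == length(active)) break
      for (b in seq((a + 1L), length(active))) {
        i <- active[a]; j <- active[b]
        dij <- D[i, j]
        key <- sort(c(rep_lab[i], rep_lab[j]))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dij, key = key)
        }
      }
    }
    i <- best$i; j <- best$j
    height[step] <- best$d
    merge[step, ] <- sort(c(id[i], id[j]))
    # fold j into i
    for (k in active) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <- sqrt(
        ((size[i] + size[k]) * D[i, k]^2 +
         (size[j] + size[k]) * D[j, k]^2 -
         size[k] * best$d^2) / (size[i] + size[j] + size[k]))
    }
    size[i] <- size[i] + size[j]
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
    id[i] <- step
    members[[i]] <- c(members[[i]], members[[j]])
    active <- active[active != j]
  }

  structure(list(merge = merge, height = height,
                 order = members[[active]], labels = labels,
                 method = "ward.D2", call = match.call(),
                 dist.method = "biomarker-count"),
            class = "hclust")
}

#' Principal component analysis of a score matrix
#'
#' Column-centered (not variance-scaled) PCA of the samples-by-features
#' score matrix via singular value decomposition, reporting the
#' fraction of total variance explained per component.
#'
#' @param x a \linkS4class{ScoreMatrix}.
#' @param nComponents number of components to retain.
#' @return list with \code{coordinates} (samples x components),
#'   \code{loadings} (features x components),
#'   \code{varianceExplained} (numeric, per retained component) and
#'   \code{localization} (per-sample labels, for plotting).
#' @export
pcaScores <- function(x, nComponents = 2) {
  stopifnot(is(x, "ScoreMatrix"))
  sc <- t(scores(x))                       # samples x features
  if (nrow(sc) < 2L || ncol(sc) < 1L)
    stop("need at least 2 samples and 1 feature")
  if (nComponents > min(dim(sc)))
    stop("nComponents exceeds matrix rank bound")
  p <- stats::prcomp(sc, center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  k <- seq_len(nComponents)
  list(coordinates = p$x[, k, drop = FALSE],
       loadings = p$rotation[, k, drop = FALSE],
       varianceExplained = ve[k],
       localization = localizations(x))
}
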