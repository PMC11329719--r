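#' Build the two-class training set for unsupervised random forests
#'
#' Unsupervised random-forest clustering trains a classifier to separate the
#' observed rows from a synthetic contrast class drawn from the product of the
#' observed marginals: each feature of the synthetic class is resampled with
#' replacement from its own column, independently of the others. The forest
#' then learns the dependence structure of the real data, and its proximities
#' measure how often two real subjects co-occur in terminal nodes.
#'
#' @param x numeric matrix (subjects x features) or [roi_matrix()].
#' @param seed integer seed (resampling is deterministic given it).
#' @return List with `x` (2n x p matrix: observed rows then synthetic rows)
#'   and `y` (factor `"observed"` / `"synthetic"`).
#' @export
synthetic_contrast <- function(x, seed) {
  if (inherits(x, "roi_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) < 10) stop("need at least 10 subjects")
  if (all(apply(x, 2, function(col) length(unique(col)) < 2)))
    stop("fewer than 2 distinct values in every feature")
  set.seed(as.integer(seed))
  synth <- apply(x, 2, function(col) sample(col, length(col), replace = TRUE))
  rownames(synth) <- paste0("synthetic_", seq_len(nrow(x)))
  list(x = rbind(x, synth),
       y = factor(rep(c("observed", "synthetic"), each = nrow(x))))
}

#' Random-forest proximity matrix over the observed subjects
#'
#' Trains a classification forest on the observed-vs-synthetic contrast and
#' returns, for the observed subjects only, the fraction of trees in which
#' each pair falls in the same terminal node. The matrix is symmetric with
#' unit diagonal and entries in \[0, 1\].
#'
#' @param x numeric matrix or [roi_matrix()] of observed subjects.
#' @param n_trees number of trees (default 2000; proximity standard error
#'   scales as `1/sqrt(n_trees)`).
#' @param seed integer seed controlling both the synthetic contrast and the
#'   forest.
#' @return A `proximity_matrix`: n x n matrix with attributes `n_trees` and
#'   `seed`.
#' @export
rf_proximity <- function(x, n_trees = 2000, seed = 1) {
  if (inherits(x, "roi_matrix")) x <- x$values
  x <- as.matrix(x)
  n <- nrow(x)
  contrast <- synthetic_contrast(x, seed)
  set.seed(as.integer(seed))
  fit <- randomForest::randomForest(x = contrast$x, y = contrast$y,
                                    ntree = n_trees, proximity = TRUE,
                                    oob.prox = FALSE, keep.forest = FALSE)
  P <- fit$proximity[seq_len(n), seq_len(n), drop = FALSE]
  if (all(P >= 0.999))
    stop("degenerate forest: all subjects share terminal nodes; ",
         "increase n_trees or provide more structured features")
  dimnames(P) <- list(rownames(x), rownames(x))
  structure(P, n_trees = n_trees, seed = as.integer(seed),
            class = c("proximity_matrix", "matrix"))
}

#' Convert a proximity matrix to a dissimilarity matrix
#'
#' Default transform `d = sqrt(1 - p)`, which behaves closer to a Euclidean
#' metric for random-forest proximities; `method = "one_minus"` gives the
#' plain `1 - p` alternative.
#'
#' @param P proximity matrix (symmetric, unit diagonal, entries in \[0, 1\]).
#' @param method `"sqrt"` (default) or `"one_minus"`.
#' @return Symmetric dissimilarity matrix with zero diagonal.
#' @export
proximity_to_dissimilarity <- function(P, method = c("sqrt", "one_minus")) {
  method <- match.arg(method)
  P <- as.matrix(P)
  if (any(P < -1e-9) || any(P > 1 + 1e-9)) stop("proximities must be in [0, 1]")
  D <- if (method == "sqrt") sqrt(pmax(1 - P, 0)) else pmax(1 - P, 0)
  diag(D) <- 0
  D
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers `-D^2 / 2`, eigendecomposes, and returns the top-`d`
#' coordinates scaled by the square root of the (non-negative) eigenvalues.
#' Exact for Euclidean input distances. If fewer than `d` positive eigenvalues
#' exist, the remaining coordinates are zero-padded with a warning.
#'
#' @param D symmetric dissimilarity matrix with zero diagonal (or `dist`).
#' @param d target dimension (`1 <= d <= n - 1`).
#' @return An `mds_embedding`: list with `points` (n x d), `eig` (all
#'   eigenvalues, descending) and `d`.
#' @export
classical_mds <- function(D, d = 3) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (d < 1 || d > n - 1) stop("`d` must be in [1, n - 1]")
  fit <- suppressWarnings(stats::cmdscale(D, k = d, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < d) {
    warning("only ", ncol(pts), " positive eigenvalue(s); padding to d = ", d)
    pts <- cbind(pts, matrix(0, n, d - ncol(pts)))
  }
  rownames(pts) <- rownames(D)
  colnames(pts) <- paste0("C", seq_len(d))
  structure(list(points = pts, eig = sort(fit$eig, decreasing = TRUE), d = d),
            class = "mds_embedding")
}

#' Choose the embedding dimension from the eigenvalue scree
#'
#' The elbow is the position of the largest drop in successive eigenvalue
#' ratios: `d = argmin_i eig[i + 1] / eig[i]` over the positive part of the
#' spectrum, capped at `max_d`. Passing `force_d` overrides the data-driven
#' choice (the production default fixes `d = 3`).
#'
#' @param eig eigenvalues sorted in descending order.
#' @param max_d cap on the returned dimension.
#' @param force_d optional fixed dimension returned regardless of spectrum.
#' @return Integer dimension.
#' @export
scree_select <- function(eig, max_d = 10, force_d = NULL) {
  if (!is.null(force_d)) return(as.integer(force_d))
  pos <- eig[eig > 0]
  if (length(pos) < 2) stop("fewer than 2 positive eigenvalues")
  ratios <- pos[-1] / pos[-length(pos)]
  min(which.min(ratios), max_d)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Unweighted pair-group agglomeration: the distance between two clusters is
#' the mean over all cross-pairs. Input may be raw points (Euclidean distances
#' are computed) or a precomputed dissimilarity.
#'
#' @param x numeric matrix of points, `dist` object, or square dissimilarity
#'   matrix.
#' @return An `hclust` object (merge heights are non-decreasing).
#' @export
average_linkage <- function(x) {
  d <- if (inherits(x, "dist")) x
  else if (is.matrix(x) && nrow(x) == ncol(x) &&
           isTRUE(all.equal(unname(x), unname(t(x)), tolerance = 1e-8)) &&
           all(abs(diag(x)) < 1e-12)) stats::as.dist(x)
  else stats::dist(as.matrix(x))
  if (any(is.na(d))) stop("NaN/NA distances")
  if (attr(d, "Size") < 2) stop("need at least 2 subjects")
  stats::hclust(d, method = "average")
}

#' Cut a linkage tree into k clusters, numbered by descending size
#'
#' Cluster 1 is always the largest retained cluster; ties break toward the
#' cluster containing the earlier subject.
#'
#' @param tree `hclust` object.
#' @param k number of clusters (`1 <= k <= n`).
#' @return Named integer vector of labels in `1..k`.
#' @export
cut_tree <- function(tree, k) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("`k` out of range")
  raw <- stats::cutree(tree, k = k)
  sizes <- table(raw)
  first_seen <- vapply(names(sizes), function(l) which(raw == l)[1], 1L)
  new_order <- names(sizes)[order(-as.vector(sizes), first_seen)]
  relab <- stats::setNames(seq_along(new_order), new_order)
  out <- relab[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Run the full clustering engine on a feature matrix
#'
#' Chains [synthetic_contrast()] + [rf_proximity()],
#' [proximity_to_dissimilarity()], [classical_mds()] and [average_linkage()]:
#' the hierarchical clustering operates on Euclidean distances in the
#' `d`-component embedding, not on the raw forest dissimilarity.
#'
#' @param x numeric matrix or [roi_matrix()] (subjects to cluster).
#' @param n_trees forest size.
#' @param seed integer seed.
#' @param d embedding dimension (default 3).
#' @param dissimilarity `"sqrt"` or `"one_minus"`.
#' @return List with `proximity`, `embedding`, `tree`.
#' @export
rf_cluster_pipeline <- function(x, n_trees = 2000, seed = 1, d = 3,
                                dissimilarity = c("sqrt", "one_minus")) {
  dissimilarity <- match.arg(dissimilarity)
  P <- rf_proximity(x, n_trees = n_trees, seed = seed)
  D <- proximity_to_dissimilarity(P, method = dissimilarity)
  emb <- classical_mds(D, d = d)
  tree <- average_linkage(emb$points)
  list(proximity = P, embedding = emb, tree = tree)
}
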