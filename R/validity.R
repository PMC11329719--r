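# Internal helpers shared by the validity indices ---------------------------

.cluster_stats <- function(X, labels) {
  labs <- sort(unique(labels))
  cent <- matrix(NA_real_, length(labs), ncol(X))
  for (i in seq_along(labs))
    cent[i, ] <- colMeans(X[labels == labs[i], , drop = FALSE])
  sizes <- vapply(labs, function(l) sum(labels == l), 1L)
  gmean <- colMeans(X)
  wgss_c <- vapply(seq_along(labs), function(i) {
    sum(sweep(X[labels == labs[i], , drop = FALSE], 2, cent[i, ])^2)
  }, numeric(1))
  list(labs = labs, k = length(labs), sizes = sizes, centroids = cent,
       wgss_c = wgss_c, wgss = sum(wgss_c),
       tss = sum(sweep(X, 2, gmean)^2),
       bgss = sum(sizes * rowSums(sweep(cent, 2, gmean)^2)))
}

.pair_split <- function(D, labels) {
  same <- outer(labels, labels, "==")
  ut <- upper.tri(D)
  list(within = D[ut & same], between = D[ut & !same])
}

.index_registry <- list(
  calinski_harabasz = list(rule = "max", needs = "points"),
  dunn              = list(rule = "max", needs = "dist"),
  silhouette        = list(rule = "max", needs = "dist"),
  davies_bouldin    = list(rule = "min", needs = "points"),
  c_index           = list(rule = "min", needs = "dist"),
  mcclain_rao       = list(rule = "min", needs = "dist"),
  point_biserial    = list(rule = "max", needs = "dist"),
  gamma             = list(rule = "max", needs = "dist"),
  xie_beni          = list(rule = "min", needs = "both"),
  ball_hall         = list(rule = "maxdiff", needs = "points"),
  hartigan          = list(rule = "maxdiff", needs = "points"),
  ratkowsky_lance   = list(rule = "max", needs = "points")
)

#' Names and direction rules of the implemented validity indices
#'
#' The registry implements twelve classical internal cluster-validity
#' indices. `rule` states how an index selects its optimal k in the ensemble:
#' `"max"`/`"min"` pick the extremum of the index over the k range;
#' `"maxdiff"` (Ball-Hall, Hartigan) picks the k with the largest drop from
#' the previous hierarchy level, the customary elbow rule for monotone
#' indices.
#'
#' @return data.frame with columns `index` and `rule`.
#' @export
validity_indices <- function() {
  data.frame(index = names(.index_registry),
             rule = vapply(.index_registry, `[[`, "", "rule"),
             row.names = NULL)
}

.silhouette_values <- function(D, labels) {
  n <- length(labels)
  labs <- sort(unique(labels))
  vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    if (sum(own) == 1) return(0)
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(labs[labs != labels[i]],
                    function(l) mean(D[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
}

.gamma_counts <- function(within, between) {
  sb <- sort(between)
  nb <- length(sb)
  c_le <- findInterval(within, sb)                   # between <= w
  c_lt <- findInterval(within, sb, left.open = TRUE) # between <  w
  s_plus <- sum(nb - c_le)   # pairs with within < between
  s_minus <- sum(c_lt)       # pairs with within > between
  c(s_plus = s_plus, s_minus = s_minus)
}

.index_value <- function(name, X, labels, D, stats = NULL, pairs = NULL,
                         wgss_next = NA) {
  if (is.null(stats)) stats <- .cluster_stats(X, labels)
  k <- stats$k
  n <- nrow(X)
  if (name %in% c("dunn", "silhouette", "c_index", "mcclain_rao",
                  "point_biserial", "gamma", "xie_beni") && is.null(pairs))
    pairs <- .pair_split(D, labels)
  switch(name,
    calinski_harabasz = {
      if (k < 2 || stats$wgss == 0) return(NaN)
      (stats$bgss / (k - 1)) / (stats$wgss / (n - k))
    },
    dunn = {
      diam <- max(pairs$within, 0)
      if (diam == 0 || !length(pairs$between)) return(NaN)
      min(pairs$between) / diam
    },
    silhouette = mean(.silhouette_values(D, labels)),
    davies_bouldin = {
      S <- vapply(seq_len(k), function(i) {
        mean(sqrt(rowSums(sweep(X[labels == stats$labs[i], , drop = FALSE],
                                2, stats$centroids[i, ])^2)))
      }, numeric(1))
      M <- as.matrix(stats::dist(stats$centroids))
      if (any(M[upper.tri(M)] == 0)) return(NaN)
      mean(vapply(seq_len(k), function(i)
        max(((S[i] + S[-i]) / M[i, -i])), numeric(1)))
    },
    c_index = {
      w <- pairs$within
      nw <- length(w)
      if (!nw) return(NaN)
      alld <- sort(c(pairs$within, pairs$between))
      smin <- sum(alld[seq_len(nw)])
      smax <- sum(alld[seq.int(length(alld) - nw + 1, length(alld))])
      if (smax == smin) return(NaN)
      (sum(w) - smin) / (smax - smin)
    },
    mcclain_rao = {
      if (!length(pairs$within) || !length(pairs$between)) return(NaN)
      mean(pairs$within) / mean(pairs$between)
    },
    point_biserial = {
      alld <- c(pairs$within, pairs$between)
      s <- stats::sd(alld)
      if (is.na(s) || s == 0) return(NaN)
      nw <- length(pairs$within); nb <- length(pairs$between)
      nt <- nw + nb
      (mean(pairs$between) - mean(pairs$within)) *
        sqrt(nw * nb / nt^2) / s
    },
    gamma = {
      cc <- .gamma_counts(pairs$within, pairs$between)
      tot <- cc["s_plus"] + cc["s_minus"]
      if (tot == 0) return(NaN)
      unname((cc["s_plus"] - cc["s_minus"]) / tot)
    },
    xie_beni = {
      sep <- if (length(pairs$between)) min(pairs$between)^2 else NA
      if (is.na(sep) || sep == 0) return(NaN)
      stats$wgss / (n * sep)
    },
    ball_hall = mean(stats$wgss_c / stats$sizes),
    hartigan = {
      if (is.na(wgss_next)) stop("hartigan requires the k + 1 partition")
      if (wgss_next == 0) return(NaN)
      (stats$wgss / wgss_next - 1) * (n - k - 1)
    },
    ratkowsky_lance = {
      gmean <- colMeans(X)
      bgss_j <- colSums(stats$sizes *
                          sweep(stats$centroids, 2, gmean)^2)
      tss_j <- colSums(sweep(X, 2, gmean)^2)
      ok <- tss_j > 0
      if (!any(ok)) return(NaN)
      sqrt(mean(bgss_j[ok] / tss_j[ok])) / sqrt(k)
    },
    stop("unknown index name: ", name)
  )
}

#' Evaluate one internal cluster-validity index
#'
#' Scores a partition with one of the indices in [validity_indices()]. The
#' result carries a `direction` attribute (`"max"`, `"min"`, or `"maxdiff"`)
#' stating how the index is optimized over k. Degenerate partitions (zero
#' within-spread, coincident centroids, ...) yield `NaN`, which the ensemble
#' treats as an abstention.
#'
#' @param name index name.
#' @param points numeric matrix of coordinates (subjects x dimensions).
#' @param labels integer cluster labels (>= 2 non-empty clusters).
#' @param D optional precomputed full Euclidean distance matrix.
#' @param labels_next partition at k + 1 clusters; required for `"hartigan"`.
#' @return Numeric score with attribute `direction`.
#' @export
validity_index <- function(name, points, labels, D = NULL,
                           labels_next = NULL) {
  if (!name %in% names(.index_registry))
    stop("unknown index name: ", name)
  points <- as.matrix(points)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("need at least 2 non-empty clusters")
  if (is.null(D) && .index_registry[[name]]$needs != "points")
    D <- as.matrix(stats::dist(points))
  wn <- NA
  if (name == "hartigan") {
    if (is.null(labels_next))
      stop("hartigan requires the k + 1 partition via `labels_next`")
    wn <- .cluster_stats(points, as.integer(labels_next))$wgss
  }
  val <- .index_value(name, points, labels, D, wgss_next = wn)
  structure(val, direction = .index_registry[[name]]$rule)
}

#' Choose the number of clusters by majority vote of validity indices
#'
#' For every k in `k_range` the linkage tree is cut and each index scored;
#' each index then votes for its optimal k according to its direction rule
#' (see [validity_indices()]). Indices returning `NaN` at some k abstain
#' there; an index with no finite value abstains entirely. The winning k is
#' the modal vote (ties broken toward smaller k) and the runner-up is the
#' second mode.
#'
#' @param points numeric matrix of coordinates used for clustering (e.g. the
#'   3-component embedding).
#' @param tree `hclust` tree over the same subjects.
#' @param k_range candidate cluster counts (subset of `2..n - 1`).
#' @param indices index names (default: the full registry).
#' @return A `vote_record`: list with `winner`, `runner_up`, `votes` (named
#'   per index), `tally`, `scores` (index x k matrix), `k_range`.
#' @export
ensemble_vote <- function(points, tree, k_range = 2:15,
                          indices = names(.index_registry)) {
  points <- as.matrix(points)
  n <- nrow(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("`k_range` must lie within [2, n - 1]")
  bad <- setdiff(indices, names(.index_registry))
  if (length(bad)) stop("unknown index name: ", paste(bad, collapse = ", "))

  D <- as.matrix(stats::dist(points))
  ks_all <- sort(unique(c(k_range, k_range - 1L, k_range + 1L)))
  ks_all <- ks_all[ks_all >= 1 & ks_all <= n]
  labels_by_k <- lapply(ks_all, function(k) cut_tree(tree, k))
  names(labels_by_k) <- ks_all
  stats_by_k <- lapply(labels_by_k, function(l) .cluster_stats(points, l))
  pairs_by_k <- lapply(labels_by_k, function(l) {
    if (length(unique(l)) < 2) NULL else .pair_split(D, l)
  })

  scores <- matrix(NA_real_, length(indices), length(k_range),
                   dimnames = list(indices, k_range))
  for (nm in indices) {
    for (j in seq_along(k_range)) {
      k <- k_range[j]
      kc <- as.character(k)
      wn <- if (nm == "hartigan") {
        knext <- as.character(k + 1L)
        if (knext %in% names(stats_by_k)) stats_by_k[[knext]]$wgss else NA
      } else NA
      val <- tryCatch(
        .index_value(nm, points, labels_by_k[[kc]], D,
                     stats = stats_by_k[[kc]], pairs = pairs_by_k[[kc]],
                     wgss_next = wn),
        error = function(e) NaN)
      scores[nm, j] <- val
    }
  }

  vote_one <- function(nm) {
    v <- scores[nm, ]
    rule <- .index_registry[[nm]]$rule
    if (rule %in% c("max", "min")) {
      if (all(!is.finite(v))) return(NA_integer_)
      if (rule == "min") v <- -v
      v[!is.finite(v)] <- -Inf
      k_range[which.max(v)]
    } else {  # maxdiff: largest drop from the previous hierarchy level
      prev <- vapply(k_range - 1L, function(kp) {
        kc <- as.character(kp)
        if (!kc %in% names(stats_by_k)) return(NA_real_)
        st <- stats_by_k[[kc]]
        if (nm == "ball_hall") return(mean(st$wgss_c / st$sizes))
        # hartigan at k - 1 uses wgss(k - 1) and wgss(k)
        wk <- stats_by_k[[as.character(kp + 1L)]]$wgss
        if (wk == 0) return(NA_real_)
        (st$wgss / wk - 1) * (nrow(points) - kp - 1)
      }, numeric(1))
      drop <- prev - v
      if (all(!is.finite(drop))) return(NA_integer_)
      drop[!is.finite(drop)] <- -Inf
      k_range[which.max(drop)]
    }
  }
  votes <- vapply(indices, vote_one, integer(1))
  if (all(is.na(votes))) stop("all indices abstained")
  tally <- sort(table(votes[!is.na(votes)]), decreasing = TRUE)
  top <- max(tally)
  winner <- min(as.integer(names(tally)[tally == top]))
  rest <- tally[as.integer(names(tally)) != winner]
  runner_up <- if (length(rest))
    min(as.integer(names(rest)[rest == max(rest)])) else NA_integer_
  structure(list(winner = winner, runner_up = runner_up, votes = votes,
                 tally = tally, scores = scores, k_range = k_range),
            class = "vote_record")
}

#' @export
print.vote_record <- function(x, ...) {
  cat(sprintf("<vote_record> winner k = %d (runner-up k = %s)\n", x$winner,
              ifelse(is.na(x$runner_up), "none", x$runner_up)))
  print(x$tally)
  invisible(x)
}

#' Exclude clusters below a minimum size
#'
#' Clusters with fewer than `min_size` members are marked excluded; their
#' subjects keep an `NA` label (they are flagged, never reassigned) and the
#' retained clusters are renumbered by descending size, so cluster 1 is
#' always the largest retained cluster.
#'
#' @param labels integer cluster labels (named by subject id).
#' @param min_size minimum retained cluster size (default 10).
#' @return A `cluster_solution`: list with `labels` (renumbered, `NA` for
#'   excluded members), `k` (retained cluster count), `retained_sizes`,
#'   `excluded` (data.frame of excluded cluster sizes).
#' @export
filter_small_clusters <- function(labels, min_size = 10) {
  if (inherits(labels, "cluster_solution")) labels <- labels$labels
  sizes <- table(labels)
  keep <- names(sizes)[sizes >= min_size]
  if (!length(keep)) stop("all clusters fall below min_size = ", min_size)
  dropped <- names(sizes)[sizes < min_size]
  first_seen <- vapply(keep, function(l) which(labels == l)[1], 1L)
  new_order <- keep[order(-as.vector(sizes[keep]), first_seen)]
  relab <- stats::setNames(seq_along(new_order), new_order)
  out <- rep(NA_integer_, length(labels))
  kept_mask <- as.character(labels) %in% keep
  out[kept_mask] <- relab[as.character(labels)[kept_mask]]
  names(out) <- names(labels)
  structure(list(labels = out, k = length(keep),
                 retained_sizes = sort(as.vector(sizes[keep]),
                                       decreasing = TRUE),
                 excluded = data.frame(
                   cluster = as.integer(dropped),
                   size = as.vector(sizes[dropped])),
                 min_size = min_size),
            class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> %d retained cluster(s), sizes: %s\n", x$k,
              paste(x$retained_sizes, collapse = ", ")))
  if (nrow(x$excluded))
    cat("excluded (<", x$min_size, "):",
        paste(x$excluded$size, collapse = ", "), "\n")
  invisible(x)
}
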