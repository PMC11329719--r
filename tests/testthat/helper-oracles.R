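# Independent brute-force oracles used to validate the package's
# implementations on small instances. Each re-derives its quantity directly
# from the textbook definition with naive loops, sharing no code with R/.

# Unweighted pair-group average agglomeration, O(n^3): cluster distance is
# the mean over all cross pairs of the *original* dissimilarity.
naive_upgma_heights <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        dd <- mean(D[clusters[[i]], clusters[[j]]])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# Kruskal-Wallis H from the rank formula with tie correction.
naive_kruskal <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) - 3 * (N + 1)
  ties <- table(values)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Benjamini-Hochberg step-up: q_(i) = min over j >= i of m * p_(j) / j.
naive_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(i)
    min(pmin(1, m * ps[i:m] / (i:m))), numeric(1))
  q[o] <- qs
  q
}

# Brute-force validity indices from their definitions (loops, no shared code)
brute_ch <- function(X, lab) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- length(unique(lab))
  g <- colMeans(X)
  b <- 0; w <- 0
  for (l in unique(lab)) {
    xs <- X[lab == l, , drop = FALSE]
    c_l <- colMeans(xs)
    b <- b + nrow(xs) * sum((c_l - g)^2)
    for (i in seq_len(nrow(xs))) w <- w + sum((xs[i, ] - c_l)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

brute_dunn <- function(X, lab) {
  D <- as.matrix(dist(X))
  inter <- Inf; diam <- 0
  n <- nrow(D)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (lab[i] == lab[j]) diam <- max(diam, D[i, j])
    else inter <- min(inter, D[i, j])
  }
  inter / diam
}

brute_silhouette <- function(X, lab) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  mean(vapply(seq_len(n), function(i) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(D[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

brute_gamma <- function(X, lab) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  within <- c(); between <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (lab[i] == lab[j]) within <- c(within, D[i, j])
    else between <- c(between, D[i, j])
  }
  sp <- 0; sm <- 0
  for (w in within) for (b in between) {
    if (w < b) sp <- sp + 1
    if (w > b) sm <- sm + 1
  }
  (sp - sm) / (sp + sm)
}

brute_c_index <- function(X, lab) {
  D <- as.matrix(dist(X))
  n <- nrow(D)
  within <- c(); alld <- c()
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    alld <- c(alld, D[i, j])
    if (lab[i] == lab[j]) within <- c(within, D[i, j])
  }
  nw <- length(within)
  s <- sort(alld)
  (sum(within) - sum(s[1:nw])) / (sum(rev(s)[1:nw]) - sum(s[1:nw]))
}

# Small helper: deterministic Gaussian blob data
make_blobs <- function(n_per, centers, sd = 1, seed = 1, p = 2) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(rnorm(n_per * p, sd = sd), n_per, p) +
      matrix(centers[i, ], n_per, p, byrow = TRUE)))
  rownames(X) <- paste0("s", seq_len(nrow(X)))
  list(x = X, labels = rep(seq_len(nrow(centers)), each = n_per))
}
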