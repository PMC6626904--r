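# Independent brute-force oracles used to validate the fast implementations.

# Greedy farthest-point selection from a fixed start, ties to lowest index.
# Quadratic reference implementation, structured differently from the C++.
oracle_fps <- function(points, k, start) {
  points <- as.matrix(points)
  n <- nrow(points)
  chosen <- integer(k)
  chosen[1L] <- start
  for (s in seq_len(k - 1L)) {
    d <- vapply(seq_len(n), function(i) {
      min(vapply(chosen[seq_len(s)], function(c)
        sqrt(sum((points[i, ] - points[c, ])^2)), 0))
    }, 0)
    chosen[s + 1L] <- which.max(d)  # which.max ties to lowest index
    if (d[chosen[s + 1L]] <= 0)
      stop("fewer distinct points than k")
  }
  chosen
}

# The start index farthest_point_sampling() derives from a seed.
fps_start <- function(n, seed) {
  set.seed(seed)
  sample.int(n, 1L)
}

# Exhaustive k-center optimum (minimal covering radius over all subsets).
oracle_kcenter_opt <- function(points, k) {
  points <- as.matrix(points)
  best <- Inf
  for (sub in utils::combn(nrow(points), k, simplify = FALSE)) {
    r <- covering_radius(points, points[sub, , drop = FALSE])
    if (r < best) best <- r
  }
  best
}

# Naive O(n^3) complete-linkage agglomeration; returns merge heights in
# order and the partition labels at every cluster count.
oracle_complete_linkage <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  groups <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  labels <- seq_len(n)
  partitions[[n]] <- labels
  while (length(groups) > 1L) {
    m <- length(groups)
    best <- c(NA, NA); besth <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      h <- max(d[groups[[i]], groups[[j]]])
      if (h < besth) { besth <- h; best <- c(i, j) }
    }
    heights <- c(heights, besth)
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
    labels <- integer(n)
    for (g in seq_along(groups)) labels[groups[[g]]] <- g
    partitions[[length(groups)]] <- labels
  }
  list(heights = heights, partitions = partitions)
}

# Exact two-sided Mann-Whitney p by full enumeration (small tie-free data).
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1, simplify = FALSE)
  us <- vapply(combs, function(idx)
    sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2, 0)
  mu <- n1 * n2 / 2
  p <- mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
  p
}

# Partitions equal up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  expected <- ai * bj / nn
  (nij - expected) / ((ai + bj) / 2 - expected)
}
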