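# Independent oracles. These deliberately avoid the package's code paths:
# Floyd-Warshall for distances, pruned exhaustive path enumeration for
# betweenness, restricted-growth-string enumeration for modularity.

# all-pairs shortest path lengths from a weight matrix, by Floyd-Warshall
fw_dist <- function(w) {
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- 0
  n <- nrow(L)
  d <- L
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

fw_global_efficiency <- function(w) {
  d <- fw_dist(w)
  n <- nrow(d)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# exhaustive betweenness: enumerate every shortest path between every pair
# by DFS, pruned with the admissible Floyd-Warshall bound. Each unordered
# pair counted once, endpoints excluded, ties share credit.
brute_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  L <- ifelse(w > 0, 1 / w, Inf)
  diag(L) <- Inf
  d <- fw_dist(w)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(d[s, t])) next
      paths <- list()
      dfs <- function(cur, len, path) {
        if (cur == t) {
          if (abs(len - d[s, t]) <= tol) paths[[length(paths) + 1]] <<- path
          return(invisible())
        }
        for (v in which(is.finite(L[cur, ]))) {
          if (v %in% path) next
          nl <- len + L[cur, v]
          if (nl + d[v, t] > d[s, t] + tol) next
          dfs(v, nl, c(path, v))
        }
      }
      dfs(s, 0, s)
      sigma <- length(paths)
      if (sigma == 0) next
      for (p in paths) {
        inner <- setdiff(p, c(s, t))
        bc[inner] <- bc[inner] + 1 / sigma
      }
    }
  }
  bc
}

# all set partitions of n elements as restricted growth strings
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, maxl) {
    if (i > n) {
      out[[length(out) + 1L]] <<- rgs[1:n]
      return(invisible())
    }
    for (l in 1:(maxl + 1L)) {
      rgs[i] <<- l
      rec(i + 1L, max(maxl, l))
    }
  }
  rec(1L, 0L)
  out
}

# exhaustive modularity optimum (uses the package's Q definition on every
# partition; the search, not the functional, is the oracle here)
exhaustive_q <- function(w) {
  max(vapply(all_partitions(nrow(w)), function(p) newman_q(w, p),
             numeric(1)))
}

# random symmetric weight matrix, zero diagonal
rand_weights <- function(n, density = 0.6) {
  m <- n * (n - 1) / 2
  up <- ifelse(stats::runif(m) < density, stats::runif(m, 0.1, 1), 0)
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- up
  w + t(w)
}
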