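test_that("shortest paths: single-edge reciprocal, disconnection, FW oracle", {
  w <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(shortest_path_lengths(w)[1, 2], 2)

  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- w3[2, 1] <- 1
  d <- shortest_path_lengths(w3)
  expect_equal(d[1, 3], Inf)
  expect_equal(unname(diag(d)), rep(0, 3))

  set.seed(31)
  for (i in 1:25) {
    w <- rand_weights(8, density = runif(1, 0.3, 0.9))
    expect_lt(max(abs(shortest_path_lengths(w) - fw_dist(w)),
                  na.rm = TRUE), 1e-9)
  }
  expect_error(shortest_path_lengths(matrix(c(0, -1, -1, 0), 2, 2)),
               "negative")
})

test_that("global efficiency: closed forms and 4-node weighted toy", {
  n <- 6
  complete <- matrix(1, n, n); diag(complete) <- 0
  expect_equal(global_efficiency(complete), 1)
  expect_equal(global_efficiency(matrix(0, 5, 5)), 0)

  # fixed documented toy; expected value frozen from the FW oracle
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.8
  w[2, 3] <- w[3, 2] <- 0.5
  w[3, 4] <- w[4, 3] <- 0.4
  w[1, 4] <- w[4, 1] <- 0.2
  w[1, 3] <- w[3, 1] <- 0.6
  expect_equal(global_efficiency(w), 0.460370370370370, tolerance = 1e-12)
  expect_equal(global_efficiency(w), fw_global_efficiency(w),
               tolerance = 1e-12)
})

test_that("increasing a weight never decreases global efficiency", {
  set.seed(32)
  for (i in 1:10) {
    w <- rand_weights(7)
    e0 <- global_efficiency(w)
    up <- which(upper.tri(w), arr.ind = TRUE)
    pick <- up[sample(nrow(up), 1), ]
    w2 <- w
    w2[pick[1], pick[2]] <- w2[pick[2], pick[1]] <-
      min(1, w[pick[1], pick[2]] + runif(1, 0.05, 0.4))
    expect_gte(global_efficiency(w2), e0 - 1e-12)
  }
})

test_that("local efficiency: degenerate neighborhoods and triangle formula", {
  # isolated node and single-neighbor node score 0
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 0.7
  e <- local_efficiency(w)
  expect_equal(unname(e), rep(0, 4))

  # unit triangle: neighborhood of each node is one unit edge;
  # hand evaluation of the cube-root formula gives 1 for every node
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(unname(local_efficiency(tri)), rep(1, 3))

  # weighted triangle, hand-derived: for node u with neighbors j,h,
  # E(u) = (w_uj w_uh)^{1/3} * min over direct edge vs two-step path of
  # the cube-root lengths, here direct: ((1/w_jh)^{1/3})^{-1}
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 0.8
  w[1, 3] <- w[3, 1] <- 0.5
  w[2, 3] <- w[3, 2] <- 0.9
  ew <- function(a, b) w[a, b]
  hand <- function(u, j, h) {
    direct <- (1 / ew(j, h))^(1 / 3)
    via_u <- Inf  # u excluded from its own neighborhood subgraph
    (ew(u, j) * ew(u, h))^(1 / 3) / min(direct, via_u)
  }
  expect_equal(local_efficiency(w)[1], c(hand(1, 2, 3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(local_efficiency(w)[3], c(hand(3, 1, 2)), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("betweenness: path and star closed forms", {
  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- 1
  path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(unname(betweenness_w(path3)), c(0, 1, 0))

  n_leaves <- 5
  star <- matrix(0, n_leaves + 1, n_leaves + 1)
  star[1, -1] <- star[-1, 1] <- 1
  bc <- betweenness_w(star)
  expect_equal(bc[1], n_leaves * (n_leaves - 1) / 2, ignore_attr = TRUE)
  expect_equal(unname(bc[-1]), rep(0, n_leaves))
})

test_that("betweenness matches exhaustive path enumeration on random graphs", {
  set.seed(33)
  for (i in 1:15) {
    w <- rand_weights(7, density = runif(1, 0.3, 0.8))
    expect_equal(betweenness_w(w), brute_betweenness(w),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # tied shortest paths get fractional credit: 4-cycle with unit weights
  cyc <- matrix(0, 4, 4)
  for (p in list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))) {
    cyc[p[1], p[2]] <- cyc[p[2], p[1]] <- 1
  }
  expect_equal(unname(betweenness_w(cyc)), rep(0.5, 4))
})

test_that("nBC normalization and hub identification follow the stated rules", {
  expect_equal(normalize_bc(c(2, 1, 1)), c(1.5, 0.75, 0.75))
  set.seed(34)
  for (i in 1:5) {
    bc <- runif(68, 0, 50)
    expect_equal(mean(normalize_bc(bc)), 1, tolerance = 1e-12)
    expect_equal(normalize_bc(bc * 7.7), normalize_bc(bc))
  }
  expect_error(normalize_bc(rep(0, 5)), "not positive")

  # threshold oracle: mean + sample SD of [2,1,.5,.5] = 1.7071...
  x <- c(a = 2, b = 1, c = 0.5, d = 0.5)
  expect_gt(2, mean(x) + sd(x))
  expect_identical(identify_subject_hubs(x), "a")
  expect_identical(identify_subject_hubs(rep(1, 10)), integer(0))
  expect_identical(identify_subject_hubs(x + 5), "a")  # location invariance
})

test_that("modularity: closed forms and exhaustive-partition oracle", {
  # two disjoint unit-weight 4-cliques -> Q = 0.5 at the 2-block partition
  clique <- function(n) { m <- matrix(1, n, n); diag(m) <- 0; m }
  two <- matrix(0, 8, 8)
  two[1:4, 1:4] <- clique(4)
  two[5:8, 5:8] <- clique(4)
  expect_equal(newman_q(two, rep(1:2, each = 4)), 0.5)
  # one community over a single clique -> Q = 0
  expect_equal(newman_q(clique(5), rep(1, 5)), 0)

  res <- modularity_best(two, rounds = 10, seed = 1)
  expect_equal(res$q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(res$membership)), 2)

  # best-of-rounds never exceeds the exhaustive optimum and usually hits
  # it; sparse 7-node graphs can have Q landscapes where greedy moves
  # cannot reach the optimum, so the strict 95% check lives in the
  # acceptance suite on its stated (denser) regime
  set.seed(35)
  hits <- 0
  for (i in 1:12) {
    w <- rand_weights(7, density = 0.5)
    if (sum(w) == 0) next
    qstar <- exhaustive_q(w)
    got <- modularity_best(w, rounds = 100, seed = i)$q
    expect_lte(got, qstar + 1e-9)
    hits <- hits + (abs(got - qstar) < 1e-9)
  }
  expect_gte(hits, 10)
  expect_error(modularity_best(two, rounds = 0), "rounds")
})

test_that("compute_all_metrics: complete graph, isomorphism, determinism", {
  tens <- zscore_features(tiny_tensor(n_sub = 1, seed = 36))
  net <- build_network(tens, 1)

  # complete unit-weight graph: efficiency 1, all BC zero, no hubs
  r1 <- matrix(1, 10, 10)
  diag(r1) <- 0
  conn <- structure(list(r = r1, subject = "toy",
                         regions = paste0("r", 1:10)),
                    class = "conn_matrix")
  expect_warning(m <- compute_all_metrics(conn, rounds = 5, seed = 1),
                 "hub screening skipped")
  expect_equal(m$e_global, 1)
  expect_equal(unname(m$bc), rep(0, 10))
  expect_length(m$hubs, 0)

  # node relabeling permutes nodal metrics, preserves globals
  set.seed(37)
  perm <- sample(68)
  conn_p <- structure(list(r = net$r[perm, perm],
                           subject = net$subject,
                           regions = net$regions[perm]),
                      class = "conn_matrix")
  m1 <- compute_all_metrics(net, rounds = 3, seed = 2)
  m2 <- compute_all_metrics(conn_p, rounds = 3, seed = 2)
  expect_equal(m2$e_global, m1$e_global, tolerance = 1e-12)
  expect_equal(unname(m2$bc), unname(m1$bc[perm]), tolerance = 1e-9)
  expect_equal(unname(m2$e_local), unname(m1$e_local[perm]),
               tolerance = 1e-9)

  # fixed seed reproduces bit-identical results
  a <- compute_all_metrics(net, rounds = 5, seed = 42)
  b <- compute_all_metrics(net, rounds = 5, seed = 42)
  expect_identical(a, b)
})
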