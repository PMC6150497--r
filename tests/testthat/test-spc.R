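# Superparamagnetic clustering: graph construction, Swendsen-Wang sampling
# against exact Boltzmann sums, temperature profiles, persistence.

test_that("knn graph connects equidistant points symmetrically", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  g <- knn_graph(D, k = 2)
  expect_equal(nrow(g$edges), 3L)              # complete triangle
  expect_equal(length(unique(round(g$weights, 12))), 1L)  # equal weights
})

test_that("knn graph separates far blocks by orders of magnitude in weight", {
  D <- two_block_distance(half = 12, within = 0.01, between = 10,
                          jitter = 0.001, seed = 2)
  # k = 12 forces each node to reach across the gap (11 block-mates only)
  g <- knn_graph(D, k = 12)
  within <- g$edges[, 1] <= 12 & g$edges[, 2] <= 12 |
            g$edges[, 1] > 12 & g$edges[, 2] > 12
  expect_true(any(!within))   # union connectivity bridges blocks
  expect_lt(max(g$weights[!within]), 1e-6 * min(g$weights[within]))
  # every node keeps degree >= k
  deg <- tabulate(c(g$edges), nbins = 24)
  expect_true(all(deg >= 12))
})

test_that("knn graph validates its input", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_error(knn_graph(D, k = 2), "more than k")
  D3 <- matrix(0.5, 3, 3); diag(D3) <- 0; D3[1, 2] <- 0.7
  expect_error(knn_graph(D3, k = 1), "symmetric")
})

test_that("pair-correlation estimates match exhaustive Boltzmann sums on a Potts toy", {
  # 4 nodes, q = 3: exact enumeration of 3^4 = 81 states
  q <- 3
  D <- matrix(c(0, 0.3, 0.8, 1.0,
                0.3, 0, 0.6, 0.9,
                0.8, 0.6, 0, 0.4,
                1.0, 0.9, 0.4, 0), 4, 4)
  dimnames(D) <- list(letters[1:4], letters[1:4])
  g <- knn_graph(D, k = 3)
  exact_agreement <- function(temp) {
    states <- as.matrix(expand.grid(rep(list(1:q), 4)))
    energy <- apply(states, 1, function(s) {
      sum(g$weights * (s[g$edges[, 1]] != s[g$edges[, 2]]))
    })
    wgt <- exp(-energy / temp)
    wgt <- wgt / sum(wgt)
    vapply(seq_len(nrow(g$edges)), function(e) {
      sum(wgt * (states[, g$edges[, 1][e]] == states[, g$edges[, 2][e]]))
    }, numeric(1))
  }
  for (temp in c(0.05, 0.1, 0.3)) {
    sweeps <- 20000L; burn <- 500L
    trace <- bakenet:::sw_agreement_trace(g$edges - 1L, g$weights, 4L,
                                          as.integer(q), temp, sweeps,
                                          burn, seed = 1234 + temp * 100)
    est <- colMeans(trace)
    # batch-means standard error accounts for sweep autocorrelation
    nb <- 100
    batches <- apply(trace, 2, function(v)
      colMeans(matrix(v[seq_len((length(v) %/% nb) * nb)], nrow = nb)))
    se <- apply(batches, 2, sd) / sqrt(nrow(batches))
    exact <- exact_agreement(temp)
    expect_true(all(abs(est - exact) <= 3 * pmax(se, 1e-4)),
                info = sprintf("T = %.2f, max dev = %.4f",
                               temp, max(abs(est - exact))))
  }
})

test_that("profiles start as one cluster, form partitions, and melt at high T", {
  D <- two_block_distance(half = 10, seed = 3)
  prof <- spc_profile(D, spc_params(sweeps = 150, burn_in = 30), seed = 5)
  # T = 0: all items in one cluster
  expect_true(all(prof$membership[1, ] == 1L))
  expect_equal(prof$max_cluster_size[1], 20L)
  # every temperature row is a partition covering all items
  expect_true(all(!is.na(prof$membership)))
  for (r in c(10, 50, 101)) {
    labs <- prof$membership[r, ]
    expect_true(all(labs >= 1))
    expect_equal(prof$max_cluster_size[r], max(table(labs)))
  }
  # determinism in the seed
  prof2 <- spc_profile(D, spc_params(sweeps = 150, burn_in = 30), seed = 5)
  expect_identical(prof$membership, prof2$membership)
})

test_that("high temperature on unstructured distances melts all clusters", {
  melted <- vapply(1:10, function(s) {
    set.seed(s)
    X <- matrix(rnorm(30 * 12), 30, 12)
    D <- 1 - cor(t(X), method = "spearman")
    diag(D) <- 0
    dimnames(D) <- list(sprintf("g%02d", 1:30), sprintf("g%02d", 1:30))
    prof <- spc_profile((D + t(D)) / 2,
                        spc_params(sweeps = 150, burn_in = 30), seed = s)
    prof$max_cluster_size[length(prof$temperatures)] <= 3
  }, logical(1))
  expect_gte(mean(melted), 0.9)
})

test_that("a planted two-block structure is recovered exactly at some temperature", {
  D <- two_block_distance(half = 20, seed = 11)
  prof <- spc_profile(D, spc_params(), seed = 7)
  expect_true(recovers_two_blocks(prof, half = 20))
  # max cluster size is (weakly) non-increasing in T up to MC noise
  sizes <- prof$max_cluster_size
  expect_lte(sum(diff(sizes) > 0), 2)
})

test_that("persistence spans count the longest consecutive run", {
  prof <- list(items = c("a", "b", "c", "d"),
               temperatures = seq(0, 0.1, by = 0.01),
               membership = rbind(
                 matrix(rep(c(1L, 1L, 1L, 1L), 3), 3, 4, byrow = TRUE),
                 matrix(rep(c(1L, 1L, 2L, 2L), 4), 4, 4, byrow = TRUE),
                 matrix(rep(c(1L, 2L, 3L, 4L), 2), 2, 4, byrow = TRUE),
                 matrix(rep(c(1L, 1L, 2L, 2L), 2), 2, 4, byrow = TRUE)))
  class(prof) <- "spc_profile"
  per <- cluster_persistence(prof, t_min = 0)
  ab <- per[per$members == "a;b", ]
  # {a,b} appears at rows 4-7 and 10-11: span is the longest run (4)
  expect_equal(ab$span, 4L)
  full <- per[per$members == "a;b;c;d", ]
  expect_equal(full$span, 3L)
  expect_equal(full$birth, 0)
  # singletons are not clusters
  expect_false(any(per$size < 2))
  # spans sorted descending
  expect_true(all(diff(per$span) <= 0))
})

test_that("duplicate probes of one gene co-travel through the cluster hierarchy", {
  # a near-duplicate probe planted among unrelated genes: the two copies
  # must share a cluster wherever clusters exist — the most persistent
  # cluster contains both, and they are co-clustered at essentially every
  # temperature at which either belongs to any non-singleton cluster
  set.seed(21)
  X <- matrix(rnorm(20 * 26), 20, 26)
  X <- rbind(X, X[1, ] + rnorm(26, sd = 0.05))
  dimnames(X) <- list(c(sprintf("g%02d", 1:20), "g01_dup"),
                      sprintf("s%02d", 1:26))
  D <- 1 - cor(t(X), method = "spearman")
  diag(D) <- 0
  D <- (D + t(D)) / 2
  prof <- spc_profile(D, spc_params(), seed = 13)
  per <- cluster_persistence(prof, t_min = 0.01)
  expect_true(grepl("g01;g01_dup", per$members[1]))
  memb <- prof$membership
  lab1 <- memb[, "g01"]
  lab2 <- memb[, "g01_dup"]
  size1 <- vapply(seq_len(nrow(memb)), function(r)
    sum(memb[r, ] == lab1[r]), integer(1))
  active <- size1 > 1
  expect_gte(mean(lab1[active] == lab2[active]), 0.9)
})
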