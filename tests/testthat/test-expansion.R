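# Expansion around anchors: neighbour selection, distance assembly,
# critical temperature, stable clusters, edges, reverse confirmation.

test_that("top neighbours rank by signed rho with deterministic tie-breaks", {
  x <- rbind(anchor = 1:8,
             n1 = c(1:7, 9),          # rho high
             n2 = c(2, 1, 3:8),       # rho lower
             n3 = rev(1:8),           # rho = -1
             n4 = c(1:7, 9))          # identical to n1: exact tie
  colnames(x) <- sprintf("s%d", 1:8)
  m <- expression_matrix(x, setNames(rep(c("A", "B"), 4), colnames(x)))
  nb <- top_neighbors("anchor", c("n1", "n2", "n3", "n4"), m, n = 2)
  # tie between n1 and n4 broken lexicographically
  expect_identical(nb$resolved_probes, c("n1", "n4"))
  rk <- attr(nb, "ranking")
  expect_equal(rk$rank, 1:2)
  # absolute ranking pulls in the anti-correlated probe
  nb_abs <- top_neighbors("anchor", c("n2", "n3"), m, n = 1,
                          absolute = TRUE)
  expect_identical(nb_abs$resolved_probes, "n3")
  # undersized pool: take all, with warning
  expect_warning(nb_all <- top_neighbors("anchor", c("n1", "n2"), m,
                                         n = 5), "taking all")
  expect_length(nb_all$resolved_probes, 2)
  expect_error(top_neighbors("anchor", c("anchor", "n1"), m, 1),
               "must not")
})

test_that("distance assembly maps correlation to [0, 2] with exact endpoints", {
  x <- rbind(a = 1:6, b = 2 * (1:6), c = rev(1:6), d = c(3, 1, 4, 1, 5, 9))
  colnames(x) <- sprintf("s%d", 1:6)
  m <- expression_matrix(x, setNames(rep(c("A", "B"), 3), colnames(x)))
  D <- assemble_distance(c("a", "b"), c("c", "d"), m)
  expect_equal(dim(D), c(4L, 4L))
  expect_equal(unname(D["a", "b"]), 0)        # identical ranks
  expect_equal(unname(D["a", "c"]), 2)        # anti-monotone
  expect_equal(diag(D), setNames(rep(0, 4), c("a", "b", "c", "d")))
  expect_equal(D, t(D))
  expect_error(assemble_distance(c("a", "b"), c("b", "c"), m), "disjoint")
  x2 <- rbind(x, flat = rep(1, 6))
  m2 <- expression_matrix(x2, m$conditions)
  expect_error(suppressWarnings(
    assemble_distance(c("a", "flat"), "b", m2)), "flat")
})

test_that("t_critical fires on a planted tight block and stays quiet on noise", {
  # 8-member near-duplicate block among 40 probes
  set.seed(55)
  base <- rnorm(26)
  block <- matrix(rep(base, 8), 8, 26, byrow = TRUE) +
    matrix(rnorm(8 * 26, sd = 0.15), 8, 26)
  noise <- matrix(rnorm(32 * 26), 32, 26)
  X <- rbind(block, noise)
  dimnames(X) <- list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:26))
  cond <- setNames(rep(c("DC8", "DW8", "DC16", "DW16"), c(7, 5, 5, 9)),
                   colnames(X))
  m <- expression_matrix(X, cond)
  sp <- spc_params(sweeps = 100, burn_in = 25)
  cfg <- expansion_config(n_null_permutations = 30)
  tc <- t_critical(m, rownames(X), sp, cfg, seed = 3)
  expect_false(is.na(tc$t_critical))
  obs_at <- tc$table$observed_max[tc$table$temperature >= tc$t_critical]
  expect_gte(max(obs_at), 8)
  # null data (independent noise) should usually stay undefined
  undef <- vapply(1:5, function(s) {
    Xn <- matrix(rnorm(40 * 26), 40, 26, dimnames = dimnames(X))
    mn <- expression_matrix(Xn, cond)
    is.na(t_critical(mn, rownames(Xn), sp, cfg, seed = s)$t_critical)
  }, logical(1))
  expect_gte(mean(undef), 0.8)
})

test_that("stable clusters apply the kept / excluded classification rule", {
  prof <- list(items = c("a1", "a2", "n1", "n2", "n3"),
               temperatures = seq(0, 0.06, by = 0.01),
               membership = rbind(
                 rep(1L, 5),
                 rep(1L, 5),              # full set above t_crit
                 c(1L, 1L, 2L, 3L, 3L),   # {a1,a2}, {n2,n3}
                 c(1L, 1L, 2L, 3L, 3L),
                 c(1L, 1L, 1L, 2L, 2L),   # {a1,a2,n1}, {n2,n3}
                 c(1L, 2L, 3L, 4L, 4L),
                 c(1L, 2L, 3L, 4L, 5L)))
  class(prof) <- "spc_profile"
  cl <- stable_clusters(prof, t_crit = 0.01, anchors = c("a1", "a2"))
  expect_identical(
    cl$classification[cl$members == "a1;a2"], "kept")
  expect_identical(
    cl$classification[cl$members == "a1;a2;n1"], "kept")
  expect_identical(
    cl$classification[cl$members == "n2;n3"], "excluded-novel-only")
  full <- cl[cl$members == "a1;a2;n1;n2;n3", ]
  expect_identical(full$classification, "excluded-multi-novel")
  expect_true(all(cl$classification[order(cl$classification != "kept")]
                  [seq_len(sum(cl$classification == "kept"))] == "kept"))
  # gene-level novelty: n2 and n3 as probes of one gene count once
  cl2 <- stable_clusters(prof, 0.01, c("a1", "a2"),
                         gene_of = c(n2 = "G", n3 = "G", n1 = "H",
                                     a1 = "A1", a2 = "A2"))
  mixed <- cl2[cl2$members == "a1;a2;n1;n2;n3", ]
  expect_identical(mixed$classification, "excluded-multi-novel")
  sub <- stable_clusters(prof, 0.03, c("a1"))   # from t = 0.03 only
  expect_error(stable_clusters(prof, NA, "a1"), "undefined")
})

test_that("edges come from kept clusters only, typed and merged by max span", {
  clusters <- data.frame(
    members = c("a1;a2;n1", "a2;n1", "n2;n3"),
    size = c(3L, 2L, 2L), n_anchor = c(2L, 1L, 0L), n_novel = c(1L, 1L, 2L),
    birth = 0.01, death = 0.03, span = c(3L, 8L, 5L),
    classification = c("kept", "kept", "excluded-novel-only"))
  net <- infer_edges(clusters, anchors = c("a1", "a2"), m = NULL)
  expect_equal(nrow(net), 3L)  # a1-a2, a1-n1, a2-n1 (merged)
  expect_identical(net$edge_type[net$gene_a == "a1" & net$gene_b == "a2"],
                   "anchor-anchor")
  expect_identical(net$edge_type[net$gene_b == "n1"],
                   c("anchor-novel", "anchor-novel"))
  # a2-n1 appears in both kept clusters: span merged to the max
  expect_equal(net$span[net$gene_a == "a2" & net$gene_b == "n1"], 8L)
  expect_false(any(c("n2", "n3") %in% c(net$gene_a, net$gene_b)))
  # a 3-member cluster alone yields its 3 within-pairs
  net3 <- infer_edges(clusters[1, ], anchors = c("a1", "a2"))
  expect_equal(nrow(net3), 3L)
})

test_that("reverse confirmation recovers the anchor with the symmetric rho", {
  sim <- simulate_expression(sim_config(n_background = 100, n_pathway = 6,
                                        n_associated = 6, seed = 17))
  m <- sim$expr
  anchor <- sim$truth$pathway_probes$resolved_probes[1]
  pool <- c(sim$truth$associated_probes$resolved_probes,
            sim$truth$pathway_probes$resolved_probes)
  nb <- top_neighbors(anchor, setdiff(pool, anchor), m, n = 5)
  novel <- nb$resolved_probes[1]
  fwd_rho <- attr(nb, "ranking")$rho[1]
  rev <- reverse_confirm(novel, anchor, pool, m, n = 10,
                         pathway = sim$truth$pathway_probes)
  expect_true(rev$confirmed)
  expect_equal(rev$rho, fwd_rho, tolerance = 1e-12)  # symmetry of rho
  expect_true(anchor %in% rev$pathway_recovered)
  # an unrelated probe is typically not confirmed at small n
  far <- reverse_confirm(probes(m)[grep("GeneBG050", probes(m))[1]],
                         anchor, pool, m, n = 1)
  expect_false(isTRUE(far$confirmed) && far$rank == 1 && far$rho > 0.9)
})
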