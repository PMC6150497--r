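# Differential expression: empirical-Bayes moderated t and the SAM-style
# permutation test.

classical_t <- function(m, ia, ib) {
  apply(m$values, 1, function(v) {
    a <- v[ia]; b <- v[ib]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / (sp * sqrt(1 / length(a) + 1 / length(b)))
  })
}

test_that("moderated t with d0 = 0 reproduces the classical two-sample t", {
  m <- toy_matrix(n_probes = 1000, n_a = 5, n_b = 5, seed = 42)
  res <- moderated_t_test(m, "A", "B", d0 = 0)
  tt <- classical_t(m, 1:5, 6:10)
  expect_equal(res$t, unname(tt), tolerance = 1e-10)
  p_classical <- 2 * pt(-abs(tt), df = 8)
  expect_equal(res$p, unname(p_classical), tolerance = 1e-10)
})

test_that("identical group means give t = 0 and p = 1", {
  x <- matrix(c(1, 2, 3, 1, 3, 2, 5, 6, 7, 7, 6, 5), 2, 6, byrow = TRUE,
              dimnames = list(c("pA", "pB"), sprintf("s%d", 1:6)))
  m <- expression_matrix(x, setNames(rep(c("A", "B"), each = 3),
                                     colnames(x)))
  res <- moderated_t_test(m, "A", "B")
  expect_equal(res$t, c(0, 0))
  expect_equal(res$p, c(1, 1))
})

test_that("moderated t agrees with the limma empirical-Bayes oracle", {
  set.seed(11)
  # heterogeneous per-probe variances so shrinkage is non-trivial
  n <- 500
  x <- matrix(rnorm(n * 10, sd = rep(sqrt(1 / rgamma(n, 4, 4)), 10)),
              n, 10, dimnames = list(sprintf("p%03d", 1:n),
                                     sprintf("s%02d", 1:10)))
  x[1:50, 6:10] <- x[1:50, 6:10] + 2
  m <- expression_matrix(x, setNames(rep(c("B", "A"), each = 5),
                                     colnames(x)))
  res <- moderated_t_test(m, "A", "B")
  design <- cbind(1, rep(c(0, 1), each = 5))
  fit <- limma::eBayes(limma::lmFit(x, design))
  expect_equal(attr(res, "d0"), fit$df.prior, tolerance = 0.05)
  expect_equal(attr(res, "s0_sq"), fit$s2.prior, tolerance = 0.02)
  expect_gt(cor(res$t, fit$t[, 2]), 0.9999)
  expect_equal(res$p, unname(fit$p.value[, 2]), tolerance = 1e-3)
  # identical top-50 call set
  expect_setequal(res$probe[rank(res$p) <= 50],
                  rownames(x)[rank(fit$p.value[, 2]) <= 50])
})

test_that("zero-variance probes stay finite under moderation", {
  x <- rbind(p1 = c(1, 1, 1, 2, 2, 2), p2 = rnorm(6), p3 = rnorm(6),
             p4 = rnorm(6), p5 = rnorm(6))
  colnames(x) <- sprintf("s%d", 1:6)
  m <- expression_matrix(x, setNames(rep(c("A", "B"), each = 3),
                                     colnames(x)))
  res <- moderated_t_test(m, "A", "B")
  expect_true(all(is.finite(res$t)))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # s2_post lies between the prior and the sample variance
  d0 <- attr(res, "d0"); s0 <- attr(res, "s0_sq")
  expect_true(all(res$s2_post >= pmin(res$s2, s0) - 1e-12 &
                  res$s2_post <= pmax(res$s2, s0) + 1e-12))
})

test_that("moderated-t recovery agrees with an exhaustive-permutation oracle", {
  # planted shift, n = 5/5; oracle = exhaustive studentized permutation
  # test (all C(10,5) label assignments, per-probe permutation p of |t|).
  # Moderation must rank essentially like the oracle and lose no planted
  # probes relative to it (shrinkage gains power at this sample size, and
  # the oracle's p granularity is only 1/252).
  set.seed(7)
  n_planted <- 50; n_bg <- 950
  x <- matrix(rnorm((n_planted + n_bg) * 10), n_planted + n_bg, 10)
  x[1:n_planted, 6:10] <- x[1:n_planted, 6:10] + 2.5
  dimnames(x) <- list(sprintf("p%04d", seq_len(nrow(x))),
                      sprintf("s%02d", 1:10))
  m <- expression_matrix(x, setNames(rep(c("B", "A"), each = 5),
                                     colnames(x)))
  res <- moderated_t_test(m, "A", "B")
  tstat <- function(ia) {
    ib <- setdiff(1:10, ia)
    ma <- rowMeans(x[, ia, drop = FALSE])
    mb <- rowMeans(x[, ib, drop = FALSE])
    s2 <- (rowSums((x[, ia, drop = FALSE] - ma)^2) +
             rowSums((x[, ib, drop = FALSE] - mb)^2)) / 8
    abs(ma - mb) / sqrt(s2 * (1 / 5 + 1 / 5))
  }
  combs <- combn(10, 5)
  obs <- tstat(6:10)
  perm_ge <- rep(0L, nrow(x))
  for (j in seq_len(ncol(combs)))
    perm_ge <- perm_ge + (tstat(combs[, j]) >= obs - 1e-12)
  p_oracle <- perm_ge / ncol(combs)
  expect_gte(cor(res$p, p_oracle, method = "spearman"), 0.9)
  planted <- sprintf("p%04d", seq_len(n_planted))
  rec_mod <- sum(rownames(x)[order(res$p)][1:50] %in% planted)
  rec_orc <- sum(rownames(x)[order(p_oracle, -obs)][1:50] %in% planted)
  expect_gte(rec_mod, rec_orc - 2)
  expect_gte(rec_mod, 35)
})

test_that("p-values are uniform under the null and BH q is monotone in p", {
  m <- toy_matrix(n_probes = 1000, n_a = 5, n_b = 5, seed = 99)
  res <- moderated_t_test(m, "A", "B")
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(res$q >= res$p - 1e-15))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-15))
})

test_that("SAM d with s0 = 0 reduces to the classical t statistic", {
  m <- toy_matrix(n_probes = 200, n_a = 4, n_b = 4, seed = 5)
  res <- sam_test(m, "A", "B", s0 = 0, n_perm = 50, seed = 1)
  tt <- classical_t(m, 1:4, 5:8)
  expect_equal(res$d, unname(tt), tolerance = 1e-10)
})

test_that("SAM is reproducible given (seed, n_perm) and calls nothing on null data", {
  m <- toy_matrix(n_probes = 300, n_a = 5, n_b = 5, seed = 21)
  r1 <- sam_test(m, "A", "B", n_perm = 60, seed = 9)
  r2 <- sam_test(m, "A", "B", n_perm = 60, seed = 9)
  expect_identical(r1$d, r2$d)
  expect_identical(r1$sig, r2$sig)
  # all-noise matrices: expect no calls at 1% FDR in most seeds
  calls <- vapply(1:20, function(s) {
    mm <- toy_matrix(n_probes = 200, n_a = 5, n_b = 5, seed = 100 + s)
    sum(sam_test(mm, "A", "B", fdr = 0.01, n_perm = 60, seed = s)$sig)
  }, numeric(1))
  expect_gte(mean(calls == 0), 0.9)
})

test_that("SAM and moderated-t calls overlap strongly on planted signal", {
  set.seed(31)
  x <- matrix(rnorm(1000 * 10), 1000, 10)
  x[1:50, 6:10] <- x[1:50, 6:10] + 2.5
  dimnames(x) <- list(sprintf("p%04d", 1:1000), sprintf("s%02d", 1:10))
  m <- expression_matrix(x, setNames(rep(c("B", "A"), each = 5),
                                     colnames(x)))
  lim <- moderated_t_test(m, "A", "B", fdr = 0.05)
  sam <- sam_test(m, "A", "B", fdr = 0.05, n_perm = 100, seed = 3)
  lim_calls <- lim$probe[lim$sig]
  sam_calls <- sam$probe[sam$sig]
  expect_gt(length(lim_calls), 20)
  expect_gt(length(sam_calls), 20)
  overlap <- length(intersect(lim_calls, sam_calls)) /
    min(length(lim_calls), length(sam_calls))
  expect_gte(overlap, 0.8)
  # intersection behaves as a set operation with deterministic order
  l0 <- intersect_de(lim, sam)
  expect_identical(l0$resolved_probes,
                   sort(intersect(lim_calls, sam_calls)))
})

test_that("intersect_de validates universes and warns when disjoint", {
  m <- toy_matrix(n_probes = 20, seed = 2)
  lim <- moderated_t_test(m, "A", "B")
  sam <- sam_test(m, "A", "B", n_perm = 40, seed = 1)
  m2 <- toy_matrix(n_probes = 10, seed = 3)
  lim2 <- moderated_t_test(m2, "A", "B")
  expect_error(intersect_de(lim2, sam), "universe")
  lim$sig <- c(TRUE, rep(FALSE, 19))
  sam$sig <- c(FALSE, TRUE, rep(FALSE, 18))
  expect_warning(l0 <- intersect_de(lim, sam), "disjoint")
  expect_length(l0$resolved_probes, 0)
})

test_that("anchor selection requires raw p below alpha in both tests", {
  set.seed(13)
  x <- matrix(rnorm(50 * 12), 50, 12)
  x[1:5, 7:12] <- x[1:5, 7:12] + 4   # strong planted pathway probes
  dimnames(x) <- list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:12))
  m <- expression_matrix(x, setNames(rep(c("B", "A"), each = 6),
                                     colnames(x)))
  lim <- moderated_t_test(m, "A", "B")
  sam <- sam_test(m, "A", "B", n_perm = 100, seed = 5)
  lpath <- gene_set("path", sprintf("p%02d", 1:8),
                    sprintf("p%02d", 1:8))
  anchors <- anchor_select(lpath, lim, sam, alpha = 0.01)
  expect_true(all(anchors$resolved_probes %in% sprintf("p%02d", 1:5)))
  expect_gte(length(anchors$resolved_probes), 3)
  # a probe significant in only one test is excluded
  p_lim <- lim$p[match(anchors$resolved_probes, lim$probe)]
  p_sam <- sam$p[match(anchors$resolved_probes, sam$probe)]
  expect_true(all(p_lim <= 0.01 & p_sam <= 0.01))
  # no pathway probe significant -> error advising larger alpha
  lpath_bg <- gene_set("bg", sprintf("p%02d", 40:45),
                       sprintf("p%02d", 40:45))
  expect_error(anchor_select(lpath_bg, lim, sam, alpha = 1e-6), "alpha")
})
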