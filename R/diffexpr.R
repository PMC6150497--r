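# Stage 1 of the anchored search: differential expression between two
# conditions by (a) an empirical-Bayes moderated t-test and (b) a SAM-style
# permutation test; candidates are the probes called by both at the target
# FDR.

group_indices <- function(m, cond_a, cond_b) {
  ia <- which(m$conditions == cond_a)
  ib <- which(m$conditions == cond_b)
  if (length(ia) < 2 || length(ib) < 2)
    stop("both conditions need at least 2 samples (",
         cond_a, ": ", length(ia), ", ", cond_b, ": ", length(ib), ")")
  list(ia = ia, ib = ib)
}

# Per-probe group means and pooled within-group variance.
pooled_stats <- function(X, ia, ib) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(X[, ia, drop = FALSE])
  mb <- rowMeans(X[, ib, drop = FALSE])
  ssa <- rowSums((X[, ia, drop = FALSE] - ma)^2)
  ssb <- rowSums((X[, ib, drop = FALSE] - mb)^2)
  df <- na + nb - 2
  list(mean_a = ma, mean_b = mb, lfc = ma - mb,
       s2 = (ssa + ssb) / df, df = df, na = na, nb = nb,
       scale = sqrt(1 / na + 1 / nb))
}

# Newton inversion of the trigamma function (for the prior-df fit).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

# Method-of-moments fit of a scaled inverse-chi-square prior to the sample
# variances, matching moments of log(s^2) (robust to the skew of s^2).
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("too few positive sample variances to fit the prior")
  e <- log(s2[ok]) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0)
    return(list(d0 = Inf, s0_sq = exp(emean)))
  d0 <- 2 * trigamma_inverse(evar)
  list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
}

#' Empirical-Bayes moderated t-test between two conditions
#'
#' Shrinks per-probe variances toward a common prior fitted by method of
#' moments to a scaled inverse-chi-square law:
#' `s2_post = (d0 * s0^2 + df * s2) / (d0 + df)`, with the moderated t
#' referred to a t distribution on `d0 + df` degrees of freedom. With
#' `d0 = 0` this is exactly the classical equal-variance two-sample t-test.
#'
#' @param m a [expression_matrix()].
#' @param cond_a contrast condition (fold changes are `cond_a - cond_b`).
#' @param cond_b reference condition.
#' @param fdr Benjamini-Hochberg FDR for the significance flag.
#' @param d0,s0_sq optional overrides of the fitted prior df / variance.
#' @return data.frame of class `bake_de` with one row per probe: group
#'   means, `lfc`, `s2`, `df`, `s2_post`, `t`, `p`, `q`, `sig`; attributes
#'   `d0`, `s0_sq`, `method = "moderated_t"`, `contrast`.
#' @export
moderated_t_test <- function(m, cond_a, cond_b, fdr = 0.01,
                             d0 = NULL, s0_sq = NULL) {
  g <- group_indices(m, cond_a, cond_b)
  st <- pooled_stats(m$values, g$ia, g$ib)
  prior <- fit_variance_prior(st$s2, st$df)
  if (!is.null(d0)) prior$d0 <- d0
  if (!is.null(s0_sq)) prior$s0_sq <- s0_sq
  s2_post <- if (is.infinite(prior$d0)) rep(prior$s0_sq, length(st$s2))
             else (prior$d0 * prior$s0_sq + st$df * st$s2) /
                  (prior$d0 + st$df)
  tt <- st$lfc / (sqrt(s2_post) * st$scale)
  tt[s2_post == 0 & st$lfc == 0] <- 0
  df_total <- prior$d0 + st$df
  p <- 2 * pt(-abs(tt), df = df_total)
  p[is.nan(p)] <- 1  # 0/0 probes: no evidence
  q <- p.adjust(p, method = "BH")
  out <- data.frame(probe = rownames(m$values), mean_a = st$mean_a,
                    mean_b = st$mean_b, lfc = st$lfc, s2 = st$s2,
                    df = st$df, s2_post = s2_post, t = tt, p = p, q = q,
                    sig = q <= fdr, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("bake_de", "data.frame"),
            d0 = prior$d0, s0_sq = prior$s0_sq, fdr = fdr,
            method = "moderated_t", contrast = c(cond_a, cond_b))
}

# d-statistics for one labelling of the columns, all probes at once.
sam_d <- function(X, ia, ib, s0) {
  st <- pooled_stats(X, ia, ib)
  st$lfc / (sqrt(st$s2) * st$scale + s0)
}

# Tusher-style fudge factor: the percentile of the per-probe standard errors
# minimizing the coefficient of variation of the d-statistic's MAD across
# windows of the standard-error distribution.
sam_fudge <- function(lfc, si) {
  alphas <- seq(0, 1, by = 0.05)
  s0_cand <- quantile(si, alphas, names = FALSE)
  qs <- quantile(si, seq(0, 1, by = 0.05), names = FALSE)
  grp <- cut(si, unique(qs), include.lowest = TRUE)
  cvs <- vapply(s0_cand, function(s0) {
    d <- lfc / (si + s0)
    mads <- tapply(d, grp, function(v) stats::mad(v))
    mads <- mads[is.finite(mads) & mads > 0]
    if (length(mads) < 2) return(Inf)
    sd(mads) / mean(mads)
  }, numeric(1))
  s0_cand[which.min(cvs)]
}

# All or sampled two-group label assignments as a list of index vectors
# (columns belonging to the synthetic "group a").
label_permutations <- function(n, na, n_perm, seed) {
  total <- choose(n, na)
  if (total <= n_perm) {
    cmb <- combn(n, na)
    lapply(seq_len(ncol(cmb)), function(j) cmb[, j])
  } else {
    with_seed(seed, replicate(n_perm, sort(sample.int(n, na)),
                              simplify = FALSE))
  }
}

#' SAM-style permutation test between two conditions
#'
#' Scores each probe with `d = lfc / (se + s0)` where `s0` is the
#' variance-stabilizing fudge factor (chosen by the canonical
#' minimum-coefficient-of-variation rule unless supplied), builds the null by
#' permuting sample labels, and calls probes at the smallest threshold
#' `delta` (distance from the expected order statistics) whose estimated
#' FDR — `pi0 *` average false-call count / observed calls — is at or
#' below `fdr`. The average false-call count (rather than the median) keeps
#' the estimate defined and conservative when a delta admits only a handful
#' of calls, where the median collapses to zero on null data;
#' `false_stat = "median"` restores the median convention. Per-probe
#' permutation p-values come from the pooled null distribution of |d|.
#'
#' @inheritParams moderated_t_test
#' @param n_perm number of label permutations; when fewer distinct
#'   assignments exist, all are enumerated.
#' @param seed integer seed for the permutation draw.
#' @param s0 optional fudge-factor override (`s0 = 0` with no moderation
#'   reduces `d` to the classical t statistic).
#' @param false_stat summary of the per-permutation false-call counts used
#'   in the FDR estimate: `"mean"` (default) or `"median"`.
#' @return data.frame of class `bake_de` with columns `probe`, `lfc`, `d`,
#'   `p` (pooled permutation p), `q` (symmetric-threshold FDR estimate),
#'   `sig` (delta-scan call at `fdr`); attributes `s0`, `pi0`, `delta`,
#'   `n_perm_used`, `method = "sam"`.
#' @export
sam_test <- function(m, cond_a, cond_b, fdr = 0.01, n_perm = 200,
                     seed = 1, s0 = NULL,
                     false_stat = c("mean", "median")) {
  false_stat <- match.arg(false_stat)
  false_summary <- if (false_stat == "mean") mean else median
  if (n_perm < 25) warning("n_perm < 25: SAM null will be very coarse")
  g <- group_indices(m, cond_a, cond_b)
  X <- m$values[, c(g$ia, g$ib), drop = FALSE]
  na <- length(g$ia); nb <- length(g$ib); n <- na + nb
  st <- pooled_stats(X, seq_len(na), na + seq_len(nb))
  si <- sqrt(st$s2) * st$scale
  if (is.null(s0)) s0 <- sam_fudge(st$lfc, si)
  d <- st$lfc / (si + s0)
  perms <- label_permutations(n, na, n_perm, seed)
  B <- length(perms)
  dstar <- vapply(perms, function(ia) {
    sam_d(X, ia, setdiff(seq_len(n), ia), s0)
  }, numeric(length(d)))
  m_probes <- length(d)
  ord <- order(d)
  d_sorted <- d[ord]
  perm_sorted_cols <- apply(dstar, 2, sort)
  dbar <- rowMeans(perm_sorted_cols)
  # pooled permutation p-values
  abs_null <- sort(abs(as.vector(dstar)))
  exceed <- length(abs_null) -
    findInterval(abs(d) - 1e-12, abs_null)
  p_perm <- (exceed + 1) / (length(abs_null) + 1)
  # pi0 from the inner quartiles of the null
  qn <- quantile(as.vector(dstar), c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d > qn[1] & d < qn[2]) / (0.5 * m_probes))
  # delta scan. For each candidate delta:
  #   cutup(delta) = min{ d_(i) : d_(i) - dbar_(i) >= delta, d_(i) > 0 }
  #   cutlo(delta) = max{ d_(i) : dbar_(i) - d_(i) >= delta, d_(i) < 0 }
  # computed for all deltas in one descending sweep (running extrema over
  # the indices that become eligible), with call/false-call counts taken
  # from pre-sorted arrays, so the scan is O(m log m + m log(mB)).
  diffs <- d_sorted - dbar
  deltas <- sort(unique(c(0, abs(diffs))), decreasing = TRUE)
  nd <- length(deltas)
  cutup <- rep(Inf, nd)
  cutlo <- rep(-Inf, nd)
  up_ord <- order(diffs, decreasing = TRUE)
  lo_ord <- order(-diffs, decreasing = TRUE)
  iu <- 1L; il <- 1L
  run_min <- Inf; run_max <- -Inf
  for (k in seq_len(nd)) {
    delta <- deltas[k]
    while (iu <= m_probes && diffs[up_ord[iu]] >= delta) {
      v <- d_sorted[up_ord[iu]]
      if (v > 0 && v < run_min) run_min <- v
      iu <- iu + 1L
    }
    while (il <= m_probes && -diffs[lo_ord[il]] >= delta) {
      v <- d_sorted[lo_ord[il]]
      if (v < 0 && v > run_max) run_max <- v
      il <- il + 1L
    }
    cutup[k] <- run_min
    cutlo[k] <- run_max
  }
  all_null_sorted <- sort(as.vector(dstar))
  n_null <- length(all_null_sorted)
  count_ge <- function(sorted, x)       # how many sorted values >= x
    length(sorted) - findInterval(x - 1e-12, sorted)
  count_le <- function(sorted, x) findInterval(x + 1e-12, sorted)
  n_called <- count_ge(d_sorted, cutup) + count_le(d_sorted, cutlo)
  if (false_stat == "mean") {
    false_calls <- (count_ge(all_null_sorted, cutup) +
                      count_le(all_null_sorted, cutlo)) / B
  } else {
    false_calls <- vapply(seq_len(nd), function(k) {
      median(vapply(seq_len(B), function(b)
        count_ge(perm_sorted_cols[, b], cutup[k]) +
          count_le(perm_sorted_cols[, b], cutlo[k]), numeric(1)))
    }, numeric(1))
  }
  est_fdr <- ifelse(n_called == 0, 0,
                    pmin(1, pi0 * false_calls / pmax(n_called, 1)))
  ok <- which(est_fdr <= fdr)
  if (length(ok)) {
    k <- max(ok)  # deltas are in descending order: max index = smallest
    delta_used <- deltas[k]
    sig <- d >= cutup[k] | d <= cutlo[k]
  } else {
    sig <- rep(FALSE, m_probes)
    delta_used <- NA_real_
  }
  # symmetric-threshold FDR estimate per probe, monotone in |d|
  abs_d <- abs(d)
  obs_ge <- vapply(abs_d, function(a) sum(abs_d >= a), numeric(1))
  null_ge <- (length(abs_null) - findInterval(abs_d - 1e-12, abs_null)) / B
  qv <- pmin(1, pi0 * null_ge / obs_ge)
  o <- order(abs_d, decreasing = TRUE)
  qv[o] <- cummax(qv[o])  # larger |d| never has larger q
  out <- data.frame(probe = rownames(m$values), mean_a = st$mean_a,
                    mean_b = st$mean_b, lfc = st$lfc, d = d, p = p_perm,
                    q = qv, sig = sig, row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out, class = c("bake_de", "data.frame"),
            s0 = s0, pi0 = pi0, delta = delta_used, n_perm_used = B,
            fdr = fdr, method = "sam", contrast = c(cond_a, cond_b))
}

#' Intersect moderated-t and SAM calls into the candidate list
#'
#' @param limma_res result of [moderated_t_test()].
#' @param sam_res result of [sam_test()].
#' @param name name for the resulting gene set.
#' @return a [gene_set()] whose `resolved_probes` are the probes significant
#'   under both tests, in sorted order.
#' @export
intersect_de <- function(limma_res, sam_res, name = "L0") {
  if (!identical(sort(limma_res$probe), sort(sam_res$probe)))
    stop("the two results cover different probe universes")
  hits <- sort(intersect(limma_res$probe[limma_res$sig],
                         sam_res$probe[sam_res$sig]))
  if (!length(hits))
    warning("the two differential-expression calls are disjoint; ",
            "candidate list is empty")
  gene_set(name, hits, hits)
}

#' Select anchor probes: pathway probes significant in both tests at raw p
#'
#' @param l_path resolved pathway [gene_set()].
#' @param limma_res,sam_res results of [moderated_t_test()] / [sam_test()]
#'   on the same probe universe.
#' @param alpha raw p-value cutoff applied to both tests.
#' @return a [gene_set()] of anchor probes.
#' @export
anchor_select <- function(l_path, limma_res, sam_res, alpha = 0.01) {
  pr <- l_path$resolved_probes
  missing <- setdiff(pr, limma_res$probe)
  if (length(missing))
    stop("pathway probe(s) absent from the test universe: ",
         paste(missing, collapse = ", "))
  p1 <- limma_res$p[match(pr, limma_res$probe)]
  p2 <- sam_res$p[match(pr, sam_res$probe)]
  keep <- pr[p1 <= alpha & p2 <= alpha]
  if (!length(keep))
    stop("no pathway probe passes raw p <= ", alpha,
         " in both tests; consider a larger alpha")
  keep <- sort(keep)
  gene_set("L_anchor", keep, keep)
}
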