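# Stage 3: correlate candidate probes with the known pathway across all
# conditions pooled, summarize each candidate by its top-5% correlation, and
# pick the significance threshold by resampled ROC curves maximizing
# Youden's J against random "pathways" drawn from a non-differential
# background pool.

as_probe_ids <- function(x) {
  if (inherits(x, "bake_geneset")) x$resolved_probes else as.character(x)
}

# Row-wise rank transform (average ranks for ties) so Spearman correlations
# reduce to Pearson correlations of the ranked rows.
rank_rows <- function(X) {
  t(apply(X, 1, rank))
}

#' Spearman correlation matrix between two probe sets
#'
#' Correlations are computed on all samples pooled across conditions, with
#' average ranks for ties. Probes with constant profiles (zero rank
#' variance) yield `NA` rows/columns with a warning and are excluded from
#' downstream summaries.
#'
#' @param m a [expression_matrix()].
#' @param rows,cols probe id vectors or [gene_set()]s.
#' @return matrix of Spearman rho, `rows` x `cols`.
#' @export
spearman_matrix <- function(m, rows, cols) {
  rows <- as_probe_ids(rows); cols <- as_probe_ids(cols)
  if (ncol(m$values) < 3) stop("need at least 3 shared samples")
  all_ids <- union(rows, cols)
  missing <- setdiff(all_ids, probes(m))
  if (length(missing))
    stop("probe(s) not in matrix: ", paste(missing, collapse = ", "))
  X <- m$values[all_ids, , drop = FALSE]
  const <- apply(X, 1, function(v) max(v) == min(v))
  if (any(const))
    warning("constant profile(s), correlations undefined: ",
            paste(all_ids[const], collapse = ", "))
  R <- rank_rows(X)
  R[const, ] <- NA_real_
  rho <- suppressWarnings(cor(t(R[rows, , drop = FALSE]),
                              t(R[cols, , drop = FALSE]),
                              method = "pearson"))
  dimnames(rho) <- list(rows, cols)
  rho
}

#' Top-fifth-percentile correlation summary per candidate
#'
#' For each row of a correlation matrix, returns the k-th largest value with
#' `k = ceiling(alpha * n_defined)` (nearest-rank, ceiling convention): for
#' 80 pathway probes at `alpha = 0.05` this is the 4th-largest rho.
#'
#' @param rho matrix of correlations (candidates x pathway probes).
#' @param alpha upper tail mass summarized (default 0.05).
#' @param absolute summarize `|rho|` instead of signed rho.
#' @return named numeric vector of summaries (`NA` when a row has no
#'   defined correlations).
#' @export
pathway_score <- function(rho, alpha = 0.05, absolute = FALSE) {
  if (absolute) rho <- abs(rho)
  apply(rho, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) return(NA_real_)
    k <- max(1L, ceiling(alpha * length(v)))
    sort(v, decreasing = TRUE)[k]
  })
}

#' Background pool of probes not differential in any pairwise contrast
#'
#' Removes probes called significant by both the moderated t-test and SAM
#' (FDR `alpha`) in any of the pairwise contrasts between the given
#' conditions; the remainder is the pool random pathway surrogates are
#' drawn from.
#'
#' @param m a [expression_matrix()].
#' @param conditions condition labels to contrast (default: all).
#' @param alpha FDR used in each contrast.
#' @param n_perm,seed passed to [sam_test()].
#' @param min_size optional minimum pool size (e.g. the pathway probe
#'   count); an error is raised if the pool is smaller.
#' @return a [gene_set()] named `L_random`.
#' @export
background_pool <- function(m, conditions = NULL, alpha = 0.01,
                            n_perm = 100, seed = 1, min_size = NULL) {
  if (is.null(conditions)) conditions <- unique(m$conditions)
  if (length(conditions) < 2) stop("need at least 2 conditions")
  pairs <- combn(conditions, 2, simplify = FALSE)
  excluded <- character()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    lim <- moderated_t_test(m, pr[1], pr[2], fdr = alpha)
    sam <- sam_test(m, pr[1], pr[2], fdr = alpha, n_perm = n_perm,
                    seed = derive_seed(seed, i))
    excluded <- union(excluded,
                      intersect(lim$probe[lim$sig], sam$probe[sam$sig]))
  }
  pool <- sort(setdiff(probes(m), excluded))
  if (!is.null(min_size) && length(pool) < min_size)
    stop("background pool (", length(pool),
         ") smaller than required size ", min_size)
  gene_set("L_random", pool, pool)
}

#' Correlation threshold by resampled ROC curves and Youden's J
#'
#' Each candidate's association with the real pathway is its
#' [pathway_score()]; for each of `n_resamples` draws of a random pathway
#' surrogate (same probe count, sampled without replacement from
#' `l_random`), the same summary against the surrogate provides the
#' negatives. An ROC over the union of observed scores gives, per resample,
#' the smallest threshold maximizing Youden's J = TPR - FPR; the reported
#' threshold is the median across resamples.
#'
#' @param m a [expression_matrix()].
#' @param l0 candidate probes (gene set or ids).
#' @param l_path resolved pathway gene set (or probe ids).
#' @param l_random background pool from [background_pool()].
#' @param n_resamples number of surrogate draws (default 100).
#' @param seed integer seed.
#' @param alpha percentile for [pathway_score()].
#' @param absolute use `|rho|` summaries.
#' @return list of class `bake_threshold`: `threshold` (median of the
#'   per-resample optima), `t_star`, `j` (per-resample optimum and J),
#'   `s_path` (named candidate scores), `n_resamples`.
#' @export
resampled_roc_threshold <- function(m, l0, l_path, l_random,
                                    n_resamples = 100, seed = 1,
                                    alpha = 0.05, absolute = FALSE) {
  l0 <- as_probe_ids(l0)
  path_probes <- as_probe_ids(l_path)
  pool <- as_probe_ids(l_random)
  if (length(pool) < length(path_probes))
    stop("background pool smaller than the pathway probe set")
  R <- rank_rows(m$values[union(l0, union(path_probes, pool)), ,
                          drop = FALSE])
  const <- apply(R, 1, function(v) max(v) == min(v))
  R[const, ] <- NA_real_
  rho_path <- suppressWarnings(
    cor(t(R[l0, , drop = FALSE]), t(R[path_probes, , drop = FALSE])))
  s_path <- pathway_score(rho_path, alpha, absolute)
  defined <- is.finite(s_path)
  if (!all(defined))
    warning("candidate(s) with undefined scores excluded: ",
            paste(l0[!defined], collapse = ", "))
  s_path_use <- s_path[defined]
  draws <- with_seed(seed, replicate(
    n_resamples, sample(pool, length(path_probes)), simplify = FALSE))
  opt <- vapply(draws, function(rand_probes) {
    rho_r <- suppressWarnings(
      cor(t(R[l0, , drop = FALSE]), t(R[rand_probes, , drop = FALSE])))
    s_rand <- pathway_score(rho_r, alpha, absolute)[defined]
    s_rand <- s_rand[is.finite(s_rand)]
    thresholds <- sort(unique(c(s_path_use, s_rand)))
    if (length(thresholds) < 2)
      stop("degenerate scores: all candidate summaries are equal")
    tpr <- vapply(thresholds, function(t) mean(s_path_use >= t), numeric(1))
    fpr <- vapply(thresholds, function(t) mean(s_rand >= t), numeric(1))
    j <- tpr - fpr
    best <- which(j == max(j))[1]  # ties -> smallest threshold
    c(thresholds[best], j[best])
  }, numeric(2))
  structure(list(threshold = median(opt[1, ]), t_star = opt[1, ],
                 j = opt[2, ], s_path = s_path,
                 n_resamples = n_resamples, alpha = alpha,
                 absolute = absolute),
            class = "bake_threshold")
}

#' @export
print.bake_threshold <- function(x, ...) {
  cat(sprintf(
    "bake_threshold: %.3f (median of %d resampled ROC optima; median J = %.3f)\n",
    x$threshold, x$n_resamples, median(x$j)))
  invisible(x)
}

#' Select pathway-associated candidates above the correlation threshold
#'
#' @param scores a `bake_threshold` object or a named numeric vector of
#'   candidate scores.
#' @param threshold numeric threshold; defaults to the auto-selected one
#'   when `scores` is a `bake_threshold`.
#' @param name name for the resulting gene set.
#' @return a [gene_set()] of candidates with `score >= threshold` (probes
#'   with undefined scores are never selected).
#' @export
select_L1 <- function(scores, threshold = NULL, name = "L1") {
  if (inherits(scores, "bake_threshold")) {
    if (is.null(threshold)) threshold <- scores$threshold
    scores <- scores$s_path
  }
  if (is.null(threshold)) stop("a threshold is required")
  keep <- sort(names(scores)[is.finite(scores) & scores >= threshold])
  gene_set(name, keep, keep)
}
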