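# Stage 4/5 orchestration: neighbour selection around anchors, correlation
# distance assembly, critical-temperature estimation against a permutation
# null, stable-cluster selection, edge inference, reverse confirmation, and
# the end-to-end pipeline.

#' Configuration of the network-expansion stage
#'
#' The published operating point clusters about 40 probes per run (anchors
#' plus neighbours); the neighbour count is adjusted automatically so that
#' `|anchors| + |neighbors| = l_total`, and the anchor set is capped at
#' `l_total / 2` (keeping the most significant probes) when larger.
#'
#' @param n_neighbors neighbours per anchor run (before adjustment).
#' @param l_total total probes clustered per run.
#' @param n_null_permutations expression-permutation replicates for the
#'   critical-temperature null.
#' @param z_threshold number of null SDs the observed maximum cluster size
#'   must exceed the null mean by.
#' @param min_consecutive number of consecutive grid temperatures the
#'   exceedance must persist for (default 2). A single-temperature rule
#'   tests ~100 grid points and fires spuriously on unstructured data;
#'   requiring the observed clustering to stay above the null over
#'   consecutive temperatures restores the intended calibration ("the
#'   temperature beyond which" observed and random patterns are distinct).
#' @param neighbor_pool `"L1"` (candidates only) or `"L1_path"`
#'   (candidates plus pathway probes, used for reverse runs).
#' @param absolute rank neighbours by `|rho|` instead of signed rho.
#' @return list of class `expansion_config`.
#' @export
expansion_config <- function(n_neighbors = 20, l_total = 40,
                             n_null_permutations = 100, z_threshold = 2,
                             min_consecutive = 2,
                             neighbor_pool = c("L1", "L1_path"),
                             absolute = FALSE) {
  if (n_null_permutations < 20)
    stop("at least 20 null permutations are required")
  stopifnot(min_consecutive >= 1)
  structure(list(n_neighbors = n_neighbors, l_total = l_total,
                 n_null_permutations = n_null_permutations,
                 z_threshold = z_threshold,
                 min_consecutive = min_consecutive,
                 neighbor_pool = match.arg(neighbor_pool),
                 absolute = absolute),
            class = "expansion_config")
}

#' Top correlated neighbours of an anchor probe
#'
#' @param anchor_probe probe id.
#' @param pool candidate probes ([gene_set()] or ids), not containing the
#'   anchor.
#' @param m a [expression_matrix()].
#' @param n neighbours to return; if the pool is smaller, all are returned
#'   with a warning.
#' @param absolute rank by `|rho|`.
#' @return a [gene_set()] of the n pool probes with largest (signed, or
#'   absolute) Spearman rho to the anchor; exact ties broken
#'   lexicographically by probe id. The ranking table (probe, rho, rank) is
#'   attached as attribute `ranking`.
#' @export
top_neighbors <- function(anchor_probe, pool, m, n = 20, absolute = FALSE) {
  pool <- as_probe_ids(pool)
  if (!length(pool)) stop("empty neighbour pool")
  if (anchor_probe %in% pool)
    stop("anchor probe must not be part of the pool")
  rho <- spearman_matrix(m, anchor_probe, pool)[1, ]
  score <- if (absolute) abs(rho) else rho
  ord <- order(-score, names(score))  # ties -> lexicographic probe id
  ord <- ord[is.finite(score[ord])]
  if (length(ord) < n) {
    warning("pool has only ", length(ord),
            " probes with defined correlation; taking all")
    n <- length(ord)
  }
  top <- ord[seq_len(n)]
  ranking <- data.frame(probe = names(rho)[top], rho = unname(rho[top]),
                        rank = seq_len(n), stringsAsFactors = FALSE)
  out <- gene_set("L_neighbor", names(rho)[top], names(rho)[top])
  attr(out, "ranking") <- ranking
  out
}

#' Correlation-distance matrix over anchors plus neighbours
#'
#' @param anchors,neighbors disjoint probe sets ([gene_set()] or ids).
#' @param m a [expression_matrix()].
#' @return symmetric matrix `D = 1 - rho` (Spearman), zero diagonal,
#'   values in `[0, 2]`, with probe ids as dimnames.
#' @export
assemble_distance <- function(anchors, neighbors, m) {
  anchors <- as_probe_ids(anchors); neighbors <- as_probe_ids(neighbors)
  if (length(intersect(anchors, neighbors)))
    stop("anchor and neighbour sets must be disjoint")
  ids <- c(anchors, neighbors)
  rho <- spearman_matrix(m, ids, ids)
  if (anyNA(rho)) {
    bad <- unique(rownames(rho)[!apply(is.finite(rho), 1, all)])
    stop("undefined correlation (constant profile) for probe(s): ",
         paste(bad, collapse = ", "))
  }
  D <- 1 - rho
  diag(D) <- 0
  D[D < 0] <- 0
  (D + t(D)) / 2
}

#' Permutation-null ensemble of maximum cluster sizes
#'
#' Row-wise permutation of expression vectors makes every pairwise
#' Spearman correlation a function of independent uniform rank orderings,
#' so the null distribution of the clustering profile's maximum cluster
#' size depends only on the number of items, the number of samples and
#' the clustering parameters — not on the probes' values. This function
#' draws that ensemble directly (one independent rank ordering per item
#' and replicate); [run_bake()] computes it once and shares it across
#' anchor runs of identical geometry.
#'
#' @param n_items items per clustering run (e.g. 40).
#' @param n_samples samples the correlations are computed over.
#' @param params an [spc_params()].
#' @param n_permutations replicates.
#' @param seed integer seed.
#' @return matrix (`n_permutations` x temperatures) of max cluster sizes.
#' @export
spc_null_max <- function(n_items, n_samples, params = spc_params(),
                         n_permutations = 100, seed = 1) {
  temps <- seq(params$t_start, params$t_end, by = params$t_step)
  out <- matrix(NA_integer_, n_permutations, length(temps))
  for (b in seq_len(n_permutations)) {
    R <- with_seed(derive_seed(seed, b), {
      t(replicate(n_items, sample.int(n_samples)))
    })
    rho <- suppressWarnings(cor(t(R)))
    D <- 1 - rho
    diag(D) <- 0
    D[D < 0] <- 0
    D <- (D + t(D)) / 2
    dimnames(D) <- list(seq_len(n_items), seq_len(n_items))
    prof <- spc_profile(D, params,
                        seed = derive_seed(seed, n_permutations + b))
    out[b, ] <- prof$max_cluster_size
  }
  out
}

#' Critical temperature from a permutation null
#'
#' Compares the observed maximum cluster size per temperature with the null
#' obtained by independently permuting each probe's expression vector across
#' samples, recomputing the distance matrix and its clustering profile, for
#' each of `n_null_permutations` replicates. The critical temperature is the
#' lowest grid temperature at which the observed maximum exceeds the null
#' mean by `z_threshold` null SDs, with the exceedance sustained over
#' `min_consecutive` grid temperatures; when no temperature qualifies it is
#' undefined (`NA`).
#'
#' @param m a [expression_matrix()] (only the rows in `probes` are used).
#' @param probes the probes of the run (anchors plus neighbours).
#' @param params an [spc_params()].
#' @param cfg an [expansion_config()].
#' @param seed integer seed.
#' @param null_max optional precomputed null ensemble from
#'   [spc_null_max()] (same item count and parameters); when `NULL` the
#'   null is built here by permuting the observed expression vectors.
#' @return list of class `tcritical_result`: `t_critical` (NA when
#'   undefined), `table` (per temperature: observed max, null mean and SD),
#'   `observed_profile` (the [spc_profile()] of the observed data), `z`.
#' @export
t_critical <- function(m, probes, params = spc_params(),
                       cfg = expansion_config(), seed = 1,
                       null_max = NULL) {
  probes <- as_probe_ids(probes)
  X <- m$values[probes, , drop = FALSE]
  D <- assemble_distance(probes, character(), m)
  obs <- spc_profile(D, params, seed = derive_seed(seed, 0))
  B <- cfg$n_null_permutations
  if (is.null(null_max)) {
    null_max <- matrix(NA_integer_, B, length(obs$temperatures))
    for (b in seq_len(B)) {
      Xp <- with_seed(derive_seed(seed, b), {
        t(apply(X, 1, sample))
      })
      dimnames(Xp) <- dimnames(X)
      Rp <- rank_rows(Xp)
      rho <- suppressWarnings(cor(t(Rp), t(Rp)))
      if (anyNA(rho)) stop("constant permuted profile; cannot build null")
      Dp <- 1 - rho
      diag(Dp) <- 0
      Dp[Dp < 0] <- 0
      Dp <- (Dp + t(Dp)) / 2
      prof_b <- spc_profile(Dp, params, seed = derive_seed(seed, B + b))
      null_max[b, ] <- prof_b$max_cluster_size
    }
  } else {
    stopifnot(ncol(null_max) == length(obs$temperatures))
    B <- nrow(null_max)
  }
  mu <- colMeans(null_max)
  sdv <- apply(null_max, 2, sd)
  if (all(sdv == 0)) {
    warning("null SD is zero at every temperature; ",
            "falling back to strict inequality against the null mean")
    exceed <- obs$max_cluster_size > mu
  } else {
    exceed <- obs$max_cluster_size > mu + cfg$z_threshold * sdv
  }
  # sustained exceedance: min_consecutive grid temperatures in a row
  k <- max(1L, cfg$min_consecutive %||% 1L)
  sustained <- exceed
  if (k > 1) for (j in seq_len(k - 1))
    sustained <- sustained & c(exceed[-seq_len(j)], rep(FALSE, j))
  tc <- if (any(sustained)) obs$temperatures[min(which(sustained))]
        else NA_real_
  structure(list(t_critical = tc,
                 table = data.frame(temperature = obs$temperatures,
                                    observed_max = obs$max_cluster_size,
                                    null_mean = mu, null_sd = sdv,
                                    exceeds = exceed),
                 observed_profile = obs, z = cfg$z_threshold,
                 n_null_permutations = B),
            class = "tcritical_result")
}

#' @export
print.tcritical_result <- function(x, ...) {
  if (is.na(x$t_critical))
    cat(sprintf("t_critical: undefined (no temperature exceeds null mean + %g SD over %d permutations)\n",
                x$z, x$n_null_permutations))
  else
    cat(sprintf("t_critical = %.2f (observed max %d vs null %.1f +/- %.2f; %d permutations, z = %g)\n",
                x$t_critical,
                x$table$observed_max[x$table$temperature == x$t_critical],
                x$table$null_mean[x$table$temperature == x$t_critical],
                x$table$null_sd[x$table$temperature == x$t_critical],
                x$n_null_permutations, x$z))
  invisible(x)
}

#' Stable clusters above the critical temperature
#'
#' Persistence is computed for temperatures at or above `t_crit`; each
#' member set is classified: kept when it contains at least one anchor
#' probe and at most one novel gene, `excluded-novel-only` when it has no
#' anchor, `excluded-multi-novel` when it has two or more novel genes.
#' Novelty is counted at gene level when a probe-to-gene map is supplied
#' (several probes of one novel gene count once, as in the duplicate-probe
#' validation clusters); otherwise each novel probe counts as a gene.
#'
#' @param profile an [spc_profile()].
#' @param t_crit critical temperature (must be defined and on the grid).
#' @param anchors anchor probe ids ([gene_set()] or ids).
#' @param gene_of optional named character vector, probe id -> gene symbol.
#' @return data.frame sorted kept-first by descending span: `members`,
#'   `size`, `n_anchor`, `n_novel` (novel genes), `birth`, `death`, `span`,
#'   `classification`.
#' @export
stable_clusters <- function(profile, t_crit, anchors, gene_of = NULL) {
  if (is.na(t_crit)) stop("t_crit is undefined")
  anchors <- as_probe_ids(anchors)
  per <- cluster_persistence(profile, t_min = t_crit)
  if (!nrow(per)) {
    per$n_anchor <- integer(); per$n_novel <- integer()
    per$classification <- character()
    return(per)
  }
  mem <- strsplit(per$members, ";", fixed = TRUE)
  per$n_anchor <- vapply(mem, function(g) sum(g %in% anchors), integer(1))
  per$n_novel <- vapply(mem, function(g) {
    nov <- setdiff(g, anchors)
    if (is.null(gene_of)) length(nov)
    else {
      sym <- gene_of[nov]
      sym[is.na(sym)] <- nov[is.na(sym)]
      length(unique(sym))
    }
  }, integer(1))
  per$classification <- ifelse(
    per$n_anchor == 0, "excluded-novel-only",
    ifelse(per$n_novel > 1, "excluded-multi-novel", "kept"))
  per <- per[order(per$classification != "kept", -per$span, per$members), ,
             drop = FALSE]
  rownames(per) <- NULL
  per
}

#' Infer typed network edges from kept stable clusters
#'
#' Every within-cluster pair of a kept cluster becomes an edge, typed
#' `anchor-anchor` or `anchor-novel`, annotated with the cluster id, the
#' pair's Spearman rho and the cluster's persistence span. The same pair
#' arising from several clusters (e.g. different anchor runs) is merged
#' keeping the maximum span.
#'
#' @param clusters result of [stable_clusters()] (only rows classified
#'   `kept` are used).
#' @param anchors anchor probe ids.
#' @param m a [expression_matrix()] (for the per-pair rho annotation); may
#'   be `NULL` to skip the annotation.
#' @param run_id label prefixed to cluster ids (e.g. the anchor of the run).
#' @return a [bake_network()].
#' @export
infer_edges <- function(clusters, anchors, m = NULL, run_id = "run") {
  anchors <- as_probe_ids(anchors)
  kept <- clusters[clusters$classification == "kept", , drop = FALSE]
  if (!nrow(kept)) return(bake_network())
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    g <- sort(strsplit(kept$members[i], ";", fixed = TRUE)[[1]])
    pr <- t(combn(g, 2))
    rho <- if (!is.null(m)) {
      rr <- spearman_matrix(m, g, g)
      rr[cbind(pr[, 1], pr[, 2])]
    } else NA_real_
    data.frame(gene_a = pr[, 1], gene_b = pr[, 2],
               edge_type = ifelse(pr[, 1] %in% anchors &
                                  pr[, 2] %in% anchors,
                                  "anchor-anchor", "anchor-novel"),
               cluster_id = sprintf("%s:%d", run_id, i),
               rho = rho, span = kept$span[i], stringsAsFactors = FALSE)
  })
  bake_network(do.call(rbind, rows))
}

#' Reverse confirmation of a novel probe
#'
#' Re-runs the neighbour search around a newly discovered probe and checks
#' that the anchor it was discovered from is recovered among its top `n`
#' neighbours; the symmetric correlation is reported and equals the forward
#' value exactly.
#'
#' @param novel_probe the discovered probe.
#' @param original_anchor the anchor probe it was discovered from.
#' @param pool the neighbour pool for the reverse run (typically the
#'   candidate list plus the pathway probes), not containing `novel_probe`.
#' @param m a [expression_matrix()].
#' @param n neighbourhood size for the confirmation rule.
#' @param pathway optional pathway probes; recovered ones are reported.
#' @return list of class `reverse_report`: `confirmed` (anchor rank <= n),
#'   `rank`, `rho`, `top` (ranking table), `pathway_recovered`.
#' @export
reverse_confirm <- function(novel_probe, original_anchor, pool, m, n = 20,
                            pathway = NULL) {
  pool <- setdiff(as_probe_ids(pool), novel_probe)
  if (!(original_anchor %in% pool))
    pool <- c(pool, original_anchor)
  rho <- spearman_matrix(m, novel_probe, pool)[1, ]
  ord <- order(-rho, names(rho))
  ord <- ord[is.finite(rho[ord])]
  ranks <- setNames(seq_along(ord), names(rho)[ord])
  anchor_rank <- unname(ranks[original_anchor])
  top_ids <- names(ranks)[seq_len(min(n, length(ranks)))]
  recovered <- if (is.null(pathway)) character()
               else intersect(top_ids, as_probe_ids(pathway))
  structure(list(novel_probe = novel_probe,
                 original_anchor = original_anchor,
                 confirmed = is.finite(anchor_rank) && anchor_rank <= n,
                 rank = anchor_rank,
                 rho = unname(rho[original_anchor]),
                 top = data.frame(probe = top_ids,
                                  rho = unname(rho[top_ids]),
                                  rank = seq_along(top_ids)),
                 pathway_recovered = recovered),
            class = "reverse_report")
}

#' @export
print.reverse_report <- function(x, ...) {
  cat(sprintf("reverse_confirm %s -> %s: %s (rank %s, rho = %.2f)\n",
              x$novel_probe, x$original_anchor,
              if (x$confirmed) "confirmed" else "not confirmed",
              x$rank, x$rho))
  invisible(x)
}
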