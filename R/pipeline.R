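#' Configuration of the full anchored-expansion pipeline
#'
#' @param contrast length-2 conditions (contrast, reference) for the
#'   differential-expression screen.
#' @param fdr FDR for the candidate list (both tests).
#' @param anchor_alpha raw p cutoff for anchor selection (both tests).
#' @param n_perm SAM label permutations.
#' @param n_resamples ROC resampling replicates for the threshold.
#' @param pool_alpha FDR for the background-pool exclusion contrasts.
#' @param threshold optional correlation-threshold override; when `NULL`
#'   the resampled ROC / Youden threshold is used.
#' @param spc an [spc_params()].
#' @param expansion an [expansion_config()].
#' @param reverse run the reverse-confirmation step for every novel probe.
#' @param absolute use `|rho|` in the association summaries and rankings.
#' @return list of class `bake_config`.
#' @export
bake_config <- function(contrast = c("DW16", "DC16"), fdr = 0.01,
                        anchor_alpha = 0.01, n_perm = 200,
                        n_resamples = 100, pool_alpha = 0.01,
                        threshold = NULL, spc = spc_params(),
                        expansion = expansion_config(), reverse = TRUE,
                        absolute = FALSE) {
  stopifnot(length(contrast) == 2)
  structure(list(contrast = contrast, fdr = fdr,
                 anchor_alpha = anchor_alpha, n_perm = n_perm,
                 n_resamples = n_resamples, pool_alpha = pool_alpha,
                 threshold = threshold, spc = spc, expansion = expansion,
                 reverse = reverse, absolute = absolute),
            class = "bake_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
}

#' Run the full anchored network-expansion pipeline
#'
#' Executes the five stages in order: (1) differential expression between
#' the contrast conditions by moderated t and SAM, intersected into the
#' candidate list; (2) resolution of the known pathway; (3) correlation of
#' candidates with the pathway across all conditions, thresholded by the
#' resampled ROC / Youden rule against a non-differential background pool;
#' (4) per-anchor expansion: top neighbours, correlation distances,
#' superparamagnetic clustering with a permutation-derived critical
#' temperature, stable-cluster selection and edge inference, merged across
#' anchors; (5) reverse confirmation of every novel probe against the
#' anchor of its best edge. Fully reproducible given `seed`.
#'
#' @param m a [expression_matrix()].
#' @param pathway the known-pathway [gene_set()]; resolved against the
#'   matrix via its `gene_symbols` map when not yet resolved.
#' @param config a [bake_config()].
#' @param seed integer seed driving every stochastic stage.
#' @return list of class `bake_result`: `network`, gene sets (`L0`, `L1`,
#'   `L_path`, `anchors`, `L_random`), per-probe DE tables, the threshold
#'   object, per-anchor run details (`t_critical`, clusters), and reverse
#'   reports.
#' @export
run_bake <- function(m, pathway, config = bake_config(), seed = 1) {
  stopifnot(inherits(m, "bake_expr"), inherits(config, "bake_config"))
  # Stage 2 first: the pathway must resolve before anything else is spent.
  l_path <- run_stage("pathway", {
    if (!length(pathway$resolved_probes)) {
      if (is.null(m$gene_symbols))
        stop("pathway is unresolved and the matrix has no gene_symbols map")
      resolve_gene_set(pathway, m$gene_symbols, probes(m))
    } else pathway
  })
  ca <- config$contrast[1]; cb <- config$contrast[2]
  lim <- run_stage("diffexpr",
                   moderated_t_test(m, ca, cb, fdr = config$fdr))
  sam <- run_stage("diffexpr",
                   sam_test(m, ca, cb, fdr = config$fdr,
                            n_perm = config$n_perm,
                            seed = derive_seed(seed, 1)))
  l0 <- run_stage("diffexpr", intersect_de(lim, sam))
  # Novel candidates are non-pathway probes; pathway members are anchors,
  # not discoveries.
  l0_novel <- setdiff(l0$resolved_probes, l_path$resolved_probes)
  l0_novel_gs <- gene_set("L0_novel", l0_novel, l0_novel)
  thr <- run_stage("association", {
    if (!length(l0_novel)) stop("no non-pathway candidate is available")
    l_random <- background_pool(m, alpha = config$pool_alpha,
                                n_perm = min(config$n_perm, 100),
                                seed = derive_seed(seed, 2),
                                min_size = length(l_path$resolved_probes))
    res <- resampled_roc_threshold(m, l0_novel_gs, l_path, l_random,
                                   n_resamples = config$n_resamples,
                                   seed = derive_seed(seed, 3),
                                   absolute = config$absolute)
    list(threshold = res, l_random = l_random)
  })
  l1 <- run_stage("association",
                  select_L1(thr$threshold, config$threshold))
  anchors <- run_stage("anchors",
                       anchor_select(l_path, lim, sam,
                                     alpha = config$anchor_alpha))
  exp_cfg <- config$expansion
  anchor_probes <- anchors$resolved_probes
  max_anchors <- floor(exp_cfg$l_total / 2)
  n_neighbors <- exp_cfg$l_total - min(length(anchor_probes), max_anchors)
  # significance order for capping the per-run anchor set
  pmax2 <- pmax(lim$p[match(anchor_probes, lim$probe)],
                sam$p[match(anchor_probes, sam$probe)])
  anchor_rank <- anchor_probes[order(pmax2, anchor_probes)]
  runs <- list()
  networks <- list()
  pool_ids <- setdiff(l1$resolved_probes, anchor_probes)
  # the permutation null of the max-cluster-size trace is rank-based and
  # identical in law for every run of the same geometry: draw it once
  shared_null <- spc_null_max(exp_cfg$l_total, ncol(m$values), config$spc,
                              exp_cfg$n_null_permutations,
                              seed = derive_seed(seed, 90))
  for (ai in seq_along(anchor_probes)) {
    a <- anchor_probes[ai]
    run <- run_stage(paste0("expand:", a), {
      # clustered anchor set: this run's anchor plus the most significant
      # others, capped so anchors fill at most half of l_total
      run_anchors <- sort(union(a, head(setdiff(anchor_rank, a),
                                        max_anchors - 1)))
      nb <- top_neighbors(a, pool_ids, m, n = n_neighbors,
                          absolute = exp_cfg$absolute)
      ids <- c(run_anchors, nb$resolved_probes)
      tc <- t_critical(m, ids, config$spc, exp_cfg,
                       seed = derive_seed(seed, 100 + ai),
                       null_max = if (length(ids) == exp_cfg$l_total)
                         shared_null else NULL)
      cl <- if (is.na(tc$t_critical)) NULL
            else stable_clusters(tc$observed_profile, tc$t_critical,
                                 run_anchors, gene_of = m$gene_symbols)
      net <- if (is.null(cl)) bake_network()
             else infer_edges(cl, run_anchors, m, run_id = a)
      list(anchor = a, run_anchors = run_anchors, neighbors = nb,
           t_critical = tc$t_critical, tcrit = tc, clusters = cl,
           network = net)
    })
    runs[[a]] <- run
    networks[[a]] <- run$network
  }
  network <- bake_network(do.call(rbind, lapply(networks, as.data.frame)))
  reverse <- list()
  if (config$reverse && nrow(network)) {
    novel_edges <- network[network$edge_type == "anchor-novel", ,
                           drop = FALSE]
    novel_ids <- unique(c(novel_edges$gene_a, novel_edges$gene_b))
    novel_ids <- setdiff(novel_ids, anchor_probes)
    rev_pool <- union(l1$resolved_probes, l_path$resolved_probes)
    for (nv in novel_ids) {
      ed <- novel_edges[novel_edges$gene_a == nv |
                        novel_edges$gene_b == nv, , drop = FALSE]
      ed <- ed[order(-ifelse(is.na(ed$span), 0, ed$span)), , drop = FALSE]
      partner <- setdiff(c(ed$gene_a[1], ed$gene_b[1]), nv)[1]
      reverse[[nv]] <- run_stage(
        paste0("reverse:", nv),
        reverse_confirm(nv, partner, rev_pool, m,
                        n = exp_cfg$n_neighbors, pathway = l_path))
    }
  }
  structure(list(network = network, L0 = l0, L0_novel = l0_novel_gs,
                 L1 = l1, L_path = l_path, anchors = anchors,
                 L_random = thr$l_random, threshold = thr$threshold,
                 de_moderated = lim, de_sam = sam, runs = runs,
                 reverse = reverse, config = config, seed = seed),
            class = "bake_result")
}

#' @export
print.bake_result <- function(x, ...) {
  cat("Anchored network expansion\n")
  cat(sprintf("  candidates (both tests, FDR %.2g): %d probes\n",
              x$config$fdr, length(x$L0$resolved_probes)))
  cat(sprintf("  pathway: %d probes; anchors: %d probes\n",
              length(x$L_path$resolved_probes),
              length(x$anchors$resolved_probes)))
  cat(sprintf("  correlation threshold: %.3f -> %d associated probes\n",
              if (!is.null(x$config$threshold)) x$config$threshold
              else x$threshold$threshold,
              length(x$L1$resolved_probes)))
  cat(sprintf("  network: %d edges (%d anchor-novel)\n", nrow(x$network),
              sum(x$network$edge_type == "anchor-novel")))
  if (length(x$reverse)) {
    conf <- vapply(x$reverse, `[[`, logical(1), "confirmed")
    cat(sprintf("  reverse confirmation: %d/%d novel probes confirmed\n",
                sum(conf), length(conf)))
  }
  invisible(x)
}

#' Novel probes of a pipeline result
#' @param result a `bake_result`.
#' @return character vector of novel (non-anchor) probes in the network.
#' @export
novel_probes <- function(result) {
  net <- result$network
  ids <- unique(c(net$gene_a, net$gene_b))
  setdiff(ids, result$anchors$resolved_probes)
}
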