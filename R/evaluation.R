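# Hidden-gene benchmark: withhold part of a known network, expand around
# the remaining anchors, and score whether the withheld members are
# rediscovered. TP/FP/FN/TN follow the adjudication rule: discoveries in
# the hidden list are true positives, other discoveries false positives,
# undiscovered hidden genes false negatives, and the true negatives are the
# rest of the declared candidate universe.

#' Random anchor / hidden split of a differentially expressed pathway
#'
#' @param pathway_de [gene_set()] (or probe ids) of the pathway probes that
#'   passed the differential-expression filter.
#' @param n_anchor_probes how many probes become anchors.
#' @param seed integer seed.
#' @return list with [gene_set()]s `anchors` and `hidden` (disjoint).
#' @export
hidden_gene_split <- function(pathway_de, n_anchor_probes = 20, seed = 1) {
  ids <- as_probe_ids(pathway_de)
  if (length(ids) <= n_anchor_probes)
    stop("need more than ", n_anchor_probes, " probes to split (got ",
         length(ids), ")")
  anchor_ids <- sort(with_seed(seed, sample(ids, n_anchor_probes)))
  hidden_ids <- sort(setdiff(ids, anchor_ids))
  list(anchors = gene_set("L_anchor", anchor_ids, anchor_ids),
       hidden = gene_set("L_hidden", hidden_ids, hidden_ids))
}

#' Score discoveries against a hidden gene list
#'
#' `TP = |discovered & hidden|`, `FP = |discovered \ hidden|`,
#' `FN = |hidden \ discovered|`, `TN = |pool \ hidden \ discovered|`;
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive predictive
#' value `TP/(TP+FP)`. Ratios with a zero denominator are reported as `NA`
#' (undefined), never as 0.
#'
#' @param discovered discovered ids ([gene_set()] or character).
#' @param hidden withheld ids.
#' @param pool the candidate universe the discoveries were drawn from
#'   (must contain every discovery).
#' @return list of class `bake_eval`: `tp`, `fp`, `fn`, `tn`,
#'   `sensitivity`, `specificity`, `ppv`, and the per-discovery
#'   adjudication `table`.
#' @export
score_recovery <- function(discovered, hidden, pool) {
  discovered <- unique(as_probe_ids(discovered))
  hidden <- unique(as_probe_ids(hidden))
  pool <- unique(as_probe_ids(pool))
  stray <- setdiff(discovered, pool)
  if (length(stray))
    stop("discovered id(s) outside the candidate pool: ",
         paste(stray, collapse = ", "))
  tp <- length(intersect(discovered, hidden))
  fp <- length(setdiff(discovered, hidden))
  fn <- length(setdiff(hidden, discovered))
  tn <- length(setdiff(setdiff(pool, hidden), discovered))
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  adjudication <- data.frame(
    id = sort(discovered),
    call = ifelse(sort(discovered) %in% hidden, "TP", "FP"),
    stringsAsFactors = FALSE)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = ratio(tp, tp + fn),
                 specificity = ratio(tn, tn + fp),
                 ppv = ratio(tp, tp + fp),
                 table = adjudication),
            class = "bake_eval")
}

#' @export
print.bake_eval <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat(sprintf("TP=%d FP=%d FN=%d TN=%d\n", x$tp, x$fp, x$fn, x$tn))
  cat(sprintf("sensitivity %s, specificity %s, PPV %s\n",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv)))
  invisible(x)
}

#' Hidden-gene benchmark of the full pipeline
#'
#' Repeats: split the differentially expressed pathway probes into anchors
#' and hidden genes, run the pipeline with the anchors as the known
#' pathway, and score the rediscovery of the hidden genes. Metrics are
#' reported per split and averaged, at both probe and gene level (probes
#' are the computational unit; gene-level collapses by "any probe").
#'
#' @param m a [expression_matrix()].
#' @param pathway the full known pathway ([gene_set()], resolved or
#'   resolvable against `m`).
#' @param config a [bake_config()].
#' @param n_splits number of random splits.
#' @param n_anchor_probes anchors per split.
#' @param seed integer seed.
#' @return list of class `bake_benchmark`: `splits` (per-split
#'   `bake_eval`s at probe and gene level), `summary` (mean and SD of each
#'   metric).
#' @export
benchmark_run <- function(m, pathway, config = bake_config(),
                          n_splits = 3, n_anchor_probes = 20, seed = 1) {
  if (!length(pathway$resolved_probes))
    pathway <- resolve_gene_set(pathway, m$gene_symbols, probes(m))
  ca <- config$contrast[1]; cb <- config$contrast[2]
  lim <- moderated_t_test(m, ca, cb, fdr = config$fdr)
  sam <- sam_test(m, ca, cb, fdr = config$fdr, n_perm = config$n_perm,
                  seed = derive_seed(seed, 9))
  path_de <- anchor_select(pathway, lim, sam, alpha = config$anchor_alpha)
  to_genes <- function(ids) {
    if (is.null(m$gene_symbols)) ids
    else unique(unname(m$gene_symbols[ids]))
  }
  splits <- vector("list", n_splits)
  for (s in seq_len(n_splits)) {
    sp <- hidden_gene_split(path_de, n_anchor_probes,
                            seed = derive_seed(seed, s))
    res <- run_bake(m, sp$anchors, config, seed = derive_seed(seed, 50 + s))
    discovered <- novel_probes(res)
    pool <- setdiff(res$L0$resolved_probes, sp$anchors$resolved_probes)
    discovered <- intersect(discovered, pool)
    probe_eval <- score_recovery(discovered, sp$hidden, pool)
    gene_eval <- score_recovery(to_genes(discovered),
                                to_genes(sp$hidden$resolved_probes),
                                to_genes(pool))
    splits[[s]] <- list(split = sp, result = res, probe = probe_eval,
                        gene = gene_eval)
  }
  metric <- function(level, what)
    vapply(splits, function(x) x[[level]][[what]], numeric(1))
  summarize <- function(level) {
    vals <- sapply(c("sensitivity", "specificity", "ppv"),
                   function(w) metric(level, w))
    vals <- rbind(vals)
    data.frame(metric = c("sensitivity", "specificity", "ppv"),
               mean = colMeans(vals, na.rm = TRUE),
               sd = apply(vals, 2, sd, na.rm = TRUE), row.names = NULL)
  }
  structure(list(splits = splits,
                 summary = list(probe = summarize("probe"),
                                gene = summarize("gene")),
                 n_splits = n_splits),
            class = "bake_benchmark")
}

#' @export
print.bake_benchmark <- function(x, ...) {
  cat(sprintf("hidden-gene benchmark over %d split(s)\n", x$n_splits))
  cat("probe level:\n"); print(x$summary$probe)
  cat("gene level:\n"); print(x$summary$gene)
  invisible(x)
}
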