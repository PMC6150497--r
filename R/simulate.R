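#' Configuration for the synthetic expression generator
#'
#' Defaults mirror the study design the package targets: four diet/time
#' conditions with small group sizes (DC8 n=7, DW8 n=5, DC16 n=5, DW16 n=9,
#' 26 samples total), a planted pathway whose members share a
#' condition-dependent latent activity, planted "novel associated" genes
#' loading on the same activity, and a large independent background.
#'
#' @param n_background background genes (i.i.d. noise).
#' @param n_pathway planted known-pathway genes.
#' @param n_associated planted novel genes sharing the pathway's latent
#'   activity (the discovery targets).
#' @param n_de_background genes that are differentially expressed in the
#'   contrast but follow private condition-response profiles uncorrelated
#'   with any pathway module (default 0). Real candidate lists are
#'   dominated by such genes; they populate the differential-expression
#'   pool without being network-associated, which the hidden-gene
#'   benchmark needs for a meaningful candidate universe.
#' @param samples_per_condition named integer vector, condition -> n.
#' @param de_log2fc shift of the latent activity in `de_contrast[1]` relative
#'   to `de_contrast[2]` (log2 units before the `latent_strength` loading).
#' @param latent_strength loading lambda in (0,1): planted genes are
#'   `baseline + noise_sd * (lambda * b_ms + sqrt(1-lambda^2) * eps)` where
#'   `b_ms` is the latent activity of the gene's module.
#' @param noise_sd residual scale of per-probe noise (log2 units).
#' @param probes_per_gene probes per gene; extra probes replicate the gene
#'   signal plus `probe_noise_sd` technical noise (emulating the platform's
#'   multiple probe sets per gene).
#' @param seed integer seed; identical seeds give bitwise-identical output.
#' @param de_contrast length-2 conditions (contrast, reference) carrying the
#'   planted differential expression.
#' @param condition_effects optional named vector of latent condition means
#'   shared by every module (the single-response-profile model). By default
#'   (`NULL`) each module draws its own condition-response profile: the
#'   contrast conditions sit at 0 (`de_contrast[2]`) and `+/- de_log2fc`
#'   (`de_contrast[1]`, sign alternating by module, as real pathways contain
#'   both up- and down-regulated members), while the remaining conditions
#'   respond by `N(0, (de_log2fc/2)^2)` draws. Diverse response shapes keep
#'   cross-module correlations moderate while module members co-vary
#'   tightly, the two-scale structure condition-series data show.
#' @param module_size pathway genes per sub-module. Real pathways are
#'   organized in sub-complexes whose members co-express much more tightly
#'   than the pathway at large; modules reproduce that two-scale correlation
#'   structure. `module_size >= n_pathway` together with a shared
#'   `condition_effects` vector collapses the model to a single factor.
#' @param module_coherence fraction `w` in `[0, 1]` of the latent activity's
#'   stochastic variance shared across modules:
#'   `b_ms = mu_m(cond(s)) + sqrt(w) eta_s + sqrt(1-w) u_ms`.
#' @param baseline_mean,baseline_sd distribution of per-gene baselines.
#' @param probe_noise_sd technical sd of replicate probes.
#' @return a list of class `bake_simconfig`.
#' @export
sim_config <- function(n_background = 940, n_pathway = 20, n_associated = 40,
                       n_de_background = 0,
                       samples_per_condition = c(DC8 = 7, DW8 = 5,
                                                 DC16 = 5, DW16 = 9),
                       de_log2fc = 5, latent_strength = 0.8, noise_sd = 1,
                       probes_per_gene = 2, seed = 1,
                       de_contrast = c("DW16", "DC16"),
                       condition_effects = NULL,
                       module_size = 2, module_coherence = 0.3,
                       baseline_mean = 8, baseline_sd = 1.5,
                       probe_noise_sd = 0.5) {
  stopifnot(n_background >= 0, n_pathway >= 0, n_associated >= 0,
            n_de_background >= 0, probes_per_gene >= 1, noise_sd > 0,
            latent_strength^2 < 1, latent_strength >= 0,
            module_size >= 1, module_coherence >= 0, module_coherence <= 1)
  if (is.null(names(samples_per_condition)))
    stop("samples_per_condition must be named by condition")
  if (any(samples_per_condition <= 0))
    stop("every declared condition needs at least one sample")
  if (!all(de_contrast %in% names(samples_per_condition)))
    stop("de_contrast conditions must be declared in samples_per_condition")
  if (!is.null(condition_effects) &&
      !all(names(samples_per_condition) %in% names(condition_effects)))
    stop("condition_effects must cover every declared condition")
  structure(list(n_background = n_background, n_pathway = n_pathway,
                 n_associated = n_associated,
                 n_de_background = n_de_background,
                 samples_per_condition = samples_per_condition,
                 de_log2fc = de_log2fc, latent_strength = latent_strength,
                 noise_sd = noise_sd, probes_per_gene = probes_per_gene,
                 seed = seed, de_contrast = de_contrast,
                 condition_effects = condition_effects,
                 module_size = module_size,
                 module_coherence = module_coherence,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 probe_noise_sd = probe_noise_sd),
            class = "bake_simconfig")
}

#' Generate a synthetic expression dataset with planted structure
#'
#' Planted (pathway and associated) genes follow
#' `x_gs = baseline_g + noise_sd * (lambda * b_ms + sqrt(1-lambda^2) * eps_gs)`
#' with `lambda = latent_strength` and a condition-dependent latent module
#' activity `b_ms = mu_cond(s) + sqrt(w) * eta_s + sqrt(1-w) * u_ms`
#' (`w = module_coherence`): the condition effect (shifted by `de_log2fc`
#' in the contrast condition) and a fraction `w` of the stochastic activity
#' are shared pathway-wide, the remainder is module-specific. Pathway genes
#' fill modules of `module_size` in order; associated genes are assigned to
#' modules round-robin. Background genes are i.i.d. Gaussian noise around
#' their baselines.
#'
#' @param config a [sim_config()].
#' @return list with elements `expr` (a [expression_matrix()]) and `truth`
#'   (gene sets `pathway_probes`, `associated_probes`, `de_probes`, the
#'   per-sample `latent_activity`, the per-gene `module_of` assignment, and
#'   the generating `config`).
#' @export
simulate_expression <- function(config = sim_config()) {
  stopifnot(inherits(config, "bake_simconfig"))
  spc <- config$samples_per_condition
  cond <- rep(names(spc), times = spc)
  sample_ids <- unlist(lapply(names(spc), function(cn)
    sprintf("%s_m%02d", cn, seq_len(spc[[cn]]))), use.names = FALSE)
  n_s <- length(sample_ids)
  lam <- config$latent_strength
  w <- config$module_coherence
  n_modules <- max(1L, ceiling(config$n_pathway / config$module_size))
  module_of_pw <- if (config$n_pathway)
    ((seq_len(config$n_pathway) - 1L) %/% config$module_size) + 1L
    else integer()
  module_of_as <- if (config$n_associated)
    ((seq_len(config$n_associated) - 1L) %% n_modules) + 1L
    else integer()
  conds <- names(spc)
  with_seed(config$seed, {
    # per-module condition-response profiles (n_modules x conditions)
    if (!is.null(config$condition_effects)) {
      mu <- matrix(rep(config$condition_effects[conds], each = n_modules),
                   n_modules, length(conds), dimnames = list(NULL, conds))
    } else {
      mu <- matrix(rnorm(n_modules * length(conds),
                         sd = config$de_log2fc / 2),
                   n_modules, length(conds), dimnames = list(NULL, conds))
      mu[, config$de_contrast[2]] <- 0
      mu[, config$de_contrast[1]] <-
        ifelse(seq_len(n_modules) %% 2 == 1, 1, -1) * config$de_log2fc
    }
    eta <- rnorm(n_s)
    u <- matrix(rnorm(n_modules * n_s), n_modules, n_s)
    a <- eta
    # per-module latent activity (rows = modules)
    b <- mu[, cond, drop = FALSE] +
      sqrt(w) * matrix(eta, n_modules, n_s, byrow = TRUE) +
      sqrt(1 - w) * u
    gene_block <- function(prefix, n_genes, modules) {
      if (n_genes == 0)
        return(list(vals = matrix(0, 0, n_s), genes = character()))
      genes <- sprintf("%s%03d", prefix, seq_len(n_genes))
      base <- rnorm(n_genes, config$baseline_mean, config$baseline_sd)
      eps <- matrix(rnorm(n_genes * n_s), n_genes, n_s)
      sig <- if (!is.null(modules))
        lam * b[modules, , drop = FALSE] + sqrt(1 - lam^2) * eps
      else eps
      list(vals = base + config$noise_sd * sig, genes = genes)
    }
    pw <- gene_block("GenePW", config$n_pathway, module_of_pw)
    as_ <- gene_block("GeneAS", config$n_associated, module_of_as)
    # DE background: private condition-response profile per gene,
    # uncorrelated with any pathway module
    deb <- if (config$n_de_background == 0)
      list(vals = matrix(0, 0, n_s), genes = character())
    else {
      nd <- config$n_de_background
      mu_d <- matrix(rnorm(nd * length(conds), sd = config$de_log2fc / 2),
                     nd, length(conds), dimnames = list(NULL, conds))
      mu_d[, config$de_contrast[2]] <- 0
      mu_d[, config$de_contrast[1]] <-
        ifelse(seq_len(nd) %% 2 == 1, 1, -1) * config$de_log2fc
      genes <- sprintf("GeneDE%03d", seq_len(nd))
      base <- rnorm(nd, config$baseline_mean, config$baseline_sd)
      bpriv <- mu_d[, cond, drop = FALSE] + matrix(rnorm(nd * n_s), nd, n_s)
      eps <- matrix(rnorm(nd * n_s), nd, n_s)
      list(vals = base + config$noise_sd *
             (lam * bpriv + sqrt(1 - lam^2) * eps), genes = genes)
    }
    bg <- gene_block("GeneBG", config$n_background, NULL)
    gene_vals <- rbind(pw$vals, as_$vals, deb$vals, bg$vals)
    genes <- c(pw$genes, as_$genes, deb$genes, bg$genes)
    ppg <- config$probes_per_gene
    if (ppg == 1) {
      vals <- gene_vals
      probe_ids <- paste0(genes, "_p1")
      probe_gene <- genes
    } else {
      idx <- rep(seq_along(genes), each = ppg)
      vals <- gene_vals[idx, , drop = FALSE] +
        matrix(rnorm(length(idx) * n_s, sd = config$probe_noise_sd),
               length(idx), n_s)
      probe_ids <- sprintf("%s_p%d", genes[idx], rep(seq_len(ppg),
                                                     length(genes)))
      probe_gene <- genes[idx]
    }
    dimnames(vals) <- list(probe_ids, sample_ids)
    em <- expression_matrix(vals, setNames(cond, sample_ids),
                            setNames(probe_gene, probe_ids))
    probes_of <- function(gs) probe_ids[probe_gene %in% gs]
    pathway_probes <- gene_set("pathway", pw$genes, probes_of(pw$genes))
    associated_probes <- gene_set("associated", as_$genes,
                                  probes_of(as_$genes))
    de_genes <- if (lam * config$de_log2fc != 0) c(pw$genes, as_$genes)
                else character()
    de_probes <- gene_set("de", de_genes, probes_of(de_genes))
    de_background_probes <- gene_set("de_background", deb$genes,
                                     probes_of(deb$genes))
    list(expr = em,
         truth = list(pathway_probes = pathway_probes,
                      associated_probes = associated_probes,
                      de_probes = de_probes,
                      de_background_probes = de_background_probes,
                      latent_activity = setNames(a, sample_ids),
                      module_of = setNames(c(module_of_pw, module_of_as),
                                           c(pw$genes, as_$genes)),
                      config = config))
  })
}

#' Write a simulated dataset to disk (expression TSV, annotation TSV, GMTs)
#'
#' @param sim result of [simulate_expression()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "annotation.tsv"))
  sets <- list(sim$truth$pathway_probes, sim$truth$associated_probes,
               sim$truth$de_probes, sim$truth$de_background_probes)
  write_gmt(sets, file.path(dir, "truth_genes.gmt"), what = "members")
  write_gmt(sets, file.path(dir, "truth_probes.gmt"), what = "probes")
  gm <- data.frame(probe = names(sim$expr$gene_symbols),
                   gene = unname(sim$expr$gene_symbols))
  write.table(gm, file.path(dir, "probe_map.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
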