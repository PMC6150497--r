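#' Gene set with probe resolution
#'
#' A named, ordered collection of gene symbols together with the probe ids
#' it resolves to on a given platform. Resolution is deterministic: for each
#' member symbol in order, its probes are appended in sorted order.
#'
#' @param name set name.
#' @param members character vector of gene symbols (deduplicated, order kept).
#' @param resolved_probes probe ids the members resolve to.
#' @param unresolved member symbols with no probe on the platform.
#' @return object of class `bake_geneset`.
#' @export
gene_set <- function(name, members, resolved_probes = character(),
                     unresolved = character()) {
  members <- as.character(members)
  members <- members[!duplicated(members)]
  structure(list(name = as.character(name), members = members,
                 resolved_probes = as.character(resolved_probes),
                 unresolved = as.character(unresolved)),
            class = "bake_geneset")
}

#' @export
print.bake_geneset <- function(x, ...) {
  cat(sprintf("bake_geneset '%s': %d members, %d resolved probes",
              x$name, length(x$members), length(x$resolved_probes)))
  if (length(x$unresolved))
    cat(sprintf(", %d unresolved", length(x$unresolved)))
  cat("\n")
  invisible(x)
}

#' @export
length.bake_geneset <- function(x) length(x$resolved_probes)

#' Resolve gene-set members to probe ids
#'
#' @param gs a [gene_set()].
#' @param probe_map named character vector, probe id -> gene symbol
#'   (many-to-one allowed).
#' @param universe optional probe universe (e.g. [probes()] of a matrix);
#'   probes outside it are dropped.
#' @return the gene set with `resolved_probes` and `unresolved` filled in;
#'   members without any probe are reported in a warning, never silently
#'   dropped from `members`.
#' @export
resolve_gene_set <- function(gs, probe_map, universe = NULL) {
  stopifnot(inherits(gs, "bake_geneset"))
  if (is.null(names(probe_map))) stop("probe_map must be named (probe -> symbol)")
  if (!is.null(universe)) probe_map <- probe_map[names(probe_map) %in% universe]
  res <- unlist(lapply(gs$members, function(sym) {
    sort(names(probe_map)[probe_map == sym])
  }), use.names = FALSE)
  hit <- unique(probe_map[res])
  unres <- setdiff(gs$members, hit)
  if (length(unres))
    warning(sprintf("gene set '%s': %d member(s) with no probe: %s",
                    gs$name, length(unres), paste(unres, collapse = ", ")))
  if (!length(res))
    stop(sprintf("gene set '%s' is empty after probe resolution", gs$name))
  gene_set(gs$name, gs$members, res, unres)
}

#' Read a gene set from a GMT or one-symbol-per-line file
#'
#' @param path GMT file (first set used unless `set` given) or plain list.
#' @param probe_map optional probe -> symbol map; when supplied the set is
#'   resolved via [resolve_gene_set()].
#' @param universe optional probe universe for resolution.
#' @param set for GMT files with several sets, the name of the set to read.
#' @param format `"auto"` (GMT when any line has >= 3 tab-separated fields),
#'   `"gmt"` or `"list"`.
#' @return a [gene_set()].
#' @export
read_gene_set <- function(path, probe_map = NULL, universe = NULL,
                          set = NULL, format = c("auto", "gmt", "list")) {
  format <- match.arg(format)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty gene-set file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (format == "auto")
    format <- if (any(lengths(fields) >= 3)) "gmt" else "list"
  if (format == "gmt") {
    nm <- vapply(fields, `[[`, character(1), 1)
    idx <- if (is.null(set)) 1L else match(set, nm)
    if (is.na(idx)) stop("set '", set, "' not found in ", path)
    f <- fields[[idx]]
    if (length(f) < 3) stop("malformed GMT line for set '", f[1], "'")
    gs <- gene_set(f[1], f[-(1:2)])
  } else {
    gs <- gene_set(tools::file_path_sans_ext(basename(path)),
                   trimws(unlist(fields)))
  }
  if (!is.null(probe_map)) gs <- resolve_gene_set(gs, probe_map, universe)
  gs
}

#' Write gene sets to a GMT file
#'
#' @param sets a [gene_set()] or list of them.
#' @param path output path.
#' @param what `"members"` writes gene symbols, `"probes"` resolved probes.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, what = c("members", "probes")) {
  what <- match.arg(what)
  if (inherits(sets, "bake_geneset")) sets <- list(sets)
  lines <- vapply(sets, function(gs) {
    ids <- if (what == "members") gs$members else gs$resolved_probes
    paste(c(gs$name, "na", ids), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
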