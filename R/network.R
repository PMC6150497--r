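#' Typed undirected gene network
#'
#' Edges are stored canonically (gene_a < gene_b lexicographically, rows
#' sorted on the pair) so emitted files are diffable. Self-edges are
#' rejected; duplicate pairs are merged keeping the maximum persistence span
#' (ties: maximum |rho|).
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`,
#'   `edge_type` (one of `"anchor-anchor"`, `"anchor-novel"`), and optional
#'   evidence columns `cluster_id`, `rho`, `span`.
#' @return object of class `bake_network` (a canonicalized data.frame).
#' @export
bake_network <- function(edges = NULL) {
  if (is.null(edges) || !nrow(edges)) {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        edge_type = character(), cluster_id = character(),
                        rho = numeric(), span = integer(),
                        stringsAsFactors = FALSE)
    return(structure(edges, class = c("bake_network", "data.frame")))
  }
  stopifnot(all(c("gene_a", "gene_b", "edge_type") %in% names(edges)))
  for (col in c("cluster_id", "rho", "span"))
    if (is.null(edges[[col]]))
      edges[[col]] <- if (col == "cluster_id") NA_character_ else NA_real_
  if (any(edges$gene_a == edges$gene_b)) stop("self-edges are not allowed")
  flip <- edges$gene_a > edges$gene_b
  tmp <- edges$gene_a[flip]
  edges$gene_a[flip] <- edges$gene_b[flip]
  edges$gene_b[flip] <- tmp
  key <- paste(edges$gene_a, edges$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    keep <- vapply(split(seq_len(nrow(edges)), key), function(idx) {
      if (length(idx) == 1) return(idx)
      sp <- edges$span[idx]
      sp[is.na(sp)] <- -Inf
      best <- idx[sp == max(sp)]
      if (length(best) > 1) {
        ar <- abs(edges$rho[best])
        ar[is.na(ar)] <- -Inf
        best <- best[which.max(ar)]
      }
      best[1]
    }, integer(1))
    edges <- edges[sort(keep), , drop = FALSE]
  }
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  structure(edges, class = c("bake_network", "data.frame"))
}

#' @export
print.bake_network <- function(x, ...) {
  cat(sprintf("bake_network: %d edges (%d anchor-anchor, %d anchor-novel)\n",
              nrow(x), sum(x$edge_type == "anchor-anchor"),
              sum(x$edge_type == "anchor-novel")))
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 10))
  invisible(x)
}

#' Write a network to SIF, GraphML or edge-list TSV
#'
#' Output is bit-stable for a given network: edges are emitted in canonical
#' lexicographic order.
#'
#' @param n a [bake_network()].
#' @param path output file.
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(n, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(n, "bake_network"))
  if (format == "sif") {
    lines <- if (nrow(n))
      sprintf("%s interacts %s", n$gene_a, n$gene_b) else character()
    writeLines(lines, path)
  } else if (format == "tsv") {
    write.table(as.data.frame(n), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(as.data.frame(n), directed = FALSE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read a network back from an edge-list TSV written by [write_network()]
#'
#' @param path TSV file.
#' @return a [bake_network()].
#' @export
read_network_tsv <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  bake_network(df)
}
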