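#' Load an interaction edge list
#'
#' Two dialects: a plain 3+-column TSV (`gene_a`, `gene_b`, `kind`[, source])
#' and a BioGRID TAB-style file read by configurable column names (defaults
#' "Official Symbol Interactor A/B" and "Experimental System Type", whose
#' values `physical`/`genetic` map to the edge kind). Self-loops are dropped,
#' unordered duplicates collapse to one edge with a kind-specific
#' multiplicity count, and rows with an unknown kind are skipped with a
#' warning.
#'
#' @param path Edge file.
#' @param dialect `"plain"` or `"biogrid"`.
#' @param col_a,col_b,col_kind BioGRID-dialect column names.
#' @return data.frame: gene_a, gene_b, kind, multiplicity (gene_a < gene_b).
#' @export
load_edges <- function(path, dialect = c("plain", "biogrid"),
                       col_a = "Official Symbol Interactor A",
                       col_b = "Official Symbol Interactor B",
                       col_kind = "Experimental System Type") {
  dialect <- match.arg(dialect)
  if (dialect == "biogrid") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    need <- c(col_a, col_b, col_kind)
    if (!all(need %in% names(tab)))
      stop("missing BioGRID columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    df <- data.frame(gene_a = tab[[col_a]], gene_b = tab[[col_b]],
                     kind = tolower(tab[[col_kind]]), stringsAsFactors = FALSE)
  } else {
    first <- readLines(path, n = 1)
    if (length(first) == 0)
      return(data.frame(gene_a = character(0), gene_b = character(0),
                        kind = character(0), multiplicity = integer(0),
                        stringsAsFactors = FALSE))
    has_header <- grepl("gene_a", first, fixed = TRUE)
    tab <- utils::read.delim(path, header = has_header,
                             stringsAsFactors = FALSE)
    if (!has_header) names(tab)[1:3] <- c("gene_a", "gene_b", "kind")
    df <- data.frame(gene_a = as.character(tab$gene_a),
                     gene_b = as.character(tab$gene_b),
                     kind = tolower(as.character(tab$kind)),
                     stringsAsFactors = FALSE)
  }
  bad <- !df$kind %in% c("physical", "genetic")
  if (any(bad)) {
    warning(sum(bad), " row(s) with unknown interaction kind skipped")
    df <- df[!bad, , drop = FALSE]
  }
  loops <- df$gene_a == df$gene_b
  if (any(loops)) {
    message("load_edges: dropped ", sum(loops), " self-loop(s)")
    df <- df[!loops, , drop = FALSE]
  }
  if (nrow(df) == 0)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      kind = character(0), multiplicity = integer(0),
                      stringsAsFactors = FALSE))
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, df$kind, sep = "\r")
  agg <- table(key)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1),
                    gene_b = vapply(parts, `[`, "", 2),
                    kind = vapply(parts, `[`, "", 3),
                    multiplicity = as.integer(agg),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene_a, out$gene_b, out$kind), , drop = FALSE]
}

#' Write an edge list in the plain TSV dialect
#'
#' Each edge row is repeated `multiplicity` times if present, so a
#' write-then-load round trip is lossless.
#'
#' @param edges Edge data.frame (gene_a, gene_b, kind[, multiplicity]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path) {
  mult <- if ("multiplicity" %in% names(edges)) edges$multiplicity else 1L
  idx <- rep(seq_len(nrow(edges)), mult)
  out <- edges[idx, c("gene_a", "gene_b", "kind"), drop = FALSE]
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the hit interaction network
#'
#' Induced subgraph of the edge list on the hit genes, keeping physical
#' interactions only — genetic edges are filtered out entirely, per the
#' screen's network procedure. Hits without any physical partner remain as
#' singleton nodes.
#'
#' @param hits Character vector of hit genes (nonempty).
#' @param edges Edge data.frame from [load_edges()] or
#'   [generate_interactions()].
#' @param annotations Optional data.frame (gene, complex) of node labels.
#' @return List of class `hit_network`: `graph` (igraph, physical edges
#'   only), `nodes`, `edges`, `modules` (from [find_modules()]),
#'   `annotations`.
#' @export
build_hit_network <- function(hits, edges, annotations = NULL) {
  if (length(hits) == 0) stop("empty hit set")
  hits <- unique(as.character(hits))
  keep <- edges$kind == "physical" &
    edges$gene_a %in% hits & edges$gene_b %in% hits
  e <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    e[, c("gene_a", "gene_b"), drop = FALSE], directed = FALSE,
    vertices = data.frame(name = sort(hits), stringsAsFactors = FALSE))
  if ("multiplicity" %in% names(e))
    igraph::E(g)$multiplicity <- e$multiplicity
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                        edge.attr.comb = list(multiplicity = "sum"))
  net <- structure(list(graph = g, nodes = sort(hits), edges = e,
                        annotations = annotations),
                   class = "hit_network")
  net$modules <- find_modules(net)
  net
}

#' Connected-component modules of a hit network
#'
#' Modules are the connected components of the physical-interaction graph,
#' ordered by decreasing size with ties broken by the lexicographically
#' smallest member; members are sorted within each module.
#'
#' @param net A `hit_network`.
#' @return data.frame: module_id, size, members (comma-joined), plus a
#'   `membership` attribute (named integer vector gene -> module_id).
#' @export
find_modules <- function(net) {
  comp <- igraph::components(net$graph)
  groups <- split(names(comp$membership), comp$membership)
  groups <- lapply(groups, sort)
  ord <- order(-lengths(groups), vapply(groups, `[`, "", 1))
  groups <- groups[ord]
  out <- data.frame(module_id = seq_along(groups),
                    size = lengths(groups),
                    members = vapply(groups, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  membership <- rep(seq_along(groups), lengths(groups))
  names(membership) <- unlist(groups)
  attr(out, "membership") <- membership
  rownames(out) <- NULL
  out
}

#' @export
print.hit_network <- function(x, ...) {
  cat(sprintf("<hit_network: %d nodes, %d physical edges, %d modules>\n",
              length(x$nodes), igraph::ecount(x$graph), nrow(x$modules)))
  invisible(x)
}

#' Export a hit network for external viewers
#'
#' Writes `network.graphml`, `network.sif` (edges `a pp b`, singletons as
#' bare nodes) and `modules.tsv`. Output is deterministic for identical
#' inputs.
#'
#' @param net A `hit_network`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
export_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  igraph::write_graph(net$graph, file.path(dir, "network.graphml"),
                      format = "graphml")
  el <- igraph::as_edgelist(net$graph)
  sif <- if (nrow(el)) sprintf("%s\tpp\t%s", pmin(el[, 1], el[, 2]),
                               pmax(el[, 1], el[, 2])) else character(0)
  sif <- sort(sif)
  deg <- igraph::degree(net$graph)
  singles <- sort(names(deg)[deg == 0])
  writeLines(c(sif, singles), file.path(dir, "network.sif"))
  utils::write.table(net$modules, file.path(dir, "modules.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}
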