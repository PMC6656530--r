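#' Construct a semantic network
#'
#' Semantic networks are undirected, unweighted, simple labelled graphs,
#' represented as [igraph][igraph::igraph-package] objects with a `name`
#' vertex attribute. Duplicate and reversed edges collapse to one edge;
#' self-loops are rejected.
#'
#' @param edges two-column matrix or data frame of endpoint labels, or NULL
#'   for an edgeless network.
#' @param nodes character vector of node labels; defaults to the labels
#'   appearing in `edges`. Extra labels become isolated nodes.
#' @return an undirected simple `igraph` graph.
#' @export
semantic_network <- function(edges = NULL, nodes = NULL) {
  if (!is.null(edges)) {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2L) stop("edges must have two columns")
    storage.mode(edges) <- "character"
    if (any(edges[, 1] == edges[, 2]))
      stop("self-loops are not allowed in a semantic network")
  }
  nodes <- unique(c(as.character(nodes), as.character(edges)))
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Validate a semantic network object
#'
#' @param net an igraph graph.
#' @return `net`, invisibly; errors if directed, weighted/multi-edged,
#'   looped or unnamed.
#' @export
validate_network <- function(net) {
  if (!igraph::is_igraph(net)) stop("not an igraph object")
  if (igraph::is_directed(net)) stop("semantic networks are undirected")
  if (!igraph::is_simple(net)) stop("semantic networks have no loops or multi-edges")
  if (is.null(igraph::V(net)$name)) stop("vertices must be named")
  invisible(net)
}

#' Dense adjacency matrix of a semantic network
#'
#' @param net semantic network.
#' @param nodes optional node ordering (must be a permutation of the node
#'   labels, or a superset; absent labels become isolated rows).
#' @return symmetric 0/1 matrix with dimnames.
#' @export
network_adjacency <- function(net, nodes = NULL) {
  validate_network(net)
  A <- as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  if (is.null(nodes)) return(A)
  nodes <- as.character(nodes)
  out <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  keep <- intersect(nodes, rownames(A))
  out[keep, keep] <- A[keep, keep]
  out
}

#' Read / write semantic networks
#'
#' Supported formats: 2-column tab-separated edge list (`edgelist`) and
#' GraphML (`graphml`). `format = "auto"` keys off the file extension
#' (`.graphml` vs anything else). Edge-list input collapses duplicate and
#' reversed rows and rejects self-loops.
#'
#' @param path file path.
#' @param format `"auto"`, `"edgelist"` or `"graphml"`.
#' @return [read_network()]: a semantic network.
#' @export
read_network <- function(path, format = c("auto", "edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse")
    return(validate_network(igraph::simplify(g)))
  }
  first <- readLines(path, n = 1L)
  df <- tryCatch(
    read.table(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE,
               colClasses = "character"),
    error = function(e) NULL)
  if (is.null(df) && !nzchar(first))
    return(semantic_network())
  if (is.null(df) || ncol(df) < 2L)
    stop("edge-list file must have two tab-separated columns")
  semantic_network(edges = df[, 1:2])
}

#' @param net semantic network to write.
#' @rdname read_network
#' @export
write_network <- function(net, path, format = c("auto", "edgelist", "graphml")) {
  validate_network(net)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "edgelist"
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(net, names = TRUE)
    write.table(el, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    if (nrow(el) == 0L) cat("", file = path)  # ensure the file exists
  }
  invisible(path)
}

# internal: integer encoding of a corpus against a fixed node ordering.
# For each list: uidx = 0-based node indices of unique items in
# first-occurrence order; upos = 0-based index into uidx per emission.
prepare_corpus <- function(corpus, nodes) {
  lapply(corpus$lists, function(fl) {
    idx <- match(fl$items, nodes)
    if (anyNA(idx))
      stop("list contains items absent from the network node set: ",
           paste(unique(fl$items[is.na(idx)]), collapse = ", "))
    u <- unique(idx)
    list(uidx = as.integer(u - 1L), upos = as.integer(match(idx, u) - 1L))
  })
}
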