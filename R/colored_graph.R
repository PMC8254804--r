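#' Vertex-colored graphs
#'
#' A simple undirected graph whose vertices (genes) are colored by the
#' species they reside in.  The color universe `M` is stored explicitly
#' and may strictly contain the observed colors `sigma(L)`; this matters
#' for rs-Fitch recognition, where unobserved species can make the
#' difference between a graph being realizable by a scenario or not.
#'
#' @param edges two-column character matrix or data frame of edges (may
#'   have zero rows)
#' @param sigma named character vector mapping every vertex to its color
#' @param M color universe; defaults to the observed colors
#' @param vertices optional vertex set (defaults to `names(sigma)`)
#' @return an object of class `colored_graph` with fields `A` (logical
#'   adjacency matrix), `sigma`, and `M`
#' @export
colored_graph <- function(edges, sigma, M = NULL, vertices = names(sigma)) {
  sigma <- vapply(sigma, as.character, character(1))
  if (is.null(names(sigma))) stop("'sigma' must be named by vertex")
  vertices <- as.character(vertices)
  if (!all(names(sigma) %in% vertices) || !all(vertices %in% names(sigma)))
    stop("'sigma' must be total on the vertex set")
  A <- matrix(FALSE, length(vertices), length(vertices),
              dimnames = list(vertices, vertices))
  edges <- as.matrix(edges)
  if (length(edges)) {
    if (ncol(edges) != 2L) stop("'edges' needs two columns")
    mode(edges) <- "character"
    if (!all(edges %in% vertices))
      stop("edge endpoints must be vertices")
    if (any(edges[, 1L] == edges[, 2L])) stop("loops are not allowed")
    A[edges] <- TRUE
    A[edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  if (is.null(M)) M <- sort(unique(unname(sigma)))
  M <- as.character(M)
  if (!all(sigma %in% M)) stop("'M' must contain all observed colors")
  structure(list(A = A, sigma = sigma, M = M), class = "colored_graph")
}

#' Construct a colored graph from an adjacency matrix
#' @param A logical adjacency matrix with dimnames
#' @param sigma,M as in [colored_graph()]
#' @export
colored_graph_from_adjacency <- function(A, sigma, M = NULL) {
  diag(A) <- FALSE
  A <- A | t(A)
  g <- colored_graph(matrix(character(0), 0, 2), sigma, M,
                     vertices = rownames(A))
  g$A <- A[names(sigma), names(sigma), drop = FALSE]
  g
}

#' @export
print.colored_graph <- function(x, ...) {
  cat("colored graph: ", nrow(x$A), " vertices, ", sum(x$A) / 2, " edges, ",
      length(unique(x$sigma)), " observed colors (|M| = ", length(x$M), ")\n",
      sep = "")
  invisible(x)
}

#' Adjacency matrix of a graph-like object
#' @param g a `colored_graph`, a logical adjacency matrix, or an
#'   `edge_labeled_tree`-derived graph
#' @export
as_adjacency <- function(g) {
  if (inherits(g, "colored_graph")) g$A
  else if (is.matrix(g) && is.logical(g)) g
  else stop("cannot interpret 'g' as a graph")
}

#' Number of edges / edge list of a graph
#' @param g graph-like object (see [as_adjacency()])
#' @export
graph_edges <- function(g) {
  A <- as_adjacency(g)
  idx <- which(A & upper.tri(A), arr.ind = TRUE)
  cbind(rownames(A)[idx[, 1L]], rownames(A)[idx[, 2L]])
}

#' Induced subgraph of a colored graph
#'
#' By default the color universe `M` is kept unchanged (it is never
#' silently shrunk to the observed colors); set `restrict_colors = TRUE`
#' to restrict `M` to the colors observed on `W`.
#' @param g a `colored_graph`
#' @param W vertex subset
#' @param restrict_colors restrict `M` to `sigma(W)`?
#' @export
induced_subgraph <- function(g, W, restrict_colors = FALSE) {
  W <- as.character(W)
  stopifnot(all(W %in% rownames(g$A)))
  colored_graph_from_adjacency(
    g$A[W, W, drop = FALSE], g$sigma[W],
    M = if (restrict_colors) sort(unique(unname(g$sigma[W]))) else g$M)
}

#' Proper coloring check
#'
#' `TRUE` iff no edge joins two vertices of equal color.  Every LDT graph
#' is properly colored.
#' @param g a `colored_graph`
#' @export
is_properly_colored <- function(g) {
  e <- graph_edges(g)
  nrow(e) == 0L || all(g$sigma[e[, 1L]] != g$sigma[e[, 2L]])
}

# ---- cographs and cotrees ---------------------------------------------

#' Cotree of a cograph
#'
#' Recursively decomposes the graph into disjoint unions (inner label 0)
#' and joins (inner label 1), starting from single vertices.  The
#' resulting cotree satisfies `xy` is an edge iff the label of
#' `lca(x, y)` is 1.  Because the recursion alternates between
#' union and join steps, the returned cotree is discriminating (adjacent
#' inner labels differ).  If the graph is not a cograph, an object of
#' class `not_cograph` carrying an induced P4 witness is returned.
#'
#' @param g a `colored_graph` or logical adjacency matrix
#' @return an object of class `cotree` (fields `parent`, `label`, `root`,
#'   `leaves`), or `not_cograph`
#' @export
cotree <- function(g) {
  A <- as_adjacency(g)
  verts <- rownames(A)
  counter <- new.env(); counter$i <- 0L
  parent <- character(0)
  label <- stats::setNames(integer(0), character(0))
  p4 <- NULL
  rec <- function(W, join_level) {
    if (length(W) == 1L) return(W)
    sub <- if (join_level) !A[W, W, drop = FALSE] else A[W, W, drop = FALSE]
    if (join_level) diag(sub) <- FALSE
    comps <- adj_components(sub)
    if (length(comps) == 1L) {
      if (!join_level) return(rec(W, TRUE))
      p4 <<- find_induced_p4(A, W)
      return(NULL)
    }
    counter$i <- counter$i + 1L
    v <- paste0(if (join_level) "j" else "u", counter$i)
    label[v] <<- if (join_level) 1L else 0L
    for (comp in comps) {
      child <- rec(comp, !join_level)
      if (is.null(child)) return(NULL)
      parent[child] <<- v
    }
    v
  }
  root <- rec(sort(verts), FALSE)
  if (is.null(root))
    return(structure(list(p4 = p4), class = "not_cograph"))
  parent[root] <- NA_character_
  structure(list(parent = parent, label = label, root = root, leaves = verts),
            class = "cotree")
}

#' @export
print.cotree <- function(x, ...) {
  cat("cotree:", length(x$leaves), "leaves,", length(x$label), "inner vertices\n")
  invisible(x)
}

#' @export
print.not_cograph <- function(x, ...) {
  cat("not a cograph; induced P4:", paste(x$p4, collapse = " - "), "\n")
  invisible(x)
}

#' Is the graph a cograph (P4-free)?
#' @param g graph-like object
#' @export
is_cograph <- function(g) !inherits(cotree(g), "not_cograph")

# locate an induced P4 inside W (assumes one exists when G[W] is connected
# and co-connected); O(m n^2) scan over edges (y,z) with private
# neighbours x of y and w of z such that xw is a non-edge
find_induced_p4 <- function(A, W = rownames(A)) {
  sub <- A[W, W, drop = FALSE]
  n <- length(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || !sub[i, j]) next
    X <- which(sub[, i] & !sub[, j]); X <- setdiff(X, j)
    Ws <- which(sub[, j] & !sub[, i]); Ws <- setdiff(Ws, i)
    if (!length(X) || !length(Ws)) next
    nonadj <- !sub[X, Ws, drop = FALSE]
    hit <- which(nonadj, arr.ind = TRUE)
    hit <- hit[X[hit[, 1L]] != Ws[hit[, 2L]], , drop = FALSE]
    if (nrow(hit))
      return(W[c(X[hit[1L, 1L]], i, j, Ws[hit[1L, 2L]])])
  }
  NULL
}

#' Rebuild the edge set encoded by a cotree
#' @param ct a `cotree`
#' @return logical adjacency matrix on the cotree's leaves
#' @export
cotree_graph <- function(ct) {
  verts <- names(ct$parent)
  leaves <- ct$leaves
  A <- matrix(FALSE, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  depth <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  depth[ct$root] <- 0L
  repeat {
    todo <- verts[is.na(depth) & !is.na(depth[ct$parent[verts]])]
    if (!length(todo)) break
    depth[todo] <- depth[ct$parent[todo]] + 1L
  }
  below <- stats::setNames(vector("list", length(verts)), verts)
  for (v in names(sort(depth, decreasing = TRUE))) {
    ch <- names(ct$parent)[!is.na(ct$parent) & ct$parent == v]
    if (!length(ch)) { below[[v]] <- v; next }
    acc <- character(0)
    for (cset in below[ch]) {
      if (length(acc) && length(cset) && identical(ct$label[[v]], 1L))
        A[acc, cset] <- A[cset, acc] <- TRUE
      acc <- c(acc, cset)
    }
    below[[v]] <- acc
  }
  A
}

#' Contract equal-label edges of a cotree (discriminating form)
#'
#' Contracting every inner edge whose endpoints carry the same 0/1 label
#' yields the discriminating cotree, which is unique up to isomorphism.
#' [cotree()] already returns the discriminating form; this operation is
#' provided to canonicalize cotrees from other sources.
#' @param ct a `cotree`
#' @export
discriminating_cotree <- function(ct) {
  if (inherits(ct, "colored_graph") || is.matrix(ct)) ct <- cotree(ct)
  if (inherits(ct, "not_cograph")) stop("input is not a cograph")
  parent <- ct$parent; label <- ct$label
  repeat {
    inner <- names(label)
    pv <- parent[inner]
    cand <- inner[!is.na(pv) & pv %in% inner]
    cand <- cand[label[cand] == label[parent[cand]]]
    if (!length(cand)) break
    v <- cand[1L]; p <- parent[[v]]
    kids <- names(parent)[!is.na(parent) & parent == v]
    parent[kids] <- p
    parent <- parent[names(parent) != v]
    label <- label[names(label) != v]
  }
  structure(list(parent = parent, label = label, root = ct$root,
                 leaves = ct$leaves), class = "cotree")
}

#' Maximal independent-set partition of a complete multipartite graph
#'
#' A graph is complete multipartite iff it has no induced `K2 + K1`;
#' in that case its maximal independent sets are the connected components
#' of the complement and form a unique partition.  Returns the partition
#' (a list of vertex sets) or an object of class `not_multipartite`
#' carrying an induced `K2 + K1` witness (`x`, `y` adjacent, `z` isolated
#' from both).
#'
#' @param g graph-like object
#' @export
complete_multipartite_parts <- function(g) {
  A <- as_adjacency(g)
  comp <- !A; diag(comp) <- FALSE
  parts <- adj_components(comp)
  ok <- all(vapply(parts, function(P) !any(A[P, P]), logical(1)))
  if (!ok) {
    # G is not complete multipartite, so an induced K2+K1 exists: scan
    # edges (u, v) for a vertex w non-adjacent to both
    verts <- rownames(A)
    e <- graph_edges(A)
    for (i in seq_len(nrow(e))) {
      u <- e[i, 1L]; v <- e[i, 2L]
      w <- verts[!A[, u] & !A[, v] & verts != u & verts != v]
      if (length(w))
        return(structure(list(witness = c(u, v, w[1L])),
                         class = "not_multipartite"))
    }
    stop("internal error: failed to locate a K2+K1 witness")
  }
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

#' @export
print.not_multipartite <- function(x, ...) {
  cat("not complete multipartite; induced K2+K1 witness: edge",
      x$witness[1L], "-", x$witness[2L], ", isolated", x$witness[3L], "\n")
  invisible(x)
}

# ---- I/O ---------------------------------------------------------------

#' Read / write colored graphs
#'
#' Plain-text interchange: an edge-list TSV (`u<TAB>v`, possibly empty), a
#' vertex/color TSV (`v<TAB>color`, one line per vertex), and optionally a
#' one-column file listing the color universe.  GraphML (with a `color`
#' vertex attribute) is supported through igraph.
#'
#' @param edge_file path to the edge list TSV, or a GraphML file when
#'   `format = "graphml"`
#' @param color_file path to the vertex-color TSV (ignored for GraphML)
#' @param universe_file optional path to the color-universe file
#' @param format `"tsv"` or `"graphml"`
#' @return a `colored_graph`
#' @export
read_colored_graph <- function(edge_file, color_file = NULL,
                               universe_file = NULL, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  M <- if (!is.null(universe_file)) readLines(universe_file) else NULL
  if (!is.null(M)) M <- trimws(M[nzchar(trimws(M))])
  if (format == "graphml") {
    ig <- igraph::read_graph(edge_file, format = "graphml")
    sigma <- stats::setNames(igraph::vertex_attr(ig, "color"),
                             igraph::vertex_attr(ig, "name"))
    e <- igraph::as_edgelist(ig)
    return(colored_graph(e, sigma, M = M))
  }
  cols <- utils::read.table(color_file, sep = "\t", header = FALSE,
                            colClasses = "character")
  sigma <- stats::setNames(cols[[2L]], cols[[1L]])
  edges <- if (file.size(edge_file) > 0)
    as.matrix(utils::read.table(edge_file, sep = "\t", header = FALSE,
                                colClasses = "character"))
  else matrix(character(0), 0, 2)
  colored_graph(edges, sigma, M = M)
}

#' @rdname read_colored_graph
#' @param g a `colored_graph`
#' @export
write_colored_graph <- function(g, edge_file, color_file = NULL,
                                universe_file = NULL, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    ig <- igraph::graph_from_data_frame(
      as.data.frame(graph_edges(g), stringsAsFactors = FALSE),
      directed = FALSE,
      vertices = data.frame(name = names(g$sigma), color = unname(g$sigma),
                            stringsAsFactors = FALSE))
    igraph::write_graph(ig, edge_file, format = "graphml")
  } else {
    e <- graph_edges(g)
    utils::write.table(e, edge_file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(color_file))
      utils::write.table(data.frame(names(g$sigma), unname(g$sigma)),
                         color_file, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(universe_file)) writeLines(g$M, universe_file)
  invisible(g)
}
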