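#' Relaxed evolutionary scenarios
#'
#' A relaxed scenario is the 6-tuple (T, S, sigma, mu, tau_T, tau_S): a
#' planted gene tree `T`, a planted species tree `S`, a coloring `sigma`
#' assigning each gene (leaf of T) the species (leaf of S) it resides in, a
#' reconciliation map `mu` from gene-tree vertices to vertices or edges of
#' `S`, and time maps for both trees.  No event types (speciation,
#' duplication) are assumed; only the root, leaf and time-consistency
#' constraints below are imposed:
#'
#' * (G0) `mu(x) = 0_S` iff `x = 0_T` (planted roots map to each other);
#' * (G1) `mu(x) = sigma(x)` iff `x` is a leaf of `T`;
#' * (C1) if `mu(u)` is a vertex of `S` then `tau_T(u) = tau_S(mu(u))`;
#' * (C2) if `mu(u)` is an edge `(x, y)` of `S` then
#'   `tau_S(y) < tau_T(u) < tau_S(x)`;
#' * leaf times agree: `tau_T(x) = tau_S(sigma(x))` for every gene `x`.
#'
#' Reconciliation images are tagged values: `mu_vertex(v)` for a vertex of
#' `S` and `mu_edge(child)` for the edge of `S` entering `child` (edges
#' are identified by their lower endpoint).
#'
#' @param gene_tree,species_tree `planted_tree` objects
#' @param sigma named character vector, leaves of `gene_tree` to leaves of
#'   `species_tree`
#' @param mu named list of tagged images (see [mu_vertex()]/[mu_edge()])
#'   covering all vertices of `gene_tree`
#' @param tau_T,tau_S named numeric time maps
#' @return an object of class `relaxed_scenario`
#' @seealso [validate_scenario()], [ldt_graph()], [rs_fitch_graph()]
#' @export
relaxed_scenario <- function(gene_tree, species_tree, sigma, mu, tau_T, tau_S) {
  s <- structure(list(T = gene_tree, S = species_tree, sigma = sigma,
                      mu = mu, tau_T = tau_T, tau_S = tau_S),
                 class = "relaxed_scenario")
  for (u in tree_vertices(gene_tree)) {
    im <- mu[[u]]
    if (is.null(im) || !is.list(im) || !im$type %in% c("vertex", "edge"))
      stop("malformed reconciliation image for vertex '", u, "'")
    if (im$type == "vertex" && !im$id %in% tree_vertices(species_tree))
      stop("mu image of '", u, "' is not a vertex of S")
    if (im$type == "edge" &&
        !(im$id %in% tree_vertices(species_tree) &&
          !is.na(species_tree$parent[[im$id]])))
      stop("mu image of '", u, "' is not an edge of S")
  }
  s
}

#' @rdname relaxed_scenario
#' @param v vertex id in the species tree
#' @export
mu_vertex <- function(v) list(type = "vertex", id = as.character(v))

#' @rdname relaxed_scenario
#' @param child lower endpoint identifying an edge of the species tree
#' @export
mu_edge <- function(child) list(type = "edge", id = as.character(child))

#' @export
print.relaxed_scenario <- function(x, ...) {
  cat("relaxed scenario: ", length(tree_leaves(x$T)), " genes in ",
      length(unique(unname(x$sigma))), " species\n", sep = "")
  invisible(x)
}

#' A scenario without a reconciliation map
#'
#' Only the trees, the coloring and the two time maps; sufficient to
#' define the LDT graph.  Leaf times must agree:
#' `tau_T(x) = tau_S(sigma(x))`.
#' @inheritParams relaxed_scenario
#' @export
mu_free_scenario <- function(gene_tree, species_tree, sigma, tau_T, tau_S) {
  structure(list(T = gene_tree, S = species_tree, sigma = sigma,
                 tau_T = tau_T, tau_S = tau_S),
            class = "mu_free_scenario")
}

# shared structural validity of the mu-free part; returns character vector
# of violated conditions
check_mu_free <- function(s) {
  bad <- character(0)
  if (!is_valid_time_map(s$T, s$tau_T)) bad <- c(bad, "tau_T")
  if (!is_valid_time_map(s$S, s$tau_S)) bad <- c(bad, "tau_S")
  leaves <- tree_leaves(s$T)
  if (!all(leaves %in% names(s$sigma)) ||
      !all(s$sigma[leaves] %in% tree_leaves(s$S)) ||
      !isTRUE(all(abs(s$tau_T[leaves] - s$tau_S[s$sigma[leaves]]) == 0)))
    bad <- c(bad, "leaf-times")
  bad
}

#' Validate a relaxed scenario
#'
#' Checks every condition of the definition (G0, G1, C1, C2, leaf-time
#' agreement, and validity of both time maps) and returns the list of
#' violated conditions; an empty character vector means the scenario is
#' valid.
#' @param s a `relaxed_scenario`
#' @return character vector naming the violated conditions
#' @export
validate_scenario <- function(s) {
  stopifnot(inherits(s, "relaxed_scenario"))
  bad <- check_mu_free(s)
  root_T <- s$T$root; root_S <- s$S$root
  leaves <- tree_leaves(s$T)
  for (u in tree_vertices(s$T)) {
    im <- s$mu[[u]]
    if (im$type == "vertex") {
      if ((im$id == root_S) != (u == root_T)) bad <- c(bad, "G0")
      if ((u %in% leaves) != (im$id %in% tree_leaves(s$S) &&
                              identical(unname(s$sigma[u]), im$id)))
        bad <- c(bad, "G1")
      if (!isTRUE(s$tau_T[[u]] == s$tau_S[[im$id]])) bad <- c(bad, "C1")
    } else {
      if (u == root_T) bad <- c(bad, "G0")
      if (u %in% leaves) bad <- c(bad, "G1")
      x <- s$S$parent[[im$id]]
      if (!(s$tau_S[[im$id]] < s$tau_T[[u]] && s$tau_T[[u]] < s$tau_S[[x]]))
        bad <- c(bad, "C2")
    }
  }
  unique(bad)
}

#' Later-divergence-time (LDT) graph of a scenario
#'
#' The graph on the genes with an edge `ab` whenever the two genes
#' diverged strictly later than their species:
#' `tau_T(lca_T(a, b)) < tau_S(lca_S(sigma(a), sigma(b)))`.
#' A `relaxed_scenario` is accepted and its `mu` ignored.  Times are
#' compared exactly (they are constructed, not measured).
#'
#' @param s a `mu_free_scenario` or `relaxed_scenario`
#' @return a `colored_graph` on the genes, with color universe `L(S)`
#' @export
ldt_graph <- function(s) {
  stopifnot(inherits(s, c("mu_free_scenario", "relaxed_scenario")))
  bad <- check_mu_free(s)
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = ", "))
  genes <- tree_leaves(s$T)
  mT <- lca_time_matrix(s$T, s$tau_T, genes)
  species <- tree_leaves(s$S)
  mS <- lca_time_matrix(s$S, s$tau_S, species)
  sig <- s$sigma[genes]
  A <- mT < mS[cbind(rep(sig, times = length(genes)),
                     rep(sig, each = length(genes)))]
  dim(A) <- dim(mT); dimnames(A) <- dimnames(mT)
  diag(A) <- FALSE
  colored_graph_from_adjacency(A, sig, M = species)
}

# ---- transfer edges and Fitch graphs -----------------------------------

# comparability of reconciliation images under the extended tree order:
# a vertex x and an edge e = (u, v) satisfy x < e iff x <= v and e < x iff
# u <= x; two edges e = (u, v), f = (a, b) satisfy e <= f iff v <= b.
# `paths` is a precomputed list of root paths for the species tree.
images_comparable <- function(im1, im2, paths) {
  b1 <- im1$id; b2 <- im2$id   # bottom endpoints (vertex itself or child)
  if (im1$type == "vertex" && im2$type == "edge") {
    u2 <- paths[[b2]][2L]               # upper endpoint of the edge
    # x < e iff x below-or-equal bottom(e); e < x iff top(e) below-or-equal x
    return(b2 %in% paths[[b1]] || b1 %in% paths[[u2]])
  }
  if (im1$type == "edge" && im2$type == "vertex")
    return(images_comparable(im2, im1, paths))
  # vertex/vertex or edge/edge both reduce to comparability of the bottoms
  b1 %in% paths[[b2]] || b2 %in% paths[[b1]]
}

#' Transfer-edge labeling of a relaxed scenario
#'
#' An edge `(u, v)` of the gene tree is a transfer edge iff the
#' reconciliation images `mu(u)` and `mu(v)` are incomparable in the
#' species tree.  Returns the gene tree together with the 0/1 edge
#' labeling (edges identified by their child endpoint).
#'
#' @param s a valid `relaxed_scenario`
#' @return an object of class `edge_labeled_tree` (fields `tree`, `lambda`)
#' @export
transfer_labeling <- function(s) {
  bad <- validate_scenario(s)
  if (length(bad)) stop("invalid scenario: ", paste(bad, collapse = ", "))
  tr <- s$T
  paths <- lapply(stats::setNames(nm = tree_vertices(s$S)),
                  function(v) root_path(s$S, v))
  kids <- tree_vertices(tr)[!is.na(tr$parent)]
  lambda <- stats::setNames(integer(length(kids)), kids)
  for (v in kids) {
    u <- tr$parent[[v]]
    lambda[v] <- as.integer(!images_comparable(s$mu[[u]], s$mu[[v]], paths))
  }
  edge_labeled_tree(tr, lambda)
}

#' 0/1-edge-labeled trees
#' @param tree a `planted_tree`
#' @param lambda named 0/1 integer vector over the non-root vertices
#'   (edges identified by their child endpoint)
#' @export
edge_labeled_tree <- function(tree, lambda) {
  kids <- tree_vertices(tree)[!is.na(tree$parent)]
  if (!all(kids %in% names(lambda)) || !all(lambda %in% c(0L, 1L)))
    stop("'lambda' must assign 0/1 to every edge")
  structure(list(tree = tree, lambda = lambda[kids]), class = "edge_labeled_tree")
}

#' Fitch graph of a 0/1-edge-labeled tree
#'
#' Two leaves are adjacent iff the tree path between them contains at
#' least one 1-edge.  Equivalently, the maximal independent sets are the
#' classes of leaves connected by all-0 paths, and the graph is the
#' complete multipartite graph on those classes.
#'
#' @param elt an `edge_labeled_tree`
#' @return logical adjacency matrix on the leaves
#' @export
fitch_graph <- function(elt) {
  stopifnot(inherits(elt, "edge_labeled_tree"))
  tr <- elt$tree
  verts <- tree_vertices(tr)
  # union-find over 0-edges
  rep_of <- stats::setNames(nm = verts)
  find <- function(v) {
    while (rep_of[[v]] != v) v <- rep_of[[v]]
    v
  }
  for (v in names(elt$lambda)) {
    if (elt$lambda[[v]] == 0L) {
      a <- find(v); b <- find(tr$parent[[v]])
      if (a != b) rep_of[a] <- b
    }
  }
  leaves <- tree_leaves(tr)
  cls <- vapply(leaves, find, character(1))
  A <- outer(cls, cls, `!=`)
  dimnames(A) <- list(leaves, leaves)
  A
}

#' rs-Fitch graph of a relaxed scenario
#'
#' The Fitch graph of the scenario's transfer labeling, colored by
#' `sigma`; its edges are exactly the gene pairs separated by at least one
#' horizontal transfer.  The color universe is `L(S)`.
#' @param s a valid `relaxed_scenario`
#' @return a `colored_graph`
#' @export
rs_fitch_graph <- function(s) {
  A <- fitch_graph(transfer_labeling(s))
  genes <- rownames(A)
  colored_graph_from_adjacency(A, s$sigma[genes], M = tree_leaves(s$S))
}

# ---- JSON bundle I/O ---------------------------------------------------

#' Read / write relaxed scenarios as JSON bundles
#'
#' The bundle stores both trees as annotated Newick strings, plus the
#' coloring, the reconciliation map (vertex images `"V:<id>"`, edge images
#' `"E:<child id>"`), and both time maps.  Loaders validate on read.
#'
#' @param s a `relaxed_scenario`
#' @param file path
#' @export
write_scenario <- function(s, file) {
  mu_chr <- vapply(s$mu, function(im)
    paste0(if (im$type == "vertex") "V:" else "E:", im$id), character(1))
  obj <- list(gene_tree = write_newick(s$T),
              species_tree = write_newick(s$S),
              sigma = as.list(s$sigma),
              mu = as.list(mu_chr),
              tau_T = as.list(s$tau_T),
              tau_S = as.list(s$tau_S))
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(s)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(file) {
  obj <- jsonlite::read_json(file)
  tr <- read_newick(obj$gene_tree)$tree
  sp <- read_newick(obj$species_tree)$tree
  mu <- lapply(obj$mu, function(x) {
    typ <- sub(":.*", "", x)
    list(type = if (typ == "V") "vertex" else "edge", id = sub("^[^:]*:", "", x))
  })
  s <- relaxed_scenario(tr, sp,
                        sigma = unlist(obj$sigma),
                        mu = mu,
                        tau_T = unlist(obj$tau_T),
                        tau_S = unlist(obj$tau_S))
  bad <- validate_scenario(s)
  if (length(bad))
    stop("scenario file violates: ", paste(bad, collapse = ", "))
  s
}
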