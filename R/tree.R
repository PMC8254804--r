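#' Planted phylogenetic trees
#'
#' A planted tree is a rooted phylogenetic tree whose root (the "planted
#' root") has exactly one child; the planted edge represents the ancestral
#' lineage before the first branching.  Vertices are identified by stable
#' character ids; leaf ids double as display labels unless a `labels`
#' attribute is supplied.  Every inner vertex other than the planted root
#' has at least two children (the tree is phylogenetic).
#'
#' @param parent named character vector mapping each vertex id to its
#'   parent id; the planted root has `NA_character_`.
#' @param labels optional named character vector of display labels for
#'   leaves (defaults to the leaf ids).
#' @return an object of class `planted_tree` with fields `parent`,
#'   `children`, `root` (the planted root id), and `leaves`.
#' @examples
#' tr <- planted_tree(c(rho = "0", a = "rho", b = "rho", "0" = NA))
#' tree_leaves(tr)
#' @export
planted_tree <- function(parent, labels = NULL) {
  if (is.null(names(parent)) || anyDuplicated(names(parent)))
    stop("'parent' must be uniquely named by vertex id")
  parent <- vapply(parent, as.character, character(1))
  verts <- names(parent)
  bad <- !is.na(parent) & !(parent %in% verts)
  if (any(bad)) stop("unknown parent id(s): ", paste(parent[bad], collapse = ", "))
  root <- verts[is.na(parent)]
  if (length(root) != 1L)
    stop("exactly one vertex (the planted root) must have no parent")
  children <- split(verts[!is.na(parent)], factor(parent[!is.na(parent)], levels = verts))
  nkids <- lengths(children)
  leaves <- verts[nkids == 0L]
  if (root %in% leaves) stop("the planted root cannot be a leaf")
  if (nkids[[root]] != 1L)
    stop("the planted root must have exactly one child")
  inner <- setdiff(verts[nkids > 0L], root)
  if (any(nkids[inner] < 2L))
    stop("inner vertices other than the planted root need >= 2 children (tree is not phylogenetic)")
  # acyclicity / connectivity: walk each vertex to the root
  depth <- rep(NA_integer_, length(verts)); names(depth) <- verts
  depth[root] <- 0L
  for (v in verts) {
    chain <- character(0); u <- v
    while (is.na(depth[u])) {
      chain <- c(chain, u)
      u <- parent[[u]]
      if (u %in% chain) stop("parent map contains a cycle")
    }
    if (length(chain))
      depth[chain] <- depth[u] + seq.int(length(chain), 1L)
  }
  if (is.null(labels)) labels <- stats::setNames(leaves, leaves)
  structure(list(parent = parent, children = children, root = root,
                 leaves = leaves, depth = depth, labels = labels),
            class = "planted_tree")
}

#' @export
print.planted_tree <- function(x, ...) {
  cat("planted tree: ", length(x$leaves), " leaves, ",
      length(x$parent), " vertices (planted root '", x$root, "')\n", sep = "")
  invisible(x)
}

#' @rdname planted_tree
#' @param tree a `planted_tree`
#' @export
tree_vertices <- function(tree) names(tree$parent)

#' @rdname planted_tree
#' @export
tree_leaves <- function(tree) tree$leaves

#' Inner vertices of a planted tree (excluding leaves and the planted root)
#' @param tree a `planted_tree`
#' @export
tree_inner <- function(tree)
  setdiff(tree_vertices(tree), c(tree$leaves, tree$root))

#' Children of a vertex
#' @param tree a `planted_tree`
#' @param v vertex id
#' @export
tree_children <- function(tree, v) {
  ch <- tree$children[[v]]
  if (is.null(ch)) character(0) else ch
}

#' Vertices in postorder (children before parents)
#' @param tree a `planted_tree`
#' @export
postorder <- function(tree) {
  ord <- names(sort(tree$depth, decreasing = TRUE))
  ord
}

#' Path from a vertex up to the planted root (inclusive)
#' @param tree a `planted_tree`
#' @param v vertex id
#' @export
root_path <- function(tree, v) {
  stopifnot(v %in% tree_vertices(tree))
  path <- v
  while (!is.na(tree$parent[[v]])) {
    v <- tree$parent[[v]]
    path <- c(path, v)
  }
  path
}

#' Ancestor test in the tree order
#'
#' `is_ancestor(tree, x, y)` is `TRUE` iff `x` lies on the path from `y` to
#' the root, i.e. y precedes x or y == x (y \eqn{\preceq} x).
#' @param tree a `planted_tree`
#' @param x,y vertex ids; tests whether `y` \eqn{\preceq_T} `x`
#' @export
is_ancestor <- function(tree, x, y) x %in% root_path(tree, y)

#' Last common ancestor of a set of vertices
#'
#' Returns the unique minimal vertex (w.r.t. the tree order) that is an
#' ancestor of every vertex in `W`.
#' @param tree a `planted_tree`
#' @param W non-empty character vector of vertex ids
#' @export
lca <- function(tree, W) {
  W <- unique(as.character(W))
  if (length(W) == 0L) stop("'W' must be non-empty")
  if (!all(W %in% tree_vertices(tree)))
    stop("unknown vertex id(s): ", paste(setdiff(W, tree_vertices(tree)), collapse = ", "))
  common <- root_path(tree, W[1L])
  for (w in W[-1L]) {
    if (length(common) == 1L) break
    common <- common[common %in% root_path(tree, w)]
  }
  common[1L]
}

#' Pairwise lca vertex times for a set of leaves
#'
#' Returns the symmetric matrix `m` with `m[a, b] = tau[lca(a, b)]` for all
#' leaf pairs, computed in one postorder sweep (used to evaluate the
#' later-divergence-time condition for all gene pairs at once).
#' @param tree a `planted_tree`
#' @param tau named numeric time map over the tree's vertices
#' @param leaves leaf subset (default all leaves)
#' @return numeric matrix with dimnames `leaves` x `leaves`
#' @export
lca_time_matrix <- function(tree, tau, leaves = tree_leaves(tree)) {
  n <- length(leaves)
  m <- matrix(NA_real_, n, n, dimnames = list(leaves, leaves))
  diag(m) <- tau[leaves]
  below <- stats::setNames(vector("list", length(tree$parent)), names(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree_children(tree, v)
    if (length(ch) == 0L) {
      below[[v]] <- if (v %in% leaves) v else character(0)
    } else {
      sets <- below[ch]
      acc <- character(0)
      for (s in sets) {
        if (length(s) && length(acc)) m[acc, s] <- m[s, acc] <- tau[[v]]
        acc <- c(acc, s)
      }
      below[[v]] <- acc
    }
  }
  m
}

#' Restriction of a planted tree to a subset of leaves
#'
#' The minimal subtree spanning `Lp`, with all suppressed degree-two
#' vertices removed, rooted at `lca(Lp)` and re-planted above it.
#' @param tree a `planted_tree`
#' @param Lp non-empty subset of `tree_leaves(tree)`
#' @export
restrict_tree <- function(tree, Lp) {
  Lp <- unique(as.character(Lp))
  if (length(Lp) == 0L || !all(Lp %in% tree_leaves(tree)))
    stop("'Lp' must be a non-empty subset of the leaves")
  r <- lca(tree, Lp)
  keep <- unique(unlist(lapply(Lp, function(x) {
    p <- root_path(tree, x)
    p[seq_len(which(p == r))]
  })))
  par <- tree$parent[keep]
  par[r] <- NA_character_
  # suppress degree-two vertices (single child, not r, not leaf)
  repeat {
    kids <- table(factor(par[!is.na(par)], levels = names(par)))
    unary <- names(par)[kids == 1L & names(par) != r & !(names(par) %in% Lp)]
    if (length(unary) == 0L) break
    u <- unary[1L]
    child <- names(par)[!is.na(par) & par == u]
    par[child] <- par[u]
    if (is.na(par[u])) par[child] <- NA_character_  # u was r; cannot happen
    par <- par[names(par) != u]
  }
  # re-plant: planted root above r (reuse the original planted root id)
  plant <- tree$root
  if (plant %in% names(par)) plant <- paste0(plant, "'")
  par[r] <- plant
  par[plant] <- NA_character_
  if (length(Lp) == 1L) {
    # degenerate: single leaf below the plant
    par <- par[names(par) %in% c(plant, Lp)]
    par[Lp] <- plant
  }
  planted_tree(par, labels = tree$labels[intersect(names(tree$labels), Lp)])
}

tree_clusters <- function(tree) {
  below <- stats::setNames(vector("list", length(tree$parent)), names(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree_children(tree, v)
    below[[v]] <- if (length(ch) == 0L) v else sort(unique(unlist(below[ch])))
  }
  unique(vapply(below, paste, character(1), collapse = "\r"))
}

#' Does a tree display another tree?
#'
#' `Tp` is displayed by `T` if it can be obtained from the restriction of
#' `T` to the leaves of `Tp` by contracting inner edges; equivalently, every
#' cluster (vertex leaf set) of `Tp` is a cluster of the restriction.
#' @param tree a `planted_tree`
#' @param tp a `planted_tree` with `L(tp)` a subset of `L(tree)`
#' @export
displays <- function(tree, tp) {
  if (!all(tree_leaves(tp) %in% tree_leaves(tree)))
    stop("leaves of 'tp' must be a subset of the leaves of 'tree'")
  restr <- restrict_tree(tree, tree_leaves(tp))
  all(tree_clusters(tp) %in% tree_clusters(restr))
}

#' Does a tree display the rooted triple ab|c?
#'
#' Direct test via `lca(a,b)` being a strict descendant of
#' `lca(a,c) = lca(b,c)`.
#' @param tree a `planted_tree`
#' @param a,b,c leaf ids
#' @export
displays_triple <- function(tree, a, b, c) {
  u <- lca(tree, c(a, b)); v <- lca(tree, c(a, b, c))
  u != v
}

#' Suppress all inner vertices with a single child
#'
#' Removes every inner vertex that has exactly one child (except the
#' planted root) and merges the incident edges; vertex ids of surviving
#' vertices are unchanged, so per-vertex attributes (times, reconciliation
#' images) can be carried over by subsetting.  The input may be
#' non-phylogenetic; the output satisfies the `planted_tree` invariants.
#' @param parent named parent vector (as in [planted_tree()]); a
#'   `planted_tree` is also accepted.
#' @export
suppress_unary <- function(parent) {
  if (inherits(parent, "planted_tree")) parent <- parent$parent
  root <- names(parent)[is.na(parent)]
  repeat {
    kids <- table(factor(parent[!is.na(parent)], levels = names(parent)))
    unary <- names(parent)[kids == 1L & names(parent) != root]
    if (length(unary) == 0L) break
    u <- unary[1L]
    child <- names(parent)[!is.na(parent) & parent == u]
    parent[child] <- parent[u]
    parent <- parent[names(parent) != u]
  }
  planted_tree(parent)
}

#' Construct a time map from fixed leaf times
#'
#' Builds a time map (real-valued vertex times strictly increasing from
#' leaves towards the root) in one postorder pass: leaves keep their given
#' times and every inner vertex gets the maximum over its children plus
#' `min_gap`.  Only the ordering of the times is contractual.
#' @param tree a `planted_tree`
#' @param leaf_times named numeric vector covering all leaves
#' @param min_gap positive real increment used for inner vertices (default 1)
#' @return named numeric vector over all vertices
#' @export
assign_time_map <- function(tree, leaf_times, min_gap = 1) {
  if (!is.numeric(min_gap) || min_gap <= 0) stop("'min_gap' must be positive")
  if (!all(tree_leaves(tree) %in% names(leaf_times)))
    stop("'leaf_times' must cover all leaves")
  tau <- stats::setNames(rep(NA_real_, length(tree$parent)), names(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree_children(tree, v)
    tau[v] <- if (length(ch) == 0L) leaf_times[[v]] else max(tau[ch]) + min_gap
  }
  tau
}

#' Check the time-map invariant
#'
#' A valid time map assigns strictly smaller times to descendants; it
#' suffices to check every (parent, child) edge.
#' @param tree a `planted_tree`
#' @param tau named numeric vector over the tree's vertices
#' @export
is_valid_time_map <- function(tree, tau) {
  if (!all(tree_vertices(tree) %in% names(tau))) return(FALSE)
  for (v in tree_vertices(tree)) {
    p <- tree$parent[[v]]
    if (!is.na(p) && !(tau[[v]] < tau[[p]])) return(FALSE)
  }
  TRUE
}

#' Canonical form of a planted tree (for isomorphism tests)
#'
#' Sorted recursive leaf encoding; two trees on the same leaf set are
#' isomorphic as leaf-labelled trees iff their canonical forms agree.
#' Intended for small trees.
#' @param tree a `planted_tree`
#' @export
canonical_form <- function(tree) {
  enc <- function(v) {
    ch <- tree_children(tree, v)
    if (length(ch) == 0L) return(v)
    paste0("(", paste(sort(vapply(ch, enc, character(1))), collapse = ","), ")")
  }
  enc(tree$root)
}
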