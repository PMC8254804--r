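# leaf sets below every vertex, one postorder sweep
tree_leafsets <- function(tree) {
  below <- stats::setNames(vector("list", length(tree$parent)),
                           names(tree$parent))
  for (v in postorder(tree)) {
    ch <- tree_children(tree, v)
    below[[v]] <- if (length(ch) == 0L) v else sort(unlist(below[ch], use.names = FALSE))
  }
  below
}

#' Partition of a subtree's leaves by the children of its root
#'
#' For an inner vertex `u` of the species tree the blocks are the leaf
#' sets of the children of `u`; for a leaf the single block `{u}`.
#' @param S a `planted_tree`
#' @param u a vertex of `S` other than the planted root
#' @return named list of character vectors (named by child vertex where
#'   applicable)
#' @export
child_partition <- function(S, u) {
  if (!u %in% tree_vertices(S)) stop("unknown vertex '", u, "'")
  if (u == S$root) stop("'u' must not be the planted root")
  ch <- tree_children(S, u)
  if (length(ch) == 0L) return(stats::setNames(list(u), u))
  ls <- tree_leafsets(S)
  stats::setNames(ls[ch], ch)
}

#' Component-and-color-block refinement of a vertex set
#'
#' Two vertices are related iff they lie in the same connected component
#' of the graph and their colors belong to the same block of the color
#' partition `C`.  This is an equivalence relation; every class is
#' contained in a single connected component, so each connected component
#' is a disjoint union of classes.
#'
#' @param g a `colored_graph` (on the vertex subset of interest)
#' @param C partition of (a superset of) the observed colors, as a list of
#'   character vectors
#' @return list of equivalence classes (character vectors), ordered by
#'   smallest member
#' @export
relation_R <- function(g, C) {
  A <- as_adjacency(g)
  verts <- rownames(A)
  blk <- stats::setNames(rep(NA_integer_, 0), character(0))
  for (i in seq_along(C)) blk[C[[i]]] <- i
  if (!all(g$sigma[verts] %in% names(blk)))
    stop("colors ", paste(setdiff(g$sigma[verts], names(blk)), collapse = ", "),
         " not covered by the color partition")
  comps <- adj_components(A)
  cid <- stats::setNames(rep(NA_integer_, length(verts)), verts)
  for (i in seq_along(comps)) cid[comps[[i]]] <- i
  key <- paste(cid[verts], blk[g$sigma[verts]])
  classes <- split(verts, key)
  classes <- lapply(classes, sort)
  names(classes) <- NULL
  classes[order(vapply(classes, `[`, character(1), 1L))]
}

#' Recognize LDT graphs
#'
#' A vertex-colored graph is a later-divergence-time graph (i.e., arises
#' as the LDT graph of some relaxed scenario) iff it is (i) properly
#' colored, (ii) a cograph, and (iii) its species-triple set is
#' compatible.  On rejection a certificate names the violated condition:
#' a same-color edge, an induced P4, or the incompatible color subset.
#'
#' @param g a `colored_graph`
#' @return list with elements `ldt` (logical) and `certificate` (`NULL`
#'   when accepted, otherwise a list with a `type` field)
#' @export
is_ldt_graph <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  if (!is_properly_colored(g)) {
    e <- graph_edges(g)
    bad <- e[g$sigma[e[, 1L]] == g$sigma[e[, 2L]], , drop = FALSE][1L, ]
    return(list(ldt = FALSE,
                certificate = list(type = "same-color-edge", edge = bad)))
  }
  ct <- cotree(g)
  if (inherits(ct, "not_cograph"))
    return(list(ldt = FALSE,
                certificate = list(type = "induced-p4", p4 = ct$p4)))
  St <- species_triples(g)
  bt <- build_tree(St, attr(St, "labels"))
  if (inherits(bt, "incompatible_triples"))
    return(list(ldt = FALSE,
                certificate = list(type = "incompatible-triples",
                                   colors = bt$witness)))
  list(ldt = TRUE, certificate = NULL)
}

#' Construct a relaxed scenario explaining an LDT graph
#'
#' Given a recognized LDT graph, builds a relaxed scenario whose LDT
#' graph equals the input exactly.  The species tree defaults to the
#' (planted) BUILD tree of the species triples on the observed colors —
#' the least resolved admissible choice — but any planted tree on a
#' superset of the observed colors that displays the species triples may
#' be supplied.
#'
#' The gene tree is grown top-down: one 0-type vertex per recursion step
#' separating the connected components of the current induced subgraph
#' (placed just above the current species vertex), one 1-type vertex per
#' connected component (placed just below it), and one child per
#' component-and-color-block class, recursing into the species child that
#' contains the class's colors.  Times are allocated by bisecting the
#' available open interval so that the time-consistency constraints hold
#' by construction.  Single-child vertices are suppressed at the end and
#' the result is self-verified (validated, and its LDT graph compared
#' edge-by-edge with the input).
#'
#' @param g a `colored_graph` that passes [is_ldt_graph()]
#' @param species_tree optional `planted_tree` on (a superset of) the
#'   observed colors displaying [species_triples()] of `g`
#' @return a valid `relaxed_scenario` whose [ldt_graph()] equals `g`
#' @export
explain_ldt <- function(g, species_tree = NULL) {
  chk <- is_ldt_graph(g)
  if (!chk$ldt)
    stop("not an LDT graph (", chk$certificate$type, ")")
  St <- species_triples(g)
  obs <- sort(unique(unname(g$sigma)))
  if (is.null(species_tree)) {
    S <- build_tree(St, obs)     # compatible by the recognition check
  } else {
    S <- species_tree
    if (!all(obs %in% tree_leaves(S)))
      stop("'species_tree' must contain all observed colors as leaves")
    for (i in seq_len(nrow(St)))
      if (!displays_triple(S, St$a[i], St$b[i], St$c[i]))
        stop("'species_tree' does not display the species triple ",
             St$a[i], St$b[i], "|", St$c[i])
  }
  tau_S <- assign_time_map(S, stats::setNames(rep(0, length(tree_leaves(S))),
                                              tree_leaves(S)))
  A <- as_adjacency(g)
  sigma <- g$sigma
  Sleafsets <- tree_leafsets(S)
  Sleaves <- tree_leaves(S)

  env <- new.env()
  env$parent <- character(0)
  env$tau <- numeric(0)
  env$mu <- list()
  env$i <- 0L
  new_vertex <- function(prefix) {
    env$i <- env$i + 1L
    paste0(".", prefix, env$i)
  }

  build <- function(Lp, uS, hi) {
    tS <- tau_S[[uS]]
    if (uS %in% Sleaves) {
      # base case: all genes reside in species uS; a star suffices (no
      # LDT edges are possible or wanted among equal colors)
      w <- new_vertex("u")
      env$tau[w] <- (tS + hi) / 2
      env$mu[[w]] <- mu_edge(uS)
      for (x in Lp) {
        env$parent[x] <- w
        env$tau[x] <- tS
        env$mu[[x]] <- mu_vertex(uS)
      }
      return(w)
    }
    uT <- new_vertex("u")
    env$tau[uT] <- (tS + hi) / 2   # above uS: separates the components
    env$mu[[uT]] <- mu_edge(uS)
    blocks <- child_partition(S, uS)
    child_of_color <- stats::setNames(rep(names(blocks), lengths(blocks)),
                                      unlist(blocks, use.names = FALSE))
    sub <- induced_subgraph(g, Lp)
    classes_all <- relation_R(sub, blocks)
    comps <- adj_components(A[Lp, Lp, drop = FALSE])
    for (C in comps) {
      vT <- new_vertex("v")
      env$parent[vT] <- uT
      classes <- classes_all[vapply(classes_all, function(K) K[1L] %in% C,
                                    logical(1))]
      vS_of <- vapply(classes, function(K) child_of_color[[sigma[[K[1L]]]]],
                      character(1))
      t_v <- (max(tau_S[vS_of]) + tS) / 2   # below uS, above every target child
      env$tau[vT] <- t_v
      env$mu[[vT]] <- mu_edge(vS_of[[1L]])
      for (k in seq_along(classes)) {
        wK <- build(classes[[k]], vS_of[[k]], t_v)
        env$parent[wK] <- vT
      }
    }
    uT
  }

  rho_S <- tree_children(S, S$root)
  top <- build(sort(rownames(A)), rho_S, tau_S[[S$root]])
  root0 <- ".0T"
  env$parent[top] <- root0
  env$parent[root0] <- NA_character_
  env$tau[root0] <- tau_S[[S$root]]
  env$mu[[root0]] <- mu_vertex(S$root)

  gene_tree <- suppress_unary(env$parent)
  keep <- tree_vertices(gene_tree)
  s <- relaxed_scenario(gene_tree, S, sigma = sigma,
                        mu = env$mu[keep],
                        tau_T = env$tau[keep], tau_S = tau_S)
  bad <- validate_scenario(s)
  if (length(bad))
    stop("internal error: constructed scenario violates ",
         paste(bad, collapse = ", "))
  got <- ldt_graph(s)
  if (!identical(got$A[rownames(A), colnames(A), drop = FALSE], A))
    stop("internal error: constructed scenario does not explain the input graph")
  s
}
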