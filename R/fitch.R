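#' Color auxiliary graph of an independent-set family
#'
#' The graph on the color universe `M` with an edge between two distinct
#' colors whenever both appear inside a common set of the family.  Used to
#' characterize which complete multipartite colorings are realizable by a
#' relaxed scenario.
#'
#' @param sigma named character coloring
#' @param I list of vertex sets (subsets of `names(sigma)`)
#' @param M color universe (vertex set of the result; may contain colors
#'   unused by `I`)
#' @return logical adjacency matrix on `M`
#' @export
fitch_aux_graph <- function(sigma, I, M) {
  M <- as.character(M)
  A <- matrix(FALSE, length(M), length(M), dimnames = list(M, M))
  for (Ip in I) {
    if (!all(Ip %in% names(sigma))) stop("sets in 'I' must be colored vertices")
    cols <- unique(unname(sigma[Ip]))
    if (length(cols) > 1L) {
      A[cols, cols] <- TRUE
    }
  }
  diag(A) <- FALSE
  A
}

#' Recognize rs-Fitch graphs
#'
#' A vertex-colored graph can arise as the Fitch graph of a relaxed
#' scenario iff (i) it is complete multipartite with maximal independent
#' sets `I_1, ..., I_k`, and (ii) for `k > 1` some `I'` can be removed so
#' that the color auxiliary graph of the remaining sets, taken over the
#' stored color universe `M`, is disconnected.  The color universe is the
#' graph's stored `M` — it is never silently shrunk to the observed
#' colors, because additional (unsampled) species can make an otherwise
#' unrealizable coloring realizable.
#'
#' @param g a `colored_graph`
#' @return list with `rs_fitch` (logical) and `witness` (the removable
#'   part on acceptance with `k > 1`; the failure certificate otherwise)
#' @export
is_rs_fitch <- function(g) {
  stopifnot(inherits(g, "colored_graph"))
  parts <- complete_multipartite_parts(g)
  if (inherits(parts, "not_multipartite"))
    return(list(rs_fitch = FALSE,
                witness = list(type = "not-multipartite", k2k1 = parts$witness)))
  if (length(parts) <= 1L)
    return(list(rs_fitch = TRUE, witness = NULL))
  for (i in seq_along(parts)) {
    aux <- fitch_aux_graph(g$sigma, parts[-i], g$M)
    if (length(adj_components(aux)) > 1L)
      return(list(rs_fitch = TRUE,
                  witness = list(type = "removable-part", part = parts[[i]])))
  }
  list(rs_fitch = FALSE,
       witness = list(type = "no-disconnecting-part", parts = parts))
}

# greedy maximum-clique partition of a cograph, via its cotree: at a union
# vertex concatenate the children's ordered clique lists; at a join vertex
# pair the i-th largest cliques of the children.  Optimal for cluster
# deletion on cographs; ties broken by smallest vertex label for
# reproducibility.
clique_partition_cograph <- function(ct) {
  order_cliques <- function(cl)
    cl[order(-lengths(cl), vapply(cl, `[`, character(1), 1L))]
  kids_of <- function(v) names(ct$parent)[!is.na(ct$parent) & ct$parent == v]
  rec <- function(v) {
    ch <- kids_of(v)
    if (!length(ch)) return(list(v))
    lists <- lapply(sort(ch), rec)
    if (identical(ct$label[[v]], 1L)) {
      out <- lists[[1L]]
      for (l in lists[-1L]) {
        m <- max(length(out), length(l))
        out <- lapply(seq_len(m), function(i) {
          sort(c(if (i <= length(out)) out[[i]],
                 if (i <= length(l)) l[[i]]))
        })
        out <- order_cliques(out)
      }
      out
    } else {
      order_cliques(do.call(c, lists))
    }
  }
  rec(ct$root)
}

#' Minimum edge completion of a cograph to a complete multipartite graph
#'
#' Finds a minimum-cardinality edge set `Q` such that adding `Q` makes
#' the graph complete multipartite.  Solved exactly as cluster deletion on
#' the complement cograph: the greedy maximum-clique-peeling recursion on
#' the complement's cotree yields an optimal clique partition; the
#' returned parts are those cliques (independent sets of the input), and
#' `Q` consists of all non-edges between different parts.  The part-size
#' sequence is invariant across optimal solutions.
#'
#' @param g a cograph (`colored_graph` or logical adjacency matrix)
#' @return list with `Q` (two-column character matrix of inserted edges)
#'   and `parts` (list of independent sets of the completed graph)
#' @export
complete_to_multipartite <- function(g) {
  A <- as_adjacency(g)
  comp <- !A; diag(comp) <- FALSE
  ct <- cotree(comp)
  if (inherits(ct, "not_cograph"))
    stop("input is not a cograph (induced P4: ",
         paste(ct$p4, collapse = " - "), ")")
  parts <- clique_partition_cograph(ct)
  pid <- stats::setNames(rep(seq_along(parts), lengths(parts)),
                         unlist(parts, use.names = FALSE))
  verts <- rownames(A)
  cross <- outer(pid[verts], pid[verts], `!=`)
  add <- cross & !A & upper.tri(A)
  idx <- which(add, arr.ind = TRUE)
  list(Q = cbind(verts[idx[, 1L]], verts[idx[, 2L]]), parts = parts)
}

#' Estimate the full transfer (Fitch) graph from an LDT graph
#'
#' An LDT graph is always a spanning subgraph of the Fitch graph of any
#' explaining scenario, so estimating the complete xenology relation is
#' an edge-completion problem.  Two estimators are provided:
#'
#' * `method = "completion"`: minimum edge completion to a complete
#'   multipartite graph ([complete_to_multipartite()]).  The result is
#'   not guaranteed to be an rs-Fitch graph; the diagnostics report the
#'   [is_rs_fitch()] verdict under the observed color universe
#'   `sigma(L)` (or a supplied larger one).
#' * `method = "scenario"`: the Fitch graph of the relaxed scenario
#'   constructed by [explain_ldt()]; by construction an rs-Fitch graph
#'   sharing a scenario with the input, with at least as many edges as
#'   any minimum completion.
#'
#' @param g a `colored_graph` passing [is_ldt_graph()]
#' @param method `"completion"` or `"scenario"`
#' @param color_universe color universe for the rs-Fitch diagnostic
#'   (default: the observed colors)
#' @return list with `graph` (the completed `colored_graph`), `rs_fitch`
#'   (diagnostic verdict), `method`, and for `"completion"` the inserted
#'   edge set `Q`, for `"scenario"` the constructed `scenario`
#' @export
fitch_from_ldt <- function(g, method = c("completion", "scenario"),
                           color_universe = NULL) {
  method <- match.arg(method)
  chk <- is_ldt_graph(g)
  if (!chk$ldt) stop("not an LDT graph (", chk$certificate$type, ")")
  if (is.null(color_universe)) color_universe <- sort(unique(unname(g$sigma)))
  if (method == "completion") {
    cm <- complete_to_multipartite(g)
    A <- as_adjacency(g)
    if (nrow(cm$Q)) {
      A[cm$Q] <- TRUE
      A[cm$Q[, c(2L, 1L), drop = FALSE]] <- TRUE
    }
    out <- colored_graph_from_adjacency(A, g$sigma, M = color_universe)
    list(graph = out, rs_fitch = is_rs_fitch(out)$rs_fitch,
         method = method, Q = cm$Q)
  } else {
    s <- explain_ldt(g)
    fg <- rs_fitch_graph(s)
    fg <- colored_graph_from_adjacency(fg$A, fg$sigma,
                                       M = sort(union(color_universe,
                                                      unique(unname(fg$sigma)))))
    list(graph = fg, rs_fitch = TRUE, method = method, scenario = s)
  }
}
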