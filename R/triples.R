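#' Rooted triple sets
#'
#' A rooted triple `ab|c` is a three-leaf tree stating that `a` and `b`
#' diverged from each other after either diverged from `c`.  A triple set
#' is stored as a data frame with columns `a`, `b`, `c` (with `a < b`
#' canonically so that `ab|c` and `ba|c` coincide) and an attribute
#' `labels` holding the label universe.
#'
#' @param a,b,c character vectors of equal length (recycled)
#' @param labels optional label universe; defaults to the labels that occur
#' @export
triple_set <- function(a = character(0), b = character(0), c = character(0),
                       labels = NULL) {
  df <- data.frame(a = as.character(a), b = as.character(b),
                   c = as.character(c), stringsAsFactors = FALSE)
  if (nrow(df)) {
    if (any(df$a == df$b | df$a == df$c | df$b == df$c))
      stop("triple labels must be pairwise distinct")
    sw <- df$a > df$b
    tmp <- df$a[sw]; df$a[sw] <- df$b[sw]; df$b[sw] <- tmp
    df <- unique(df)
    rownames(df) <- NULL
  }
  if (is.null(labels)) labels <- sort(unique(unlist(df)))
  structure(df, labels = labels, class = c("triple_set", "data.frame"))
}

#' @export
print.triple_set <- function(x, ...) {
  cat("triple set:", nrow(x), "triples on",
      length(attr(x, "labels")), "labels\n")
  if (nrow(x)) cat(paste0("  ", x$a, " ", x$b, " | ", x$c, collapse = "\n"), "\n")
  invisible(x)
}

#' Serialize / read triples as plain text (`a b | c` per line)
#' @param R a `triple_set`
#' @param file path
#' @export
write_triples <- function(R, file) {
  writeLines(if (nrow(R)) paste(R$a, R$b, "|", R$c) else character(0), file)
}

#' @rdname write_triples
#' @export
read_triples <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(triple_set())
  parts <- strsplit(lines, "\\s*\\|\\s*")
  ab <- strsplit(trimws(vapply(parts, `[`, character(1), 1L)), "\\s+")
  triple_set(vapply(ab, `[`, character(1), 1L),
             vapply(ab, `[`, character(1), 2L),
             trimws(vapply(parts, `[`, character(1), 2L)))
}

#' Aho graph of a triple set
#'
#' The auxiliary graph on the label set `L` with an edge `xy` whenever some
#' triple `xy|z` with all three labels inside `L` is in `R`.  Triples with
#' any label outside `L` are ignored (standard BUILD semantics).
#'
#' @param R a `triple_set`
#' @param L character label set
#' @return logical adjacency matrix with dimnames `L` x `L`
#' @export
aho_graph <- function(R, L) {
  L <- as.character(L)
  A <- matrix(FALSE, length(L), length(L), dimnames = list(L, L))
  if (nrow(R)) {
    keep <- R$a %in% L & R$b %in% L & R$c %in% L
    if (any(keep)) {
      A[cbind(R$a[keep], R$b[keep])] <- TRUE
      A[cbind(R$b[keep], R$a[keep])] <- TRUE
    }
  }
  A
}

# connected components of a logical adjacency matrix; returns a list of
# vertex-id character vectors, ordered by smallest member
adj_components <- function(A) {
  verts <- rownames(A)
  if (length(verts) == 0L) return(list())
  seen <- stats::setNames(rep(FALSE, length(verts)), verts)
  comps <- list()
  for (v in verts) {
    if (seen[v]) next
    comp <- v; seen[v] <- TRUE; frontier <- v
    while (length(frontier)) {
      nb <- verts[rowSums(A[, frontier, drop = FALSE]) > 0]
      nb <- nb[!seen[nb]]
      seen[nb] <- TRUE
      comp <- c(comp, nb)
      frontier <- nb
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, `[`, character(1), 1L))]
}

#' BUILD: construct a tree displaying a set of rooted triples
#'
#' Top-down recursion on the connected components of the Aho graph.  If
#' `R` is compatible with a tree on `L`, the (planted) Aho tree is
#' returned; it displays every triple of `R`.  Otherwise an object of
#' class `incompatible_triples` is returned, carrying the connected label
#' subset that witnesses incompatibility.
#'
#' Children are attached in sorted label order, so the output is
#' reproducible.
#'
#' @param R a `triple_set`
#' @param L label set, a superset of the labels occurring in `R`
#' @return a `planted_tree` on `L`, or an `incompatible_triples` object
#' @export
build_tree <- function(R, L) {
  L <- sort(as.character(L))
  if (!all(unlist(R[c("a", "b", "c")]) %in% L))
    stop("'L' must contain all labels of 'R'")
  counter <- new.env(); counter$i <- 0L
  parent <- character(0)
  bad <- NULL
  rec <- function(Ls) {
    if (length(Ls) == 1L) return(Ls)
    comps <- adj_components(aho_graph(R, Ls))
    if (length(comps) == 1L) { bad <<- Ls; return(NULL) }
    counter$i <- counter$i + 1L
    v <- paste0("i", counter$i)
    for (comp in comps) {
      child <- rec(comp)
      if (is.null(child)) return(NULL)
      parent[child] <<- v
    }
    v
  }
  rho <- rec(L)
  if (is.null(rho))
    return(structure(list(witness = bad), class = "incompatible_triples"))
  plant <- if ("0" %in% L) "planted_root" else "0"
  parent[rho] <- plant
  parent[plant] <- NA_character_
  planted_tree(parent)
}

#' @export
print.incompatible_triples <- function(x, ...) {
  cat("incompatible triple set; connected Aho graph on {",
      paste(x$witness, collapse = ", "), "}\n")
  invisible(x)
}

#' Is a triple set compatible?
#' @param R a `triple_set`
#' @param L optional label set (defaults to the labels of `R`)
#' @export
triples_compatible <- function(R, L = attr(R, "labels")) {
  if (length(L) == 0L) return(TRUE)
  !inherits(build_tree(R, L), "incompatible_triples")
}

#' Gene triples of a graph
#'
#' All rooted triples `xy|z` over pairwise distinct vertices with `xy` an
#' edge and `xz`, `yz` non-edges.  Every tree of a scenario explaining an
#' LDT graph must display these triples.
#'
#' @param g a `colored_graph` or a logical adjacency matrix
#' @return a `triple_set` on the vertex set
#' @export
gene_triples <- function(g) {
  A <- as_adjacency(g)
  verts <- rownames(A)
  out_a <- character(0); out_b <- character(0); out_c <- character(0)
  for (z in verts) {
    nn <- verts[!A[, z] & verts != z]
    if (length(nn) < 2L) next
    sub <- A[nn, nn, drop = FALSE]
    idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (nrow(idx)) {
      out_a <- c(out_a, nn[idx[, 1L]])
      out_b <- c(out_b, nn[idx[, 2L]])
      out_c <- c(out_c, rep(z, nrow(idx)))
    }
  }
  triple_set(out_a, out_b, out_c, labels = verts)
}

#' Species triples of a colored graph
#'
#' All color triples `AB|C` with pairwise distinct colors `A = sigma(x)`,
#' `B = sigma(y)`, `C = sigma(z)` such that `xz` and `yz` are edges but
#' `xy` is not.  The species tree of every scenario explaining an LDT
#' graph must display these triples.
#'
#' @param g a `colored_graph`
#' @return a `triple_set` on the observed colors
#' @export
species_triples <- function(g) {
  A <- as_adjacency(g)
  sigma <- g$sigma
  verts <- rownames(A)
  out_a <- character(0); out_b <- character(0); out_c <- character(0)
  for (z in verts) {
    nb <- verts[A[, z]]
    if (length(nb) < 2L) next
    sub <- !A[nb, nb, drop = FALSE]
    idx <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (nrow(idx)) {
      cx <- sigma[nb[idx[, 1L]]]; cy <- sigma[nb[idx[, 2L]]]; cz <- sigma[[z]]
      keep <- cx != cy & cx != cz & cy != cz
      out_a <- c(out_a, cx[keep]); out_b <- c(out_b, cy[keep])
      out_c <- c(out_c, rep(cz, sum(keep)))
    }
  }
  triple_set(out_a, out_b, out_c, labels = sort(unique(unname(sigma))))
}
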