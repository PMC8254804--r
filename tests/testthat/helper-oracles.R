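# fixtures and independent brute-force oracles used across the suite

# random planted phylogenetic tree on n leaves (binary splitting, then
# optional random inner-edge contractions)
random_tree <- function(n, labels = paste0("l", seq_len(n)), contract = 0) {
  parent <- character(0)
  tips <- "r"
  k <- 0L
  while (length(tips) < n) {
    k <- k + 1L
    v <- sample(tips, 1L)
    c1 <- paste0("x", k, "a"); c2 <- paste0("x", k, "b")
    parent[c1] <- v; parent[c2] <- v
    tips <- c(setdiff(tips, v), c1, c2)
  }
  ren <- stats::setNames(labels, tips)
  names(parent) <- ifelse(names(parent) %in% tips, ren[names(parent)], names(parent))
  if (contract > 0) {
    inner <- setdiff(unique(parent), c(labels, "r"))
    for (v in inner) if (stats::runif(1) < contract) {
      kids <- names(parent)[parent == v]
      parent[kids] <- parent[[v]]
      parent <- parent[names(parent) != v]
    }
  }
  parent["r"] <- "plant"
  parent["plant"] <- NA_character_
  planted_tree(parent)
}

# lca by intersecting full ancestor sets (definition-level oracle)
brute_lca <- function(tree, W) {
  paths <- lapply(W, function(w) root_path(tree, w))
  common <- Reduce(intersect, paths)
  depths <- vapply(common, function(v) length(root_path(tree, v)), integer(1))
  common[which.max(depths)]
}

# displays via exhaustive enumeration of inner-edge contraction subsets of
# the restriction (small trees only)
brute_displays <- function(tree, tp) {
  restr <- restrict_tree(tree, tree_leaves(tp))
  target <- canonical_form(tp)
  inner_edges <- Filter(function(v) {
    p <- restr$parent[[v]]
    !is.na(p) && !(v %in% tree_leaves(restr)) && p != restr$root
  }, tree_vertices(restr))
  subsets <- list(character(0))
  for (e in inner_edges) subsets <- c(subsets, lapply(subsets, c, e))
  for (sub in subsets) {
    par <- restr$parent
    for (v in sub) {                 # contract edge (parent(v), v)
      kids <- names(par)[!is.na(par) & par == v]
      par[kids] <- par[[v]]
      par <- par[names(par) != v]
    }
    cand <- planted_tree(par)
    if (canonical_form(cand) == target) return(TRUE)
  }
  FALSE
}

# all rooted phylogenetic trees on a small label set, as planted_tree
# objects (recursive enumeration over set partitions of the root children)
all_rooted_trees <- function(labels) {
  set_partitions <- function(x) {
    if (length(x) == 1L) return(list(list(x)))
    out <- list()
    rest <- set_partitions(x[-1L])
    for (p in rest) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(x[1L], q[[i]])
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(list(x[1L]), p)
    }
    out
  }
  counter <- new.env(); counter$i <- 0L
  rec <- function(lbls) {
    # returns list of parent-maps, each with the subtree root as attr
    if (length(lbls) == 1L)
      return(list(structure(stats::setNames(character(0), character(0)),
                            root = lbls)))
    out <- list()
    for (p in set_partitions(lbls)) {
      if (length(p) < 2L) next
      blocks <- lapply(p, rec)
      combos <- expand.grid(lapply(blocks, seq_along))
      for (r in seq_len(nrow(combos))) {
        counter$i <- counter$i + 1L
        v <- paste0("n", counter$i)
        par <- stats::setNames(character(0), character(0))
        for (bi in seq_along(blocks)) {
          sub <- blocks[[bi]][[combos[r, bi]]]
          par[names(sub)] <- sub
          par[attr(sub, "root")] <- v
        }
        out[[length(out) + 1L]] <- structure(par, root = v)
      }
    }
    out
  }
  lapply(rec(labels), function(par) {
    par[attr(par, "root")] <- "plant"
    par["plant"] <- NA_character_
    planted_tree(par)
  })
}

# triple-set compatibility by exhaustive search over all trees on L
brute_compatible <- function(R, L) {
  for (tr in all_rooted_trees(L)) {
    ok <- TRUE
    for (i in seq_len(nrow(R)))
      if (!displays_triple(tr, R$a[i], R$b[i], R$c[i])) { ok <- FALSE; break }
    if (ok) return(TRUE)
  }
  FALSE
}

# gene/species triples by definitional cubic scans
brute_gene_triples <- function(A) {
  verts <- rownames(A)
  out <- data.frame(a = character(0), b = character(0), c = character(0))
  for (x in verts) for (y in verts) for (z in verts) {
    if (x >= y || z == x || z == y) next
    if (A[x, y] && !A[x, z] && !A[y, z])
      out <- rbind(out, data.frame(a = x, b = y, c = z))
  }
  triple_set(out$a, out$b, out$c, labels = verts)
}

brute_species_triples <- function(A, sigma) {
  verts <- rownames(A)
  out <- data.frame(a = character(0), b = character(0), c = character(0))
  for (x in verts) for (y in verts) for (z in verts) {
    if (x >= y || z == x || z == y) next
    cx <- sigma[[x]]; cy <- sigma[[y]]; cz <- sigma[[z]]
    if (cx == cy || cx == cz || cy == cz) next
    if (A[x, z] && A[y, z] && !A[x, y])
      out <- rbind(out, data.frame(a = cx, b = cy, c = cz))
  }
  triple_set(out$a, out$b, out$c, labels = sort(unique(unname(sigma))))
}

# quartic induced-P4 scan
brute_has_p4 <- function(A) {
  verts <- rownames(A)
  n <- length(verts)
  if (n < 4L) return(FALSE)
  for (a in 1:n) for (b in 1:n) for (c in 1:n) for (d in 1:n) {
    if (length(unique(c(a, b, c, d))) < 4L) next
    if (A[a, b] && A[b, c] && A[c, d] && !A[a, c] && !A[a, d] && !A[b, d])
      return(TRUE)
  }
  FALSE
}

# minimum number of inserted edges to reach a complete multipartite graph,
# by exhaustive search over all partitions of the vertices into
# independent sets
brute_min_completion <- function(A) {
  verts <- rownames(A)
  parts_of <- function(x) {
    if (length(x) == 0L) return(list(list()))
    rest <- parts_of(x[-1L])
    out <- list()
    for (p in rest) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(x[1L], q[[i]])
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(list(x[1L]), p)
    }
    out
  }
  best <- Inf
  for (p in parts_of(verts)) {
    ok <- all(vapply(p, function(P) !any(A[P, P]), logical(1)))
    if (!ok) next
    pid <- stats::setNames(rep(seq_along(p), lengths(p)), unlist(p))
    cross <- outer(pid[verts], pid[verts], `!=`)
    q <- sum(cross & !A & upper.tri(A))
    best <- min(best, q)
  }
  best
}

# Fitch graph by brute-force path scans
brute_fitch <- function(elt) {
  tr <- elt$tree
  leaves <- tree_leaves(tr)
  A <- matrix(FALSE, length(leaves), length(leaves),
              dimnames = list(leaves, leaves))
  for (x in leaves) for (y in leaves) {
    if (x == y) next
    u <- lca(tr, c(x, y))
    path <- c(setdiff(root_path(tr, x), root_path(tr, u)),
              setdiff(root_path(tr, y), root_path(tr, u)))
    A[x, y] <- any(elt$lambda[path] == 1L)
  }
  A
}

# random cograph via a random cotree
random_cograph <- function(n) {
  verts <- paste0("v", seq_len(n))
  rec <- function(W, lab) {
    A <- matrix(FALSE, length(W), length(W), dimnames = list(W, W))
    if (length(W) == 1L) return(A)
    k <- sample(seq_len(length(W) - 1L), 1L)
    W1 <- W[seq_len(k)]; W2 <- W[-seq_len(k)]
    A[W1, W1] <- rec(W1, 1L - lab)
    A[W2, W2] <- rec(W2, 1L - lab)
    if (lab == 1L) { A[W1, W2] <- TRUE; A[W2, W1] <- TRUE }
    diag(A) <- FALSE
    A
  }
  rec(sample(verts), sample(0:1, 1L))
}

# random simple graph
random_graph <- function(n, p = 0.4) {
  verts <- paste0("v", seq_len(n))
  A <- matrix(stats::runif(n * n) < p, n, n, dimnames = list(verts, verts))
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- FALSE
  A
}

# the printed counterexample: properly colored cograph that is not an LDT
# graph because its species triples AC|B and BC|A are incompatible
cex_graph <- function() {
  sigma <- c(a = "A", a2 = "A", b = "B", b2 = "B", c = "C", c2 = "C")
  colored_graph(rbind(c("a", "b"), c("b", "c"), c("a2", "b2"), c("a2", "c2")),
                sigma)
}

# a quick random observable scenario from the simulator
random_observable <- function(leaf_range = c(4L, 12L),
                              rates = c(0.5, 0.5, 0.5)) {
  repeat {
    sp <- simulate_species_tree(leaf_range = leaf_range)
    ts <- simulate_true_scenario(sp$tree, sp$tau, rates[1L], rates[2L], rates[3L])
    obs <- prune_to_observable(ts)
    if (!is.null(obs)) return(list(ts = ts, obs = obs))
  }
}

# hand-built true scenario reproducing the hidden-transfer situation: a
# transfer into species B followed by a back-transfer into A and loss of
# the B copy; the observable scenario shows no transfer although the true
# restricted Fitch graph has the edge a-a'
back_transfer_fixture <- function() {
  Spar <- c(rhoS = "0S", A = "rhoS", B = "rhoS", `0S` = NA)
  S <- planted_tree(Spar)
  tau_S <- c(`0S` = 2, rhoS = 1, A = 0, B = 0)
  Tpar <- c(u1 = "0T", a = "u1", u2 = "u1", l = "u2", a2 = "u2", `0T` = NA)
  gene_tree <- planted_tree(Tpar)
  mu <- list(`0T` = mu_vertex("0S"), u1 = mu_edge("A"), a = mu_vertex("A"),
             u2 = mu_edge("B"), l = mu_edge("B"), a2 = mu_vertex("A"))
  tau_T <- c(`0T` = 2, u1 = 0.9, a = 0, u2 = 0.5, l = 0.3, a2 = 0)
  structure(list(gene_tree = gene_tree, S = S, tau_S = tau_S, tau_T = tau_T,
                 mu = mu,
                 event = c(`0T` = "planted", u1 = "hgt", a = "extant",
                           u2 = "hgt", l = "loss", a2 = "extant"),
                 survivors = c("a", "a2"),
                 sigma = c(a = "A", a2 = "A"),
                 rates = c(dup = 0, loss = 1, hgt = 1)),
            class = "true_scenario")
}
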