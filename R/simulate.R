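#' Simulate a dated species tree
#'
#' Generates a planted, time-stamped species tree.  The default
#' "innovation" model grows the tree by an innovation/feature-loss
#' process: each species is a set of features; an innovation event adds a
#' brand-new feature to a random species and always founds a new species,
#' while a feature-loss event founds a new species only if the reduced
#' feature set is not already present (otherwise the event is discarded).
#' This produces the imbalanced tree shapes typical of real taxonomies.
#' A Yule (uniform random splitting) model is available as a fallback.
#'
#' Node times come from a constant-rate branching clock: with `k` extant
#' lineages the waiting time to the next speciation is exponential with
#' rate `k`, and a final exponential stretch separates the last speciation
#' from the present.  Cumulative depths are rescaled so the first
#' branching (the root) is at time 1 and all leaves are at time 0
#' (ultrametric); the planted root lies above the root at the origin of
#' the process.
#'
#' Multifurcations, modelling limited phylogenetic resolution, are
#' introduced by contracting each inner edge independently with
#' probability `contraction_prob`.
#'
#' @param n_leaves number of species; if `NULL`, drawn uniformly from
#'   `leaf_range`
#' @param leaf_range integer interval for the leaf count (default 10-50)
#' @param contraction_prob per-inner-edge contraction probability
#'   (default 0.2)
#' @param model `"innovation"` or `"yule"`
#' @return list with `tree` (a `planted_tree`, leaves `sp1`, `sp2`, ...)
#'   and `tau` (named time map)
#' @export
simulate_species_tree <- function(n_leaves = NULL, leaf_range = c(10L, 50L),
                                  contraction_prob = 0.2,
                                  model = c("innovation", "yule")) {
  model <- match.arg(model)
  if (is.null(n_leaves))
    n_leaves <- sample(seq.int(leaf_range[1L], leaf_range[2L]), 1L)
  n <- as.integer(n_leaves)
  if (n < 2L) stop("need at least 2 species")
  parent <- character(0)
  etime <- numeric(0)          # branching index per internal node
  tip_id <- "t1"; nodes <- 1L
  new_node <- function() { nodes <<- nodes + 1L; paste0("t", nodes) }
  if (model == "yule") {
    tips <- tip_id
    ev <- 0L
    while (length(tips) < n) {
      ev <- ev + 1L
      v <- sample(tips, 1L)
      c1 <- new_node(); c2 <- new_node()
      parent[c1] <- v; parent[c2] <- v
      etime[v] <- ev
      tips <- c(setdiff(tips, v), c1, c2)
    }
  } else {
    feats <- list(1L)              # feature sets, one per current species
    tips <- tip_id
    nfeat <- 1L; ev <- 0L
    while (length(tips) < n) {
      i <- sample.int(length(tips), 1L)
      if (stats::runif(1) < 0.5) {           # innovation: always speciates
        nfeat <- nfeat + 1L
        newset <- c(feats[[i]], nfeat)
      } else {                               # feature loss
        if (length(feats[[i]]) < 2L) next
        drop <- sample(feats[[i]], 1L)
        newset <- setdiff(feats[[i]], drop)
        exists <- any(vapply(feats, function(f) setequal(f, newset), logical(1)))
        if (exists) next                     # discarded event
      }
      ev <- ev + 1L
      v <- tips[i]
      c1 <- new_node(); c2 <- new_node()
      parent[c1] <- v; parent[c2] <- v
      etime[v] <- ev
      tips <- c(tips[-i], c1, c2)
      feats <- c(feats[-i], feats[i], list(newset))
    }
  }
  # rename tips to stable species ids
  leafname <- stats::setNames(paste0("sp", seq_along(tips)), tips)
  names(parent) <- ifelse(names(parent) %in% tips,
                          leafname[names(parent)], names(parent))
  # constant-rate branching clock: event k at cumulative depth of k
  # exponential waits (rate = number of lineages); present after a final
  # wait with n lineages; backward times rescaled so the root is at 1
  waits <- stats::rexp(n, rate = seq_len(n))
  depth <- cumsum(waits)[seq_len(n - 1L)]
  D <- sum(waits)
  span <- D - depth[1L]
  tau <- stats::setNames((D - depth[etime]) / span, names(etime))
  tau[leafname] <- 0
  # contract inner edges with the given probability
  inner <- names(etime)
  for (v in setdiff(inner, tip_id)) {
    if (stats::runif(1) < contraction_prob) {
      p <- parent[[v]]
      kids <- names(parent)[parent == v]
      parent[kids] <- p
      parent <- parent[names(parent) != v]
      tau <- tau[names(tau) != v]
    }
  }
  parent[tip_id] <- "0S"
  parent["0S"] <- NA_character_
  tau["0S"] <- D / span   # origin of the process, above the root
  if (!tip_id %in% names(tau)) stop("internal error: root lost")
  list(tree = planted_tree(parent), tau = tau)
}

#' Simulate gene family evolution along a species tree
#'
#' Event-based constant-rate birth-death process with horizontal
#' transfer: a single ancestral gene enters at the planted root of the
#' species tree (no events occur above the first speciation); at every
#' species-tree vertex each resident gene lineage speciates into all
#' descendant branches; within a branch, duplications, losses and
#' transfers occur as Poisson events with the given rates.  Duplications
#' and transfers are bifurcations; losses terminate a lineage.  The
#' recipient of a transfer is chosen uniformly among the species branches
#' co-existing at the event time (excluding the donor); if no such branch
#' exists the event is discarded.
#'
#' The full ("true") gene tree retains loss leaves; the surviving genes
#' are its non-loss leaves and are colored by the species they reside in.
#'
#' @param S a planted species tree
#' @param tau_S time map of `S`
#' @param dup,loss,hgt nonnegative event rates (per lineage per unit time)
#' @return object of class `true_scenario`: the full gene tree with
#'   reconciliation `mu`, time map `tau_T`, per-vertex `event` type, the
#'   survivor set and their coloring `sigma`
#' @export
simulate_true_scenario <- function(S, tau_S, dup = 0.25, loss = 0.25, hgt = 0.25) {
  stopifnot(all(c(dup, loss, hgt) >= 0))
  rho <- tree_children(S, S$root)
  sverts <- tree_vertices(S)
  spar <- S$parent
  sleaves <- tree_leaves(S)
  # branch list for recipient lookup: non-root vertices below the root edge
  branches <- setdiff(sverts, c(S$root, rho))
  b_lo <- tau_S[branches]; b_hi <- tau_S[spar[branches]]
  total <- dup + loss + hgt
  parent <- character(0); tau <- numeric(0); mu <- list(); event <- character(0)
  k <- 0L
  new_gene <- function() { k <<- k + 1L; paste0("g", k) }
  root0 <- new_gene()
  parent[root0] <- NA_character_
  tau[root0] <- tau_S[[S$root]]
  mu[[root0]] <- mu_vertex(S$root)
  event[root0] <- "planted"
  # stack of lineages: species branch (child vertex), start time, gene parent
  stack <- list(list(v = rho, t = tau_S[[S$root]], par = root0))
  while (length(stack)) {
    ln <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    v <- ln$v; t0 <- ln$t
    on_planted_edge <- identical(v, rho) && spar[[v]] == S$root
    t_ev <- if (total > 0 && !on_planted_edge)
      t0 - stats::rexp(1L, total) else -Inf
    if (t_ev <= tau_S[[v]]) {
      # reach the branch endpoint v
      u <- new_gene()
      parent[u] <- ln$par
      tau[u] <- tau_S[[v]]
      mu[[u]] <- mu_vertex(v)
      if (v %in% sleaves) {
        event[u] <- "extant"
      } else {
        event[u] <- "speciation"
        for (w in tree_children(S, v))
          stack[[length(stack) + 1L]] <- list(v = w, t = tau_S[[v]], par = u)
      }
    } else {
      type <- sample(c("duplication", "loss", "hgt"), 1L,
                     prob = c(dup, loss, hgt))
      if (type == "hgt") {
        cand <- branches[b_lo < t_ev & t_ev < b_hi]
        cand <- cand[cand != v]
        if (!length(cand)) {
          # no co-existing recipient: discard the event, continue lineage
          stack[[length(stack) + 1L]] <- list(v = v, t = t_ev, par = ln$par)
          next
        }
        u <- new_gene()
        parent[u] <- ln$par
        tau[u] <- t_ev
        mu[[u]] <- mu_edge(v)
        event[u] <- "hgt"
        recipient <- if (length(cand) == 1L) cand else sample(cand, 1L)
        stack[[length(stack) + 1L]] <- list(v = v, t = t_ev, par = u)
        stack[[length(stack) + 1L]] <- list(v = recipient, t = t_ev, par = u)
      } else if (type == "duplication") {
        u <- new_gene()
        parent[u] <- ln$par
        tau[u] <- t_ev
        mu[[u]] <- mu_edge(v)
        event[u] <- "duplication"
        stack[[length(stack) + 1L]] <- list(v = v, t = t_ev, par = u)
        stack[[length(stack) + 1L]] <- list(v = v, t = t_ev, par = u)
      } else {
        u <- new_gene()
        parent[u] <- ln$par
        tau[u] <- t_ev
        mu[[u]] <- mu_edge(v)
        event[u] <- "loss"
      }
    }
    if (k > 50000L) stop("gene family exploded; lower the duplication rate")
  }
  survivors <- names(event)[event == "extant"]
  sigma <- vapply(survivors, function(x) mu[[x]]$id, character(1))
  structure(list(gene_tree = planted_tree(parent), S = S, tau_S = tau_S,
                 tau_T = tau, mu = mu, event = event,
                 survivors = survivors, sigma = sigma,
                 rates = c(dup = dup, loss = loss, hgt = hgt)),
            class = "true_scenario")
}

#' @export
print.true_scenario <- function(x, ...) {
  cat("true scenario: ", length(x$survivors), " surviving genes, ",
      sum(x$event == "loss"), " losses, ", sum(x$event == "hgt"),
      " transfers in ", length(tree_leaves(x$S)), " species\n", sep = "")
  invisible(x)
}

# transfer labels of an arbitrary (possibly non-phylogenetic-scenario)
# reconciled tree: 1 iff the mu images of the edge's endpoints are
# incomparable in S
lambda_from_mu <- function(tree, mu, S) {
  paths <- lapply(stats::setNames(nm = tree_vertices(S)),
                  function(v) root_path(S, v))
  kids <- tree_vertices(tree)[!is.na(tree$parent)]
  lam <- stats::setNames(integer(length(kids)), kids)
  for (v in kids)
    lam[v] <- as.integer(!images_comparable(mu[[tree$parent[[v]]]], mu[[v]], paths))
  lam
}

#' Prune a true scenario to its observable part
#'
#' Removes loss leaves and all subtrees without surviving genes,
#' suppresses the resulting single-child vertices, and inherits times and
#' reconciliation images on the surviving vertices.  The result is a
#' valid relaxed scenario; its LDT graph coincides with the LDT graph of
#' the unpruned scenario restricted to the survivors, because both are
#' based on the same time maps.
#'
#' @param ts a `true_scenario`
#' @return a `relaxed_scenario`, or `NULL` when no gene survived
#' @export
prune_to_observable <- function(ts) {
  L <- ts$survivors
  if (length(L) == 0L) return(NULL)
  keep <- unique(unlist(lapply(L, function(x) root_path(ts$gene_tree, x))))
  tr <- suppress_unary(ts$gene_tree$parent[keep])
  verts <- tree_vertices(tr)
  relaxed_scenario(tr, ts$S, sigma = ts$sigma,
                   mu = ts$mu[verts], tau_T = ts$tau_T[verts],
                   tau_S = ts$tau_S)
}

#' True Fitch graph restricted to the surviving genes
#'
#' The Fitch graph of the full gene tree (with transfer edges determined
#' by the unpruned reconciliation) induced on the survivors.  Because
#' paths in the full tree may contain transfers that are invisible after
#' pruning (e.g. a transfer followed by a back-transfer and a loss), this
#' graph can strictly contain the Fitch graph of the observable scenario.
#'
#' @param ts a `true_scenario`
#' @return logical adjacency matrix on the surviving genes
#' @export
true_fitch_restricted <- function(ts) {
  L <- ts$survivors
  lam <- lambda_from_mu(ts$gene_tree, ts$mu, ts$S)
  A <- fitch_graph(edge_labeled_tree(ts$gene_tree, lam))
  A[L, L, drop = FALSE]
}

# per-edge "true path" labels on the pruned tree: 1 iff the full-tree path
# contracted into this edge contains a transfer edge w.r.t. the unpruned
# reconciliation
path_transfer_labels <- function(ts, obs) {
  lam <- lambda_from_mu(ts$gene_tree, ts$mu, ts$S)
  tr <- obs$T
  full_par <- ts$gene_tree$parent
  kids <- tree_vertices(tr)[!is.na(tr$parent)]
  out <- stats::setNames(integer(length(kids)), kids)
  for (v in kids) {
    stop_at <- tr$parent[[v]]
    u <- v; hit <- 0L
    while (u != stop_at) {
      if (lam[[u]] == 1L) { hit <- 1L; break }
      u <- full_par[[u]]
    }
    out[v] <- hit
  }
  out
}

#' Simulate and score one observable scenario
#'
#' Runs the full pipeline for a single rate combination: species tree,
#' true scenario, pruning, the observable LDT and Fitch graphs, the true
#' restricted Fitch graph, and (when the LDT graph has edges) the two
#' Fitch estimates — greedy minimum edge completion and the scenario
#' constructed from the LDT graph — scored against the observable Fitch
#' graph over all unordered gene pairs.
#'
#' @inheritParams simulate_true_scenario
#' @inheritParams simulate_species_tree
#' @return one-row data frame of scenario statistics (see
#'   [evaluate_batch()])
#' @export
simulate_scenario_stats <- function(dup, loss, hgt,
                                    leaf_range = c(10L, 50L),
                                    contraction_prob = 0.2,
                                    model = "innovation") {
  sp <- simulate_species_tree(leaf_range = leaf_range,
                              contraction_prob = contraction_prob,
                              model = model)
  ts <- simulate_true_scenario(sp$tree, sp$tau, dup = dup, loss = loss, hgt = hgt)
  obs <- prune_to_observable(ts)
  base <- data.frame(dup = dup, loss = loss, hgt = hgt,
                     n_species = length(tree_leaves(sp$tree)),
                     n_genes = length(ts$survivors),
                     n_losses = sum(ts$event == "loss"),
                     n_hgt = sum(ts$event == "hgt"))
  if (is.null(obs)) {
    base$pairs <- 0L; base$ldt_edges <- NA_integer_
    base$fitch_true_equal <- NA; base$visible_frac <- NA_real_
    for (p in c("ldt", "mec", "alg1"))
      for (m in c("recall", "precision", "accuracy"))
        base[[paste(p, m, sep = "_")]] <- NA_real_
    base$mec_rs_fitch <- NA
    return(base)
  }
  G <- ldt_graph(obs)
  Ftruth <- rs_fitch_graph(obs)
  Ftilde <- true_fitch_restricted(ts)
  genes <- rownames(G$A)
  n <- length(genes)
  base$pairs <- n * (n - 1L) / 2L
  base$ldt_edges <- sum(G$A) / 2L
  base$fitch_true_equal <-
    identical(Ftruth$A[genes, genes], Ftilde[genes, genes])
  lam_path <- path_transfer_labels(ts, obs)
  lam_obs <- transfer_labeling(obs)$lambda
  base$visible_frac <- if (sum(lam_path) > 0)
    sum(lam_obs[names(lam_path)] == 1L & lam_path == 1L) / sum(lam_path)
  else NA_real_
  score <- function(pred) {
    Tm <- Ftruth$A[genes, genes]; Pm <- pred[genes, genes]
    ut <- upper.tri(Tm)
    tp <- sum(Pm & Tm & ut); fp <- sum(Pm & !Tm & ut)
    fn <- sum(!Pm & Tm & ut); tn <- sum(!Pm & !Tm & ut)
    c(recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      accuracy = (tp + tn) / (tp + fp + fn + tn))
  }
  if (!is.na(base$ldt_edges) && base$ldt_edges > 0) {
    mec <- fitch_from_ldt(G, method = "completion")
    alg1 <- fitch_from_ldt(G, method = "scenario")
    for (nm in list(list("ldt", G$A), list("mec", mec$graph$A),
                    list("alg1", alg1$graph$A))) {
      sc <- score(nm[[2L]])
      base[[paste0(nm[[1L]], "_recall")]] <- sc[["recall"]]
      base[[paste0(nm[[1L]], "_precision")]] <- sc[["precision"]]
      base[[paste0(nm[[1L]], "_accuracy")]] <- sc[["accuracy"]]
    }
    base$mec_rs_fitch <- mec$rs_fitch
  } else {
    for (p in c("ldt", "mec", "alg1"))
      for (m in c("recall", "precision", "accuracy"))
        base[[paste(p, m, sep = "_")]] <- NA_real_
    base$mec_rs_fitch <- NA
  }
  base
}

#' Run the simulation study over a rate grid
#'
#' Simulates `n_per_combo` scenarios for every row of the rate grid and
#' collects per-scenario statistics: basic counts, the LDT edge count,
#' whether the observable Fitch graph equals the true Fitch graph
#' restricted to survivors, the visible-transfer fraction, and
#' recall/precision/accuracy of the three Fitch estimates (raw LDT,
#' minimum edge completion, scenario construction) against the observable
#' Fitch graph.  Scenarios whose LDT graph has no edges carry `NA`
#' metrics and are excluded from precision/recall aggregation (but counted
#' in the edgeless fraction), mirroring the usual inclusion rule.
#'
#' @param grid data frame with columns `dup`, `loss`, `hgt`; defaults to
#'   duplication = loss in \{0.25, 0.5, 1\} crossed with
#'   hgt in \{0.25, 0.5, 1\}
#' @param n_per_combo scenarios per rate combination
#' @param seed integer seed (all randomness derives from it)
#' @inheritParams simulate_species_tree
#' @return data frame, one row per scenario
#' @export
evaluate_batch <- function(grid = default_rate_grid(), n_per_combo = 100L,
                           seed = 1L, leaf_range = c(10L, 50L),
                           contraction_prob = 0.2, model = "innovation") {
  set.seed(as.integer(seed))
  rows <- vector("list", nrow(grid) * n_per_combo)
  idx <- 0L
  for (i in seq_len(nrow(grid))) {
    for (r in seq_len(n_per_combo)) {
      idx <- idx + 1L
      row <- simulate_scenario_stats(grid$dup[i], grid$loss[i], grid$hgt[i],
                                     leaf_range = leaf_range,
                                     contraction_prob = contraction_prob,
                                     model = model)
      row$rep <- r
      rows[[idx]] <- row
    }
  }
  do.call(rbind, rows)
}

#' @rdname evaluate_batch
#' @export
default_rate_grid <- function() {
  g <- expand.grid(dup = c(0.25, 0.5, 1), hgt = c(0.25, 0.5, 1))
  data.frame(dup = g$dup, loss = g$dup, hgt = g$hgt)
}

#' Aggregate a simulation batch
#'
#' Summary statistics over a batch from [evaluate_batch()], on the
#' percentage scale: the fraction of scenarios whose observable Fitch
#' graph equals the true restricted one, the fraction of observable
#' scenarios with an edgeless LDT graph, the fraction of minimum edge
#' completions that are rs-Fitch graphs under the observed colors, and
#' the median accuracy/precision/recall of the completion estimate over
#' scenarios with at least one LDT edge.
#'
#' @param stats data frame from [evaluate_batch()]
#' @return named list of aggregates (percent)
#' @export
summarize_batch <- function(stats) {
  obs <- stats[!is.na(stats$ldt_edges), , drop = FALSE]
  incl <- obs[obs$ldt_edges > 0, , drop = FALSE]
  list(
    pct_fitch_true_equal = 100 * mean(obs$fitch_true_equal),
    pct_ldt_edgeless = 100 * mean(obs$ldt_edges == 0),
    pct_mec_rs_fitch = 100 * mean(incl$mec_rs_fitch),
    median_mec_accuracy = 100 * stats::median(incl$mec_accuracy),
    median_mec_precision = 100 * stats::median(incl$mec_precision, na.rm = TRUE),
    median_mec_recall = 100 * stats::median(incl$mec_recall, na.rm = TRUE),
    median_ldt_recall = 100 * stats::median(incl$ldt_recall, na.rm = TRUE),
    median_alg1_recall = 100 * stats::median(incl$alg1_recall, na.rm = TRUE),
    n_scenarios = nrow(obs),
    n_included = nrow(incl))
}
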