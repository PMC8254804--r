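# relaxed scenarios: validation, LDT graphs, transfer labels, Fitch graphs

# small hand-made scenario: two species, one transfer making the gene pair
# diverge later than the species
two_leaf_scenario <- function() {
  S <- planted_tree(c(rhoS = "0S", A = "rhoS", B = "rhoS", `0S` = NA))
  tau_S <- c(`0S` = 3, rhoS = 2, A = 0, B = 0)
  Tg <- planted_tree(c(rhoT = "0T", a = "rhoT", b = "rhoT", `0T` = NA))
  tau_T <- c(`0T` = 3, rhoT = 1, a = 0, b = 0)
  mu <- list(`0T` = mu_vertex("0S"), rhoT = mu_edge("A"),
             a = mu_vertex("A"), b = mu_vertex("B"))
  relaxed_scenario(Tg, S, c(a = "A", b = "B"), mu, tau_T, tau_S)
}

test_that("scenario validation reports exactly the violated conditions", {
  s <- two_leaf_scenario()
  expect_length(validate_scenario(s), 0)
  # C2: vertex mapped onto an edge but above the edge's upper end
  s2 <- s; s2$tau_T["rhoT"] <- 2.5
  expect_true("C2" %in% validate_scenario(s2))
  # G0: planted root mapped elsewhere
  s3 <- s; s3$mu[["0T"]] <- mu_vertex("rhoS")
  expect_true(all(c("G0", "C1") %in% validate_scenario(s3)))
  # G1: leaf mapped to the wrong species
  s4 <- s; s4$mu[["a"]] <- mu_vertex("B")
  expect_true("G1" %in% validate_scenario(s4))
  # leaf time disagreement
  s5 <- s; s5$tau_T["a"] <- 0.5
  expect_true("leaf-times" %in% validate_scenario(s5))
  # malformed image rejected at construction
  expect_error(relaxed_scenario(s$T, s$S, s$sigma,
                                c(s$mu[-1], list(`0T` = mu_vertex("nope"))),
                                s$tau_T, s$tau_S), "not a vertex")
  # independent re-check of every condition on simulator output
  set.seed(401)
  for (i in 1:10) {
    sc <- random_observable()
    expect_length(validate_scenario(sc$obs), 0)
  }
})

test_that("LDT graph follows the pairwise later-divergence definition", {
  s <- two_leaf_scenario()
  G <- ldt_graph(s)
  expect_true(G$A["a", "b"])            # 1 < 2
  # no-transfer scenarios give edgeless LDT graphs
  set.seed(402)
  sp <- simulate_species_tree(leaf_range = c(5, 10))
  ts <- simulate_true_scenario(sp$tree, sp$tau, dup = 0.5, loss = 0.3, hgt = 0)
  obs <- prune_to_observable(ts)
  if (!is.null(obs)) expect_equal(sum(ldt_graph(obs)$A), 0)
  # direct double-loop re-evaluation on random scenarios
  for (i in 1:10) {
    sc <- random_observable()
    G <- ldt_graph(sc$obs)
    genes <- rownames(G$A)
    for (a in genes) for (b in genes) {
      if (a >= b) next
      want <- sc$obs$tau_T[[lca(sc$obs$T, c(a, b))]] <
        sc$obs$tau_S[[lca(sc$obs$S, c(sc$obs$sigma[[a]], sc$obs$sigma[[b]]))]]
      expect_identical(unname(G$A[a, b]), want)
    }
  }
})

test_that("transfer labeling marks exactly the incomparably mapped edges", {
  s <- two_leaf_scenario()
  elt <- transfer_labeling(s)
  # rhoT sits in edge above A, b is the leaf B: incomparable -> transfer
  expect_identical(unname(elt$lambda[c("a", "b", "rhoT")]), c(0L, 1L, 0L))
  # a scenario mapped entirely onto one root-to-leaf path has no transfers
  S <- planted_tree(c(rhoS = "0S", A = "rhoS", B = "rhoS", `0S` = NA))
  tau_S <- c(`0S` = 3, rhoS = 2, A = 0, B = 0)
  Tg <- planted_tree(c(rhoT = "0T", a = "rhoT", a2 = "rhoT", `0T` = NA))
  mu <- list(`0T` = mu_vertex("0S"), rhoT = mu_edge("A"),
             a = mu_vertex("A"), a2 = mu_vertex("A"))
  s2 <- relaxed_scenario(Tg, S, c(a = "A", a2 = "A"), mu,
                         c(`0T` = 3, rhoT = 1, a = 0, a2 = 0), tau_S)
  expect_true(all(transfer_labeling(s2)$lambda == 0L))
  # totality and binarity on random scenarios
  set.seed(403)
  for (i in 1:8) {
    sc <- random_observable()
    lam <- transfer_labeling(sc$obs)$lambda
    tr <- sc$obs$T
    expect_setequal(names(lam), tree_vertices(tr)[!is.na(tr$parent)])
    expect_true(all(lam %in% c(0L, 1L)))
  }
})

test_that("Fitch graphs of labeled trees match brute-force path scans", {
  tr <- planted_tree(c(a = "r", b = "r", c = "r", r = "0", "0" = NA))
  lam0 <- c(a = 0L, b = 0L, c = 0L, r = 0L)
  expect_equal(sum(fitch_graph(edge_labeled_tree(tr, lam0))), 0)
  lam1 <- c(a = 1L, b = 0L, c = 0L, r = 0L)
  A <- fitch_graph(edge_labeled_tree(tr, lam1))
  expect_true(A["a", "b"] && A["a", "c"] && !A["b", "c"])
  set.seed(404)
  for (i in 1:15) {
    tr <- random_tree(sample(3:9, 1), contract = 0.3)
    kids <- tree_vertices(tr)[!is.na(tr$parent)]
    lam <- stats::setNames(sample(0:1, length(kids), replace = TRUE,
                                  prob = c(0.7, 0.3)), kids)
    elt <- edge_labeled_tree(tr, lam)
    l <- tree_leaves(tr)
    expect_identical(fitch_graph(elt)[l, l], brute_fitch(elt)[l, l])
  }
})

test_that("LDT graph is always a subgraph of the scenario Fitch graph", {
  set.seed(405)
  for (i in 1:20) {
    sc <- random_observable()
    G <- ldt_graph(sc$obs)
    F1 <- rs_fitch_graph(sc$obs)
    expect_true(all(!G$A | F1$A))
    # non-Fitch pairs have their species lca at or below the mu image of
    # their gene lca
    genes <- rownames(F1$A)
    for (a in genes) for (b in genes) {
      if (a >= b || F1$A[a, b]) next
      u <- sc$obs$mu[[lca(sc$obs$T, c(a, b))]]
      v <- lca(sc$obs$S, c(sc$obs$sigma[[a]], sc$obs$sigma[[b]]))
      # species lca lies at or below the image (extended order: an edge
      # image is compared through its lower endpoint)
      expect_true(is_ancestor(sc$obs$S, u$id, v))
    }
  }
})

test_that("scenario JSON bundles round-trip and validate on read", {
  s <- two_leaf_scenario()
  f <- tempfile(fileext = ".json")
  write_scenario(s, f)
  back <- read_scenario(f)
  expect_length(validate_scenario(back), 0)
  expect_identical(canonical_form(back$T), canonical_form(s$T))
  expect_identical(canonical_form(back$S), canonical_form(s$S))
  expect_identical(ldt_graph(back)$A[c("a", "b"), c("a", "b")],
                   ldt_graph(s)$A[c("a", "b"), c("a", "b")])
})
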