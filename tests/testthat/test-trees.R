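# planted trees, lca, restriction, display relation, time maps

test_that("planted tree invariants are enforced", {
  expect_error(planted_tree(c(a = NA, b = NA)), "exactly one")
  # planted root with two children is not planted
  expect_error(planted_tree(c(a = "0", b = "0", "0" = NA)), "exactly one child")
  # unary inner vertex is not phylogenetic
  expect_error(planted_tree(c(u = "r", a = "u", r = "0", "0" = NA)),
               "not phylogenetic")
  expect_error(planted_tree(c(a = "b", b = "a", r = "0", "0" = NA)),
               "cycle|unknown|exactly one|phylogenetic")
})

test_that("lca: identity, triple ordering, and agreement with the ancestor-set oracle", {
  tr <- random_tree(6)
  for (v in tree_vertices(tr)) expect_identical(lca(tr, v), v)
  # the defining property of a triple tree ab|c
  tt <- planted_tree(c(a = "u", b = "u", u = "r", c = "r", r = "0", "0" = NA))
  expect_true(is_ancestor(tt, lca(tt, c("a", "c")), lca(tt, c("a", "b"))))
  expect_identical(lca(tt, c("a", "c")), lca(tt, c("b", "c")))
  expect_error(lca(tr, "nope"), "unknown")
  set.seed(101)
  for (i in 1:25) {
    tr <- random_tree(sample(3:12, 1), contract = 0.3)
    W <- sample(tree_leaves(tr), sample(2:3, 1))
    expect_identical(lca(tr, W), brute_lca(tr, W))
  }
})

test_that("restriction spans the chosen leaves and commutes with relabeling", {
  tr <- planted_tree(c(a = "u", b = "u", u = "r", c = "r", r = "0", "0" = NA))
  r1 <- restrict_tree(tr, c("a", "c"))
  expect_setequal(tree_leaves(r1), c("a", "c"))
  expect_equal(length(tree_inner(r1)), 1)   # just the cherry vertex lca(a, c)
  expect_identical(canonical_form(restrict_tree(tr, tree_leaves(tr))),
                   canonical_form(tr))
  expect_error(restrict_tree(tr, character(0)), "non-empty")
  expect_error(restrict_tree(tr, "u"), "leaves")
  set.seed(102)
  for (i in 1:20) {
    tr <- random_tree(sample(4:10, 1), contract = 0.2)
    Lp <- sample(tree_leaves(tr), sample(2:4, 1))
    r <- restrict_tree(tr, Lp)
    expect_setequal(tree_leaves(r), Lp)
    # relabel leaves, restrict, and compare canonical forms
    perm <- stats::setNames(paste0("z", seq_along(tree_leaves(tr))),
                            tree_leaves(tr))
    par2 <- tr$parent
    names(par2) <- ifelse(names(par2) %in% names(perm),
                          perm[names(par2)], names(par2))
    tr2 <- planted_tree(par2)
    r2 <- restrict_tree(tr2, unname(perm[Lp]))
    par_r <- r$parent
    names(par_r) <- ifelse(names(par_r) %in% names(perm),
                           perm[names(par_r)], names(par_r))
    expect_identical(canonical_form(planted_tree(par_r)), canonical_form(r2))
  }
})

test_that("display relation: restrictions, the star, and the contraction oracle", {
  tr <- planted_tree(c(a = "u", b = "u", u = "r", c = "r", r = "0", "0" = NA))
  star <- planted_tree(c(a = "r", b = "r", c = "r", r = "0", "0" = NA))
  expect_true(displays(tr, star))          # contraction of one inner edge
  expect_false(displays(star, tr))         # a star displays no resolved triple
  set.seed(103)
  for (i in 1:15) {
    tr <- random_tree(sample(4:8, 1), contract = 0.25)
    Lp <- sample(tree_leaves(tr), sample(2:4, 1))
    expect_true(displays(tr, restrict_tree(tr, Lp)))
    tp <- random_tree(length(Lp), labels = Lp, contract = 0.4)
    expect_identical(displays(tr, tp), brute_displays(tr, tp))
  }
})

test_that("suppression of single-child vertices preserves structure and ids", {
  tr <- random_tree(5)
  expect_identical(suppress_unary(tr)$parent, tr$parent)
  chain <- c(leaf = "v", v = "u", u = "0", "0" = NA)
  out <- suppress_unary(chain)
  expect_identical(tree_leaves(out), "leaf")
  expect_identical(out$parent[["leaf"]], "0")
  set.seed(104)
  for (i in 1:10) {
    tr <- random_tree(sample(4:9, 1))
    # mutilate: drop a random subset of leaves, then suppress
    drop <- sample(tree_leaves(tr), sample(1:2, 1))
    keep <- unique(unlist(lapply(setdiff(tree_leaves(tr), drop),
                                 function(x) root_path(tr, x))))
    out <- suppress_unary(tr$parent[keep])
    expect_s3_class(out, "planted_tree")   # constructor re-checks invariants
    expect_true(all(tree_vertices(out) %in% keep))
  }
})

test_that("time map construction satisfies strict ancestor ordering", {
  cherry <- planted_tree(c(a = "r", b = "r", r = "0", "0" = NA))
  tau <- assign_time_map(cherry, c(a = 0, b = 0), min_gap = 1)
  expect_equal(unname(tau[c("a", "b", "r", "0")]), c(0, 0, 1, 2))
  expect_error(assign_time_map(cherry, c(a = 0, b = 0), min_gap = 0), "positive")
  set.seed(105)
  for (i in 1:15) {
    tr <- random_tree(sample(3:20, 1), contract = 0.3)
    lt <- stats::setNames(stats::runif(length(tree_leaves(tr))), tree_leaves(tr))
    tau <- assign_time_map(tr, lt, min_gap = 0.5)
    expect_identical(unname(tau[tree_leaves(tr)]), unname(lt))
    # exhaustive comparability check
    for (x in tree_vertices(tr)) for (y in setdiff(root_path(tr, x), x))
      expect_lt(tau[[x]], tau[[y]])
    expect_true(is_valid_time_map(tr, tau))
  }
})

test_that("Newick writer and reader round-trip trees with annotations", {
  tr <- random_tree(7, contract = 0.3)
  tau <- assign_time_map(tr, stats::setNames(rep(0, 7), tree_leaves(tr)))
  s <- write_newick(tr, tau = tau)
  back <- read_newick(s)
  expect_identical(canonical_form(back$tree), canonical_form(tr))
  expect_equal(back$tau[names(tau)], tau)
  # cross-check the parser against trees written by ape
  skip_if_not_installed("ape")
  set.seed(106)
  for (i in 1:5) {
    ap <- ape::rtree(8)
    ours <- read_newick(ape::write.tree(ap))$tree
    ap_clades <- lapply(ape::prop.part(ap), function(ix) sort(ap$tip.label[ix]))
    our_clusters <- strsplit(ldthgt:::tree_clusters(ours), "\r", fixed = TRUE)
    for (cl in ap_clades)
      expect_true(any(vapply(our_clusters, identical, logical(1), y = cl)))
  }
})
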