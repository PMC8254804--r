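# rs-Fitch recognition and completion of LDT graphs toward Fitch graphs

test_that("color auxiliary graph follows its definition and is monotone", {
  sigma <- c(a = "A", b = "B", c = "C")
  M <- c("A", "B", "C")
  expect_false(any(fitch_aux_graph(sigma, list("a", "b", "c"), M)))
  one <- fitch_aux_graph(sigma, list(c("a", "b")), c("A", "B"))
  expect_true(one["A", "B"] && sum(one) == 2)
  set.seed(601)
  for (i in 1:10) {
    n <- 8
    sigma <- stats::setNames(sample(LETTERS[1:4], n, replace = TRUE),
                             paste0("v", 1:n))
    I <- replicate(4, sample(names(sigma), sample(1:4, 1)), simplify = FALSE)
    big <- fitch_aux_graph(sigma, I, LETTERS[1:5])
    small <- fitch_aux_graph(sigma, I[1:2], LETTERS[1:5])
    expect_true(all(!small | big))   # subfamily gives a subgraph
  }
})

test_that("rs-Fitch recognition reproduces the printed positive and negative cases", {
  # triangle on {a, a', b} with two colors is realizable
  tri <- colored_graph(rbind(c("a", "a2"), c("a", "b"), c("a2", "b")),
                       c(a = "A", a2 = "A", b = "B"), M = c("A", "B"))
  expect_true(is_rs_fitch(tri)$rs_fitch)
  # same-color K2 with only the observed species available is not
  k2_small <- colored_graph(rbind(c("a", "a2")), c(a = "A", a2 = "A"), M = "A")
  expect_false(is_rs_fitch(k2_small)$rs_fitch)
  # ... but a second (unobserved) species makes it realizable
  k2_big <- colored_graph(rbind(c("a", "a2")), c(a = "A", a2 = "A"),
                          M = c("A", "B"))
  expect_true(is_rs_fitch(k2_big)$rs_fitch)
  # any induced K2+K1 fails outright
  k2k1 <- colored_graph(rbind(c("x", "y")), c(x = "X", y = "Y", z = "Z"))
  out <- is_rs_fitch(k2k1)
  expect_false(out$rs_fitch)
  expect_identical(out$witness$type, "not-multipartite")
  # edgeless graphs (a single part) are always realizable
  expect_true(is_rs_fitch(colored_graph(matrix(character(0), 0, 2),
                                        c(a = "A", a2 = "A"), M = "A"))$rs_fitch)
})

test_that("rs-Fitch recognition accepts every simulated scenario Fitch graph and is hereditary", {
  set.seed(602)
  for (i in 1:15) {
    sc <- random_observable(rates = c(0.5, 0.5, 1))
    F1 <- rs_fitch_graph(sc$obs)
    expect_true(is_rs_fitch(F1)$rs_fitch)
    genes <- rownames(F1$A)
    if (length(genes) >= 3) {
      W <- sample(genes, max(2, length(genes) - 2))
      expect_true(is_rs_fitch(induced_subgraph(F1, W))$rs_fitch)
    }
  }
})

test_that("greedy multipartite completion is optimal (exhaustive partition oracle)", {
  # already complete multipartite: nothing to add
  kn <- matrix(TRUE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(kn) <- FALSE
  expect_equal(nrow(complete_to_multipartite(kn)$Q), 0)
  # K2 + K1 needs exactly one edge
  k2k1 <- matrix(FALSE, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  k2k1["x", "y"] <- k2k1["y", "x"] <- TRUE
  expect_equal(nrow(complete_to_multipartite(k2k1)$Q), 1)
  expect_equal(brute_min_completion(k2k1), 1)
  # non-cographs are rejected
  p4 <- matrix(FALSE, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  p4[cbind(c("a", "b", "c"), c("b", "c", "d"))] <- TRUE
  p4 <- p4 | t(p4)
  expect_error(complete_to_multipartite(p4), "not a cograph")
  set.seed(603)
  for (i in 1:20) {
    A <- random_cograph(sample(4:8, 1))
    got <- complete_to_multipartite(A)
    expect_equal(nrow(got$Q), brute_min_completion(A))
    # the result really is complete multipartite with the reported parts
    B <- A
    if (nrow(got$Q)) {
      B[got$Q] <- TRUE
      B[got$Q[, 2:1, drop = FALSE]] <- TRUE
    }
    expect_false(inherits(complete_multipartite_parts(B), "not_multipartite"))
  }
})

test_that("part-size sequence of the greedy completion matches the optimum structure", {
  set.seed(604)
  for (i in 1:10) {
    A <- random_cograph(sample(5:8, 1))
    sizes <- sort(lengths(complete_to_multipartite(A)$parts), decreasing = TRUE)
    # recompute after relabeling vertices: sizes are invariant
    perm <- sample(rownames(A))
    B <- A[perm, perm]
    rownames(B) <- colnames(B) <- paste0("w", seq_along(perm))
    sizes2 <- sort(lengths(complete_to_multipartite(B)$parts), decreasing = TRUE)
    expect_identical(sizes, sizes2)
  }
})

test_that("Fitch estimation from LDT graphs: supergraph law and method ordering", {
  set.seed(605)
  for (i in 1:12) {
    sc <- random_observable(rates = c(0.5, 0.5, 1))
    G <- ldt_graph(sc$obs)
    mec <- fitch_from_ldt(G, method = "completion")
    alg1 <- fitch_from_ldt(G, method = "scenario")
    gn <- rownames(G$A)
    expect_true(all(!G$A | mec$graph$A[gn, gn]))   # completion only adds edges
    expect_true(all(!G$A | alg1$graph$A[gn, gn]))
    # the scenario-based estimate has at least as many edges as the
    # minimal completion
    expect_gte(sum(alg1$graph$A), sum(mec$graph$A))
    expect_true(alg1$rs_fitch)
  }
  # an already complete multipartite LDT graph is returned unchanged
  tri <- colored_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")),
                       c(a = "A", b = "B", c = "C"))
  out <- fitch_from_ldt(tri, method = "completion")
  expect_identical(out$graph$A[rownames(tri$A), colnames(tri$A)], tri$A)
  expect_equal(nrow(out$Q), 0)
})
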