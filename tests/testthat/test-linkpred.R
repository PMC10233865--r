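test_that("neighborhood indices reproduce hand-worked values", {
  # path fixture: edges A-C, B-C, C-D; C is the only common neighbor of A,B
  g <- chem_graph(list(c("A", "C"), c("B", "C"), c("C", "D")))
  expect_equal(aa_index(g, "A", "B"), 1 / log(3))
  expect_equal(jaccard_index(g, "A", "B"), 1.0)      # N(A)=N(B)={C}
  expect_equal(pa_index(g, "A", "B"), 1)
  expect_equal(aa_index(g, "A", "D"), 1 / log(3))
  g2 <- chem_graph(list(c("A", "C"), c("A", "D"), c("B", "D"), c("B", "E")))
  expect_equal(jaccard_index(g2, "A", "B"), 1 / 3)   # {C,D} vs {D,E}
  expect_equal(pa_index(g2, "C", "D"), 2)            # degrees 1 x 2
  # isolated endpoints: zero by convention
  g3 <- chem_graph(list(c("A", "B")), extra_nodes = c("X", "Y"))
  expect_equal(aa_index(g3, "X", "Y"), 0)
  expect_equal(jaccard_index(g3, "X", "Y"), 0)
  expect_equal(pa_index(g3, "X", "A"), 0)
})

test_that("indices agree with matrix-route oracles on random graphs", {
  for (seed in 1:20) {
    g <- random_typed_graph(n = sample(10:30, 1), p = 0.15, seed = 100 + seed)
    ids <- g$nodes$node_id
    pr <- utils::combn(length(ids), 2L)
    u <- ids[pr[1, ]]; v <- ids[pr[2, ]]
    expect_equal(aa_index(g, u, v), unname(oracle_aa(g, u, v)), tolerance = 1e-12)
    expect_equal(jaccard_index(g, u, v), unname(oracle_jaccard(g, u, v)),
                 tolerance = 1e-12)
    expect_equal(pa_index(g, u, v), unname(oracle_pa(g, u, v)))
  }
})

test_that("indices are invariant to node relabeling", {
  g <- random_typed_graph(n = 15, p = 0.25, seed = 5)
  ids <- g$nodes$node_id
  set.seed(6)
  relab <- stats::setNames(sprintf("z%02d", sample(length(ids))), ids)
  meta2 <- node_meta(unname(relab[ids]), g$nodes$role, g$nodes$origins)
  g2 <- hetgraph(meta2, layered_edges(relab[g$edges$u], relab[g$edges$v],
                                      g$edges$layer, g$edges$score))
  pr <- utils::combn(length(ids), 2L)
  u <- ids[pr[1, ]]; v <- ids[pr[2, ]]
  expect_equal(aa_index(g, u, v), aa_index(g2, relab[u], relab[v]))
  expect_equal(jaccard_index(g, u, v), jaccard_index(g2, relab[u], relab[v]))
  expect_equal(pa_index(g, u, v), pa_index(g2, relab[u], relab[v]))
})

test_that("biased walk transitions follow the p/q second-order rule", {
  # v's neighbors: t (previous), x1 (adjacent to t), x2 (not adjacent to t)
  g <- chem_graph(list(c("t", "v"), c("v", "x1"), c("v", "x2"), c("t", "x1")))
  pr <- walk_transition_probs(g, t = "t", v = "v", p = 0.5, q = 2)
  expect_equal(unname(pr[c("t", "x1", "x2")]), c(4, 2, 1) / 7)
  # with p = q = 1 the bias cancels and the distribution is uniform
  pr1 <- walk_transition_probs(g, "t", "v", p = 1, q = 1)
  expect_equal(unname(pr1), rep(1 / 3, 3))
})

test_that("empirical walk frequencies match the exact bias distribution", {
  g <- chem_graph(list(c("t", "v"), c("v", "x1"), c("v", "x2"), c("t", "x1")))
  params <- node2vec_params(p = 0.5, q = 2, walk_length = 60,
                            walks_per_node = 120, seed = 42)
  corpus <- biased_walks(g, params)
  ids <- corpus$node_ids
  steps <- table(factor(unlist(lapply(corpus$walks, function(w) {
    n <- ids[w]
    j <- which(n == "v")
    j <- j[j > 1 & j < length(n)]
    j <- j[n[j - 1] == "t"]
    n[j + 1]
  })), levels = c("t", "x1", "x2")))
  expect_gt(sum(steps), 2000)
  pval <- stats::chisq.test(as.vector(steps), p = c(4, 2, 1) / 7)$p.value
  expect_gt(pval, 0.01)
})

test_that("unbiased walks are uniform over neighbors (chi-squared)", {
  # star: every step from the hub must pick a leaf uniformly
  leaves <- sprintf("L%02d", 1:8)
  g <- chem_graph(lapply(leaves, function(l) c("hub", l)))
  params <- node2vec_params(p = 1, q = 1, walk_length = 80,
                            walks_per_node = 40, seed = 9)
  corpus <- biased_walks(g, params)
  ids <- corpus$node_ids
  visits <- unlist(lapply(corpus$walks, function(w) {
    n <- ids[w]
    n[which(n == "hub") + 1]
  }))
  visits <- visits[!is.na(visits)]
  expect_gt(length(visits), 1e4)
  cnt <- table(factor(visits, levels = leaves))
  expect_gt(stats::chisq.test(as.vector(cnt))$p.value, 0.01)
})

test_that("walks alternate on a single edge and respect length/count contracts", {
  g <- chem_graph(list(c("A", "B")))
  params <- node2vec_params(walk_length = 10, walks_per_node = 3, seed = 1)
  corpus <- biased_walks(g, params)
  expect_length(corpus$walks, 2 * 3)
  for (w in corpus$walks) {
    n <- corpus$node_ids[w]
    expect_length(n, 10)
    expect_true(all(n == rep(c(n[1], setdiff(c("A", "B"), n[1])), 5)))
  }
  # isolated nodes start no walks
  g2 <- chem_graph(list(c("A", "B")), extra_nodes = "X")
  expect_length(biased_walks(g2, params)$walks, 2 * 3)
})

test_that("skip-gram embeddings separate planted cliques and are reproducible", {
  cl1 <- sprintf("a%02d", 1:20); cl2 <- sprintf("b%02d", 1:20)
  pairs <- c(utils::combn(cl1, 2, simplify = FALSE),
             utils::combn(cl2, 2, simplify = FALSE),
             list(c("a01", "b01")))
  g <- chem_graph(pairs)
  params <- node2vec_params(dims = 32, walk_length = 20, walks_per_node = 5,
                            epochs = 2, seed = 17)
  corpus <- biased_walks(g, params)
  emb <- train_embeddings(corpus, params)
  expect_equal(dim(emb), c(40L, 32L))
  cosine <- function(x, y) sum(x * y) / sqrt(sum(x^2) * sum(y^2))
  cs <- function(a, b) {
    m <- 0; k <- 0
    for (i in a) for (j in b) if (i != j) { m <- m + cosine(emb[i, ], emb[j, ]); k <- k + 1 }
    m / k
  }
  intra <- (cs(cl1, cl1) + cs(cl2, cl2)) / 2
  inter <- cs(cl1, cl2)
  expect_gt(intra, inter)
  # fixed seed, single-threaded: bitwise identical rerun
  emb2 <- train_embeddings(biased_walks(g, params), params)
  expect_identical(emb, emb2)
})

test_that("edge feature operators follow their definitions", {
  emb <- rbind(u = c(1, 2), v = c(3, 1), w = c(-1, -2))
  pairs <- data.frame(u = "u", v = "v")
  expect_equal(unname(edge_features(emb, pairs, "hadamard")), rbind(c(3, 2)))
  expect_equal(unname(edge_features(emb, pairs, "l1")), rbind(c(2, 1)))
  expect_equal(unname(edge_features(emb, pairs, "l2")), rbind(c(4, 1)))
  expect_equal(unname(edge_features(emb, data.frame(u = "u", v = "w"),
                                    "average")), rbind(c(0, 0)))
  expect_error(edge_features(emb, data.frame(u = "u", v = "zz")), "zz")
})

test_that("Laplacian identities hold and spectral embedding separates cliques", {
  tri <- chem_graph(list(c("A", "B"), c("B", "C"), c("A", "C")))
  L <- laplacian_matrix(tri)
  expect_equal(unname(rowSums(L)), rep(0, 3))
  Ln <- laplacian_matrix(tri, normalized = TRUE)
  expect_equal(min(eigen(Ln, symmetric = TRUE)$values), 0, tolerance = 1e-10)

  cl1 <- sprintf("a%02d", 1:8); cl2 <- sprintf("b%02d", 1:8)
  g <- chem_graph(c(utils::combn(cl1, 2, simplify = FALSE),
                    utils::combn(cl2, 2, simplify = FALSE)))
  emb <- suppressMessages(spectral_embed(g, spectral_params(k = 2)))
  km <- stats::kmeans(emb, centers = 2, nstart = 5)
  grp <- split(names(km$cluster), km$cluster)
  expect_true(setequal(grp[[1]], cl1) || setequal(grp[[1]], cl2))
})

test_that("classifier-backed scorers emit probabilities; index scorers calibrate", {
  sim <- generate_hetnet(tiny_config(seed = 4))
  g <- assemble_dataset(build_layers(sim), sim$meta)
  sp <- suppressWarnings(split_edges(g, split_spec(seed = 2), fold = 1))
  params <- node2vec_params(dims = 16, walk_length = 20, walks_per_node = 3,
                            epochs = 1, seed = 8)
  sc <- suppressWarnings(train_scorer(sp$train_graph, "node2vec",
                                      train_pairs = sp$sets$train,
                                      params = params))
  p <- suppressWarnings(predict(sc, sp$sets$test))
  expect_true(all(p >= 0 & p <= 1))
  # a pair already linked in the training graph is scored like any candidate
  linked <- sp$train_graph$edges[1, c("u", "v")]
  expect_length(suppressWarnings(predict(sc, linked)), 1L)
  sc_aa <- train_scorer(sp$train_graph, "AA", train_pairs = sp$sets$train,
                        calibrate = TRUE)
  p_aa <- predict(sc_aa, sp$sets$test)
  expect_true(all(p_aa >= 0 & p_aa <= 1))
  expect_error(predict(sc_aa, data.frame(u = "nope", v = "C0001")), "outside")
  expect_error(train_scorer(g, "bogus"), "unknown algorithm")
})
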