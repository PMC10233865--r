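test_that("tanimoto matches set arithmetic and is symmetric in [0,1]", {
  expect_equal(tanimoto(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0.0)
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_error(tanimoto(integer(0), integer(0)), "undefined")
  set.seed(41)
  for (i in 1:25) {
    a <- sample.int(64, sample(1:20, 1))
    b <- sample.int(64, sample(1:20, 1))
    t1 <- tanimoto(a, b)
    expect_identical(t1, tanimoto(b, a))
    expect_gte(t1, 0); expect_lte(t1, 1)
    expect_identical(t1 == 1, setequal(a, b))
  }
})

test_that("CCC layer matches a brute-force pairwise scan", {
  # three identical fingerprints form a triangle; dissimilar ones connect nothing
  fps3 <- list(a = c(1, 5, 9), b = c(1, 5, 9), c = c(1, 5, 9))
  expect_equal(nrow(build_ccc_layer(fps3)), 3L)
  fps_far <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(20, 21, 22))
  expect_equal(nrow(build_ccc_layer(fps_far)), 0L)

  set.seed(7)
  fps <- lapply(1:20, function(i) sample.int(64, sample(5:30, 1)))
  names(fps) <- sprintf("c%02d", 1:20)
  got <- build_ccc_layer(fps, threshold = 0.6)
  want <- list()
  for (i in 1:19) for (j in (i + 1):20) {
    s <- tanimoto(fps[[i]], fps[[j]])
    if (s >= 0.6) want[[length(want) + 1]] <- c(names(fps)[i], names(fps)[j], s)
  }
  expect_equal(nrow(got), length(want))
  if (length(want)) {
    wk <- sort(sapply(want, function(w) paste(sort(w[1:2]), collapse = "|")))
    expect_equal(sort(paste(got$u, got$v, sep = "|")), wk)
  }
  # lowering the threshold never removes an edge
  low <- build_ccc_layer(fps, threshold = 0.3)
  expect_true(all(paste(got$u, got$v) %in% paste(low$u, low$v)))
})

test_that("PPI layer keeps the inclusive 0.9 cut and drops self/duplicate pairs", {
  pairs <- data.frame(u = c("A", "B", "A", "B", "A"),
                      v = c("B", "C", "A", "A", "B"),
                      score = c(0.95, 0.2, 0.99, 0.9, 0.91))
  got <- build_ppi_layer(pairs)
  expect_equal(nrow(got), 1L)
  expect_equal(got$u, "A"); expect_equal(got$v, "B")
  expect_equal(got$score, 0.95)     # symmetric duplicate keeps the max
  expect_equal(nrow(build_ppi_layer(data.frame(u = "A", v = "B", score = 0.9))), 1L)
  expect_equal(nrow(build_ppi_layer(data.frame(u = "A", v = "A", score = 0.99))), 0L)
  meta <- node_meta(c("A", "B", "X"), c("target", "target", "chemical"),
                    rep("drug", 3))
  expect_error(build_ppi_layer(data.frame(u = "A", v = "X", score = 0.95),
                               meta = meta), "not a target")
  # monotonicity in the threshold
  set.seed(11)
  rnd <- data.frame(u = sprintf("P%d", sample(40, 200, TRUE)),
                    v = sprintf("P%d", sample(40, 200, TRUE)),
                    score = runif(200))
  hi <- build_ppi_layer(rnd, threshold = 0.9)
  lo <- build_ppi_layer(rnd, threshold = 0.5)
  expect_true(all(paste(hi$u, hi$v) %in% paste(lo$u, lo$v)))
})

test_that("CTC layer deduplicates records and enforces roles", {
  rec <- data.frame(chemical_id = c("c1", "c1"), target_id = c("t1", "t1"))
  expect_equal(nrow(build_ctc_layer(rec)), 1L)
  expect_equal(nrow(build_ctc_layer(data.frame(chemical_id = character(),
                                               target_id = character()))), 0L)
  set.seed(3)
  rec <- data.frame(chemical_id = sprintf("c%d", sample(8, 50, TRUE)),
                    target_id = sprintf("t%d", sample(10, 50, TRUE)))
  k <- nrow(unique(rec))
  expect_equal(nrow(build_ctc_layer(rec)), k)
  meta <- node_meta(c("c1", "t1"), c("chemical", "target"), c("DS", "drug"))
  expect_error(build_ctc_layer(data.frame(chemical_id = "t1", target_id = "c1"),
                               meta = meta), "role")
})

test_that("hetgraph enforces layer role-typing and simplicity", {
  meta <- node_meta(c("c1", "c2", "t1"), c("chemical", "chemical", "target"),
                    c("DS", "drug", "drug"))
  ok <- hetgraph(meta, layered_edges(c("c1", "c1", "c1"), c("t1", "c2", "t1"),
                                     c("CTC", "CCC", "CTC")))
  expect_equal(nrow(ok$edges), 2L)   # duplicate CTC edge merged
  expect_error(hetgraph(meta, layered_edges("c1", "c2", "CTC")), "role violation")
  expect_error(hetgraph(meta, layered_edges("c1", "t1", "PPI")), "role violation")
  expect_error(hetgraph(meta, layered_edges("c1", "zz", "CCC")), "not in node table")
  # neighbor function is symmetric
  expect_true("t1" %in% het_neighbors(ok, "c1"))
  expect_true("c1" %in% het_neighbors(ok, "t1"))
})

test_that("assembled datasets count edges as the sum of included layers", {
  for (seed in 1:5) {
    set.seed(seed)
    nc <- sample(5:12, 1); nt <- sample(5:12, 1)
    meta <- node_meta(c(sprintf("c%02d", 1:nc), sprintf("t%02d", 1:nt)),
                      c(rep("chemical", nc), rep("target", nt)),
                      rep("drug", nc + nt))
    ctc <- build_ctc_layer(data.frame(
      chemical_id = sprintf("c%02d", sample(nc, 30, TRUE)),
      target_id = sprintf("t%02d", sample(nt, 30, TRUE))))
    ccc <- layered_edges(sprintf("c%02d", 1:(nc - 1)), sprintf("c%02d", 2:nc), "CCC")
    ppi <- layered_edges(sprintf("t%02d", 1:(nt - 1)), sprintf("t%02d", 2:nt), "PPI")
    g <- assemble_dataset(list(CTC = ctc, CCC = ccc, PPI = ppi), meta)
    s <- het_summary(g)
    expect_equal(s$n_edges, nrow(ctc) + nrow(ccc) + nrow(ppi))
    expect_equal(s$n_edges, sum(s$edges_by_layer))
    expect_equal(s$n_nodes, s$n_chemicals + s$n_targets)
  }
  expect_error(assemble_dataset(list(CCC = layered_edges("a", "b", "CCC")),
                                meta = NULL), "CTC")
})

test_that("group filtering keeps origin-matched chemicals and their targets", {
  meta <- node_meta(c("cDS", "cCX", "cDG", "t1", "t2", "t3"),
                    c("chemical", "chemical", "chemical",
                      "target", "target", "target"),
                    c("DS", "CX", "drug", "DS", "CX", "drug"))
  ctc <- layered_edges(c("cDS", "cCX", "cDG"), c("t1", "t2", "t3"), "CTC")
  ccc <- layered_edges(c("cDS", "cDS"), c("cCX", "cDG"), "CCC")
  g <- assemble_dataset(list(CTC = ctc, CCC = ccc), meta,
                        spec = dataset_spec("DS-drug", c("CTC", "CCC")))
  expect_setequal(g$nodes$node_id, c("cDS", "cDG", "t1", "t3"))
  # the CX chemical and its similarity edge are excluded from DS-drug
  expect_false(any(g$edges$u == "cCX" | g$edges$v == "cCX"))
  full <- assemble_dataset(list(CTC = ctc, CCC = ccc), meta,
                           spec = dataset_spec("DS-CX-drug", c("CTC", "CCC")))
  expect_equal(nrow(full$edges), nrow(ctc) + nrow(ccc))
})

test_that("edge, metadata and fingerprint files round-trip losslessly", {
  dir <- withr::local_tempdir()
  meta <- node_meta(c("c1", "c2", "t1"), c("chemical", "chemical", "target"),
                    c("DS;CX", "drug", "drug"))
  edges <- layered_edges(c("c1", "c1"), c("t1", "c2"), c("CTC", "CCC"),
                         c(NA, 0.75))
  fps <- list(c1 = c(3L, 7L, 11L), c2 = c(2L, 7L))
  write_edges_tsv(edges, file.path(dir, "e.tsv"), header = "seed=5")
  write_node_meta(meta, file.path(dir, "m.tsv"), header = "seed=5")
  write_fingerprints(fps, file.path(dir, "f.tsv"), header = "seed=5")
  expect_equal(read_edges_tsv(file.path(dir, "e.tsv")), edges)
  expect_equal(read_node_meta(file.path(dir, "m.tsv")), meta)
  expect_equal(read_fingerprints(file.path(dir, "f.tsv")), fps)
})
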