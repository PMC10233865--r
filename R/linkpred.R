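# The five link-prediction scorers. Three are neighborhood indices computed
# straight off the training graph (Adamic-Adar, Jaccard, preferential
# attachment); two embed the graph (node2vec biased walks + skip-gram,
# spectral Laplacian eigenvectors) and feed per-edge feature vectors to a
# logistic classifier.

degrees <- function(graph) lengths(graph$adj)

#' Adamic-Adar index
#'
#' Weighted common-neighbor count: each shared neighbor Z contributes
#' `1 / log |N(Z)|`, so rare shared neighbors count more than hubs. Natural
#' logarithm; the base only rescales scores and leaves rankings unchanged.
#'
#' @param graph a `hetgraph`.
#' @param u,v node-id vectors (recycled elementwise).
#' @return numeric vector of non-negative index values.
#' @export
aa_index <- function(graph, u, v) {
  deg <- degrees(graph)
  mapply(function(a, b) {
    z <- intersect(graph$adj[[a]], graph$adj[[b]])
    if (!length(z)) 0 else sum(1 / log(deg[z]))
  }, as.character(u), as.character(v), USE.NAMES = FALSE)
}

#' Jaccard similarity index
#'
#' Shared neighbors over all neighbors, `|N(A) ∩ N(B)| / |N(A) ∪ N(B)|`;
#' 0 by convention when both nodes are isolated.
#'
#' @inheritParams aa_index
#' @return numeric vector in `[0, 1]`.
#' @export
jaccard_index <- function(graph, u, v) {
  mapply(function(a, b) {
    na <- graph$adj[[a]]; nb <- graph$adj[[b]]
    un <- length(union(na, nb))
    if (un == 0L) 0 else length(intersect(na, nb)) / un
  }, as.character(u), as.character(v), USE.NAMES = FALSE)
}

#' Preferential-attachment index
#'
#' Degree product `|N(A)| x |N(B)|`: well-connected nodes are the most
#' likely to gain new links.
#'
#' @inheritParams aa_index
#' @return numeric vector of non-negative index values.
#' @export
pa_index <- function(graph, u, v) {
  deg <- degrees(graph)
  as.numeric(deg[as.character(u)] * deg[as.character(v)])
}

#' node2vec hyperparameters
#'
#' @param p return parameter: weight `1/p` on stepping back to the node the
#'   walk just left (small p keeps walks local).
#' @param q in-out parameter: weight `1/q` on stepping to nodes not adjacent
#'   to the previous node (small q pushes walks outward, DFS-like).
#' @param dims embedding dimension.
#' @param walk_length nodes per walk.
#' @param walks_per_node walks started from every non-isolated node.
#' @param window skip-gram context window.
#' @param epochs passes over the walk corpus.
#' @param negative negative samples per positive context pair.
#' @param alpha initial SGD learning rate (decays linearly).
#' @param seed RNG seed for walks and training.
#' @return list of class `node2vec_params`.
#' @export
node2vec_params <- function(p = 1, q = 1, dims = 128L, walk_length = 80L,
                            walks_per_node = 10L, window = 10L, epochs = 3L,
                            negative = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(p > 0, q > 0, dims >= 1, walk_length >= 1, walks_per_node >= 1,
            window >= 1, epochs >= 1)
  structure(as.list(environment()), class = "node2vec_params")
}

graph_index <- function(graph) {
  ids <- graph$nodes$node_id
  adj0 <- lapply(graph$adj[ids], function(nb) sort(match(nb, ids)) - 1L)
  list(ids = ids, adj0 = unname(adj0))
}

#' Second-order biased random walks over the merged graph
#'
#' Walks start `walks_per_node` times from every non-isolated node and
#' ignore layer labels. The transition from state (t -> v) to a neighbor x
#' of v has unnormalized weight `1/p` if x = t, `1` if x is adjacent to t,
#' and `1/q` otherwise, normalized over N(v). A walk reaching a dead end is
#' recorded shorter.
#'
#' @param graph a `hetgraph`.
#' @param params [node2vec_params()].
#' @return object of class `walk_corpus`: list with `walks` (integer
#'   sequences, 1-based into `node_ids`) and `node_ids`.
#' @export
biased_walks <- function(graph, params = node2vec_params()) {
  if (nrow(graph$nodes) == 0L) stop("empty graph")
  gi <- graph_index(graph)
  starts0 <- which(lengths(gi$adj0) > 0L) - 1L
  walks <- with_local_seed(params$seed,
    rcpp_biased_walks(gi$adj0, starts0, params$walk_length,
                      params$walks_per_node, params$p, params$q))
  structure(list(walks = lapply(walks, function(w) w + 1L),
                 node_ids = gi$ids),
            class = "walk_corpus")
}

#' Exact one-step transition distribution of the biased walk
#'
#' @param graph a `hetgraph`.
#' @param t previous node; @param v current node.
#' @param p,q bias parameters.
#' @return named probability vector over the neighbors of `v`.
#' @export
walk_transition_probs <- function(graph, t, v, p = 1, q = 1) {
  gi <- graph_index(graph)
  pr <- rcpp_transition_probs(gi$adj0, match(t, gi$ids) - 1L,
                              match(v, gi$ids) - 1L, p, q)
  stats::setNames(as.numeric(pr), graph$adj[[v]])
}

#' Write a walk corpus as a word2vec-style text file
#' @param corpus a `walk_corpus`.
#' @param path output path (one space-separated walk per line).
#' @export
write_walks <- function(corpus, path) {
  writeLines(vapply(corpus$walks, function(w)
    paste(corpus$node_ids[w], collapse = " "), ""), path)
  invisible(path)
}

#' Train skip-gram node embeddings over a walk corpus
#'
#' Skip-gram with negative sampling (word2vec-style SGD: shrunk context
#' windows, unigram^0.75 negative table, linearly decaying learning rate),
#' single-threaded and fully seeded, so reruns are bitwise identical.
#'
#' @param corpus a `walk_corpus` from [biased_walks()].
#' @param params [node2vec_params()] (uses `dims`, `window`, `epochs`,
#'   `negative`, `alpha`, `seed`).
#' @return numeric matrix, one row per node appearing in the walks, with
#'   node ids as rownames.
#' @export
train_embeddings <- function(corpus, params = node2vec_params()) {
  if (!length(corpus$walks)) stop("empty walk corpus")
  n <- length(corpus$node_ids)
  if (params$dims >= n) {
    warning("embedding dims >= vocabulary size (", n, ")")
  }
  counts <- tabulate(unlist(corpus$walks), nbins = n)
  walks0 <- lapply(corpus$walks, function(w) w - 1L)
  emb <- with_local_seed(params$seed + 1L,
    rcpp_sgns(walks0, n, as.numeric(counts), params$dims, params$window,
              params$epochs, params$negative, params$alpha))
  rownames(emb) <- corpus$node_ids
  emb[counts > 0L, , drop = FALSE]
}

#' Spectral-embedding parameters
#' @param k number of Laplacian eigenvectors (smallest eigenvalues) to keep.
#' @param seed RNG seed for the downstream classifier.
#' @return list of class `spectral_params`.
#' @export
spectral_params <- function(k = 16L, seed = 1L) {
  stopifnot(k >= 1)
  structure(list(k = as.integer(k), seed = seed), class = "spectral_params")
}

#' Graph Laplacian matrices
#'
#' `L = D - A` (unnormalized) or the symmetric normalized form
#' `I - D^{-1/2} A D^{-1/2}` (rows/columns of isolated nodes are zero).
#'
#' @param graph a `hetgraph`.
#' @param normalized logical.
#' @return dense symmetric matrix with node-id dimnames.
#' @export
laplacian_matrix <- function(graph, normalized = FALSE) {
  ids <- graph$nodes$node_id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(graph$edges)) {
    ui <- match(graph$edges$u, ids); vi <- match(graph$edges$v, ids)
    A[cbind(ui, vi)] <- 1
    A[cbind(vi, ui)] <- 1
  }
  d <- rowSums(A)
  if (!normalized) return(diag(d, n) - A)
  dm <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(as.numeric(d > 0), n) - (dm * A) * rep(dm, each = n)
}

#' Spectral node embedding from the normalized Laplacian
#'
#' Rows of the k eigenvectors of the symmetric normalized Laplacian with the
#' smallest eigenvalues, ordered by eigenvalue. On a disconnected graph the
#' zero eigenvalue has multiplicity equal to the number of components, which
#' is reported via a message.
#'
#' @param graph a `hetgraph`.
#' @param params [spectral_params()].
#' @return numeric matrix (nodes x k) with node-id rownames and eigenvalues
#'   in `attr(, "eigenvalues")`.
#' @export
spectral_embed <- function(graph, params = spectral_params()) {
  n <- nrow(graph$nodes)
  if (params$k >= n) stop("k must be smaller than the number of nodes")
  L <- laplacian_matrix(graph, normalized = TRUE)
  es <- eigen(L, symmetric = TRUE)
  idx <- seq(n, n - params$k + 1L)    # eigen() sorts decreasing
  emb <- es$vectors[, idx, drop = FALSE]
  rownames(emb) <- graph$nodes$node_id
  vals <- es$values[idx]
  nzero <- sum(abs(es$values) < 1e-8)
  if (nzero > 1L) message(nzero, " near-zero Laplacian eigenvalues (graph has ",
                          nzero, " components among non-isolated structure)")
  attr(emb, "eigenvalues") <- vals
  emb
}

#' Per-edge feature vectors from node embeddings
#'
#' @param emb embedding matrix with node-id rownames.
#' @param pairs `data.frame` with columns `u`, `v`.
#' @param operator binary operator combining the endpoint vectors:
#'   `hadamard` (elementwise product, the default), `average`, `l1`
#'   (elementwise absolute difference) or `l2` (elementwise squared
#'   difference).
#' @return numeric matrix, one row per pair.
#' @export
edge_features <- function(emb, pairs,
                          operator = c("hadamard", "average", "l1", "l2")) {
  operator <- match.arg(operator)
  miss <- setdiff(unique(c(pairs$u, pairs$v)), rownames(emb))
  if (length(miss)) {
    stop("no embedding for node(s): ", paste(utils::head(miss, 5), collapse = ", "))
  }
  a <- emb[pairs$u, , drop = FALSE]
  b <- emb[pairs$v, , drop = FALSE]
  switch(operator,
         hadamard = a * b,
         average = (a + b) / 2,
         l1 = abs(a - b),
         l2 = (a - b)^2)
}

fit_logistic <- function(x, y) {
  x <- cbind(1, x)
  fit <- suppressWarnings(stats::glm.fit(x, y, family = stats::binomial()))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  coefs
}

predict_logistic <- function(coefs, x) {
  as.numeric(stats::plogis(cbind(1, x) %*% coefs))
}

ALGORITHMS <- c("node2vec", "AA", "JS", "PA", "SC")

#' Train a link-prediction scorer
#'
#' For `node2vec` and `SC`, embeds the training graph and fits a logistic
#' classifier on edge features of the labeled training pairs; scores are
#' then probabilities. For `AA`, `JS` and `PA` the training graph itself is
#' the model; scores are raw index values unless `calibrate = TRUE`, which
#' fits a one-feature logistic calibration on the training pairs so the
#' indices can be read as probabilities (needed for the 0.5 prediction-value
#' filter; AUROC/AP are rank-based and unaffected).
#'
#' @param graph the training `hetgraph`.
#' @param algorithm one of `"node2vec"`, `"AA"`, `"JS"`, `"PA"`, `"SC"`.
#' @param train_pairs `data.frame` with `u`, `v`, `label` (1 = edge);
#'   required for classifier-backed algorithms and for calibration.
#' @param params [node2vec_params()] or [spectral_params()] as appropriate.
#' @param operator edge-feature operator for classifier-backed algorithms.
#' @param calibrate logical: calibrate index scorers to probabilities.
#' @return object of class `edge_scorer`.
#' @export
train_scorer <- function(graph, algorithm, train_pairs = NULL, params = NULL,
                         operator = "hadamard", calibrate = FALSE) {
  if (!algorithm %in% ALGORITHMS) {
    stop("unknown algorithm '", algorithm, "'; valid: ",
         paste(ALGORITHMS, collapse = ", "))
  }
  sc <- list(algorithm = algorithm, graph = graph, operator = operator)
  if (algorithm == "node2vec") {
    if (is.null(params)) params <- node2vec_params()
    if (is.null(train_pairs)) stop("node2vec needs labeled train_pairs")
    corpus <- biased_walks(graph, params)
    sc$emb <- train_embeddings(corpus, params)
    feat <- edge_features_safe(sc$emb, train_pairs, operator)
    sc$coefs <- fit_logistic(feat, train_pairs$label)
  } else if (algorithm == "SC") {
    if (is.null(params)) params <- spectral_params()
    if (is.null(train_pairs)) stop("SC needs labeled train_pairs")
    sc$emb <- suppressMessages(spectral_embed(graph, params))
    feat <- edge_features_safe(sc$emb, train_pairs, operator)
    sc$coefs <- fit_logistic(feat, train_pairs$label)
  } else if (calibrate) {
    if (is.null(train_pairs)) stop("calibration needs labeled train_pairs")
    idx <- index_scores(graph, algorithm, train_pairs)
    sc$coefs <- fit_logistic(matrix(idx, ncol = 1), train_pairs$label)
    sc$calibrated <- TRUE
  }
  class(sc) <- "edge_scorer"
  sc
}

index_scores <- function(graph, algorithm, pairs) {
  switch(algorithm,
         AA = aa_index(graph, pairs$u, pairs$v),
         JS = jaccard_index(graph, pairs$u, pairs$v),
         PA = pa_index(graph, pairs$u, pairs$v))
}

# like edge_features() but substitutes zero vectors (with a warning) for
# nodes the embedding never saw, e.g. isolated in the training graph
edge_features_safe <- function(emb, pairs, operator) {
  miss <- setdiff(unique(c(pairs$u, pairs$v)), rownames(emb))
  if (length(miss)) {
    warning(length(miss), " node(s) without embedding scored via zero vectors")
    emb <- rbind(emb, matrix(0, length(miss), ncol(emb),
                             dimnames = list(miss, NULL)))
  }
  edge_features(emb, pairs, operator)
}

#' Score candidate node pairs with a trained scorer
#'
#' Pairs already linked in the training graph are scored like any other
#' candidate. Classifier-backed scorers return probabilities in `[0, 1]`;
#' index scorers return raw (or calibrated) index values.
#'
#' @param object an `edge_scorer`.
#' @param pairs `data.frame` with columns `u`, `v`.
#' @param ... unused.
#' @return numeric score vector aligned with `pairs`.
#' @export
predict.edge_scorer <- function(object, pairs, ...) {
  unknown <- setdiff(unique(c(pairs$u, pairs$v)), object$graph$nodes$node_id)
  if (length(unknown)) {
    stop("pair endpoint(s) outside graph: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (object$algorithm %in% c("node2vec", "SC")) {
    feat <- edge_features_safe(object$emb, pairs, object$operator)
    predict_logistic(object$coefs, feat)
  } else {
    idx <- index_scores(object$graph, object$algorithm, pairs)
    if (isTRUE(object$calibrated)) {
      predict_logistic(object$coefs, matrix(idx, ncol = 1))
    } else idx
  }
}
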